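# Digital phantoms with ground-truth relaxation parameters and smooth
# simulated coil sensitivities. Pixels are indexed column-major over the
# side x side grid ([row = y, col = x]), like the k-space frames.

pixel_coords <- function(side) {
  # centered pixel coordinates, matching the DFT convention (DC at side/2)
  x <- rep(seq_len(side) - 1 - side / 2, each = side)
  y <- rep(seq_len(side) - 1 - side / 2, times = side)
  list(x = x, y = y)
}

ground_truth <- function(side, T1, M0, alpha, labels, label_names) {
  structure(list(side = as.integer(side), T1 = T1, M0 = M0, alpha = alpha,
                 labels = labels, label_names = label_names),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground truth: %dx%d grid, %d compartments (%s)\n", x$side, x$side,
              length(x$label_names), paste(x$label_names, collapse = ", ")))
  invisible(x)
}

rasterize_spec <- function(spec) {
  side <- spec$grid_side
  co <- pixel_coords(side)
  n <- side * side
  T1 <- rep(NA_real_, n); M0 <- rep(0, n); alpha <- rep(NA_real_, n)
  labels <- rep(0L, n)
  for (i in seq_along(spec$compartments)) {
    cm <- spec$compartments[[i]]
    dx <- (co$x - cm$center[1]) / cm$radii[1]
    dy <- (co$y - cm$center[2]) / cm$radii[2]
    inside <- dx * dx + dy * dy <= 1
    T1[inside] <- cm$T1; M0[inside] <- cm$M0; alpha[inside] <- cm$alpha
    labels[inside] <- i
  }
  ground_truth(side, T1, M0, alpha, labels,
               vapply(spec$compartments, `[[`, "", "name"))
}

#' Seven-vial digital phantom
#'
#' Disks arranged on a circle inside a signal-free background, one per T1
#' value. The default T1 list is the gold-standard set of the seven-vial
#' contrast-agent phantom: 208, 573, 998, 1659, 2123, 2560, 2929 ms
#' (vials A--G). All vials have unit equilibrium magnetization and the
#' nominal flip angle.
#'
#' @param grid_side image matrix side (>= 32).
#' @param t1_values 1--9 vial T1 values (ms).
#' @param alpha flip angle assigned to every vial (degrees).
#' @return List with `spec` (a `phantom_spec`) and `truth` (a
#'   `ground_truth` with `T1`, `M0`, `alpha` and compartment `labels`).
#' @export
make_vial_phantom <- function(grid_side = 128,
                              t1_values = c(208, 573, 998, 1659, 2123, 2560, 2929),
                              alpha = 7) {
  if (grid_side < 32) stop_arg("grid_side must be >= 32")
  nv <- length(t1_values)
  if (nv < 1 || nv > 9) stop_arg("between 1 and 9 vials supported")
  if (any(t1_values <= 0)) stop_arg("T1 values must be > 0")
  r <- 0.09 * grid_side
  comps <- if (nv == 1) {
    list(list(name = "A", shape = "disk", center = c(0, 0), radii = c(r, r),
              T1 = t1_values, M0 = 1, alpha = alpha))
  } else {
    ring <- 0.30 * grid_side
    lapply(seq_len(nv), function(i) {
      th <- 2 * pi * (i - 1) / nv - pi / 2
      list(name = LETTERS[i], shape = "disk",
           center = c(ring * cos(th), ring * sin(th)), radii = c(r, r),
           T1 = t1_values[i], M0 = 1, alpha = alpha)
    })
  }
  if (nv > 1) {
    cen <- t(vapply(comps, `[[`, numeric(2), "center"))
    dmin <- min(stats::dist(cen))
    if (dmin <= 2 * r) stop_arg("vials overlap")
  }
  spec <- structure(list(grid_side = as.integer(grid_side), compartments = comps,
                         fov = 200), class = "phantom_spec")
  list(spec = spec, truth = rasterize_spec(spec))
}

#' Brain-like digital phantom (WM / GM / CSF)
#'
#' Elliptical "head" with a grey-matter ribbon around a white-matter
#' interior and two CSF ventricles, using the volunteer-averaged T1 values
#' WM 722 ms, GM 1432 ms, CSF 4350 ms. Relative proton densities 0.77 /
#' 0.86 / 1.0 emulate the tissue signal ordering at 3T.
#'
#' @param grid_side image matrix side (>= 64).
#' @return List with `spec` and `truth` as in [make_vial_phantom()]; labels
#'   1 = WM, 2 = GM, 3 = CSF.
#' @export
make_brain_phantom <- function(grid_side = 128) {
  if (grid_side < 64) stop_arg("grid_side must be >= 64")
  s <- grid_side
  comps <- list(
    # outer ellipse first: interior compartments overwrite it
    list(name = "GM", shape = "ellipse", center = c(0, 0),
         radii = c(0.42 * s, 0.34 * s), T1 = 1432, M0 = 0.86, alpha = 7),
    list(name = "WM", shape = "ellipse", center = c(0, 0),
         radii = c(0.33 * s, 0.26 * s), T1 = 722, M0 = 0.77, alpha = 7),
    list(name = "CSF-L", shape = "ellipse", center = c(-0.09 * s, 0.02 * s),
         radii = c(0.055 * s, 0.13 * s), T1 = 4350, M0 = 1, alpha = 7),
    list(name = "CSF-R", shape = "ellipse", center = c(0.09 * s, 0.02 * s),
         radii = c(0.055 * s, 0.13 * s), T1 = 4350, M0 = 1, alpha = 7))
  spec <- structure(list(grid_side = as.integer(grid_side), compartments = comps,
                         fov = 220), class = "phantom_spec")
  truth <- rasterize_spec(spec)
  # merge the two ventricles into one CSF label: 1 = WM, 2 = GM, 3 = CSF
  lab <- truth$labels
  new <- integer(length(lab))
  new[lab == 2] <- 1L
  new[lab == 1] <- 2L
  new[lab >= 3] <- 3L
  truth$labels <- new
  truth$label_names <- c("WM", "GM", "CSF")
  list(spec = spec, truth = truth)
}

#' Smooth simulated coil sensitivity maps
#'
#' Gaussian magnitude profiles centered around the object (emulating a
#' phased-array head coil) with distinct smooth phase ramps per coil,
#' normalized so the sum-of-squares magnitude is 1 everywhere. With a
#' single coil the map is identically `1 + 0i`.
#'
#' @param grid_side image matrix side.
#' @param n_coils number of receiver coils (>= 1).
#' @param seed RNG seed for the (small) randomized placement jitter;
#'   bit-reproducible for a fixed seed.
#' @return Complex matrix `[grid_side^2 x n_coils]`.
#' @export
simulate_coil_sensitivities <- function(grid_side, n_coils, seed = 1) {
  if (n_coils < 1) stop_arg("n_coils must be >= 1")
  n <- grid_side * grid_side
  if (n_coils == 1) return(matrix(1 + 0i, n, 1))
  co <- pixel_coords(grid_side)
  local_seed(seed, {
    sens <- matrix(0+0i, n, n_coils)
    for (g in seq_len(n_coils)) {
      th <- 2 * pi * (g - 1) / n_coils + runif(1, -0.15, 0.15)
      cx <- 0.55 * grid_side * cos(th)
      cy <- 0.55 * grid_side * sin(th)
      sig <- 0.55 * grid_side * runif(1, 0.95, 1.05)
      mag <- exp(-((co$x - cx)^2 + (co$y - cy)^2) / (2 * sig^2))
      ramp <- (runif(1, -1, 1) * co$x + runif(1, -1, 1) * co$y) * 2 * pi * 0.1 / grid_side
      sens[, g] <- mag * exp(complex(imaginary = ramp + runif(1, -pi, pi)))
    }
    sos <- sqrt(rowSums(Mod(sens)^2))
    sens / sos
  })
}
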