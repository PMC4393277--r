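# Model enforcement: a dictionary of mono-exponential IR-LL curves over a
# (T1, alpha) grid, orthogonal matching pursuit per pixel, and the final
# three-parameter mono-exponential fit that yields T1.

#' Build the (T1, alpha) dictionary of IR-LL relaxation curves
#'
#' For every combination of `t1_grid` and `alphas` the effective relaxation
#' time and steady-state level are computed (with unit equilibrium
#' magnetization) and the inversion-recovery Look-Locker curve
#' [irll_signal()] is sampled at the frame times, then L2-normalized. The
#' defaults reproduce the 740-atom dictionary: 185 uniformly spaced T1
#' values covering 10--5000 ms times flip angles 3, 5, 7, 9 degrees around
#' the nominal 7 degrees.
#'
#' @param t1_grid T1 values (ms); default 185 uniform values in `[10, 5000]`.
#' @param alphas flip angles (degrees), all `< 90`.
#' @param seq a [seq_params()] supplying `TR`.
#' @param frame_times sorted sampling times after inversion (ms).
#' @return An `irll_dictionary`: `atoms` (matrix `n_frames x n_atoms`, unit
#'   columns), `params` (data.frame with `T1`, `alpha`, and the underlying
#'   `T1_star`, `M0_star`), `norms` (pre-normalization scales),
#'   `frame_times`, `gram` (atom Gram matrix, used by the batched pursuit).
#' @examples
#' tr <- golden_angle_trajectory(50, 16, seq_params(n_projections = 50, n_readout = 16))
#' d <- build_dictionary(frame_times = tr$TI)
#' ncol(d$atoms)  # 740
#' @export
build_dictionary <- function(t1_grid = seq(10, 5000, length.out = 185),
                             alphas = c(3, 5, 7, 9),
                             seq = seq_params(), frame_times) {
  if (length(t1_grid) == 0 || length(alphas) == 0) stop_arg("empty parameter grids")
  if (any(alphas >= 90)) stop("flip angles must be < 90 degrees", call. = FALSE)
  if (is.unsorted(frame_times)) stop_arg("frame_times must be sorted")
  pars <- expand.grid(T1 = t1_grid, alpha = alphas, KEEP.OUT.ATTRS = FALSE)
  t1s <- effective_t1(pars$T1, seq$TR, pars$alpha)
  m0s <- t1s / pars$T1                        # M0 = 1
  # atoms[t, a] = M0s[a] - (1 + M0s[a]) * exp(-t / T1s[a])
  E <- exp(-outer(frame_times, 1 / t1s))
  A <- matrix(m0s, length(frame_times), nrow(pars), byrow = TRUE) -
    E * matrix(1 + m0s, length(frame_times), nrow(pars), byrow = TRUE)
  norms <- sqrt(colSums(A * A))
  A <- sweep(A, 2, norms, "/")
  structure(list(atoms = A,
                 params = cbind(pars, T1_star = t1s, M0_star = m0s),
                 norms = norms, frame_times = frame_times,
                 gram = crossprod(A)),
            class = "irll_dictionary")
}

#' @export
print.irll_dictionary <- function(x, ...) {
  cat(sprintf("IR-LL dictionary: %d atoms (%d T1 x %d alpha) at %d frame times\n",
              ncol(x$atoms), length(unique(x$params$T1)),
              length(unique(x$params$alpha)), nrow(x$atoms)))
  invisible(x)
}

#' Orthogonal matching pursuit of one relaxation curve
#'
#' Standard OMP: iteratively select the atom with maximal absolute
#' correlation with the current residual, re-solve the least-squares problem
#' on all selected atoms, and update the residual. Stops after `k_max` atoms
#' or once the residual norm drops below `tol` (relative to the signal
#' norm). Coefficients are unconstrained in sign.
#'
#' @param signal real vector of length `n_frames`.
#' @param dict an `irll_dictionary`.
#' @param k_max maximal number of atoms (default 3).
#' @param tol relative residual tolerance for early stopping (default 1e-6).
#' @return An `omp_result`: `atom_indices`, `coefficients`, `fitted`,
#'   `residual_norm`.
#' @export
omp_fit_curve <- function(signal, dict, k_max = 3, tol = 1e-6) {
  stopifnot(inherits(dict, "irll_dictionary"))
  A <- dict$atoms
  if (length(signal) != nrow(A)) stop_arg("signal length must equal n_frames")
  if (k_max < 1 || k_max > ncol(A)) stop_arg("k_max out of range")
  snorm <- sqrt(sum(signal^2))
  sel <- integer(0); coefs <- numeric(0)
  r <- signal
  if (snorm > 0) {
    for (k in seq_len(k_max)) {
      corr <- crossprod(A, r)
      j <- which.max(abs(corr))
      if (abs(corr[j]) <= 1e-14 * snorm || j %in% sel) break
      sel <- c(sel, j)
      coefs <- qr.solve(A[, sel, drop = FALSE], signal)
      r <- signal - A[, sel, drop = FALSE] %*% coefs
      if (sqrt(sum(r^2)) < tol * snorm) break
    }
  }
  fitted <- if (length(sel)) drop(A[, sel, drop = FALSE] %*% coefs) else rep(0, length(signal))
  structure(list(atom_indices = sel, coefficients = drop(coefs),
                 fitted = fitted, residual_norm = sqrt(sum((signal - fitted)^2))),
            class = "omp_result")
}

#' Enforce the relaxation model on an image series by dictionary pursuit
#'
#' Replaces every pixel's time curve by its `k_max`-atom orthogonal matching
#' pursuit approximation over the dictionary (the model-enforcement step of
#' the iteration). Pixels excluded by `mask` are set to zero.
#'
#' @param images real matrix `[n_pixels x n_frames]` (combined image series).
#' @param dict an `irll_dictionary` sampled at the same frame times.
#' @param k_max atoms per pixel (default 3).
#' @param mask optional logical vector over pixels; `FALSE` pixels are zeroed
#'   (default: fit all pixels).
#' @param tol relative residual early-stop tolerance (default 1e-6).
#' @return Real matrix of fitted curves, same shape as `images`.
#' @export
enforce_model <- function(images, dict, k_max = 3, mask = NULL, tol = 1e-6) {
  stopifnot(inherits(dict, "irll_dictionary"))
  if (ncol(images) != nrow(dict$atoms))
    stop_arg("image frame count must equal dictionary frame count")
  out <- matrix(0, nrow(images), ncol(images))
  rows <- if (is.null(mask)) seq_len(nrow(images)) else which(mask)
  if (length(rows) == 0) return(out)
  X <- t(images[rows, , drop = FALSE])        # n_frames x n_pixels
  F <- omp_batch_cpp(dict$atoms, dict$gram, X, as.integer(k_max), tol)
  out[rows, ] <- t(F)
  out
}

#' Three-parameter mono-exponential IR-LL fit of one curve
#'
#' Nonlinear least squares of \eqn{M(t) = M_0^* - (M_0 + M_0^*) e^{-t/T_1^*}}
#' over \eqn{(T_1^*, M_0^*, M_0)}. The problem is solved by variable
#' projection: for each candidate \eqn{T_1^*} the two magnetization levels
#' enter linearly and are eliminated in closed form, leaving a 1-D
#' minimization over \eqn{T_1^*} in (1, 10000] ms (coarse log-spaced grid
#' followed by local refinement) -- the exact minimizer of the stated
#' three-parameter problem, without initialization sensitivity. A fit is
#' flagged invalid when \eqn{T_1^*} pins to a bound or the recovered
#' \eqn{M_0^*} or \eqn{M_0} is non-positive (e.g. a constant curve).
#'
#' @param curve real vector of samples of the relaxation curve.
#' @param frame_times sampling times (ms), same length; must span the zero
#'   crossing and tail for an accurate fit (>= 4 frames).
#' @param init optional `c(T1_star, M0_star, M0)`; if given, the T1* search
#'   is confined to a bracket around `init[1]`.
#' @param bounds T1* search interval (ms), default `c(1, 10000)`.
#' @return List `T1_star`, `M0_star`, `M0`, `residual` (RMS), `valid`.
#' @examples
#' t <- seq(2.5, 6000, by = 6)
#' y <- irll_signal(t, 1, 0.445, 445)
#' monoexp_fit3(y, t)$T1_star
#' @export
monoexp_fit3 <- function(curve, frame_times, init = NULL, bounds = c(1, 10000)) {
  if (length(curve) != length(frame_times)) stop_arg("length mismatch")
  if (length(curve) < 4) stop_arg("at least 4 frames required")
  invalid <- list(T1_star = NA_real_, M0_star = NA_real_, M0 = NA_real_,
                  residual = NA_real_, valid = FALSE)
  if (!all(is.finite(curve)) || sd(curve) == 0) return(invalid)
  t <- frame_times; x <- curve; m <- length(x)
  Sx <- sum(x); Sxx <- sum(x * x)
  sse_at <- function(logT) {
    e <- exp(-t / exp(logT))
    S1 <- sum(e); S2 <- sum(e * e); Sxe <- sum(x * e)
    det <- m * S2 - S1 * S1
    if (det <= 0) return(list(sse = Inf, a = NA, b = NA))
    a <- (S2 * Sx - S1 * Sxe) / det
    b <- (m * Sxe - S1 * Sx) / det
    list(sse = Sxx - a * Sx - b * Sxe, a = a, b = b)
  }
  if (!is.null(init) && is.finite(init[1]) && init[1] > bounds[1] && init[1] < bounds[2]) {
    lo <- log(max(bounds[1], init[1] / 4)); hi <- log(min(bounds[2], init[1] * 4))
  } else {
    grid <- seq(log(bounds[1]), log(bounds[2]), length.out = 80)
    sses <- vapply(grid, function(g) sse_at(g)$sse, numeric(1))
    j <- which.min(sses)
    lo <- grid[max(1, j - 1)]; hi <- grid[min(length(grid), j + 1)]
  }
  opt <- optimize(function(g) sse_at(g)$sse, c(lo, hi), tol = 1e-10)
  T1s <- exp(opt$minimum)
  fit <- sse_at(opt$minimum)
  M0s <- fit$a
  M0 <- -fit$b - fit$a
  valid <- is.finite(T1s) && is.finite(M0s) && is.finite(M0) &&
    M0s > 0 && M0 > 0 &&
    T1s > bounds[1] * 1.001 && T1s < bounds[2] * 0.999
  list(T1_star = T1s, M0_star = M0s, M0 = M0,
       residual = sqrt(max(fit$sse, 0) / m), valid = valid)
}

#' Pixel-wise mono-exponential fit of an image series
#'
#' Batched version of [monoexp_fit3()] (shared C++ variable-projection
#' path): fits every included pixel's time curve and assembles the
#' parameter maps, including the derived T1 map via [t1_map_from_fit()].
#'
#' @param images real matrix `[n_pixels x n_frames]`.
#' @param frame_times sampling times (ms).
#' @param mask optional logical vector; excluded pixels are invalid.
#' @param side grid side for map orientation bookkeeping (optional).
#' @param bounds T1* search interval (ms).
#' @return A `parameter_maps` object (see [parameter_maps()]).
#' @export
monoexp_fit_map <- function(images, frame_times, mask = NULL, side = NULL,
                            bounds = c(1, 10000)) {
  n_pix <- nrow(images)
  rows <- if (is.null(mask)) seq_len(n_pix) else which(mask)
  X <- t(images[rows, , drop = FALSE])
  grid <- exp(seq(log(bounds[1]), log(bounds[2]), length.out = 120))
  fit <- monoexp_varpro_cpp(X, frame_times, grid, bounds[1], bounds[2], 60L)
  T1_star <- M0_star <- M0 <- resid <- rep(NA_real_, n_pix)
  T1_star[rows] <- fit$T1_star
  M0_star[rows] <- fit$M0_star
  M0[rows] <- fit$M0
  resid[rows] <- fit$residual
  valid <- rep(FALSE, n_pix)
  valid[rows] <- is.finite(fit$T1_star) & is.finite(fit$M0_star) &
    fit$M0_star > 0 & fit$M0 > 0 &
    fit$T1_star > bounds[1] * 1.001 & fit$T1_star < bounds[2] * 0.999
  maps <- parameter_maps(T1_star = T1_star, M0_star = M0_star, M0 = M0,
                         valid = valid, residual = resid, side = side)
  t1_map_from_fit(maps)
}

#' Per-pixel parameter maps
#'
#' Container for the fitted maps: `T1_star`, `M0_star`, `M0`, derived `T1`
#' (ms), a `valid` flag and the fit RMS `residual`, stored as vectors over
#' pixels (column-major over the `side x side` grid when `side` is set).
#'
#' @param T1_star,M0_star,M0 fitted parameter vectors.
#' @param T1 derived T1 (filled by [t1_map_from_fit()] if `NULL`).
#' @param valid logical vector of per-pixel fit validity.
#' @param residual per-pixel fit RMS.
#' @param side optional grid side.
#' @return An object of class `parameter_maps`.
#' @export
parameter_maps <- function(T1_star, M0_star, M0, T1 = NULL, valid = NULL,
                           residual = NULL, side = NULL) {
  n <- length(T1_star)
  if (is.null(valid)) valid <- rep(TRUE, n)
  structure(list(T1_star = T1_star, M0_star = M0_star, M0 = M0, T1 = T1,
                 valid = valid, residual = residual,
                 side = if (is.null(side)) as.integer(round(sqrt(n))) else as.integer(side)),
            class = "parameter_maps")
}

#' @export
print.parameter_maps <- function(x, ...) {
  cat(sprintf("parameter maps: %d pixels (%d valid)", length(x$T1_star), sum(x$valid)))
  if (!is.null(x$T1))
    cat(sprintf(", T1 median %.0f ms", stats::median(x$T1[x$valid], na.rm = TRUE)))
  cat("\n")
  invisible(x)
}

#' Derive the T1 map from the fitted Look-Locker parameters
#'
#' Applies [true_t1_from_fit()] pixel-wise: `T1 = T1_star * M0 / M0_star`
#' wherever the fit is valid; invalid pixels propagate as `NA`.
#'
#' @param maps a `parameter_maps` object with `T1_star`, `M0_star`, `M0`.
#' @return The same object with the `T1` field filled.
#' @export
t1_map_from_fit <- function(maps) {
  stopifnot(inherits(maps, "parameter_maps"))
  T1 <- rep(NA_real_, length(maps$T1_star))
  ok <- maps$valid & is.finite(maps$T1_star) & is.finite(maps$M0_star) &
    maps$M0_star > 0
  T1[ok] <- maps$T1_star[ok] * maps$M0[ok] / maps$M0_star[ok]
  ok[ok] <- is.finite(T1[ok]) & T1[ok] > 0
  T1[!ok] <- NA_real_
  maps$valid <- ok
  maps$T1 <- T1
  maps
}
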