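# Per-projection gridding, the centered unitary DFT contract, temporal
# interpolation of the initial estimates, and the data-consistency
# projection. The Cartesian k-space frames of one acquisition are held in a
# `cartesian_series`:
#   side        grid side (= n_readout)
#   n_frames    one frame per projection (single-inversion) or per readout
#               slot (segmented reference)
#   frame_times inversion time of each frame (ms)
#   samp        acquired cells: parallel vectors cell (1-based linear index
#               into the side x side grid, column-major [ky, kx]), frame, and
#               hits (number of radial samples averaged into the cell)
#   acquired    complex matrix [n_samp x n_coils] of collision-averaged values
#   kspace      list over coils of complex [side^2 x n_frames] matrices

cartesian_series <- function(side, n_frames, frame_times, samp, acquired, kspace) {
  structure(list(side = as.integer(side), n_frames = as.integer(n_frames),
                 n_coils = length(kspace), frame_times = frame_times,
                 samp = samp, acquired = acquired, kspace = kspace),
            class = "cartesian_series")
}

#' @export
print.cartesian_series <- function(x, ...) {
  cat(sprintf("Cartesian k-space series: %d coil(s), %d frames on a %dx%d grid, %d acquired cells\n",
              x$n_coils, x$n_frames, x$side, x$side, length(x$samp$cell)))
  invisible(x)
}

# Round to nearest integer cell, ties toward -Inf (deterministic).
round_half_down <- function(x) ceiling(x - 0.5)

# Nearest-cell coordinates of radial samples: one sample owns exactly one
# cell, the property the data-consistency substitution relies on (the
# stand-in for GRAPPA-operator gridding).
gridder_nearest_cell <- function(kx, ky) {
  list(rx = round_half_down(kx), ry = round_half_down(ky))
}

resolve_gridder <- function(gridder) {
  if (is.function(gridder)) return(gridder)
  if (identical(gridder, "nearest_cell")) return(gridder_nearest_cell)
  stop(sprintf("unknown gridder '%s' (configuration error)", gridder), call. = FALSE)
}

# Internal: grid a set of projections (samples [coil, proj, readout]) onto
# frames given by `frame_of` (integer per projection). Returns the sparse
# representation shared by all downstream steps.
#
# nearest_cell: each sample owns exactly one cell (weight 1); collisions
# within a frame are averaged. kernel: each sample spreads over its four
# neighboring cells with bilinear weights and cell values are
# weight-normalized -- a better interpolant of the underlying k-space for
# densely sampled frames, at the cost of the one-sample-one-cell property.
grid_projections <- function(samples, angles, offsets, side, frame_of, gridder) {
  n_proj <- length(angles)
  m <- length(offsets)
  th <- angles * pi / 180
  kx <- outer(offsets, cos(th))            # m x n_proj, cell units
  ky <- outer(offsets, sin(th))
  frame <- matrix(frame_of, m, n_proj, byrow = TRUE)
  if (is.function(gridder) || identical(gridder, "nearest_cell")) {
    gfun <- resolve_gridder(gridder)
    rc <- gfun(kx, ky)
    rx <- rc$rx; ry <- rc$ry
    w <- rep(1, length(rx))
    samp_of <- seq_along(rx)
  } else if (identical(gridder, "kernel")) {
    x0 <- floor(kx); y0 <- floor(ky)
    wx <- kx - x0; wy <- ky - y0
    rx <- c(x0, x0 + 1, x0, x0 + 1)
    ry <- c(y0, y0, y0 + 1, y0 + 1)
    w <- c((1 - wx) * (1 - wy), wx * (1 - wy), (1 - wx) * wy, wx * wy)
    samp_of <- rep(seq_len(m * n_proj), 4)
    frame <- rep(frame, 4)
  } else {
    resolve_gridder(gridder)               # raises the configuration error
  }
  keep <- rx >= -side / 2 & rx <= side / 2 - 1 &
          ry >= -side / 2 & ry <= side / 2 - 1 & w > 0
  cell <- (rx + side / 2) * side + (ry + side / 2) + 1  # 1-based linear
  cell <- cell[keep]; frame <- frame[keep]; w <- w[keep]
  samp_of <- samp_of[keep]
  key <- (frame - 1) * (side * side) + cell
  ukey <- sort(unique(key))
  grp <- match(key, ukey)
  wsum <- as.vector(rowsum(w, grp, reorder = TRUE))
  n_coils <- dim(samples)[1]
  acquired <- matrix(0+0i, length(ukey), n_coils)
  for (g in seq_len(n_coils)) {
    v <- t(samples[g, , , drop = TRUE])      # m x n_proj (readout x proj)
    if (n_proj == 1) v <- matrix(samples[g, 1, ], m, 1)
    v <- v[samp_of] * w
    sre <- rowsum(Re(v), grp, reorder = TRUE)
    sim <- rowsum(Im(v), grp, reorder = TRUE)
    acquired[, g] <- complex(real = sre / wsum, imaginary = sim / wsum)
  }
  list(cell = ((ukey - 1) %% (side * side)) + 1,
       frame = ((ukey - 1) %/% (side * side)) + 1,
       hits = wsum, acquired = acquired)
}

# Internal: raw per-sample geometry for the model-shift consistency mode.
# For every in-grid sample: its owner (nearest) cell, frame, readout index
# and measured values.
raw_sample_info <- function(samples, angles, offsets, side, frame_of) {
  n_proj <- length(angles)
  m <- length(offsets)
  th <- angles * pi / 180
  kx <- outer(offsets, cos(th))
  ky <- outer(offsets, sin(th))
  rx <- round_half_down(kx); ry <- round_half_down(ky)
  keep <- rx >= -side / 2 & rx <= side / 2 - 1 &
          ry >= -side / 2 & ry <= side / 2 - 1
  frame <- matrix(frame_of, m, n_proj, byrow = TRUE)[keep]
  cell <- ((rx + side / 2) * side + (ry + side / 2) + 1)[keep]
  readout <- matrix(seq_len(m), m, n_proj)[keep]
  n_coils <- dim(samples)[1]
  vals <- matrix(0+0i, sum(keep), n_coils)
  for (g in seq_len(n_coils)) {
    v <- t(samples[g, , , drop = TRUE])
    if (n_proj == 1) v <- matrix(samples[g, 1, ], m, 1)
    vals[, g] <- v[keep]
  }
  list(cell = cell, frame = frame, readout = readout, values = vals,
       kx = kx[keep], ky = ky[keep])
}

#' Grid each radial projection onto its own Cartesian k-space frame
#'
#' Every projection populates only the frame matching its inversion time;
#' with the default nearest-cell gridder each radial sample lands in exactly
#' one Cartesian cell (collisions within a frame are averaged), so the
#' acquired cells remain identifiable for the data-consistency substitution.
#'
#' @param acq a [radial_acquisition()]. For the single-inversion experiment
#'   each projection becomes one frame; for segmented acquisitions see
#'   [segmented_irll_reference()].
#' @param grid_side Cartesian grid side; defaults to `n_readout`.
#' @param gridder `"nearest_cell"` (default) or a function
#'   `function(kx, ky)` returning integer cell coordinates `list(rx, ry)`;
#'   an unknown name raises a configuration error.
#' @return A `cartesian_series` whose k-spaces contain the gridded samples
#'   (zero elsewhere) and whose `samp`/`acquired` fields record the
#'   populated cells for later consistency projections.
#' @export
grid_radial_frames <- function(acq, grid_side = NULL, gridder = "nearest_cell") {
  stopifnot(inherits(acq, "radial_acquisition"))
  tr <- acq$trajectory
  side <- if (is.null(grid_side)) tr$n_readout else as.integer(grid_side)
  if (side %% 2 != 0) stop_arg("grid_side must be even")
  n_frames <- length(tr$angles)
  sp <- grid_projections(acq$samples, tr$angles, tr$readout_offsets, side,
                         frame_of = seq_len(n_frames), gridder = gridder)
  n_coils <- dim(acq$samples)[1]
  kspace <- vector("list", n_coils)
  idx <- cbind(sp$cell, sp$frame)
  for (g in seq_len(n_coils)) {
    K <- matrix(0+0i, side * side, n_frames)
    K[idx] <- sp$acquired[, g]
    kspace[[g]] <- K
  }
  out <- cartesian_series(side, n_frames, tr$TI,
                          samp = list(cell = sp$cell, frame = sp$frame,
                                      hits = sp$hits),
                          acquired = sp$acquired, kspace = kspace)
  # raw per-sample geometry for the model-shift consistency mode (only
  # meaningful for the one-sample-one-cell gridder)
  if (identical(gridder, "nearest_cell")) {
    raw <- raw_sample_info(acq$samples, tr$angles, tr$readout_offsets, side,
                           frame_of = seq_len(n_frames))
    raw$grp <- match((raw$frame - 1) * (side * side) + raw$cell,
                     (sp$frame - 1) * (side * side) + sp$cell)
    out$raw <- raw
    out$spoke_angles <- tr$angles
    out$readout_offsets <- tr$readout_offsets
  }
  out
}

#' Centered unitary 2D discrete Fourier transform
#'
#' Norm-preserving DFT with the DC term at the central cell (0-based index
#' `side/2`), the convention used for all image/k-space transforms in the
#' package: `forward` followed by `inverse` is the identity to machine
#' precision and Parseval's identity holds exactly.
#'
#' @param data square complex (or numeric) matrix with even side.
#' @param direction `"forward"` (image to k-space) or `"inverse"`.
#' @return Complex matrix of the same size.
#' @examples
#' d <- matrix(0, 8, 8); d[5, 5] <- 1          # delta at the center
#' Mod(centered_dft2(d, "forward")[1, 1])      # 1/8 everywhere
#' @export
centered_dft2 <- function(data, direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  if (!is.matrix(data) || nrow(data) != ncol(data))
    stop_arg("data must be a square matrix")
  side <- nrow(data)
  if (side %% 2 != 0) stop_arg("side must be even")
  sh <- c((side / 2 + 1):side, 1:(side / 2))   # fftshift = ifftshift (even)
  x <- data[sh, sh]
  y <- stats::fft(x, inverse = (direction == "inverse"))
  y[sh, sh] / side
}

# Batched centered unitary DFT of every frame of every coil, in place on the
# [side^2 x n_frames] matrices (C++ hot path; centered_dft2 is the
# single-frame reference implementation).
dft2_series <- function(kspace_list, side, inverse) {
  lapply(kspace_list, function(K) centered_dft2_stack(K, side, inverse))
}

#' Temporal linear interpolation of the initial k-space estimates
#'
#' The single-projection frames are almost empty, which slows convergence.
#' Improved initial estimates are obtained by linearly interpolating every
#' acquired k-space cell through time: for a cell acquired in two or more
#' frames, intermediate frames get the complex linear interpolant (real and
#' imaginary parts independently) of the acquired values versus frame time;
#' before the first and after the last acquisition the nearest acquired
#' value is held. Cells never acquired stay zero. Masks (the record of
#' acquired cells) are not altered.
#'
#' @param series a `cartesian_series` from [grid_radial_frames()].
#' @return A `cartesian_series` with filled k-spaces.
#' @export
temporal_interp_init <- function(series) {
  stopifnot(inherits(series, "cartesian_series"))
  if (length(series$samp$cell) == 0) stop_arg("series has no acquired samples")
  ft <- series$frame_times
  groups <- split(seq_along(series$samp$cell), series$samp$cell)
  cells <- as.integer(names(groups))
  out <- series
  for (g in seq_len(series$n_coils)) {
    K <- matrix(0+0i, series$side^2, series$n_frames)
    vals <- series$acquired[, g]
    for (ci in seq_along(groups)) {
      ii <- groups[[ci]]
      v <- vals[ii]
      if (length(ii) == 1L) {
        K[cells[ci], ] <- v
      } else {
        tt <- ft[series$samp$frame[ii]]
        K[cells[ci], ] <- complex(
          real = approx(tt, Re(v), xout = ft, rule = 2, ties = mean)$y,
          imaginary = approx(tt, Im(v), xout = ft, rule = 2, ties = mean)$y)
      }
    }
    out$kspace[[g]] <- K
  }
  out
}

#' k-space data-consistency projection
#'
#' Replaces the model k-space values by the measured (gridded) values on
#' every acquired cell of every frame; unacquired cells pass through
#' unchanged. This is an orthogonal projection: idempotent and bit-exact on
#' the masked cells.
#'
#' @param model a `cartesian_series` holding the current model k-spaces.
#' @param measured the `cartesian_series` holding the acquired data; must
#'   share grid geometry, frames and masks with `model`.
#' @return `model` with the acquired cells overwritten.
#' @export
data_consistency <- function(model, measured) {
  stopifnot(inherits(model, "cartesian_series"),
            inherits(measured, "cartesian_series"))
  if (model$side != measured$side || model$n_frames != measured$n_frames ||
      model$n_coils != measured$n_coils ||
      length(model$samp$cell) != length(measured$samp$cell) ||
      any(model$samp$cell != measured$samp$cell) ||
      any(model$samp$frame != measured$samp$frame))
    stop_arg("model and measured series have mismatched geometry or masks")
  idx <- cbind(measured$samp$cell, measured$samp$frame)
  for (g in seq_len(model$n_coils))
    model$kspace[[g]][idx] <- measured$acquired[, g]
  model
}

#' Model-assisted shifted data-consistency projection
#'
#' Like [data_consistency()], every acquired sample updates exactly its own
#' (nearest) k-space cell, but the substituted value is corrected for the
#' sub-cell displacement between the cell center and the true spoke
#' position of the sample:
#' \deqn{K(c) \leftarrow s + [K_{model}(c) - K_{model}(p)]}
#' where \eqn{p} is the true sample position and \eqn{K_{model}(p)} is the
#' model k-space evaluated exactly at \eqn{p} -- a support-restricted
#' nonuniform DFT of the model images, cheap because the model is zero
#' outside the object. At the fixed point the model satisfies
#' \eqn{K_{model}(p) = s}: consistency holds at the true spoke positions,
#' which removes the sub-cell displacement error of plain nearest-cell
#' substitution -- the role the calibrated shift operators of
#' GRAPPA-operator gridding play for measured multi-coil data. Collisions
#' (several samples owning one cell) are averaged.
#'
#' @param model a `cartesian_series` with the current model k-spaces.
#' @param measured the measured series from [grid_radial_frames()] with the
#'   default `nearest_cell` gridder (which records the raw sample
#'   geometry); one projection per frame.
#' @param model_images list over coils of complex model image matrices
#'   `[n_pixels x n_frames]` (the images whose forward DFTs are
#'   `model$kspace`); may be restricted to a pixel subset given by `rows`.
#' @param rows integer vector of pixel indices when `model_images` rows are
#'   a subset of the grid (default: all pixels).
#' @param angles per-frame spoke angles (degrees); defaults to the
#'   trajectory angles stored with `measured`.
#' @return `model` with the acquired cells updated.
#' @seealso [data_consistency()] for the exact-substitution contract.
#' @export
data_consistency_shifted <- function(model, measured, model_images,
                                     rows = NULL, angles = NULL) {
  stopifnot(inherits(model, "cartesian_series"),
            inherits(measured, "cartesian_series"))
  raw <- measured$raw
  if (is.null(raw))
    stop_arg("measured series carries no raw sample geometry (use gridder = 'nearest_cell')")
  if (model$side != measured$side || model$n_frames != measured$n_frames ||
      model$n_coils != measured$n_coils)
    stop_arg("model and measured series have mismatched geometry")
  side <- model$side
  if (is.null(angles)) angles <- measured$spoke_angles
  if (is.null(angles)) stop_arg("per-frame spoke angles required")
  co <- pixel_coords(side)
  if (is.null(rows)) rows <- seq_len(side * side)
  side2 <- side * side
  own <- (raw$frame - 1) * side2 + raw$cell
  at <- cbind(raw$readout, raw$frame)
  idx <- cbind(measured$samp$cell, measured$samp$frame)
  cnt <- tabulate(raw$grp, nbins = length(measured$samp$cell))
  offsets <- as.numeric(measured$readout_offsets)
  spoke_vals_all <- nudft_model_spokes_cpp(model_images,
                                           co$x[rows], co$y[rows], side,
                                           angles * pi / 180, offsets)
  for (g in seq_len(model$n_coils)) {
    spoke_vals <- spoke_vals_all[[g]]
    K <- model$kspace[[g]]
    val <- raw$values[, g] + K[own] - spoke_vals[at]
    sre <- rowsum(Re(val), raw$grp, reorder = TRUE)
    sim <- rowsum(Im(val), raw$grp, reorder = TRUE)
    model$kspace[[g]][idx] <- complex(real = sre / cnt, imaginary = sim / cnt)
  }
  model
}

# Internal: density-compensated adjoint nonuniform FFT image formation for
# (near) fully sampled radial frames: per-spoke Voronoi angular weights
# times a radial ramp, Kaiser-Bessel spreading onto a 2x oversampled grid,
# inverse FFT, deapodization, FOV crop. Used by the segmented reference,
# where no data-consistency step needs cell ownership.
adjoint_nufft_images <- function(samples, angles, offsets, side, frame_of,
                                 os = 2L, width = 4, n_frames = max(frame_of)) {
  beta <- pi * sqrt((width / os * (os - 0.5))^2 - 0.8)
  big <- os * side
  m <- length(offsets)
  n_proj <- length(angles)
  # per-spoke angular Voronoi weights within each frame (spokes mod 180)
  dtheta <- numeric(n_proj)
  amod <- (angles %% 180) * pi / 180
  for (f in unique(frame_of)) {
    ii <- which(frame_of == f)
    o <- order(amod[ii])
    a <- amod[ii][o]
    gaps <- diff(c(a, a[1] + pi))
    half <- (c(gaps[length(gaps)], gaps[-length(gaps)]) + gaps) / 2
    dtheta[ii[o]] <- half
  }
  w <- outer(abs(offsets), dtheta)
  w[offsets == 0, ] <- matrix(0.25 * dtheta, sum(offsets == 0), n_proj,
                              byrow = TRUE)
  th <- angles * pi / 180
  kx <- outer(offsets, cos(th)) * os        # oversampled-grid units
  ky <- outer(offsets, sin(th)) * os
  fr <- matrix(frame_of, m, n_proj, byrow = TRUE)
  hw <- width / 2                            # kernel half-width (os cells)
  kb <- function(d) {                        # Kaiser-Bessel, radius hw
    z <- 1 - (d / hw)^2
    ifelse(z > 0, besselI(beta * sqrt(pmax(z, 0)), 0), 0)
  }
  n_coils <- dim(samples)[1]
  sv <- vector("list", n_coils)
  for (g in seq_len(n_coils)) {
    v <- t(samples[g, , , drop = TRUE])
    if (n_proj == 1) v <- matrix(samples[g, 1, ], m, 1)
    sv[[g]] <- v * w
  }
  Ks <- lapply(seq_len(n_coils), function(g) matrix(0+0i, big * big, n_frames))
  x0 <- floor(kx); y0 <- floor(ky)
  for (dx in (1 - hw):hw) for (dy in (1 - hw):hw) {
    xx <- x0 + dx; yy <- y0 + dy
    ww <- kb(xx - kx) * kb(yy - ky)
    keep <- xx >= -big / 2 & xx <= big / 2 - 1 &
            yy >= -big / 2 & yy <= big / 2 - 1 & ww > 0
    if (!any(keep)) next
    key <- (fr[keep] - 1) * (big * big) +
           (xx[keep] + big / 2) * big + (yy[keep] + big / 2) + 1
    for (g in seq_len(n_coils)) {
      v <- (sv[[g]] * ww)[keep]
      sre <- rowsum(Re(v), key, reorder = TRUE)
      sim <- rowsum(Im(v), key, reorder = TRUE)
      uk <- as.numeric(rownames(sre))
      Ks[[g]][uk] <- Ks[[g]][uk] + complex(real = sre, imaginary = sim)
    }
  }
  # deapodization over the cropped FOV
  xpix <- rep(seq_len(side) - 1 - side / 2, each = side)
  ypix <- rep(seq_len(side) - 1 - side / 2, times = side)
  apod1 <- function(xc) {
    u <- pi * width * xc / big
    tt <- beta^2 - u^2
    ifelse(tt > 0, sinh(sqrt(tt)) / sqrt(tt), sin(sqrt(-tt)) / sqrt(pmax(-tt, 1e-12)))
  }
  deap <- apod1(xpix) * apod1(ypix)
  crop <- (ypix + big / 2 + 1) + (xpix + big / 2) * big  # center block
  lapply(seq_len(n_coils), function(g) {
    img <- centered_dft2_stack(Ks[[g]], as.integer(big), TRUE)
    img[crop, , drop = FALSE] / deap
  })
}

# || model - acquired || over masked cells, all coils (diagnostic).
consistency_residual <- function(model, measured) {
  idx <- cbind(measured$samp$cell, measured$samp$frame)
  s <- 0
  for (g in seq_len(model$n_coils))
    s <- s + sum(Mod(model$kspace[[g]][idx] - measured$acquired[, g])^2)
  sqrt(s)
}
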