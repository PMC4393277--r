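# The full model-based reconstruction loop, the segmented fully-sampled
# IR-LL reference, the gold-standard segmented IR fit, and ROI statistics.

#' Reconstruction configuration
#'
#' @param n_iterations fixed iteration count (default 50; no convergence
#'   based early exit, residual logging is diagnostic only).
#' @param k_max dictionary atoms per pixel in the pursuit (default 3).
#' @param gridder gridder passed to [grid_radial_frames()].
#' @param n_tail trailing projections for the phase maps (default 200).
#' @param t1_grid,alphas dictionary grids (defaults: 185 T1 values in
#'   10--5000 ms; flip angles 3, 5, 7, 9 degrees).
#' @param omp_tol relative residual early-stop tolerance of the pursuit.
#' @param fit_bounds T1* search interval of the final fit (ms).
#' @param grid_side Cartesian grid side; default `n_readout`.
#' @param consistency `"model_shift"` (default): every sample updates its
#'   own nearest cell with the measured value corrected for the sub-cell
#'   displacement using the current model
#'   ([data_consistency_shifted()]); `"cell"`: plain bit-exact substitution
#'   of the gridded values ([data_consistency()]).
#' @param mask_background if `TRUE`, pixels whose tail-image magnitude
#'   falls below `mask_threshold` times the maximum are excluded from the
#'   dictionary fit and final fit (their model is zero). Default `FALSE`:
#'   fit all pixels.
#' @param mask_threshold background threshold fraction (default 0.05).
#' @return A `recon_config` list.
#' @export
recon_config <- function(n_iterations = 50, k_max = 3, gridder = "nearest_cell",
                         n_tail = 200, t1_grid = seq(10, 5000, length.out = 185),
                         alphas = c(3, 5, 7, 9), omp_tol = 1e-6,
                         fit_bounds = c(1, 10000), grid_side = NULL,
                         consistency = c("model_shift", "cell"),
                         mask_background = FALSE, mask_threshold = 0.05) {
  if (n_iterations < 1) stop_arg("n_iterations must be >= 1")
  structure(list(n_iterations = as.integer(n_iterations),
                 k_max = as.integer(k_max), gridder = gridder,
                 n_tail = as.integer(n_tail), t1_grid = t1_grid,
                 alphas = alphas, omp_tol = omp_tol, fit_bounds = fit_bounds,
                 grid_side = grid_side,
                 consistency = match.arg(consistency),
                 mask_background = mask_background,
                 mask_threshold = mask_threshold),
            class = "recon_config")
}

#' Model-based reconstruction of a single-inversion radial IR-LL acquisition
#'
#' Implements the full iteration: each projection is gridded onto its own
#' Cartesian k-space frame, the nearly-empty frames are filled by temporal
#' linear interpolation ([temporal_interp_init()]), and per-coil phase maps
#' are estimated once from the acquisition tail. Each of the
#' `cfg$n_iterations` iterations then performs: inverse DFT of the current
#' model k-spaces per coil and frame, rotation to the real axis
#' ([realify()]), sign-dependent sum-of-squares combination, dictionary
#' model enforcement by orthogonal matching pursuit ([enforce_model()]),
#' re-separation into coil models ([reseparate_coils()]), forward DFT, and
#' the data-consistency substitution of the measured samples
#' ([data_consistency()]). After the last iteration a pixel-wise
#' three-parameter mono-exponential fit of the combined consistent images
#' yields T1*, M0* and M0, and the T1 map follows from
#' [true_t1_from_fit()].
#'
#' @param acq a single-segment [radial_acquisition()]; one projection per
#'   frame.
#' @param cfg a [recon_config()].
#' @param verbose print per-iteration residuals.
#' @return List with `maps` (a `parameter_maps` including `T1`), `images`
#'   (the final combined consistent image series, `[n_pixels x n_frames]`),
#'   `residuals` (per-iteration pre-consistency residual on the acquired
#'   cells), `delta` (per-iteration relative RMS change of the combined
#'   images), `phase_maps`, and `dictionary`.
#' @export
irmap_reconstruct <- function(acq, cfg = recon_config(), verbose = FALSE) {
  stopifnot(inherits(acq, "radial_acquisition"))
  if (max(acq$segment_index) != 1)
    stop_arg("irmap_reconstruct expects a single-inversion acquisition")
  if (max(Mod(acq$samples)) == 0) stop_arg("all-zero acquisition")
  side <- if (is.null(cfg$grid_side)) acq$trajectory$n_readout else cfg$grid_side
  measured <- grid_radial_frames(acq, grid_side = side, gridder = cfg$gridder)
  model <- temporal_interp_init(measured)
  phi <- phase_maps_from_tail(acq, n_tail = min(cfg$n_tail, length(acq$trajectory$angles)),
                              grid_side = side)
  dict <- build_dictionary(cfg$t1_grid, cfg$alphas, acq$seq,
                           frame_times = measured$frame_times)
  n_coils <- measured$n_coils
  n_pix <- side * side
  # optional background exclusion from the model fits (tail-image support)
  rows <- seq_len(n_pix)
  if (isTRUE(cfg$mask_background)) {
    tail_mag <- sqrt(Reduce(`+`, lapply(seq_len(n_coils), function(g) {
      sel <- (length(acq$trajectory$angles) - min(cfg$n_tail, length(acq$trajectory$angles)) + 1):length(acq$trajectory$angles)
      sp <- grid_projections(acq$samples[, sel, , drop = FALSE],
                             acq$trajectory$angles[sel],
                             acq$trajectory$readout_offsets, side,
                             frame_of = rep(1L, length(sel)),
                             gridder = "nearest_cell")
      K <- matrix(0+0i, n_pix, 1L)
      K[sp$cell, 1L] <- sp$acquired[, g]
      Mod(centered_dft2(matrix(K, side, side), "inverse"))^2
    })))
    rows <- which(as.vector(tail_mag) >= cfg$mask_threshold * max(tail_mag))
  }
  phi_sub <- phi$phi
  dim(phi_sub) <- c(n_pix, n_coils)
  phi_sub <- phi_sub[rows, , drop = FALSE]
  residuals <- delta <- numeric(cfg$n_iterations)
  combined_prev <- NULL
  for (it in seq_len(cfg$n_iterations)) {
    imgs <- dft2_series(model$kspace, side, inverse = TRUE)
    imgs_sub <- lapply(imgs, function(M) M[rows, , drop = FALSE])
    combined <- sign_dependent_sos(lapply(seq_len(n_coils), function(g)
      Re(imgs_sub[[g]] * exp(complex(imaginary = -phi_sub[, g])))))
    Mfit <- enforce_model(combined, dict, k_max = cfg$k_max, tol = cfg$omp_tol)
    rs <- reseparate_coils(Mfit, imgs_sub)
    for (g in seq_len(n_coils)) {
      cm <- matrix(0+0i, n_pix, model$n_frames)
      cm[rows, ] <- rs$coil_models[[g]]
      model$kspace[[g]] <- centered_dft2_stack(cm, side, FALSE)
    }
    residuals[it] <- consistency_residual(model, measured)
    model <- if (cfg$consistency == "model_shift")
      data_consistency_shifted(model, measured, rs$coil_models, rows = rows)
    else data_consistency(model, measured)
    rs <- NULL
    if (!is.null(combined_prev))
      delta[it] <- sqrt(mean((combined - combined_prev)^2)) /
        sqrt(mean(combined^2))
    else delta[it] <- NA_real_
    combined_prev <- combined
    if (verbose)
      message(sprintf("iteration %3d: residual %.4g, delta %.3g",
                      it, residuals[it], delta[it]))
  }
  imgs <- dft2_series(model$kspace, side, inverse = TRUE)
  final <- matrix(0, n_pix, model$n_frames)
  final[rows, ] <- sign_dependent_sos(lapply(seq_len(n_coils), function(g)
    Re(imgs[[g]][rows, , drop = FALSE] *
         exp(complex(imaginary = -phi_sub[, g])))))
  mask <- rep(FALSE, n_pix); mask[rows] <- TRUE
  maps <- monoexp_fit_map(final, measured$frame_times, side = side,
                          bounds = cfg$fit_bounds,
                          mask = if (isTRUE(cfg$mask_background)) mask else NULL)
  list(maps = maps, images = final, residuals = residuals, delta = delta,
       phase_maps = phi, dictionary = dict, config = cfg,
       fit_mask = mask)
}

#' Fully sampled segmented IR-LL reference reconstruction
#'
#' In the segmented acquisition every inversion segment re-acquires all
#' readout slots with fresh golden-angle spokes; reordering collects, for
#' each readout slot, the spokes of all segments into one (near) fully
#' sampled k-space frame at that inversion time. Each frame is gridded,
#' inverse transformed, the coils are combined phase-sensitively (tail
#' phase maps + sign-dependent sum of squares, restoring the polarity of
#' the recovery), and a pixel-wise three-parameter fit plus the T1 relation
#' yields the reference maps -- no iteration involved.
#'
#' @param acq a segmented [radial_acquisition()] (segment labels required).
#' @param cfg a [recon_config()] (only the fit settings are used).
#' @return A `parameter_maps` object.
#' @export
segmented_irll_reference <- function(acq, cfg = recon_config()) {
  stopifnot(inherits(acq, "radial_acquisition"))
  tr <- acq$trajectory
  if (is.null(tr$within) || is.null(tr$segment))
    stop_arg("per-projection segment labels required")
  side <- if (is.null(cfg$grid_side)) tr$n_readout else cfg$grid_side
  n_frames <- tr$n_projections
  n_seg <- max(tr$segment)
  # Nyquist check on the first frame: populated fraction of the k-space disk
  # under one-cell-per-sample gridding
  sp1 <- grid_projections(acq$samples[, tr$within == 0L, , drop = FALSE],
                          tr$angles[tr$within == 0L], tr$readout_offsets,
                          side, frame_of = rep(1L, sum(tr$within == 0L)),
                          gridder = "nearest_cell")
  co <- pixel_coords(side)
  disk <- which(co$x^2 + co$y^2 <= (side / 2)^2)
  cover <- length(intersect(sp1$cell, disk)) / length(disk)
  if (cover < 0.85)
    warning(sprintf(
      "frames are undersampled (%.0f%% of the k-space disk populated); %d segment(s) is below the Nyquist requirement",
      100 * cover, n_seg), call. = FALSE)
  frame_times <- sort(unique(tr$TI))
  n_coils <- dim(acq$samples)[1]
  imgs <- adjoint_nufft_images(acq$samples, tr$angles, tr$readout_offsets,
                               side, frame_of = tr$within + 1L,
                               n_frames = n_frames)
  # tail phase maps: mean complex image over the last 10% of frames
  tail_frames <- max(1, round(0.1 * n_frames))
  phi <- array(0, c(side, side, n_coils))
  for (g in seq_len(n_coils)) {
    tail_img <- rowMeans(imgs[[g]][, (n_frames - tail_frames + 1):n_frames,
                                   drop = FALSE])
    phi[, , g] <- matrix(Arg(tail_img), side, side)
  }
  combined <- sign_dependent_sos(realify(imgs, phi))
  monoexp_fit_map(combined, frame_times, side = side, bounds = cfg$fit_bounds)
}

#' Gold-standard segmented inversion-recovery fit
#'
#' For an inversion-recovery experiment with a single excitation and
#' readout per inversion there is no Look-Locker drive: the recovery
#' proceeds with the true T1 towards the true M0, so the three-parameter
#' fit of the signal model returns `(T1, M0)` directly in place of
#' `(T1_star, M0_star)`.
#'
#' @param images real matrix `[n_pixels x n_TI]` (or array
#'   `[side, side, n_TI]`) of fully sampled signed images.
#' @param TIs inversion times (ms), >= 4 values.
#' @return A `parameter_maps` object whose `T1` equals the fitted time
#'   constant.
#' @export
gold_standard_ir_fit <- function(images, TIs) {
  if (length(dim(images)) == 3)
    images <- matrix(images, prod(dim(images)[1:2]), dim(images)[3])
  if (length(TIs) < 4) stop_arg("at least 4 inversion times required")
  if (ncol(images) != length(TIs)) stop_arg("image/TI count mismatch")
  maps <- monoexp_fit_map(images, TIs)
  maps$T1 <- ifelse(maps$valid, maps$T1_star, NA_real_)
  maps
}

#' ROI statistics of a parameter map
#'
#' Mean, population standard deviation (1/N) and SNR = mean/std of the T1
#' map over each labeled region, using only valid pixels.
#'
#' @param map a `parameter_maps` object, or a numeric vector of values.
#' @param rois integer label vector/matrix (0 = outside any ROI).
#' @return A data.frame with columns `roi`, `mean_ms`, `std_ms`, `snr`,
#'   `n_pixels`, `flagged` (empty ROI, no valid pixels, or zero spread).
#' @export
roi_statistics <- function(map, rois) {
  vals <- if (inherits(map, "parameter_maps")) ifelse(map$valid, map$T1, NA_real_)
          else as.numeric(map)
  rois <- as.integer(rois)
  if (length(rois) != length(vals)) stop_arg("ROI geometry mismatch")
  labs <- sort(unique(rois[rois > 0]))
  out <- do.call(rbind, lapply(labs, function(L) {
    v <- vals[rois == L]
    n <- length(v)
    v <- v[is.finite(v)]
    if (length(v) == 0)
      return(data.frame(roi = L, mean_ms = NA_real_, std_ms = NA_real_,
                        snr = NA_real_, n_pixels = n, flagged = TRUE))
    mu <- mean(v)
    sig <- sqrt(mean((v - mu)^2))           # population (1/N) std
    data.frame(roi = L, mean_ms = mu, std_ms = sig,
               snr = if (sig > 0) mu / sig else NA_real_,
               n_pixels = n, flagged = (sig == 0))
  }))
  out
}

#' Erode a label map
#'
#' Keeps a pixel only if every pixel within Chebyshev distance `by` carries
#' the same label (out-of-bounds counts as background), shrinking each ROI
#' away from compartment boundaries -- the usual practice when placing ROIs
#' inside phantom vials or tissue regions.
#'
#' @param labels integer matrix (or vector with `side` given).
#' @param by erosion radius in pixels.
#' @param side grid side if `labels` is a vector.
#' @return Integer label object of the same shape.
#' @export
erode_labels <- function(labels, by = 1, side = NULL) {
  was_vec <- is.null(dim(labels))
  if (was_vec) labels <- matrix(labels, side, side)
  s <- nrow(labels)
  out <- labels
  pad <- matrix(0L, s + 2 * by, s + 2 * by)
  pad[by + seq_len(s), by + seq_len(s)] <- labels
  for (dx in -by:by) for (dy in -by:by) {
    if (dx == 0 && dy == 0) next
    sh <- pad[by + dy + seq_len(s), by + dx + seq_len(s)]
    out[sh != labels] <- 0L
  }
  if (was_vec) as.integer(out) else out
}
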