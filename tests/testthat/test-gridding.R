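test_that("centered unitary DFT honors its contract", {
  side <- 8
  d <- matrix(0, side, side); d[side / 2 + 1, side / 2 + 1] <- 1
  K <- centered_dft2(d, "forward")
  expect_equal(Mod(K), matrix(1 / side, side, side))   # flat, 1/side
  set.seed(11)
  x <- matrix(complex(real = rnorm(side^2), imaginary = rnorm(side^2)), side)
  y <- centered_dft2(x, "forward")
  expect_equal(sum(Mod(x)^2), sum(Mod(y)^2), tolerance = 1e-12)  # Parseval
  expect_lt(max(Mod(centered_dft2(y, "inverse") - x)), 1e-12)
  # against the brute-force O(N^4) oracle
  expect_lt(max(Mod(y - dft2_oracle(x))), 1e-10)
  expect_error(centered_dft2(matrix(0, 4, 6)), "square")
})

test_that("batched DFT stack matches the single-frame reference both ways", {
  set.seed(3)
  for (side in c(8L, 12L)) {                # radix-2 path and fallback path
    K <- matrix(complex(real = rnorm(side^2 * 3), imaginary = rnorm(side^2 * 3)),
                side^2, 3)
    for (inv in c(TRUE, FALSE)) {
      S <- irmap:::centered_dft2_stack(K, side, inv)
      ref <- centered_dft2(matrix(K[, 2], side, side),
                           if (inv) "inverse" else "forward")
      expect_lt(max(Mod(matrix(S[, 2], side, side) - ref)), 1e-11)
    }
  }
})

test_that("each projection grids onto its own frame, one cell per sample", {
  sq <- seq_params(n_projections = 1, n_readout = 16)
  tr <- golden_angle_trajectory(1, 16, sq)        # spoke at 0 degrees
  acq <- radial_acquisition(array(1 + 0i, c(1, 1, 16)), tr, sq)
  cs <- grid_radial_frames(acq)
  K <- matrix(cs$kspace[[1]][, 1], 16, 16)
  expect_equal(which(rowSums(Mod(K)) > 0), 9L)    # central row (ky = 0) only
  expect_lte(sum(Mod(K) > 0), 16)                 # <= n_readout cells
  sq2 <- seq_params(n_projections = 20, n_readout = 16)
  tr2 <- golden_angle_trajectory(20, 16, sq2)
  acq2 <- radial_acquisition(array(1 + 0i, c(1, 20, 16)), tr2, sq2)
  cs2 <- grid_radial_frames(acq2)
  pop <- tabulate(cs2$samp$frame, 20)
  expect_true(all(pop <= 16))
  expect_error(grid_radial_frames(acq2, gridder = "whatever"), "gridder")
})

test_that("gridded reconstruction approximates the adjoint NUDFT on smooth images", {
  side <- 16L
  n_proj <- 200                 # dense angular coverage averages collisions
  sq <- seq_params(n_projections = n_proj, n_readout = side)
  tr <- golden_angle_trajectory(n_proj, side, sq)
  # smooth test image: compact Gaussian blob (k-space smooth on the cell
  # scale, so nearest-cell displacement errors stay small)
  x <- rep(seq_len(side) - 1 - side / 2, each = side)
  y <- rep(seq_len(side) - 1 - side / 2, times = side)
  img <- exp(-(x^2 + y^2) / (2 * 1.2^2))
  th <- tr$angles * pi / 180
  kx <- as.vector(outer(tr$readout_offsets, cos(th)))
  ky <- as.vector(outer(tr$readout_offsets, sin(th)))
  s <- nudft_oracle(img, side, kx, ky)
  samples <- array(0i, c(1, n_proj, side))
  samples[1, , ] <- t(matrix(s, side, n_proj))
  acq <- radial_acquisition(samples, tr, sq)
  cs <- grid_radial_frames(acq)
  # collapse all frames into one k-space (as the phase-map path does) and
  # compare to the brute-force adjoint nonuniform DFT
  sp <- irmap:::grid_projections(samples, tr$angles, tr$readout_offsets,
                                 side, rep(1L, n_proj), "nearest_cell")
  K <- matrix(0+0i, side^2, 1); K[sp$cell, 1] <- sp$acquired[, 1]
  rec <- as.vector(centered_dft2(matrix(K, side, side), "inverse"))
  # oracle: brute-force adjoint nonuniform DFT at the true sample positions,
  # with the same collision-averaging weights (1/hits of the owner cell) so
  # that only the sub-cell displacement error separates the two
  raw <- irmap:::raw_sample_info(samples, tr$angles, tr$readout_offsets,
                                 side, rep(1L, n_proj))
  w <- 1 / sp$hits[match(raw$cell, sp$cell)]
  adj <- vapply(seq_len(side^2), function(j)
    sum(w * raw$values[, 1] *
          exp(2i * pi * (raw$kx * x[j] + raw$ky * y[j]) / side)) / side,
    complex(1))
  rec <- rec / sqrt(sum(Mod(rec)^2))
  adj <- adj / sqrt(sum(Mod(adj)^2))
  expect_lt(sqrt(sum(Mod(rec - adj)^2)), 0.15)
})

test_that("gridding + centered DFT passes the adjoint inner-product test", {
  side <- 16L
  n_proj <- 25
  sq <- seq_params(n_projections = n_proj, n_readout = side)
  tr <- golden_angle_trajectory(n_proj, side, sq)
  set.seed(5)
  v <- array(complex(real = rnorm(n_proj * side),
                     imaginary = rnorm(n_proj * side)), c(1, n_proj, side))
  acq <- radial_acquisition(v, tr, sq)
  # A: radial samples -> one combined image (grid with averaging, then
  # inverse DFT); A^H: image -> forward DFT -> read owner cell / hits
  sp <- irmap:::grid_projections(v, tr$angles, tr$readout_offsets, side,
                                 rep(1L, n_proj), "nearest_cell")
  K <- matrix(0+0i, side^2, 1); K[sp$cell, 1] <- sp$acquired[, 1]
  Ax <- centered_dft2(matrix(K, side, side), "inverse")
  set.seed(6)
  yimg <- matrix(complex(real = rnorm(side^2), imaginary = rnorm(side^2)),
                 side, side)
  Yk <- centered_dft2(yimg, "forward")
  raw <- irmap:::raw_sample_info(v, tr$angles, tr$readout_offsets, side,
                                 rep(1L, n_proj))
  grp <- match(raw$cell, sp$cell)            # single frame: cells identify
  hits_of <- sp$hits[grp]
  AHy_samples <- Yk[raw$cell] / hits_of
  lhs <- sum(Ax * Conj(yimg))
  rhs <- sum(raw$values[, 1] * Conj(AHy_samples))
  expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-10)
})

test_that("temporal interpolation fills cells by the stated rules", {
  side <- 8L
  n_frames <- 25L
  ft <- seq(2.5, by = 6, length.out = n_frames)
  samp <- list(cell = c(10L, 10L, 22L, 40L), frame = c(10L, 20L, 5L, 1L),
               hits = rep(1, 4))
  acquired <- matrix(c(1 + 0i, 3 + 0i, 2 - 1i, 5 + 5i), 4, 1)
  ks <- list(matrix(0+0i, side^2, n_frames))
  ks[[1]][cbind(samp$cell, samp$frame)] <- acquired[, 1]
  series <- irmap:::cartesian_series(side, n_frames, ft, samp, acquired, ks)
  out <- temporal_interp_init(series)
  K <- out$kspace[[1]]
  expect_equal(K[10, 15], 2 + 0i)                  # linear between frames
  expect_equal(K[10, 10], 1 + 0i)                  # knots unchanged
  expect_equal(K[10, 20], 3 + 0i)
  expect_equal(K[10, 3], 1 + 0i)                   # held before first
  expect_equal(K[10, 25], 3 + 0i)                  # held after last
  expect_equal(K[22, ], rep(2 - 1i, n_frames))     # single acquisition held
  expect_equal(K[11, ], rep(0 + 0i, n_frames))     # never acquired stays 0
})

test_that("data consistency is an exact idempotent projection", {
  fx <- tiny_vial_acq(side = 16, n_proj = 40)
  measured <- grid_radial_frames(fx$acq)
  model <- measured
  set.seed(8)
  model$kspace[[1]] <- matrix(complex(real = rnorm(16^2 * 40),
                                      imaginary = rnorm(16^2 * 40)), 16^2, 40)
  pre <- model$kspace[[1]]
  out <- data_consistency(model, measured)
  idx <- cbind(measured$samp$cell, measured$samp$frame)
  expect_identical(out$kspace[[1]][idx], measured$acquired[, 1])  # bit-exact
  untouched <- out$kspace[[1]]; untouched[idx] <- pre[idx]
  expect_identical(untouched, pre)                 # unmasked cells unchanged
  out2 <- data_consistency(out, measured)
  expect_identical(out2$kspace[[1]], out$kspace[[1]])  # idempotent
  bad <- measured; bad$samp$cell <- rev(bad$samp$cell)
  expect_error(data_consistency(model, bad), "mismatch")
})

test_that("model-shift consistency leaves an exactly consistent model alone", {
  side <- 16L; n_proj <- 30L
  sq <- seq_params(n_projections = n_proj, n_readout = side)
  tr <- golden_angle_trajectory(n_proj, side, sq)
  set.seed(12)
  x <- rep(seq_len(side) - 1 - side / 2, each = side)
  y <- rep(seq_len(side) - 1 - side / 2, times = side)
  img <- complex(real = exp(-(x^2 + y^2) / 18) * rnorm(side^2, 1, 0.1))
  # static object: every frame's image is the same, samples are its exact
  # nonuniform DFT along the spokes
  S <- irmap:::nudft_spokes_cpp(matrix(img, side^2, 1), side,
                                tr$angles * pi / 180,
                                as.numeric(tr$readout_offsets))
  samples <- array(0+0i, c(1, n_proj, side)); samples[1, , ] <- t(S[, , 1])
  acq <- radial_acquisition(samples, tr, sq)
  measured <- grid_radial_frames(acq)
  model <- measured
  Kimg <- as.vector(centered_dft2(matrix(img, side, side), "forward"))
  model$kspace[[1]] <- matrix(Kimg, side^2, n_proj)
  model_images <- list(matrix(img, side^2, n_proj))
  out <- data_consistency_shifted(model, measured, model_images)
  # the model already satisfies K_model(p) = s, so nothing changes
  expect_lt(max(Mod(out$kspace[[1]] - model$kspace[[1]])), 1e-12)
  # whereas plain substitution moves masked cells by the displacement error
  plain <- data_consistency(model, measured)
  idx <- cbind(measured$samp$cell, measured$samp$frame)
  expect_gt(max(Mod(plain$kspace[[1]][idx] - model$kspace[[1]][idx])), 1e-3)
})
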