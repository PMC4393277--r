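test_that("simulated samples follow the unitary DC convention", {
  side <- 32L
  sq <- seq_params(n_projections = 15, n_readout = side)
  tr <- golden_angle_trajectory(15, side, sq)
  ph <- make_vial_phantom(side)
  acq <- simulate_radial_irll(ph$truth, NULL, tr, sq)
  ok <- ph$truth$M0 > 0
  t1s <- effective_t1(ph$truth$T1[ok], sq$TR, ph$truth$alpha[ok])
  m0s <- ph$truth$M0[ok] * t1s / ph$truth$T1[ok]
  dc0 <- which(tr$readout_offsets == 0)
  for (i in c(1, 8, 15)) {
    img_sum <- sum(irll_signal(tr$TI[i], ph$truth$M0[ok], m0s, t1s))
    expect_equal(Re(acq$samples[1, i, dc0]), img_sum / side, tolerance = 1e-10)
    expect_equal(Im(acq$samples[1, i, dc0]), 0, tolerance = 1e-10)
  }
})

test_that("a single bright center pixel gives flat-magnitude spokes", {
  side <- 16L
  sq <- seq_params(n_projections = 5, n_readout = side)
  tr <- golden_angle_trajectory(5, side, sq)
  truth <- irmap:::ground_truth(side,
    T1 = rep(NA_real_, side^2), M0 = rep(0, side^2),
    alpha = rep(NA_real_, side^2), labels = rep(0L, side^2), label_names = "X")
  ctr <- (side / 2) * side + side / 2 + 1            # pixel at the DC position
  truth$T1[ctr] <- 1000; truth$M0[ctr] <- 1; truth$alpha[ctr] <- 7
  truth$labels[ctr] <- 1L
  acq <- simulate_radial_irll(truth, NULL, tr, sq)
  for (i in 1:5)
    expect_lt(diff(range(Mod(acq$samples[1, i, ]))), 1e-12)
})

test_that("fast FFT mode matches the exact nonuniform DFT oracle", {
  side <- 32L
  sq <- seq_params(n_projections = 50, n_readout = side)
  tr <- golden_angle_trajectory(50, side, sq)
  ph <- make_vial_phantom(side)
  exact <- simulate_radial_irll(ph$truth, NULL, tr, sq, mode = "exact")
  fast <- simulate_radial_irll(ph$truth, NULL, tr, sq, mode = "fft")
  rel <- sqrt(mean(Mod(fast$samples - exact$samples)^2)) /
    sqrt(mean(Mod(exact$samples)^2))
  expect_lt(rel, 0.01)
})

test_that("exact mode agrees with a brute-force R oracle on a tiny grid", {
  side <- 16L
  sq <- seq_params(n_projections = 7, n_readout = side)
  tr <- golden_angle_trajectory(7, side, sq)
  set.seed(31)
  img <- complex(real = rnorm(side^2), imaginary = rnorm(side^2))
  S <- irmap:::nudft_spokes_cpp(matrix(img, side^2, 1), side,
                                tr$angles * pi / 180,
                                as.numeric(tr$readout_offsets))
  th <- tr$angles * pi / 180
  for (i in c(1, 4, 7)) {
    kx <- tr$readout_offsets * cos(th[i])
    ky <- tr$readout_offsets * sin(th[i])
    expect_lt(max(Mod(S[, i, 1] - nudft_oracle(img, side, kx, ky))), 1e-10)
  }
})

test_that("simulation is bit-reproducible under a fixed seed", {
  fx1 <- tiny_vial_acq(side = 16, n_proj = 30, noise_sigma = 0.01, seed = 5)
  fx2 <- tiny_vial_acq(side = 16, n_proj = 30, noise_sigma = 0.01, seed = 5)
  expect_identical(fx1$acq$samples, fx2$acq$samples)
  fx3 <- tiny_vial_acq(side = 16, n_proj = 30, noise_sigma = 0.01, seed = 6)
  expect_false(identical(fx1$acq$samples, fx3$acq$samples))
  # noise must not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(tiny_vial_acq(side = 16, n_proj = 10,
                                        noise_sigma = 0.01, seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("incomplete recovery depresses long-T1 curves in later segments", {
  sq <- seq_params(n_projections = 400, n_readout = 32)
  tr <- golden_angle_trajectory(400, 32, sq, segments = 3)
  ft <- sq$TE + (0:399) * sq$TR
  fit_t1 <- function(T1, inc) {
    f <- irmap:::compartment_curves(T1, 1, 7, tr, sq,
                                    incomplete_recovery = inc, delay = 15000)
    vapply(1:3, function(s) {
      m <- monoexp_fit3(f[tr$segment == s], ft)
      true_t1_from_fit(m$T1_star, m$M0_star, m$M0)
    }, numeric(1))
  }
  csf <- fit_t1(4350, TRUE)
  expect_lt(csf[2], csf[1] * 0.99)                   # visibly depressed
  expect_lt(abs(csf[3] - csf[2]) / csf[2], 0.01)     # then quasi-stationary
  wm <- fit_t1(722, TRUE)
  expect_lt(abs(wm[2] - wm[1]) / wm[1], 0.005)       # WM essentially stable
  none <- fit_t1(4350, FALSE)
  expect_equal(none[1], none[2], tolerance = 1e-8)   # option off: identical
})

test_that("noise calibration hits the requested tail SNR", {
  fx <- tiny_vial_acq(side = 32, n_proj = 200)
  sigma <- noise_sigma_for_tail_snr(fx$acq, target_snr = 30, n_tail = 100)
  expect_gt(sigma, 0)
  # empirical check: measured tail-image SNR within ~25% of the target
  acq <- simulate_radial_irll(fx$phantom$truth, NULL, fx$traj, fx$seq,
                              noise_sigma = sigma, seed = 11)
  sp <- irmap:::grid_projections(acq$samples[, 101:200, , drop = FALSE],
                                 fx$traj$angles[101:200],
                                 fx$traj$readout_offsets, 32L,
                                 rep(1L, 100), "nearest_cell")
  K <- matrix(0+0i, 32^2, 1); K[sp$cell, 1] <- sp$acquired[, 1]
  img <- Mod(centered_dft2(matrix(K, 32, 32), "inverse"))
  spn <- irmap:::grid_projections(fx$acq$samples[, 101:200, , drop = FALSE],
                                  fx$traj$angles[101:200],
                                  fx$traj$readout_offsets, 32L,
                                  rep(1L, 100), "nearest_cell")
  Kn <- matrix(0+0i, 32^2, 1); Kn[spn$cell, 1] <- spn$acquired[, 1]
  clean <- Mod(centered_dft2(matrix(Kn, 32, 32), "inverse"))
  obj <- clean > 0.2 * max(clean)
  snr <- mean(clean[obj]) / sd((img - clean)[obj])
  expect_gt(snr, 30 * 0.75); expect_lt(snr, 30 * 1.35)
})
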