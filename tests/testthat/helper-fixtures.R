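# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the whole suite stays fast.

tiny_seq <- function(n_projections = 50, n_readout = 16, ...) {
  seq_params(n_projections = n_projections, n_readout = n_readout, ...)
}

# A small single-inversion acquisition of the vial phantom. Below the
# supported phantom grid (32) a hand-built three-disk stand-in is used.
tiny_vial_acq <- function(side = 32, n_proj = 300, noise_sigma = 0,
                          seed = NULL, n_coils = 1, t1_values = NULL) {
  sq <- seq_params(n_projections = n_proj, n_readout = side)
  tr <- golden_angle_trajectory(n_proj, side, sq)
  ph <- if (side < 32) {
    r <- 0.12 * side
    spec <- structure(list(
      grid_side = as.integer(side),
      compartments = list(
        list(name = "A", shape = "disk", center = c(-0.22 * side, 0),
             radii = c(r, r), T1 = 300, M0 = 1, alpha = 7),
        list(name = "B", shape = "disk", center = c(0.22 * side, 0.15 * side),
             radii = c(r, r), T1 = 1000, M0 = 1, alpha = 7),
        list(name = "C", shape = "disk", center = c(0.1 * side, -0.25 * side),
             radii = c(r, r), T1 = 2200, M0 = 1, alpha = 7)),
      fov = 200), class = "phantom_spec")
    list(spec = spec, truth = irmap:::rasterize_spec(spec))
  } else if (is.null(t1_values)) make_vial_phantom(side)
  else make_vial_phantom(side, t1_values = t1_values)
  sens <- if (n_coils > 1) simulate_coil_sensitivities(side, n_coils, seed = 7)
          else NULL
  acq <- simulate_radial_irll(ph$truth, sens, tr, sq,
                              noise_sigma = noise_sigma, seed = seed)
  list(acq = acq, phantom = ph, traj = tr, seq = sq, sens = sens)
}

# Brute-force nonuniform DFT oracle (unitary centered convention), O(N^2)
# per sample -- only for tiny grids.
nudft_oracle <- function(img, side, kx, ky) {
  x <- rep(seq_len(side) - 1 - side / 2, each = side)
  y <- rep(seq_len(side) - 1 - side / 2, times = side)
  vapply(seq_along(kx), function(i)
    sum(img * exp(-2i * pi * (kx[i] * x + ky[i] * y) / side)) / side,
    complex(1))
}

# Brute-force O(N^4) centered unitary 2D DFT oracle (rows = y, cols = x,
# DC at 0-based side/2).
dft2_oracle <- function(X, inverse = FALSE) {
  side <- nrow(X)
  idx <- seq_len(side) - 1 - side / 2
  s <- if (inverse) 2i else -2i
  out <- matrix(0+0i, side, side)
  for (r in seq_len(side)) for (c in seq_len(side)) {
    acc <- 0+0i
    for (rr in seq_len(side)) for (cc in seq_len(side))
      acc <- acc + X[rr, cc] *
        exp(s * pi * (idx[r] * idx[rr] + idx[c] * idx[cc]) / side)
    out[r, c] <- acc / side
  }
  out
}

expect_rel_error <- function(x, ref, tol) {
  expect_lt(max(abs(x - ref)) / max(abs(ref)), tol)
}
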