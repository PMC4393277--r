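# Golden-angle trajectory and the raw-acquisition container.

# 180 * 2 / (1 + sqrt(5)) = 180 * (sqrt(5) - 1) / 2 = 111.2461...
GOLDEN_ANGLE_DEG <- 180 * (sqrt(5) - 1) / 2

#' Golden-angle radial trajectory with inversion-time bookkeeping
#'
#' Spoke `i` (0-based global counter) is rotated by `i * 111.2461...` degrees
#' (mod 360), the golden-angle increment `180 * 2 / (1 + sqrt(5))`, giving
#' near-uniform angular coverage over any temporal window. The inversion
#' time of projection `j` within its segment is `TI(j) = ti_offset + j * TR`
#' (0-based `j`), with `ti_offset` defaulting to the echo time. In segmented
#' mode the angle counter advances continuously across segments while the
#' inversion-time clock restarts, so that the spokes collected at a given
#' readout slot differ between segments and jointly fill k-space.
#'
#' @param n_projections projections per inversion segment.
#' @param n_readout readout samples per projection; the readout offsets are
#'   the signed integers `-n_readout/2, ..., n_readout/2 - 1` in units of
#'   k-space cells (DC sample included).
#' @param seq a [seq_params()] object supplying `TR` (and the default
#'   `ti_offset = TE`).
#' @param segments number of inversion segments (default 1).
#' @param ti_offset inversion time of the first projection (ms).
#' @return A `radial_trajectory`: list with `angles` (degrees, one per
#'   projection, all segments concatenated), `readout_offsets`, `TI` (ms,
#'   restarting per segment), `segment` (1-based label) and `within`
#'   (0-based index inside the segment).
#' @examples
#' tr <- golden_angle_trajectory(1000, 128, seq_params())
#' head(tr$angles, 3)  # 0, 111.246..., 222.492...
#' @export
golden_angle_trajectory <- function(n_projections, n_readout, seq = seq_params(),
                                    segments = 1L, ti_offset = seq$TE) {
  if (n_projections < 1) stop_arg("n_projections must be >= 1")
  if (n_readout < 2) stop_arg("n_readout must be >= 2")
  if (n_readout %% 2 != 0) stop_arg("n_readout must be even")
  n_total <- n_projections * segments
  i <- seq_len(n_total) - 1                    # global spoke counter
  within <- (seq_len(n_total) - 1) %% n_projections
  structure(list(
    angles = (i * GOLDEN_ANGLE_DEG) %% 360,
    readout_offsets = seq.int(-n_readout / 2, n_readout / 2 - 1),
    TI = ti_offset + within * seq$TR,
    segment = as.integer(i %/% n_projections + 1),
    within = as.integer(within),
    n_projections = as.integer(n_projections),
    n_readout = as.integer(n_readout)
  ), class = "radial_trajectory")
}

#' @export
print.radial_trajectory <- function(x, ...) {
  cat(sprintf("golden-angle radial trajectory: %d spokes (%d segment(s)) x %d samples, TI %g..%g ms\n",
              length(x$angles), max(x$segment), x$n_readout, min(x$TI), max(x$TI)))
  invisible(x)
}

#' Raw radial IR-LL acquisition container
#'
#' @param samples complex array indexed `[coil, projection, readout]`.
#' @param trajectory a `radial_trajectory` consistent with `samples`.
#' @param seq the [seq_params()] of the acquisition.
#' @return An object of class `radial_acquisition`.
#' @export
radial_acquisition <- function(samples, trajectory, seq) {
  if (length(dim(samples)) != 3)
    stop_arg("samples must be a 3-d array [coil, projection, readout]")
  if (dim(samples)[2] != length(trajectory$angles) ||
      dim(samples)[3] != length(trajectory$readout_offsets))
    stop_arg("sample array dimensions inconsistent with trajectory")
  if (dim(samples)[1] < 1) stop_arg("at least one coil required")
  structure(list(samples = samples, trajectory = trajectory, seq = seq,
                 segment_index = trajectory$segment),
            class = "radial_acquisition")
}

#' @export
print.radial_acquisition <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("radial IR-LL acquisition: %d coil(s), %d projections x %d samples, %d segment(s)\n",
              d[1], d[2], d[3], max(x$segment_index)))
  invisible(x)
}

#' Serialize / load an acquisition
#'
#' Acquisitions are stored as plain R serialization (`.rds`). An HDF5-based
#' container is not provided because no HDF5 bindings are available in the
#' supported environment.
#'
#' @param acq a `radial_acquisition`.
#' @param file path to write / read.
#' @return `read_acquisition` returns the `radial_acquisition`.
#' @export
write_acquisition <- function(acq, file) {
  stopifnot(inherits(acq, "radial_acquisition"))
  saveRDS(acq, file)
  invisible(file)
}

#' @rdname write_acquisition
#' @export
read_acquisition <- function(file) {
  acq <- readRDS(file)
  if (!inherits(acq, "radial_acquisition")) stop_arg("not a radial_acquisition file")
  acq
}
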