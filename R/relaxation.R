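#' Sequence parameters of a radial IR-LL acquisition
#'
#' Bundles the pulse-sequence constants of an inversion-recovery Look-Locker
#' (IR-LL) spoiled gradient-echo acquisition. All times are in milliseconds
#' and angles in degrees, matching the units used throughout the package.
#'
#' @param TR repetition time between consecutive excitations (ms).
#' @param TE echo time (ms); also the inversion time of the first projection
#'   (see [golden_angle_trajectory()]).
#' @param alpha_nominal nominal excitation flip angle (degrees), in (0, 90).
#' @param n_projections number of radial projections per inversion.
#' @param n_readout number of readout samples per projection (grid side).
#' @param inversion_delay recovery gap between repeated inversions (ms).
#' @return An object of class `seq_params`.
#' @examples
#' seq_params()  # the protocol used throughout: TR 6 ms, TE 2.5 ms, 7 deg
#' @export
seq_params <- function(TR = 6, TE = 2.5, alpha_nominal = 7,
                       n_projections = 1000, n_readout = 128,
                       inversion_delay = 15000) {
  if (!is.numeric(TR) || TR <= 0) stop_arg("TR must be > 0")
  if (!is.numeric(TE) || TE < 0) stop_arg("TE must be >= 0")
  if (alpha_nominal <= 0 || alpha_nominal >= 90)
    stop_arg("alpha_nominal must be in (0, 90) degrees")
  if (n_projections < 1) stop_arg("n_projections must be >= 1")
  if (n_readout < 2) stop_arg("n_readout must be >= 2")
  structure(list(TR = TR, TE = TE, alpha_nominal = alpha_nominal,
                 n_projections = as.integer(n_projections),
                 n_readout = as.integer(n_readout),
                 inversion_delay = inversion_delay),
            class = "seq_params")
}

#' @export
print.seq_params <- function(x, ...) {
  cat(sprintf(
    "IR-LL sequence: TR %g ms, TE %g ms, alpha %g deg, %d projections x %d samples\n",
    x$TR, x$TE, x$alpha_nominal, x$n_projections, x$n_readout))
  invisible(x)
}

#' Effective longitudinal relaxation time under continuous excitation
#'
#' During a Look-Locker readout train the repeated low-angle excitations
#' drive the longitudinal magnetization towards a reduced steady state, and
#' the apparent relaxation proceeds with a shortened effective time constant
#' \deqn{T_1^* = [1/T_1 - (1/T_R)\,\ln\cos\alpha]^{-1}.}
#'
#' @param T1 true longitudinal relaxation time (ms), > 0. Vectorized.
#' @param TR repetition time between excitations (ms), > 0.
#' @param alpha flip angle (degrees), in \eqn{[0, 90)}.
#' @return Effective relaxation time \eqn{T_1^*} (ms), always `<= T1`.
#' @seealso [steady_state_magnetization()], [true_t1_from_fit()]
#' @examples
#' effective_t1(1000, TR = 6, alpha = 7)  # about 445 ms
#' @export
effective_t1 <- function(T1, TR, alpha) {
  if (any(T1 <= 0)) stop_arg("T1 must be > 0")
  if (any(TR <= 0)) stop_arg("TR must be > 0")
  if (any(alpha < 0) || any(alpha >= 90))
    stop("flip angle must lie in [0, 90) degrees for cos(alpha) > 0",
         call. = FALSE)
  1 / (1 / T1 - log(cos(alpha * pi / 180)) / TR)
}

#' Steady-state magnetization of the Look-Locker readout train
#'
#' The driven steady state is reduced from the equilibrium magnetization by
#' the same factor that shortens the relaxation time:
#' \eqn{M_0^* = M_0 \, T_1^*/T_1}. The relation assumes `TR < T1_star`
#' (rapid sampling of the recovery); a warning is emitted otherwise because
#' intermediate fitting steps may transiently visit such values.
#'
#' @param M0 equilibrium magnetization (arbitrary units), > 0.
#' @param T1_star effective relaxation time (ms), in (0, T1].
#' @param T1 true relaxation time (ms), > 0.
#' @param TR optional repetition time (ms); if supplied, used only to warn
#'   when `TR >= T1_star`.
#' @return Steady-state magnetization, same units as `M0`, always `<= M0`.
#' @examples
#' steady_state_magnetization(1, effective_t1(1000, 6, 7), 1000)
#' @export
steady_state_magnetization <- function(M0, T1_star, T1, TR = NULL) {
  if (any(M0 <= 0)) stop_arg("M0 must be > 0")
  if (any(T1_star <= 0) || any(T1 <= 0)) stop_arg("T1_star and T1 must be > 0")
  if (any(T1_star > T1 * (1 + 1e-12)))
    stop_arg("T1_star must not exceed T1")
  if (!is.null(TR) && any(TR >= T1_star))
    warning("steady-state relation assumes TR < T1_star", call. = FALSE)
  M0 * T1_star / T1
}

#' Inversion-recovery Look-Locker signal curve
#'
#' Longitudinal magnetization at time `t` after a perfect global inversion,
#' relaxing under continuous low-angle excitation:
#' \deqn{M(t) = M_0^* - (M_0 + M_0^*)\exp(-t/T_1^*).}
#' The curve starts at \eqn{-M_0}, crosses zero at
#' \eqn{t_0 = T_1^*\ln[(M_0+M_0^*)/M_0^*]} and saturates at \eqn{M_0^*}.
#'
#' @param t time after inversion (ms); vectorized.
#' @param M0 equilibrium magnetization (> 0 for a physical curve).
#' @param M0_star steady-state magnetization.
#' @param T1_star effective relaxation time (ms), > 0.
#' @return Magnetization at each `t`, same units as `M0`.
#' @examples
#' irll_signal(c(0, 500, 5000), M0 = 1, M0_star = 0.445, T1_star = 445)
#' @export
irll_signal <- function(t, M0, M0_star, T1_star) {
  if (any(T1_star <= 0)) stop_arg("T1_star must be > 0")
  if (any(t < 0)) stop_arg("t must be >= 0")
  M0_star - (M0 + M0_star) * exp(-t / T1_star)
}

#' True T1 from the three fitted Look-Locker parameters
#'
#' Combines the fitted effective relaxation time and the two magnetization
#' levels into the flip-angle-independent relaxation time
#' \deqn{T_1 = T_1^*[(M_0 + M_0^*)/M_0^* - 1] = T_1^* M_0 / M_0^*.}
#'
#' @param T1_star fitted effective relaxation time (ms), > 0. Vectorized.
#' @param M0_star fitted steady-state magnetization, > 0 (else `NA`).
#' @param M0 fitted equilibrium magnetization.
#' @return True T1 (ms); `NA` where `M0_star <= 0` (undefined pixel).
#' @examples
#' true_t1_from_fit(445.04, 0.44504, 1)  # recovers 1000 ms
#' @export
true_t1_from_fit <- function(T1_star, M0_star, M0) {
  if (any(T1_star <= 0)) stop_arg("T1_star must be > 0")
  out <- T1_star * M0 / M0_star
  out[M0_star <= 0] <- NA_real_
  out
}

#' Fraction of the inversion deficit recovered after a relaxation break
#'
#' After a Look-Locker segment the magnetization needs a delay to return to
#' equilibrium before the next inversion. For pure longitudinal relaxation
#' (no excitation during the break) the recovered fraction of the deficit is
#' \eqn{1 - \exp(-\mathrm{delay}/T_1)}: 99.9\% is reached within 15 s for
#' T1 < 2000 ms, but less than 98\% for T1 > 4000 ms (e.g. CSF), which
#' biases repeated acquisitions of long-T1 compartments.
#'
#' @param T1 longitudinal relaxation time (ms), > 0. Vectorized.
#' @param delay relaxation break (ms), >= 0.
#' @return Recovered fraction in \eqn{[0, 1)}.
#' @examples
#' recovered_fraction(2000, 15000)  # 0.99945
#' recovered_fraction(4000, 15000)  # 0.97648
#' @export
recovered_fraction <- function(T1, delay) {
  if (any(T1 <= 0)) stop_arg("T1 must be > 0")
  if (any(delay < 0)) stop_arg("delay must be >= 0")
  1 - exp(-delay / T1)
}
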