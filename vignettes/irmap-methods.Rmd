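---
title: "Model-based T1 mapping from a single-inversion radial Look-Locker acquisition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based T1 mapping from a single-inversion radial Look-Locker acquisition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Quantitative T1 maps are usually acquired in a segmented fashion: many
inversion pulses, each followed by a fragment of k-space, with long
relaxation breaks in between. A single slice then costs minutes to hours.
`irmap` reconstructs a T1 map from *one* global inversion followed by a
continuous golden-angle radial spoiled gradient-echo readout (1000
projections, about 6 s at TR = 6 ms): every projection carries a different
inversion time, so no time point is ever sampled beyond a single spoke, and
the reconstruction must supply the missing information through the known
relaxation physics.

## Signal model

Under continuous low-angle excitation (flip angle $\alpha$, repetition time
$T_R$) the longitudinal magnetization relaxes with an effective time
constant

$$T_1^\ast = \left[ \frac{1}{T_1} - \frac{1}{T_R}\ln\cos\alpha \right]^{-1}
\le T_1$$

towards a reduced steady state $M_0^\ast = M_0\, T_1^\ast / T_1$ (valid for
$T_R < T_1^\ast$). After a perfect inversion the signed magnetization
follows

$$M(t) = M_0^\ast - (M_0 + M_0^\ast)\, e^{-t/T_1^\ast},$$

and a three-parameter fit of $(T_1^\ast, M_0^\ast, M_0)$ yields the true
relaxation time *independently of the local flip angle*:

$$T_1 = T_1^\ast \, \frac{M_0}{M_0^\ast}.$$

All interfaces use milliseconds and degrees, the units in which these
protocols are specified.

## The iteration

Each projection is gridded onto its own Cartesian k-space frame
(`grid_radial_frames()`), almost-empty frames are filled by linear
interpolation of every acquired cell through time (`temporal_interp_init()`),
and per-coil phase maps are estimated once from the last 200 projections —
by then the magnetization has passed its zero crossing and sits near
$M_0^\ast$, so the tail forms a fully sampled, constant-contrast image
(Nyquist for 128 readout points is ~200 spokes).

Each of the (fixed) 50 iterations then performs:

1. inverse DFT of the model k-spaces into per-coil image series;
2. rotation of each coil series to the real axis with its phase map and
   sign-dependent sum-of-squares combination, which preserves the negative
   lobe of the inversion-recovery curve;
3. model enforcement: every pixel's curve is replaced by its best
   approximation by at most `k_max = 3` atoms of a dictionary of
   mono-exponential relaxation curves (185 T1 values from 10 to 5000 ms
   times flip angles 3, 5, 7, 9 degrees = 740 atoms, unit-normalized),
   selected by orthogonal matching pursuit — the multi-atom fit absorbs
   partial-volume and slice-profile (flip-angle) deviations that a strict
   mono-exponential enforcement would turn into systematic errors;
4. re-separation into per-coil model series via per-pixel complex
   least-squares weights, forward DFT, and data consistency: every measured
   sample is restored in its own k-space cell.

After the last iteration a pixel-wise three-parameter fit of the combined
consistent images gives $(T_1^\ast, M_0^\ast, M_0)$ and hence T1. The
dictionary only serves to describe the curves as exactly as possible inside
the loop; the final fit is the same mono-exponential fit a conventional
IR-LL experiment would use, which keeps the output comparable.

## Numerical choices

**Centered unitary DFT.** All transforms put DC at cell `side/2` (0-based)
and preserve norms; power-of-two grids use a batched radix-2 kernel.

**Gridding and the data-consistency variants.** Scanner implementations of this reconstruction grid
with self-calibrating GRAPPA-operator gridding (GROG), which *shifts* each
radial sample onto its nearest Cartesian cell using operators calibrated
from multi-coil data. That shift is the load-bearing detail: replacing it
by a plain nearest-cell deposit leaves a sub-cell position error of up to
half a cell, and since k-space of a head-sized object oscillates on exactly
that scale, noiseless phantom reconstructions carry 6–12% ROI-mean T1
errors — while the identical pipeline fed data sampled exactly at the cell
positions recovers every vial within 0.5%. `irmap` therefore keeps
one-sample-one-cell ownership but corrects the substituted value with the
model itself:

$$K(c) \leftarrow s + \left[ K_{\text{model}}(c) - K_{\text{model}}(p) \right],$$

where $p$ is the true spoke position and $K_{\text{model}}(p)$ is evaluated
*exactly* by a nonuniform DFT restricted to the object support (the model is
zero elsewhere, so this is cheap). At the fixed point the model satisfies
$K_{\text{model}}(p) = s$: consistency holds at the true sample positions.
This is the default (`consistency = "model_shift"`); the literal bit-exact
substitution remains available as `consistency = "cell"` and as the
`data_consistency()` primitive with its exact contract. Single-coil data
cannot support actual self-calibrating GROG (it needs coil diversity), which
is why the model supplies the shift information instead.

**Segmented reference.** The fully sampled multi-inversion reference has no
consistency step, so cell ownership is irrelevant there; its per-frame
images are formed by the field-standard regridding reconstruction:
per-spoke Voronoi angular weights times a radial ramp (density
compensation), Kaiser-Bessel spreading onto a 2x oversampled grid, inverse
FFT, deapodization, crop. Cell-value interpolation variants were tried
first and left 3–9% noiseless errors from frame-dependent gridding wobble;
the adjoint route cuts that several-fold. A residual quasi-random
frame-to-frame wobble remains because each frame necessarily holds a
*different* golden-angle subset (each segment acquires every angle exactly
once, so identical per-frame subsets are combinatorially impossible), which
together with few-pixel ROIs keeps desk-scale noiseless recovery at the
few-percent level; the floor set by the radially-covered k-space disk
itself is ~1.8% at a 32-cell grid and ~0.2% at the full 128-cell protocol
resolution.

**Polarity of the reference.** The reference fits signed curves; polarity
is restored by rotating each coil's frames with phase maps taken from the
mean complex image of the last 10% of frames, then combining with the
sign-dependent sum of squares — the acquisition-tail convention of the
single-inversion path, reused because the protocol leaves the
re-signing step unspecified.

**Three-parameter fit.** The nonlinear least-squares problem is solved by
variable projection: for fixed $T_1^\ast$ the two magnetization levels are
linear and eliminated in closed form, leaving a 1-D minimization over
$T_1^\ast \in (1, 10^4]$ ms (coarse log-spaced grid, then golden-section
refinement). This is the exact minimizer of the stated three-parameter
problem without initialization sensitivity; fits pinned to a bound, or with
non-positive $M_0^\ast$ or $M_0$ (e.g. constant curves), are flagged
invalid. The batched C++ path and the plain R implementation
(`monoexp_fit3()`) are tested against each other.

**OMP details.** Coefficients are unconstrained in sign; iteration stops at
`k_max` atoms or when the residual drops below $10^{-6}$ of the signal
norm. On IR-LL dictionaries the atoms are highly correlated, so greedy
pursuit is a fitting device, not a support-recovery method — the test suite
checks exact equivalence with exhaustive search on an incoherent random
dictionary and only functional approximation quality on the relaxation
dictionary.

**Background masking.** Optionally (`mask_background = TRUE`) pixels whose
tail-image magnitude is below 5% of the maximum are excluded from the
dictionary and final fits. The default fits all pixels; the option exists
because the fit cost is proportional to the pixel count and background
carries no signal.

## The synthetic test bed

The simulator emulates the two phantoms used for validation: seven vials
(T1 = 208, 573, 998, 1659, 2123, 2560, 2929 ms — the gold-standard values
of the contrast-agent phantom) on a signal-free background, and a brain-like
phantom with WM 722 ms, GM 1432 ms, CSF 4350 ms (volunteer-averaged values;
proton densities 0.77/0.86/1.0). Coil maps are smooth Gaussian profiles
with distinct phase ramps, sum-of-squares-normalized to 1. The forward
model evaluates the relaxation curve per compartment and takes the *exact*
nonuniform DFT of the coil-weighted image along every spoke (an
FFT-interpolation fast mode matches it to <1% RMS and is available for
large grids); complex Gaussian noise is added per k-space sample, per coil
— noise in k-space, not image space, so SNR is analytically controllable
(`noise_sigma_for_tail_snr()` targets a tail-image SNR, e.g. 50). Segmented
acquisitions restart the inversion-time clock while the golden-angle
counter keeps advancing; an option propagates incomplete recovery through
the 15 s relaxation breaks, reproducing the depression of long-T1 (CSF)
estimates in repeated acquisitions while WM/GM stay stable.

What the simulator does *not* emulate: imperfect inversion, slice-profile
flip-angle spread (available only as an explicit option), off-resonance,
T2* decay along the readout, motion, and scanner noise correlations. A
green test therefore establishes correctness of the reconstruction given
the stated signal model, not robustness to every scanner non-ideality.

## Scaled-down validation targets

The reference validation figures (≤2.6% vial deviation, ≤5.5% WM/GM
deviation) refer to scanner data reconstructed against a same-gridding
reference. The package's acceptance checks re-create them as simulation
analogues against known ground truth, with the full temporal protocol
(1000 projections, 50 iterations, 740-atom dictionary) on a 64-cell grid —
half the spatial resolution, chosen so two complete reconstructions fit a
20-minute single-CPU budget. ROI means are taken over compartment labels
eroded by 2 pixels, the usual practice of drawing ROIs inside vials. On
this stated world the maximum vial deviation lands around 2.5–3% (the
smallest, shortest-T1 vial dominates) and WM/GM within ~1%; the reference
2.6% bound is met with little margin at this resolution, and the
acceptance script reports whatever the computation yields.

## Known limitations

- True self-calibrating GROG is not implemented (out of scope); the
  model-shift consistency is this package's substitute, and with
  `consistency = "cell"` the reconstruction reproduces the plain
  nearest-cell behavior with its documented bias.
- The dictionary's T1 grid is uniform (the count and range are specified
  upstream, the spacing is not); `build_dictionary()` accepts any grid.
- The segmented reference needs roughly Nyquist many segments; below ~85%
  k-space-disk coverage it warns and the fit quality degrades.
- Very long T1 (≳ the acquisition duration) is estimated from a curve that
  never reaches its steady state; accuracy degrades gracefully (visible in
  the CSF compartment).
- The iteration does not reach full numerical stationarity within the
  fixed 50 iterations: the discrete atom re-selection of the pursuit
  leaves a small churn floor (relative image change per iteration of order
  10⁻³ even on noiseless, perfectly consistent data), which is why the
  convergence tests assert strong contraction of the per-iteration change
  rather than a hard stationarity threshold.
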