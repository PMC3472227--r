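---
title: "Area-based wave intensity analysis: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Area-based wave intensity analysis: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wia)
```

## The model

Wave intensity analysis treats the arterial pulse as a superposition of
incremental wavefronts. For a wavefront travelling with speed $c$ the
waterhammer equation links its pressure and velocity increments,
$dP_\pm = \pm\rho c\, dU_\pm$, with $+$ for waves running away from the
heart and $-$ for waves running toward it. Combining this with the
Bramwell–Hill relation $c^2 = A\,dP/(\rho\,dA)$ eliminates pressure
entirely and leaves only quantities an imaging acquisition measures:

$$c = \frac{dU}{d\ln A}, \qquad
dU_\pm = \tfrac12\,(dU \pm c\,d\ln A), \qquad
d\ln A_\pm = \tfrac12\,\Big(d\ln A \pm \frac{dU}{c}\Big).$$

Net wave intensity is $dI = dU\,d\ln A$ and the separated intensities are
$dI_\pm = dU_\pm\, d\ln A_\pm$. Two algebraic consequences are used as
machine-precision invariants throughout the test suite: the cross terms
cancel, so $dI = dI_+ + dI_-$ exactly, and $dI_+ = c\,d\ln A_+^2 \ge 0$,
$dI_- = -c\,d\ln A_-^2 \le 0$ for any $c > 0$.

Working with area rather than diameter avoids any assumption about the
cross-sectional shape of the vessel; working with $\ln A$ makes every
downstream quantity invariant to the area unit (an additive constant in
$\ln A$), which the tests verify end to end.

The assumptions inherited from the model are: a single dominant propagation
speed over the analysed segment and cycle (the separation uses one scalar
$c$); reflection-free early systole, so the early limb of the $U$–$\ln A$
loop is linear with slope $c$; and increments taken at a fixed sampling
interval — $dI$ in this raw form scales as $dt^2$, which is fine when all
acquisitions share one temporal resolution and is otherwise addressed by
the time-corrected form $(dU/dt)(d\ln A/dt) = dI/dt^2$, invariant to the
sampling interval in the continuum limit.

## The processing chain and its parameters

`wia_analyze()` runs: load → resample → smooth → foot → loop → window →
wave speed → separation → intensity → peaks. The tunable parameters, their
defaults and the reasoning:

* **Resampling interval, 1 ms.** Native PC-CMR frames arrive at ~9.6 ms;
  all downstream windows are defined on a 1 ms grid. Default interpolation
  is shape-preserving monotone cubic (Fritsch–Carlson, as in PCHIP): it
  passes through every sample and cannot overshoot between knots, which
  matters because $A > 0$ must be preserved. Linear interpolation is
  available; on the bundled template the two give wave speeds within 2 %,
  so the choice is immaterial in practice (asserted in the tests).
  Downsampling is refused rather than silently antialiased.
* **Savitzky–Golay smoothing of A: order 3, window 101 samples.** The
  101-sample window is the odd centred equivalent of a 100 ms window at
  1 ms sampling (an even window cannot be centred). Order 3 preserves
  cubics exactly, so smooth physiologic curvature passes through
  undistorted. Edge samples use the filter's startup transients — the full
  polynomial fit over the first/last window evaluated at the edge
  positions. Windows longer than the series shrink to the largest valid
  odd size, recorded in the output.
* **Which signals are smoothed.** By default only the area curve is
  smoothed, velocity untouched. For noisy native-resolution data the
  recommended estimator configuration (`smooth_velocity = TRUE`, used by
  default in `recovery_experiment()`) passes *both* signals through the
  same filter: a shared linear filter preserves the linear early-systolic
  loop relation, so the wave-speed estimate stays essentially unbiased
  while the noise is suppressed. Asymmetric smoothing (A only) of signals
  whose feature width is comparable to the window distorts the loop and
  biases $c$ upward — visible on the noise-free synthetic template, where
  feature widths (~80 ms) sit just below the 101 ms window. For noise-free
  inputs, smoothing is pure distortion and `smooth = FALSE` is the correct
  configuration; the exactness experiments use it.
* **Systolic foot: 5 % upstroke threshold.** Baseline is the median of the
  first 5 % of samples; the foot is the last sample before $U$ first
  exceeds baseline + 5 % of the excursion to the global maximum. The rule
  is baseline-relative (offset-invariant), needs no second derivative, and
  is robust at 1 ms sampling. A flat record (excursion < 0.02 m/s) is a
  detection error, not a silent foot.
* **Loop window: maximum r² over contiguous windows of ≥ 20 ms, bounded by
  the velocity peak.** "Most linear portion" is operationalized as the
  window maximizing the r² of the OLS fit of $U$ on $\ln A$; the 20 ms
  minimum prevents degenerate two-point perfect fits, and the search stops
  at peak velocity because reflections are expected beyond early systole.
  The window may start after the foot — the loop often needs a few
  milliseconds to straighten. No time-alignment shift between $U$ and $A$
  is applied; simultaneity of the two signals is an advantage of
  area-based acquisitions.
* **OLS of U on lnA**, matching the loop-gradient convention of the P–U
  loop literature; a convention, not a claim of superiority over
  orthogonal regression.
* **Separation constants.** Separated increments are reintegrated by
  cumulative summation. How to split the initial values $U_0$, $\ln A_0$
  between forward and backward curves is not determined by the algebra; we
  assign both to the forward curves so backward curves start at zero, the
  usual presentation. Recorded in the output metadata.
* **Peak classification.** Phase boundaries are defined by signs and
  ordering, not fixed times: FCW is the largest $dI_+$ with $dU_+ > 0$
  between foot and mid-record, FEW the largest $dI_+$ with $dU_+ < 0$
  after the FCW, BCW the most negative $dI_-$ between them. Using the
  deceleration sign (rather than a time cut) to bound the FEW keeps the
  rule heart-rate independent. A wave below 2 % of the FCW peak
  (configurable) is reported absent with a reason rather than as a noise
  extremum.

## What the synthetic generator emulates — and what it does not

`generate_waveforms()` builds one cardiac cycle from raised-cosine forward
wavelets in the velocity-increment rate. Compression wavelets carry
positive $dU_+$, expansion wavelets negative; forward log-area increments
are $dU_+/c$; an optional backward wave is a delayed copy of the forward
compression scaled by a reflection coefficient $R$, with
$dU_- = -c\,d\ln A_-$. Velocity and $\ln A$ follow by integration (closed
form, so the same continuum signal can be sampled at any rate without
quadrature error), $A = A_0 e^{\ln A - \ln A_0}$, then native-rate
sampling, prospective-gating truncation and additive white Gaussian noise.

Defaults describe a healthy-volunteer ascending aorta: $c = 5.8$ m/s,
$A_0 = 520$ mm², 900 ms cycle with 85 % acquired, 9.6 ms native sampling;
FCW wavelet centre 110 ms, width 80 ms, peak rate 0.025 m/s per ms (peak
velocity ≈ 1 m/s, forward-intensity peak ≈ 1.1 × 10⁻⁴ m/s); FEW centre
310 ms, width 160 ms (late deceleration is broader and weaker than early
acceleration); $R = 0.15$ arriving 90 ms behind the FCW. These were chosen
once for physiologic realism and are the conditions under which the
package's validation suite runs.

Because raised-cosine wavelets switch on with zero slope and zero
curvature, the instant the wavelet support begins is not detectable by any
threshold rule; the generator therefore records as ground-truth foot the
5 % crossing of the noise-free continuum signal — the same rule the
detector applies — alongside the support onset itself.

The generator emulates the acquisition envelope, not the physiology it
abstracts: noise is additive white Gaussian on $U$ and $A$ independently
(no Rician magnitude noise, no segmentation-induced correlated error), the
reflection is a single discrete site (no distributed reflections or
re-reflections), wave speed is constant (no pressure-dependent stiffening
within the cycle), and there is no beat-to-beat variability. Passing the
recovery tests therefore demonstrates correctness of the estimators under
the model's own assumptions, not robustness to everything real data can
do. Conversely, because generated signals satisfy the separation algebra
exactly before noise, any nonzero backward residual in a forward-only run
is attributable to the pipeline, which is what makes the machine-precision
exactness tests meaningful.

## Numerical choices

* **Window-selection ties.** With an exactly linear loop every candidate
  window has r² = 1 up to rounding, so "the" maximum is decided by
  floating-point noise. Windows within 1e-12 of the maximum are treated as
  tied, then the longest and earliest wins. The brute-force enumeration
  oracle in the tests applies the same rule; the production search screens
  with cumulative sums (on region-centred data, keeping cancellation error
  ~1e-14) and re-scores the near-maximal candidates with an exact two-pass
  computation.
* **Degenerate inputs.** Vertical loop segments (zero $\ln A$ variance)
  are excluded from the window search and are an explicit error in the
  slope fit; non-positive areas are rejected at validation with the sample
  index; a smoothing window that would produce non-positive area aborts.
* **Exactness configurations.** Noise-free recovery is exact (relative
  error at machine precision, backward residual < 1e-12 m/s) when the
  generator samples natively at the analysis interval and smoothing is
  off. Resampling $A$ (not $\ln A$) between grids introduces a small
  interpolation mismatch with the affine $U$–$\ln A$ relation, and
  smoothing a noise-free curve perturbs it by design; both effects are
  properties of any such pipeline, documented here so that exactness
  claims are made under the configuration in which they hold.
* **Determinism.** All stochastic components take explicit integer seeds;
  replicate $r$ of a recovery experiment uses `seed + r - 1`. Identical
  seeds give bit-identical series, tables and serialized reports.

## Agreement statistics

Observer variability uses the single-measure absolute-agreement ICC(2,1)
from the two-way random-effects ANOVA decomposition — the standard choice
for reproducibility of a single reading; the average-measure variant
ICC(2,k) is exposed as a flag since published reports do not always say
which was used. Confidence intervals use the McGraw–Wong F approximation
with Satterthwaite degrees of freedom. Negative estimates from degenerate
variance structures are reported, never clipped. Bland–Altman differences
are oriented observer1 − observer2 so bias signs are comparable across
tables; limits of agreement are bias ± 1.96 SD. The unpaired t test is the
classic equal-variance form with Welch as an option.

## Problem sizes used in validation

The test-suite and acceptance-script workloads were sized to exercise the
estimators well past their asymptotic behaviour while staying quick on a
laptop: 1,000 random increment series for the separation algebra, a
10-value wave-speed sweep (3–12 m/s), 100 Monte-Carlo replicates at
$\sigma_U = 0.01$ m/s and $\sigma_A = 0.5$ mm², 50 random loops of 50–300
samples against the exhaustive window oracle, and 15 × 2 ratings matrices
for the ICC oracle. The full suite runs in about half a minute.

## Known limitations

* Prospectively gated input is never wrapped: all windows are confined to
  the acquired span, and the truncation flag is carried through for
  reporting. For central vessels little happens in the missing
  end-diastole; for peripheral sites a full-cycle acquisition would be
  needed.
* A single scalar wave speed is used for the whole cycle; time-varying or
  pressure-dependent $c$ is out of scope.
* The raw intensity scale depends on the sampling interval ($dt^2$);
  comparisons across temporal resolutions must use
  `time_corrected_intensity()`.
* Segmentation quality is upstream of this package: the pipeline consumes
  $U$/$A$ curves and cannot repair systematic area-tracking errors, which
  in practice dominate the reproducibility of late-systolic quantities.
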