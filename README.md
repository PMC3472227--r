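# wia — non-invasive wave intensity analysis from velocity and area waveforms

Wave intensity analysis (WIA) decomposes the arterial pulse into incremental
wavefronts and separates them into waves travelling away from the heart
(forward) and toward it (backward). It yields pulse wave speed *c* (an index
of arterial stiffness), the forward compression wave (FCW, related to
ventricular contractility), the backward compression wave (BCW, reflections)
and the forward expansion wave (FEW, related to diastolic relaxation). The
classic formulation needs invasive pressure; the **area formulation**
replaces pressure by the log of vessel cross-sectional area, so that
everything is computable from a phase-contrast CMR (or ultrasound) flow
acquisition that measures mean velocity *U(t)* and lumen area *A(t)*
simultaneously.

The package is for physiologists and imaging scientists who already have
segmented *U*/*A* curves and want a validated, scriptable processing chain.

## The method

With blood density ρ and distensibility D, wave speed obeys the
Bramwell–Hill relation c² = 1/(ρD) = A dP/(ρ dA). Eliminating pressure
through the waterhammer equation dP± = ±ρc·dU± gives

```
c = dU / dlnA                    (gradient of the U–lnA loop in early
                                  systole, where no reflections are expected)
dU±   = (dU ± c·dlnA) / 2        (forward/backward velocity increments)
dlnA± = (dlnA ± dU/c) / 2        (forward/backward log-area increments)
dI    = dU · dlnA                (net wave intensity; dI± = dU±·dlnA±)
```

The processing chain mirrors standard practice for 1-ms-resampled aortic
curves: interpolate to 1 ms (shape-preserving monotone cubic), smooth the
area curve with a 3rd-order Savitzky–Golay filter (101-sample window),
anchor early systole at the 5 % upstroke foot, select the most linear
portion of the U–lnA loop (maximum r² over all contiguous windows of at
least 20 ms up to the velocity peak), take *c* from its OLS gradient,
separate the increments, and classify the FCW/BCW/FEW peaks by the sign of
dU⁺ and their ordering.

A bundled synthetic generator produces aortic-like cycles from raised-cosine
forward wavelets that satisfy the waterhammer algebra exactly, with a
programmable reflection, prospective-gating truncation, native 9.6 ms
sampling and additive noise — so every estimator can be checked against
ground truth.

## Worked example

```r
library(wia)

# a noisy volunteer-like acquisition with known ground truth (c = 5.8 m/s)
gen <- generate_waveforms(synthetic_spec(noise_sd_U = 0.01,
                                         noise_sd_A = 0.5, seed = 1))
rep <- wia_analyze(gen$series, wia_config(smooth_velocity = TRUE))
print(rep$wave_speed)
print(rep$peaks)
```

```
<wave_speed_fit> c = 5.531 m/s (r2 = 1.0000), window 83-103 ms
  distensibility = 3.083e-05 1/Pa
<wave_peaks>
  FCW: 6.34 x 1e-5 m/s at t = 108.5 ms
  BCW: -0.17 x 1e-5 m/s at t = 198.5 ms
  FEW: 2.09 x 1e-5 m/s at t = 311.5 ms
```

The recovered wave speed is within 5 % of the generative 5.8 m/s despite
measurement noise; the intensity pattern shows the canonical dominant FCW in
early systole, a small mid-systolic reflection (BCW) and a late-systolic
FEW, with peak values on the 10⁻⁵ m/s scale conventional for 1-ms aortic
data. `recovery_experiment()` repeats this over many seeded replicates and
tabulates bias/SD/RMSE; `agreement_report()` produces the ICC(2,1) +
Bland–Altman tables used in observer-variability studies.

A command-line front end is installed with the package
(`<library>/wia/exec/wia`) with subcommands `analyze`, `simulate`,
`recover` and `agreement`.

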