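Package: wia
Title: Non-Invasive Wave Intensity Analysis from Velocity and Area Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Area-based wave intensity analysis for arterial haemodynamics.
    From time series of blood velocity U(t) and vessel cross-sectional area
    A(t), as produced by phase-contrast cardiovascular magnetic resonance
    flow post-processing, the package estimates pulse wave speed c from the
    gradient of the early-systolic U-lnA loop, separates velocity and
    log-area increments into forward and backward travelling components via
    the waterhammer relation dU = +/- c dlnA, computes net and separated
    wave intensity dI = dU dlnA, and locates the forward compression,
    backward compression and forward expansion wave peaks. A synthetic
    aortic waveform simulator with known ground truth supports parameter
    recovery experiments, and two-way random-effects intraclass correlation
    with Bland-Altman agreement statistics support reproducibility studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
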