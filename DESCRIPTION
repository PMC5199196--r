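Package: nmlock
Title: Cross-Frequency n:m Phase-Phase Coupling with Surrogate Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures n:m phase-phase coupling between band-limited neural
    oscillations (e.g. hippocampal theta and gamma) via the mean resultant
    length R_n:m of the accelerated phase difference, with statistically
    sound surrogate testing (time-shift, random-permutation and
    phase-scramble mock phases; single-run versus pooled chance
    distributions), zero-phase least-squares FIR filtering and Hilbert
    instantaneous phase, phase-phase plots with bin-wise Holm-Bonferroni
    significance maps, and the generative simulations (coupled Kuramoto
    phase oscillators, variable-frequency sawtooth waves, white-noise
    controls) that expose the analysis pitfalls of the method:
    epoch-length bias, filtering-induced sinusoidality, harmonic
    artifacts, and false positives from pooled or scrambled surrogates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
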