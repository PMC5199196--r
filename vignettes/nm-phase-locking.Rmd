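---
title: "Measuring and testing n:m phase-phase coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and testing n:m phase-phase coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The statistic

Two oscillations of different frequencies are *n:m phase-locked* when m
cycles of the fast rhythm hold a consistent phase relationship to n cycles
of the slow one. Writing $\phi_\theta(t)$ and $\phi_\gamma(t)$ for the
instantaneous phases, the accelerated phase difference is

$$\Delta\varphi_{nm}(t) = n\,\phi_\gamma(t) - m\,\phi_\theta(t),$$

and the coupling statistic is the mean resultant length

$$R_{n:m} = \left\| \frac{1}{N}\sum_{j=1}^{N} e^{i\,\Delta\varphi_{nm}(t_j)} \right\|,$$

which is 1 when the difference is constant and 0 when it is uniform on the
circle. `phase_difference()` and `rnm()` implement exactly this;
`rnm_curve()` sweeps m at fixed n (conventionally n = 1, m = 1–25).

The whole point of this package is that an $R_{n:m}$ value **in isolation
is uninterpretable**. Three mechanical effects produce non-zero — even
"impressive" — values without any coupling:

1. **Small-sample bias.** For N independent uniform phase differences,
   $E[R] \approx \tfrac{\sqrt{\pi}}{2} N^{-1/2}$. Shorter epochs give
   systematically larger chance values, so original and surrogate epochs
   must have identical length.
2. **Filtering-induced sinusoidality.** A band-pass filter imposes a
   quasi-linear phase progression on *any* input: consecutive phase samples
   of filtered white noise step by approximately $2\pi f_c/f_s$ radians
   ($f_c$ the band center). Neighboring samples are therefore strongly
   dependent, and $R_{n:m}$ curves of filtered noise show a bump at the
   ratio of the band centers (`phase_step_mode()` exposes the effect;
   subsampling with `subsample_phase()` at a period longer than one fast
   cycle removes it).
3. **Harmonics of non-sinusoidal waveforms.** The k-th harmonic of an
   asymmetric wave is by construction 1:(k+1) locked to the fundamental, so
   a sharp-edged theta wave produces genuine-looking "gamma" locking
   (`gen_sawtooth()` reproduces this; `count_stripes()` quantifies its
   signature in phase-phase plots).

## Preprocessing conventions

* **Filtering** (`bandpass()`): least-squares linear-phase FIR, order
  $3 f_s / f_{low}$ rounded up to even so the filter stays Type I
  (symmetric, odd length), transition bands 15% of each cutoff, applied
  forward and backward for zero net phase. The passband ripple of this
  design means an in-band sinusoid is reproduced to about 1% per pass
  (≈1.3% after the forward–backward application); tests allow 2%.
  Butterworth (order 4) and complex-Morlet alternatives sit behind
  `method =`; a Bessel variant is not provided because no digital Bessel
  design is available in the dependency set.
* **Phase** (`hilbert_phase()`): argument of the FFT-based analytic signal.
  Convention: phase 0 at the waveform peak of a cosine, ±π at the trough,
  increasing with time; all emitted phases lie in $(-\pi, \pi]$.
  A constant signal raises an error rather than returning an arbitrary
  phase.
* **Landmark phase** (`waveform_theta_phase()`): piecewise-linear
  interpolation through four anchors per cycle — peak 0, descending
  zero-crossing π/2, trough π, ascending zero-crossing −π/2 — matching the
  Hilbert convention so the two estimators can be swapped. Anchors are
  located on the 4–20 Hz filtered trace; extrema are refined on a 10 ms
  moving-average smoothed copy of the raw trace. Edges beyond the first and
  last anchor are extrapolated at the neighboring inter-anchor slope.
  The anchor-phase assignment is a package convention: the interpolation
  method in the literature does not state which landmark carries phase 0.
* **Edges**: forward–backward FIR filtering leaves transients of roughly
  one filter length at each end of a record. Analyses here follow the
  convention of dropping 0.5 s per session end (`trim_edges()`) before
  epochs are cut; epochs themselves are then used in full.

## Surrogate testing

Theta phases stay intact; gamma phases are mocked three ways
(`time_shift_surrogate()`, `random_permutation_surrogate()`,
`phase_scramble_surrogate()`). All three preserve the gamma-phase marginal
exactly. Time shifts are drawn uniformly from 1–200 ms, forward only (the
direction is a package choice — the convention in the literature does not
state a sign; `symmetric = TRUE` enables ±). Random permutation draws a
contiguous window anywhere in the session, excluding only the exact
original start; overlap is allowed.

Chance distributions come in two flavors (`surrogate_rnm_distribution()`):

* **Single run** — one R per surrogate run. This is the valid control.
* **Pooled** — phase differences of (conventionally 100) runs pooled before
  one R is computed. Because R on a pooled sample equals R on a
  concatenated epoch (the *pooling identity*, tested exactly), pooling
  deflates chance values by lengthening the effective epoch, and testing
  originals against pooled distributions produces false positives even on
  white noise. The package implements pooling precisely so that this
  failure mode can be demonstrated.

`test_rnm()` performs the conventional one-tailed two-sample t-test of
original against surrogate R values and reports the original's percentile
within the chance distribution.

**Phase-phase plots** (`phase_phase_histogram()`): 120×120 joint histograms
over $(-\pi, \pi]$, half-open uniform bins, smoothed with a circular
Gaussian kernel of σ = 10 bins (the kernel wraps on both axes because
phases are circular — boundary handling is a package decision — and is
normalized to preserve total counts). Bin-wise testing
(`phase_phase_significance()`, `pp_plot_test()`) compares each bin of the
original plot to the mean and SD of the same bin over individual surrogate
plots: $z = (c - \mu_{surr})/\sigma_{surr}$, one-sided upper-tail normal
p, then Holm–Bonferroni jointly over all 14,400 bins (Benjamini–Hochberg
FDR and no correction available for comparison). Two numerical choices
matter here:

* Statistics are computed on the **smoothed** counts — the form in which
  phase-phase plots are constructed and displayed. Raw per-bin counts are
  strongly skewed at these occupancies, and the upper tail of the normal
  approximation misstates them badly enough that isolated bins can cross
  the Holm threshold on pure noise; the smoothed counts (each effectively
  an average over many bins) are much closer to Gaussian and give a
  calibrated, conservative test. Passing `sigma_bins = 0` reproduces the
  raw-count variant.
* Bins whose surrogate SD is zero are flagged and assigned p = 1 rather
  than producing infinite z.

An empirical alternative to the normal approximation (rank within the
surrogate distribution) is intentionally not the default: with 1000 runs
its resolution floor of 1/1001 is coarser than the Holm threshold
0.05/14400, so it can never reject — the normal plug-in is what makes the
correction meaningful.

## The generators: what they emulate

* `gen_white_noise()` — i.i.d. standard Gaussian samples: the null signal
  with a flat spectrum and no phase structure. Every chance-level claim in
  the package is calibrated on it.
* `simulate_kuramoto_pair()` — two phase oscillators with sine coupling
  $\dot\phi_\theta = \omega_\theta + \varepsilon\sin(n\phi_\gamma - m\phi_\theta)$,
  $\dot\phi_\gamma = \omega_\gamma + \varepsilon\sin(m\phi_\theta - n\phi_\gamma)$,
  integrated by forward Euler at dt = 1 ms (deliberately first-order: the
  per-step frequency noise dominates the integration error, and a
  higher-order scheme would not change any statistic of interest). Natural
  frequencies are redrawn i.i.d. from $N(2\pi\bar f, 2\pi\sigma)$ at
  **every step** (white frequency noise) — the most literal reading of
  "Gaussian at each time step"; holding draws over longer intervals would
  give slower frequency wander and higher chance R_1:5 for uncoupled
  pairs. Defaults are the study conditions: ε = 10 rad/s, σ = 5 Hz, 1:5
  ratio, 8 and 43 Hz. With these, coupling pulls the mean frequencies to
  8.5/42.5 Hz (analytically: the locked state satisfies
  $\sin\psi^* = 2\pi(n\bar f_\gamma - m\bar f_\theta)/((n+m)\varepsilon)$,
  shifting each oscillator by $\pm\varepsilon\sin\psi^*/2\pi \approx 0.5$
  Hz), and probing the locked pair at m = 3 or 7 shows Δφ precession at
  $\pm(42.5 - 3\cdot 8.5\;\mathrm{or}\;7\cdot 8.5) = \pm 17$ Hz. Initial
  phases are uniform on $(-\pi,\pi]$ from the seeded generator.
* `gen_sawtooth()` — unit peak-to-peak linear ramp with a sharp falling
  edge (polarity flag available; the asymmetry direction is a package
  choice). Frequency jitter is drawn **per cycle**, not per sample, so each
  cycle stays a clean ramp; per-sample jitter would destroy the waveform
  whose asymmetry is the point. Draws below 1 Hz are clamped (a Gaussian
  with mean 8, σ 5 Hz has ~8% mass below 1 Hz; the clamp raises the
  effective mean cycle frequency to ≈8.18 Hz, and tests check the census
  against that clamped-Gaussian expectation, not against 8). Defaults are
  the study conditions: mean 8 Hz, σ 5 Hz, additive noise SD 0.1.
* `gen_sinusoid()` — unit cosine; the positive control
  (R_1:5 of perfect 8 and 40 Hz sines is 1 to numerical precision).

What the generators do **not** emulate: 1/f background spectra,
non-stationary power, theta-nested gamma *amplitude* modulation, volume
conduction, or recording artifacts. Tests passing on these signals
establish the statistical machinery (bias laws, surrogate calibration,
correction behavior), not that any particular real recording lacks or
shows coupling.

## Seeds and reproducibility

Every stochastic function takes a `seed` and runs it in a local RNG scope
(`withr::with_seed`), so fixed seeds give bit-identical output without
disturbing the caller's RNG stream. `surrogate_rnm_distribution()` and
`pp_plot_test()` take one master seed from which all runs derive in
sequence, making whole distributions reproducible. Experiment scenarios
(`run_experiment()`) are bit-reproducible for a fixed seed and write a
manifest recording parameters, seed and versions.

## Problem sizes

Scenario and test replicate counts are desk-scale choices: 15–30 epochs
where boxplots conventionally use 300, pooled draws over 20–100 runs,
1,000 repeated t-tests for the p-value-uniformity check (where 10,000 is
conventional; `full = TRUE` in `run_experiment()` restores conventional
counts), 20 realizations of 1200 s noise for the long-epoch chance level,
and 1000 surrogate runs for plot significance. Monte-Carlo tolerances in
the tests are set from the binomial/Rayleigh standard errors at those
sizes (typically 3 SE).

One configuration detail worth recording: the bandwidth effect ("the
narrower the filter, the higher the chance R") is probed on the **slow**
band (widths 4/8/16 Hz at a fixed 10 Hz center, m = 4, fast band fixed at
30–50 Hz). Because $\Delta\varphi_{nm}$ accelerates the slow phase m-fold,
slow-band phase jitter enters the phase difference with m² times the
variance of the fast-band jitter; varying only the fast band's width moves
chance R by ~0.002, unmeasurable at desk scale, while the slow-band
configuration separates the three widths cleanly (≈0.20/0.15/0.13).

## Known limitations

* The O–I interneuron network used elsewhere as a biophysical
  demonstration is out of scope (it lives in a neural simulator; see
  ModelDB); the Kuramoto pair covers the same inferential point.
* No metric here — or anywhere yet — distinguishes true n:m coupling from
  harmonic artifacts in a single collective signal; the package's sawtooth
  machinery demonstrates the confound rather than resolving it.
* The bin-wise normal approximation is calibrated for the smoothed-count
  pipeline with hundreds to thousands of surrogate runs; with very few
  runs (< ~100) the SD estimates are noisy and the Holm-corrected test,
  while still conservative in our checks, loses power.
* `waveform_theta_phase()` assumes one dominant slow rhythm in the
  landmark band; on broadband or multi-rhythm signals landmark detection
  becomes unstable (the function errors when fewer than two clean cycles
  are found rather than guessing).
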