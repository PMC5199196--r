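# nmlock

Cross-frequency **n:m phase-phase coupling** analysis for neural time
series, with the statistical controls that keep it honest.

Hippocampal theta (~4–12 Hz) and gamma (~30–150 Hz) rhythms have been
reported to phase-lock at integer ratios: m gamma cycles consistently
nested in n theta cycles. The standard statistic is the mean resultant
length of the accelerated phase difference,

```
Δφ_nm(t) = n·φ_γ(t) − m·φ_θ(t),      R_n:m = ‖ (1/N) Σ_j exp(i·Δφ_nm(t_j)) ‖,
```

where R = 1 means perfect locking and R = 0 a uniform phase difference.
The catch is that R_n:m is strongly biased by epoch length
(E[R] ≈ √π/2·N^(−1/2) for independent uniform phases), by the quasi-linear
phase progression any band-pass filter imposes (even filtered **white
noise** shows an R_n:m bump at the ratio of the band centers), and by
harmonics of non-sinusoidal waveforms (the k-th harmonic is intrinsically
1:(k+1) locked to its fundamental). This package implements the statistic,
the preprocessing (zero-phase least-squares FIR filtering, Hilbert and
waveform-landmark phase, CSD, burst masks, subsampling), the surrogate
framework that separates genuine coupling from these artifacts
(time-shift / random-permutation / phase-scramble mock phases, single-run
vs pooled chance distributions, bin-wise Holm-Bonferroni testing of
phase-phase plots), and the generative simulations that calibrate all of
it (coupled Kuramoto oscillator pairs, variable-frequency sawtooth waves,
white-noise controls). It is aimed at electrophysiologists analyzing
LFP/EEG/MEG-type signals and at methodologists studying the pitfalls.

## Worked example

White noise contains no coupling, yet filtered noise has substantial
R values — and the wrong surrogate test "detects" coupling:

```r
library(nmlock)

x     <- gen_white_noise(31, fs = 1000, seed = 42)   # 31 s of pure noise
b     <- hippocampal_bands()
theta <- trim_edges(band_phase(x, b$theta))          # 4-12 Hz phase
gamma <- trim_edges(band_phase(x, b$gamma_slow))     # 30-50 Hz phase

orig <- vapply(0:29, function(k) {
  rnm(phase_difference(epoch_window(theta, k, 1), epoch_window(gamma, k, 1)))
}, numeric(1))
mean(orig)
#> [1] 0.148        # chance level for 1 s epochs -- far from 0

# proper control: single-run time-shift surrogates of the same length
surr <- surrogate_rnm_distribution(epoch_window(theta, 0, 1), gamma,
          method = "time_shift", mode = "single_run", n_runs = 300, seed = 43)
test_rnm(orig, surr$R)
#>   statistic    df p_value percentile mean_original mean_surrogate
#> 1      1.24  31.8   0.112       55.3         0.148          0.127
# p = 0.11: correctly not significant

# improper control: pooling 100 surrogate runs before computing R
pool <- surrogate_rnm_distribution(epoch_window(theta, 0, 1), gamma,
          method = "time_shift", mode = "pooled", n_runs = 30, n_pool = 100,
          seed = 44)
test_rnm(orig, pool$R)
#>   statistic    df       p_value percentile mean_original mean_surrogate
#> 1      7.95  29.3 0.00000000423        100         0.148         0.0130
# "p < 1e-8" -- a false positive manufactured by the pooled surrogate
```

The pooled chance value (0.013) is an order of magnitude below the
single-run one (0.127) because pooling k runs is equivalent to analyzing
one k-times-longer epoch. Genuine coupling, by contrast, stands out
against the proper control:

```r
k <- simulate_kuramoto_pair(30, epsilon = 10, mean_freq_gamma = 40, seed = 7)
rnm(phase_difference(k$theta, k$gamma))   # 1:5-coupled oscillator pair
#> [1] 0.874
```

Phase-phase plots (`phase_phase_histogram()`, `autoplot()`), stripe
counting (`count_stripes()`), bin-wise significance maps with multiplicity
correction (`pp_plot_test()`), PPC (`ppc()`), and eight packaged
end-to-end scenarios (`run_experiment()`) round out the toolkit. A thin
command-line interface ships at `inst/cli/nmlock` (subcommands `synth`,
`phase`, `nm`, `surrogate`, `run`). See the vignette
(`vignettes/nm-phase-locking.Rmd`) for conventions, parameter meanings and
design decisions.

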