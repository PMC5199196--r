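# generators: statistical structure, determinism, argument validation

test_that("white noise has unit-Gaussian moments, is seed-reproducible, and rejects bad args", {
  x <- gen_white_noise(1, fs = 1000, seed = 7)
  expect_equal(nrow(x), 1000)
  expect_lt(abs(mean(x$value)), 3 / sqrt(1000))
  expect_lt(abs(var(x$value) - 1), 0.15)
  expect_identical(x$value, gen_white_noise(1, 1000, seed = 7)$value)
  expect_false(identical(x$value, gen_white_noise(1, 1000, seed = 8)$value))
  expect_error(gen_white_noise(-1, 1000), "positive")
  expect_error(gen_white_noise(1, -5), "positive")
})

test_that("white-noise band power is proportional to bandwidth (flat spectrum)", {
  x <- gen_white_noise(100, 1000, seed = 11)
  sp <- spec.pgram(stats::ts(x$value, frequency = 1000), spans = 51,
                   plot = FALSE, taper = 0)
  bp <- function(lo, hi) mean(sp$spec[sp$freq >= lo & sp$freq <= hi])
  # flat spectrum: equal mean power density in distant bands
  expect_lt(abs(bp(4, 12) / bp(30, 50) - 1), 0.15)
})

test_that("sinusoid generator honours phase, cycle count and Nyquist limit", {
  x <- gen_sinusoid(8, 1, fs = 1000, phase0 = 0)
  expect_equal(x$value[1], 1)
  # exactly 8 full cycles in 1 s: 16 zero crossings
  expect_equal(sum(diff(sign(x$value)) != 0), 16)
  expect_error(gen_sinusoid(500, 1, fs = 1000), "Nyquist")
  two <- gen_sinusoid(8, 10, 1000)
  two$value <- two$value + gen_sinusoid(40, 10, 1000)$value
  expect_setequal(round(top_spectral_peaks(two, 2)), c(8, 40))
})

test_that("fixed-frequency sawtooth has equal cycles and harmonic spectral peaks", {
  s <- gen_sawtooth(30, mean_freq = 7, freq_sigma = 0, noise_sigma = 0,
                    fs = 1000, seed = 3)
  cyc <- sawtooth_cycle_lengths(s)
  expect_true(all(abs(cyc - 1000 / 7) <= 1))  # integer sampling of 142.86
  sp <- spec.pgram(stats::ts(s$value, frequency = 1000), plot = FALSE,
                   taper = 0, detrend = TRUE)
  for (f in c(7, 14, 21, 28, 35)) {
    near <- sp$freq > f - 1 & sp$freq < f + 1
    away <- sp$freq > f + 1.5 & sp$freq < f + 5.5
    expect_gt(max(sp$spec[near]), 10 * max(sp$spec[away]))
  }
})

test_that("jittered sawtooth cycle frequencies match the clamped-Gaussian mean", {
  s <- gen_sawtooth(60, mean_freq = 8, freq_sigma = 5, noise_sigma = 0,
                    fs = 1000, seed = 4)
  f_cyc <- 1000 / sawtooth_cycle_lengths(s)
  # oracle: E[max(X, 1)] for X ~ N(8, 5) clamped at 1 Hz
  z <- (1 - 8) / 5
  expected <- 8 * (1 - pnorm(z)) + 1 * pnorm(z) + 5 * dnorm(z)
  expect_lt(abs(mean(f_cyc) - expected), 3 * sd(f_cyc) / sqrt(length(f_cyc)))
  expect_identical(s$value,
                   gen_sawtooth(60, 8, 5, 0, 1000, seed = 4)$value)
})

test_that("uncoupled Kuramoto oscillators keep their natural frequencies", {
  k <- simulate_kuramoto_pair(60, epsilon = 0, seed = 21)
  expect_lt(abs(mean(instantaneous_frequency(k$theta)$value) - 8), 0.1)
  expect_lt(abs(mean(instantaneous_frequency(k$gamma)$value) - 43), 0.1)
  expect_true(all(k$theta$phase > -pi & k$theta$phase <= pi))
  # phases advance on average
  expect_gt(mean(instantaneous_frequency(k$theta)$value), 0)
})

test_that("1:5 coupling pulls 8/43 Hz to 8.5/42.5 Hz but leaves 8/40 Hz untouched", {
  k <- simulate_kuramoto_pair(60, epsilon = 10, seed = 22)
  expect_lt(abs(mean(instantaneous_frequency(k$theta)$value) - 8.5), 0.25)
  expect_lt(abs(mean(instantaneous_frequency(k$gamma)$value) - 42.5), 0.25)
  k40 <- simulate_kuramoto_pair(60, epsilon = 10, mean_freq_gamma = 40,
                                seed = 23)
  expect_lt(abs(mean(instantaneous_frequency(k40$theta)$value) - 8), 0.25)
  expect_lt(abs(mean(instantaneous_frequency(k40$gamma)$value) - 40), 0.25)
  expect_error(simulate_kuramoto_pair(10, epsilon = -1), "non-negative")
  expect_error(simulate_kuramoto_pair(10, dt = 0), "positive")
})

test_that("Kuramoto runs are bit-reproducible for a fixed seed", {
  a <- simulate_kuramoto_pair(5, seed = 31)
  b <- simulate_kuramoto_pair(5, seed = 31)
  expect_identical(a$theta$phase, b$theta$phase)
  expect_identical(a$gamma$phase, b$gamma$phase)
})

test_that("frequency-estimate SE shrinks roughly as 1/sqrt(duration)", {
  est <- function(dur, seeds) {
    vapply(seeds, function(s) {
      k <- simulate_kuramoto_pair(dur, epsilon = 0, seed = s)
      mean(instantaneous_frequency(k$theta)$value)
    }, numeric(1))
  }
  sd_short <- sd(est(4, 101:125))
  sd_long <- sd(est(16, 201:225))
  # fourfold duration: expect ~2x smaller SE (wide stochastic margin)
  expect_gt(sd_short / sd_long, 1.3)
  expect_lt(sd_short / sd_long, 3.2)
})

test_that("uncoupled pairs pass a random-permutation surrogate test at calibrated rate", {
  exceed <- vapply(1:40, function(i) {
    k <- simulate_kuramoto_pair(90, epsilon = 0, mean_freq_gamma = 40,
                                seed = 900 + i)
    th <- epoch_window(k$theta, 0, 30)
    r0 <- rnm(phase_difference(th, epoch_window(k$gamma, 0, 30)))
    d <- surrogate_rnm_distribution(th, k$gamma, method = "random_permutation",
                                    n_runs = 100, seed = 950 + i)
    r0 > quantile(d$R, 0.975)
  }, logical(1))
  # nominal exceedance 2.5%; demand >= 90% non-exceedance (Monte-Carlo margin)
  expect_gte(mean(!exceed), 0.90)
})
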