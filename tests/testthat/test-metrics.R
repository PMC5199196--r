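# R_n:m, PPC, binned radial distance, phase-phase plots

test_that("phase difference is wrapped, exact for identical inputs, and checks lengths", {
  ps <- wn_phases(3, seed = 71)
  d <- phase_difference(ps$theta, ps$theta, n = 1, m = 1)
  expect_true(all(d$dphi == 0))
  expect_true(all(d$dphi > -pi & d$dphi <= pi))
  expect_error(phase_difference(ps$theta, epoch_window(ps$gamma, 0, 1)),
               "equal length")
})

test_that("rnm is 1 for constant, 0 for balanced, rotation-invariant, in [0,1]", {
  expect_equal(rnm(rep(1.3, 50)), 1)
  expect_lt(rnm(wrap_phase(seq(0, 2 * pi, length.out = 13)[-13])), 1e-12)
  set.seed(72)
  v <- runif(500, -pi, pi)
  expect_equal(rnm(v), rnm(wrap_phase(v + 2.1)), tolerance = 1e-12)
  for (i in 1:20) expect_true(rnm(runif(50, -pi, pi)) >= 0 &&
                              rnm(runif(50, -pi, pi)) <= 1)
  expect_error(rnm(numeric(0)), "empty")
})

test_that("rnm on concatenated epochs equals rnm of the pooled sample (pooling identity)", {
  set.seed(73)
  eps <- lapply(1:5, function(i) runif(200, -pi, pi))
  expect_identical(rnm(unlist(eps)), rnm(do.call(c, eps)))
  # and equals the count-weighted combination of per-epoch resultants
  zs <- vapply(eps, function(e) mean(exp(1i * e)), complex(1))
  expect_equal(rnm(unlist(eps)), Mod(mean(zs)), tolerance = 1e-12)
})

test_that("E[R] for uniform phases follows sqrt(pi)/2 / sqrt(N) within 5%", {
  set.seed(74)
  for (N in c(100, 1000, 10000)) {
    # enough replicates that the Monte-Carlo SE of the mean is ~1%
    reps <- max(2500, round(2e6 / N))
    r <- vapply(seq_len(reps), function(i) rnm(runif(N, -pi, pi)), numeric(1))
    expect_lt(abs(mean(r) / (sqrt(pi) / 2 / sqrt(N)) - 1), 0.05)
  }
})

test_that("PPC equals its O(k^2) brute-force definition and is unbiased at 0", {
  set.seed(75)
  v <- runif(50, -pi, pi)
  brute <- {
    s <- 0
    for (i in 1:49) for (j in (i + 1):50) s <- s + cos(v[i] - v[j])
    s / choose(50, 2)
  }
  expect_equal(ppc(v), brute, tolerance = 1e-12)
  expect_equal(ppc(rep(0.7, 20)), 1, tolerance = 1e-12)
  est <- vapply(1:800, function(i) ppc(runif(60, -pi, pi)), numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est)), 3 * se)
  expect_error(ppc(v, subsample_n = 1), "at least 2")
})

test_that("binned radial distance: deterministic mapping, single-bin identity, empty bins flagged", {
  ps <- wn_phases(5, seed = 76)
  lock <- ps$theta
  lock$phase <- wrap_phase(ps$theta$phase + 0.4)
  # gamma a smooth function of theta: within a 2*pi/36 bin the gamma phases
  # span one bin width, so R per bin is sinc(pi/36) > 0.99
  out <- binned_radial_distance(ps$theta, lock, n_bins = 36)
  expect_true(all(out$R > 0.99, na.rm = TRUE))
  expect_gt(sum(!is.na(out$R)), 30)
  one <- binned_radial_distance(ps$theta, ps$gamma, n_bins = 1)
  expect_equal(one$R, rnm(ps$gamma$phase))
  # confine theta to the upper half circle -> lower-half bins are empty
  half <- ps$theta
  half$phase <- abs(half$phase)
  out2 <- binned_radial_distance(half, ps$gamma, n_bins = 8)
  expect_true(any(is.na(out2$R)))
  expect_true(all(out2$n_samples[is.na(out2$R)] == 0))
})

test_that("per-bin chance R rises as bins shrink (fewer samples per bin)", {
  ps <- wn_phases(40, seed = 77)
  r5 <- mean(binned_radial_distance(ps$theta, ps$gamma, 5)$R, na.rm = TRUE)
  r80 <- mean(binned_radial_distance(ps$theta, ps$gamma, 80)$R, na.rm = TRUE)
  expect_gt(r80, r5)
})

test_that("chance R_n:m curves peak at the band-center frequency ratio", {
  curves <- lapply(1:20, function(i) {
    ps <- wn_phases(2, seed = 300 + i)
    list(s = rnm_curve(epoch_window(ps$theta, 0, 1),
                       epoch_window(ps$gamma, 0, 1)),
         f = rnm_curve(epoch_window(ps$theta, 0, 1),
                       epoch_window(trim_edges(band_phase(
                         gen_white_noise(3, 1000, seed = 300 + i),
                         bands$gamma_fast)), 0, 1)))
  })
  mean_curve <- function(key) {
    Reduce(`+`, lapply(curves, function(cv) cv[[key]]$R)) / length(curves)
  }
  expect_true(which.max(mean_curve("s")) %in% 4:6)    # theta vs slow gamma
  expect_true(which.max(mean_curve("f")) %in% 12:20)  # theta vs fast gamma
})

test_that("coupled 8/40 Hz oscillators give a global R-curve maximum at m = 5", {
  k <- simulate_kuramoto_pair(30, epsilon = 10, mean_freq_gamma = 40, seed = 78)
  cv <- rnm_curve(k$theta, k$gamma)
  expect_equal(glance(cv)$peak_m, 5L)
  expect_gt(glance(cv)$peak_R, 0.5)
})

test_that("phase-phase histograms conserve counts and flatten for independent phases", {
  ps <- wn_phases(100, seed = 79)
  pp <- phase_phase_histogram(ps$theta, ps$gamma)
  expect_equal(sum(pp$counts), nrow(ps$theta))
  expect_equal(sum(pp$smoothed), nrow(ps$theta), tolerance = 1e-9)
  expect_equal(length(pp$edges), 121)
  # independent uniform phases at large N: smoothed plot is nearly flat
  set.seed(80)
  u1 <- new_phase_series(runif(2e5, -pi, pi), 1000)
  u2 <- new_phase_series(runif(2e5, -pi, pi), 1000)
  flat <- phase_phase_histogram(u1, u2)
  expect_lt(max(flat$smoothed) / min(flat$smoothed), 1.25)
  d <- tidy(pp)
  expect_equal(nrow(d), 14400)
  expect_equal(sum(d$count), pp$N)
})

test_that("count_stripes returns m for constructed 1:m locking and nothing for noise", {
  set.seed(81)
  th <- new_phase_series(runif(5e4, -pi, pi), 1000)
  for (m in 2:5) {
    ga <- new_phase_series(wrap_phase(m * th$phase + 1), 1000)
    pp <- phase_phase_histogram(th, ga)
    expect_equal(as.integer(count_stripes(pp)), m)
  }
  u2 <- new_phase_series(runif(5e4, -pi, pi), 1000)
  ppu <- phase_phase_histogram(th, u2)
  su <- count_stripes(ppu)
  expect_lt(max(attr(su, "profile")$S), 0.05)
  empty <- phase_phase_histogram(epoch_window(th, 0, 0.01),
                                 epoch_window(u2, 0, 0.01))
  empty$counts[] <- 0
  expect_error(count_stripes(empty), "no counts")
})

test_that("drift rate recovers the 17 Hz frequency mismatch with opposite signs", {
  k <- simulate_kuramoto_pair(60, epsilon = 10, seed = 82)
  d3 <- drift_rate(phase_difference(k$theta, k$gamma, n = 1, m = 3))
  d7 <- drift_rate(phase_difference(k$theta, k$gamma, n = 1, m = 7))
  d5 <- drift_rate(phase_difference(k$theta, k$gamma, n = 1, m = 5))
  expect_lt(abs(d3 - 17), 0.6)
  expect_lt(abs(d7 + 17), 0.6)
  expect_lt(abs(d5), 0.6)
})
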