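# mock gamma phases and chance distributions

test_that("all surrogate methods preserve the gamma-phase marginal exactly", {
  ps <- wn_phases(5, seed = 91)
  ep <- epoch_window(ps$gamma, 1, 2)
  ts <- time_shift_surrogate(ps$gamma, 1, 2, seed = 1)
  rp <- random_permutation_surrogate(ps$gamma, 2, seed = 2)
  sc <- phase_scramble_surrogate(ep, seed = 3)
  expect_identical(sort(sc$phase), sort(ep$phase))
  expect_equal(nrow(ts), nrow(ep))
  expect_equal(nrow(rp), nrow(ep))
  # relocated windows come from the same session series
  expect_true(all(ts$phase %in% ps$gamma$phase))
  expect_true(all(rp$phase %in% ps$gamma$phase))
})

test_that("a zero time shift reproduces the original epoch; margins are enforced", {
  ps <- wn_phases(3, seed = 92)
  ep <- epoch_window(ps$gamma, 0.5, 1)
  expect_identical(time_shift_surrogate(ps$gamma, 0.5, 1, shift_ms = 0)$phase,
                   ep$phase)
  s <- time_shift_surrogate(ps$gamma, 0.5, 1, seed = 4)
  expect_true(attr(s, "shift_ms") >= 1 && attr(s, "shift_ms") <= 200)
  expect_error(time_shift_surrogate(ps$gamma, 2.5, 1, shift_ms = 200),
               "does not extend")
})

test_that("random permutation draws contiguous windows and can avoid the original", {
  ps <- wn_phases(3, seed = 93)
  short <- epoch_window(ps$gamma, 0, 1.001)  # epoch + 1 sample
  for (i in 1:5) {
    w <- random_permutation_surrogate(short, 1, seed = i)
    expect_true(attr(w, "start_s") %in% c(0, 1 / 1000))
  }
  w2 <- random_permutation_surrogate(short, 1, avoid_start_s = 0, seed = 9)
  expect_equal(attr(w2, "start_s"), 1 / 1000)
  expect_error(random_permutation_surrogate(epoch_window(ps$gamma, 0, 1), 1),
               "longer than")
})

test_that("scrambling a length-1 series is the identity", {
  one <- new_phase_series(0.3, 1000)
  expect_identical(phase_scramble_surrogate(one, seed = 1)$phase, 0.3)
})

test_that("scrambled phases concentrate R at the uniform chance level", {
  ps <- wn_phases(3, seed = 94)
  th <- epoch_window(ps$theta, 0, 1)
  d <- surrogate_rnm_distribution(th, ps$gamma, epoch_start_s = 0,
                                  method = "phase_scramble", n_runs = 100,
                                  seed = 5)
  expect_lt(abs(mean(d$R) / (sqrt(pi) / 2 / sqrt(1000)) - 1), 0.1)
})

test_that("original chance R matches continuity-preserving single runs but exceeds scrambles", {
  ps <- wn_phases(35, seed = 95)
  orig <- epoch_rnm(ps$theta, ps$gamma, 1, 30)
  th <- epoch_window(ps$theta, 0, 1)
  shift <- surrogate_rnm_distribution(th, ps$gamma, method = "time_shift",
                                      n_runs = 100, seed = 6)
  scram <- surrogate_rnm_distribution(th, ps$gamma, method = "phase_scramble",
                                      n_runs = 100, seed = 7)
  expect_gt(t.test(orig, shift$R)$p.value, 0.01)        # indistinguishable
  expect_lt(test_rnm(orig, scram$R)$p_value, 1e-6)      # false positive
})

test_that("time-shift and random-permutation single-run distributions agree", {
  # within one session, runs of a given method are mutually correlated, so
  # draw one surrogate R of each kind per independent session
  draws <- vapply(1:60, function(i) {
    ps <- wn_phases(4, seed = 9600 + i)
    th <- epoch_window(ps$theta, 0, 1)
    c(ts = surrogate_rnm_distribution(th, ps$gamma, method = "time_shift",
                                      n_runs = 1, seed = 8)$R,
      rp = surrogate_rnm_distribution(th, ps$gamma,
                                      method = "random_permutation",
                                      n_runs = 1, seed = 9)$R)
  }, c(ts = 0, rp = 0))
  expect_gt(t.test(draws["ts", ], draws["rp", ])$p.value, 0.01)
  expect_gt(ks.test(draws["ts", ], draws["rp", ])$p.value, 0.01)
})

test_that("pooling surrogate runs deflates chance R (epoch-length equivalence)", {
  ps <- wn_phases(40, seed = 97)
  th <- epoch_window(ps$theta, 0, 1)
  sing <- surrogate_rnm_distribution(th, ps$gamma, method = "time_shift",
                                     n_runs = 10, seed = 10)
  pool <- surrogate_rnm_distribution(th, ps$gamma, method = "time_shift",
                                     mode = "pooled", n_runs = 5,
                                     n_pool = 100, seed = 11)
  expect_lt(max(pool$R), min(sing$R))
  # pooling identity: a pooled draw equals one R over the concatenated runs
  set.seed(12)
  parts <- lapply(1:4, function(i) runif(300, -pi, pi))
  expect_identical(rnm(unlist(parts)), rnm(c(parts[[1]], parts[[2]],
                                             parts[[3]], parts[[4]])))
})

test_that("test_rnm reports t, p, percentile; identical groups give p = 0.5", {
  set.seed(13)
  v <- runif(30)
  out <- test_rnm(v, v)
  expect_equal(out$p_value, 0.5)
  expect_equal(out$statistic, 0)
  expect_warning(test_rnm(rep(1, 5), rep(1, 5)), "zero variance")
  expect_error(test_rnm(1, 1:5), "at least 2")
})

test_that("coupled oscillators are detected against single-run surrogates, uncoupled are not", {
  run_cond <- function(eps, seed) {
    k <- simulate_kuramoto_pair(330, epsilon = eps, mean_freq_gamma = 40,
                                seed = seed)
    orig <- epoch_rnm(k$theta, k$gamma, 30, 10)
    surr <- surrogate_rnm_distribution(epoch_window(k$theta, 0, 30), k$gamma,
                                       method = "random_permutation",
                                       n_runs = 30, seed = seed + 1)
    test_rnm(orig, surr$R)
  }
  coupled <- run_cond(10, 141)
  uncoupled <- run_cond(0, 151)
  expect_lt(coupled$p_value, 1e-3)
  expect_gt(coupled$percentile, 99)
  expect_gt(uncoupled$p_value, 0.01)
})

test_that("sawtooth asymmetry yields artifactual coupling, stronger vs random permutation", {
  e <- run_experiment("sawtooth_artifact",
                      params = list(n_epochs = 20, epoch_len_s = 20), seed = 11)
  tt <- e$tables$tests
  rp <- tt[tt$method == "random_permutation", ]
  ts <- tt[tt$method == "time_shift", ]
  expect_lt(rp$p_value, 1e-3)
  expect_gt(rp$statistic, ts$statistic)  # time shift is less sensitive here
  env <- e$tables$envelope_by_phase
  expect_equal(nrow(env), 18)
  expect_gt(max(env$mean_envelope) / min(env$mean_envelope), 1.5)
})
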