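# surrogate (mock) gamma-phase construction and chance distributions
#
# All three procedures leave the theta phases untouched and mock the gamma
# phases; each preserves the marginal distribution of gamma phase exactly
# (they only relocate or reorder samples). Time Shift and Random
# Permutation preserve phase continuity; Phase Scramble deliberately does
# not, which makes it far too liberal as a control.

#' Time-shift surrogate gamma epoch
#'
#' Takes the gamma phases from a window displaced forward by an integer
#' shift drawn uniformly from `shift_range_ms` (1-200 ms by default; set
#' `symmetric = TRUE` to allow negative shifts). The session must extend
#' beyond the epoch by at least the maximum shift.
#'
#' @param gamma_session phase-series tibble for the whole session.
#' @param epoch_start_s start of the original epoch, seconds from the first
#'   session sample.
#' @param epoch_len_s epoch duration, seconds.
#' @param shift_range_ms integer shift bounds in milliseconds.
#' @param shift_ms fixed shift (test hook; 0 returns the original epoch).
#' @param symmetric allow negative shifts.
#' @param seed optional integer.
#' @return a phase-series tibble of the epoch length.
#' @export
time_shift_surrogate <- function(gamma_session, epoch_start_s, epoch_len_s,
                                 shift_range_ms = c(1, 200), shift_ms = NULL,
                                 symmetric = FALSE, seed = NULL) {
  assert_phase(gamma_session)
  fs <- signal_fs(gamma_session)
  i0 <- round(epoch_start_s * fs) + 1
  len <- round(epoch_len_s * fs)
  if (is.null(shift_ms)) {
    shift_ms <- with_seed_if(seed, {
      s <- sample(shift_range_ms[1]:shift_range_ms[2], 1)
      if (symmetric && sample(c(TRUE, FALSE), 1)) -s else s
    })
  }
  k <- round(shift_ms * fs / 1000)
  j0 <- i0 + k
  if (j0 < 1 || j0 + len - 1 > nrow(gamma_session)) {
    abort("session does not extend far enough beyond the epoch for this shift")
  }
  out <- gamma_session[j0:(j0 + len - 1), ]
  attr(out, "fs") <- fs
  attr(out, "shift_ms") <- shift_ms
  class(out) <- class(gamma_session)
  out
}

#' Random-permutation surrogate gamma epoch
#'
#' Extracts a contiguous gamma-phase window of the epoch length at a
#' uniformly drawn start anywhere in the session (excluding the exact
#' original start, if given). Continuity is preserved; the window may
#' overlap the original epoch.
#'
#' @param gamma_session phase-series tibble for the whole session.
#' @param epoch_len_s epoch duration, seconds.
#' @param avoid_start_s original epoch start to exclude (seconds), or `NULL`.
#' @param seed optional integer.
#' @return a phase-series tibble of the epoch length.
#' @export
random_permutation_surrogate <- function(gamma_session, epoch_len_s,
                                         avoid_start_s = NULL, seed = NULL) {
  assert_phase(gamma_session)
  fs <- signal_fs(gamma_session)
  len <- round(epoch_len_s * fs)
  n <- nrow(gamma_session)
  if (n <= len) abort("session must be longer than the epoch")
  starts <- 1:(n - len + 1)
  if (!is.null(avoid_start_s)) starts <- setdiff(starts, round(avoid_start_s * fs) + 1)
  j0 <- with_seed_if(seed, starts[sample.int(length(starts), 1)])
  out <- gamma_session[j0:(j0 + len - 1), ]
  attr(out, "fs") <- fs
  attr(out, "start_s") <- (j0 - 1) / fs
  class(out) <- class(gamma_session)
  out
}

#' Phase-scramble surrogate
#'
#' Randomly shuffles the timestamps of the gamma phase series, destroying
#' phase continuity. Included because it has been used in the literature:
#' it makes the surrogate phase differences effectively independent, which
#' deflates chance R values and produces false-positive coupling even on
#' white noise.
#'
#' @param gamma phase-series tibble (the epoch itself).
#' @param seed optional integer.
#' @return a phase-series tibble with the phases in permuted order.
#' @export
phase_scramble_surrogate <- function(gamma, seed = NULL) {
  assert_phase(gamma)
  out <- gamma
  out$phase <- with_seed_if(seed, sample(gamma$phase))
  out
}

#' Chance distribution of R_n:m from surrogate runs
#'
#' Builds the surrogate R_n:m distribution for an original theta/gamma
#' epoch. With `mode = "single_run"` each surrogate run yields one R value
#' (`n_runs` values) -- the statistically valid chance distribution. With
#' `mode = "pooled"` the phase differences of `n_pool` runs are pooled
#' before one R is computed per draw; pooling is equivalent to lengthening
#' the epoch `n_pool`-fold, so pooled chance values are systematically
#' deflated and must not be used for inference.
#'
#' @param theta phase-series tibble for the original epoch (stays intact).
#' @param gamma_session phase-series tibble for the whole session the epoch
#'   was cut from.
#' @param epoch_start_s start of the original epoch within the session (s).
#' @param n,m acceleration factors.
#' @param method `"time_shift"`, `"random_permutation"` or `"phase_scramble"`.
#' @param mode `"single_run"` or `"pooled"`.
#' @param n_runs number of R values returned (300 is the conventional
#'   single-run count; 100-run pools are conventional for pooled mode).
#' @param n_pool surrogate runs pooled per draw in pooled mode.
#' @param shift_range_ms time-shift bounds, ms.
#' @param seed master seed; per-run draws derive from it deterministically.
#' @return tibble (`run`, `R`) with attributes `method` and `mode`.
#' @export
surrogate_rnm_distribution <- function(theta, gamma_session, epoch_start_s = 0,
                                       n = 1, m = 5,
                                       method = c("time_shift",
                                                  "random_permutation",
                                                  "phase_scramble"),
                                       mode = c("single_run", "pooled"),
                                       n_runs = 300, n_pool = 100,
                                       shift_range_ms = c(1, 200),
                                       seed = NULL) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  assert_phase(theta)
  fs <- signal_fs(theta)
  len_s <- nrow(theta) / fs
  total <- if (mode == "pooled") n_runs * n_pool else n_runs
  with_seed_if(seed, {
    one_dphi <- function() {
      g <- switch(method,
        time_shift = time_shift_surrogate(gamma_session, epoch_start_s, len_s,
                                          shift_range_ms = shift_range_ms),
        random_permutation = random_permutation_surrogate(
          gamma_session, len_s, avoid_start_s = epoch_start_s),
        phase_scramble = phase_scramble_surrogate(
          epoch_window(gamma_session, epoch_start_s, len_s))
      )
      wrap_phase(n * g$phase - m * theta$phase)
    }
    if (mode == "single_run") {
      R <- purrr::map_dbl(seq_len(n_runs), function(i) rnm(one_dphi()))
    } else {
      R <- purrr::map_dbl(seq_len(n_runs), function(i) {
        rnm(unlist(purrr::map(seq_len(n_pool), function(j) one_dphi())))
      })
    }
    out <- tibble(run = seq_len(n_runs), R = R)
    attr(out, "method") <- method
    attr(out, "mode") <- mode
    out
  })
}

#' One-tailed test of original R values against a chance distribution
#'
#' Two-sample t-test of the alternative that original R_n:m values exceed
#' the surrogate values, plus the percentile of the mean original value
#' within the surrogate distribution.
#'
#' @param original numeric vector of original R values (or tibble with `R`).
#' @param surrogate numeric vector of surrogate R values (or tibble with `R`).
#' @param alternative passed to [stats::t.test()]; default `"greater"`.
#' @return one-row tibble: `statistic`, `df`, `p_value`, `percentile`,
#'   `mean_original`, `mean_surrogate`, `degenerate` (TRUE when both groups
#'   have zero variance, in which case the t-test is undefined).
#' @export
test_rnm <- function(original, surrogate, alternative = "greater") {
  ov <- if (is.data.frame(original)) original$R else as.numeric(original)
  sv <- if (is.data.frame(surrogate)) surrogate$R else as.numeric(surrogate)
  if (length(ov) < 2 || length(sv) < 2) abort("need at least 2 values per group")
  degenerate <- sd(ov) == 0 && sd(sv) == 0
  if (degenerate) {
    warn("both groups have zero variance; t-test undefined")
    tt <- list(statistic = NA_real_, parameter = NA_real_, p.value = NA_real_)
  } else {
    tt <- t.test(ov, sv, alternative = alternative)
  }
  tibble(
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    percentile = mean(sv < mean(ov)) * 100,
    mean_original = mean(ov), mean_surrogate = mean(sv),
    degenerate = degenerate
  )
}
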