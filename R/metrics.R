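# n:m phase-locking statistics

#' Accelerated phase difference
#'
#' Computes `delta_phi = n * phi_gamma - m * phi_theta`, wrapped to
#' `(-pi, pi]`, per sample. n:m phase-locking means this difference is
#' concentrated around a preferred value rather than uniform.
#'
#' @param theta,gamma phase-series tibbles of equal length and sampling rate
#'   (the slow and fast oscillation respectively).
#' @param n,m integer acceleration factors (gamma accelerated `n` times,
#'   theta `m` times).
#' @return an `nm_phasediff` tibble (`time`, `dphi`) with attributes `n`,
#'   `m`, `fs` and `N = nrow`.
#' @export
phase_difference <- function(theta, gamma, n = 1, m = 5) {
  assert_phase(theta); assert_phase(gamma)
  check_scalar(n, "n", positive = TRUE, integerish = TRUE)
  check_scalar(m, "m", positive = TRUE, integerish = TRUE)
  if (nrow(theta) != nrow(gamma)) abort("phase series must have equal length")
  fs <- signal_fs(theta)
  if (!isTRUE(all.equal(fs, signal_fs(gamma)))) {
    abort("phase series must share the sampling rate")
  }
  out <- tibble(time = theta$time,
                dphi = wrap_phase(n * gamma$phase - m * theta$phase))
  attr(out, "fs") <- fs
  attr(out, "n") <- n
  attr(out, "m") <- m
  class(out) <- c("nm_phasediff", class(out))
  out
}

#' Mean resultant length R_n:m
#'
#' The n:m phase-locking statistic: modulus of the mean unit vector of the
#' phase differences, `R = |mean(exp(i * dphi))|`. 1 for a constant phase
#' difference (perfect locking), 0 for a uniform one. Note the strong
#' positive small-sample bias: for N independent uniform phases
#' `E[R] ~ sqrt(pi)/2 * N^(-1/2)`, so R values are only interpretable
#' against surrogate values computed on epochs of the same length.
#'
#' @param d an `nm_phasediff` tibble from [phase_difference()], or a bare
#'   numeric vector of angles (radians).
#' @return scalar in `[0, 1]`.
#' @export
rnm <- function(d) {
  v <- if (is.data.frame(d)) {
    if (!"dphi" %in% names(d)) abort("expected a phase-difference tibble with `dphi`")
    d$dphi
  } else {
    as.numeric(d)
  }
  if (length(v) < 1) abort("empty phase-difference series")
  Mod(mean(exp(1i * v)))
}

#' R_n:m over a grid of m
#'
#' Computes the phase-locking curve R_n:m for fixed `n` and a range of `m`
#' (conventionally n = 1, m = 1..25). On any pair of band-filtered signals
#' -- including filtered white noise -- the curve shows a chance bump
#' peaking near the ratio of the band center frequencies, so a bump alone
#' is not evidence of coupling.
#'
#' @param theta,gamma phase-series tibbles.
#' @param n fixed acceleration of the gamma phase.
#' @param m_range integer vector of theta accelerations.
#' @return an `nm_curve` tibble (`n`, `m`, `R`) with attribute
#'   `epoch_length_s`.
#' @export
rnm_curve <- function(theta, gamma, n = 1, m_range = 1:25) {
  if (length(m_range) < 1) abort("`m_range` must be non-empty")
  fs <- signal_fs(theta)
  R <- purrr::map_dbl(m_range, function(m) {
    rnm(wrap_phase(n * gamma$phase - m * theta$phase))
  })
  out <- tibble(n = n, m = as.integer(m_range), R = R)
  attr(out, "epoch_length_s") <- nrow(theta) / fs
  class(out) <- c("nm_curve", class(out))
  out
}

#' Pairwise phase consistency
#'
#' Bias-free circular concentration: the mean cosine of the phase
#' difference over all pairs of samples, equal in closed form to
#' `(k * R^2 - 1) / (k - 1)` for `k` samples. Unlike R, its expectation is
#' 0 for uniform phases at any sample size. PPC assumes independent
#' observations, so the phase differences are subsampled first -- either
#' randomly or at a fixed spacing longer than one cycle of the fast band.
#'
#' @param d `nm_phasediff` tibble or numeric vector of angles.
#' @param subsample_n number of samples to draw (`>= 2`); `NULL` uses all.
#' @param mode `"random"` (seeded random subsample) or `"spaced"` (every
#'   `spacing_s` seconds).
#' @param spacing_s spacing for `mode = "spaced"`; defaults to 25 ms (one
#'   slow-gamma cycle).
#' @param seed optional integer for the random subsample.
#' @return scalar in `[-1, 1]`.
#' @export
ppc <- function(d, subsample_n = NULL, mode = c("random", "spaced"),
                spacing_s = 0.025, seed = NULL) {
  mode <- match.arg(mode)
  v <- if (is.data.frame(d)) d$dphi else as.numeric(d)
  if (mode == "spaced" && is.data.frame(d)) {
    k <- max(1, round(spacing_s * signal_fs(d)))
    v <- v[seq(1, length(v), by = k)]
  }
  if (!is.null(subsample_n)) {
    if (subsample_n < 2) abort("`subsample_n` must be at least 2")
    if (subsample_n > length(v)) abort("`subsample_n` exceeds the series length")
    if (mode == "random") {
      v <- with_seed_if(seed, sample(v, subsample_n))
    } else {
      v <- v[seq(1, length(v), length.out = subsample_n)]
    }
  }
  k <- length(v)
  if (k < 2) abort("PPC needs at least 2 samples")
  R <- rnm(v)
  (k * R^2 - 1) / (k - 1)
}

#' Mean resultant length of gamma phases within theta-phase bins
#'
#' Assigns samples to `n_bins` equal theta-phase bins and computes the mean
#' resultant length of the gamma phases falling in each bin. Note the
#' mechanical dependence on bin count: more bins means fewer samples per
#' bin and hence higher chance R.
#'
#' @param theta,gamma phase-series tibbles of equal length.
#' @param n_bins number of theta-phase bins.
#' @return tibble (`bin`, `theta_center`, `n_samples`, `R`); `R` is `NA`
#'   (flagged, not zero) for empty bins.
#' @export
binned_radial_distance <- function(theta, gamma, n_bins = 20) {
  check_scalar(n_bins, "n_bins", positive = TRUE, integerish = TRUE)
  if (nrow(theta) != nrow(gamma)) abort("phase series must have equal length")
  idx <- bin_index(theta$phase, n_bins)
  centers <- -pi + (seq_len(n_bins) - 0.5) * 2 * pi / n_bins
  purrr::map_dfr(seq_len(n_bins), function(b) {
    g <- gamma$phase[idx == b]
    tibble(bin = b, theta_center = centers[b], n_samples = length(g),
           R = if (length(g) == 0) NA_real_ else rnm(g))
  })
}

# map wrapped phases in (-pi, pi] to 1..n_bins (half-open bins [lo, hi))
bin_index <- function(p, n_bins) {
  pmin(pmax(ceiling((p + pi) / (2 * pi) * n_bins), 1L), as.integer(n_bins))
}

#' Mean drift rate of the accelerated phase difference
#'
#' Mean slope of the unwrapped phase difference, in Hz. Zero (up to noise)
#' when the oscillators are n:m locked; otherwise the frequency mismatch
#' `n*f_gamma - m*f_theta` -- e.g. the 1:5-coupled pair probed at m = 3 or
#' m = 7 precesses at +/- 17 Hz.
#'
#' @param d an `nm_phasediff` tibble from [phase_difference()].
#' @return drift rate in Hz (signed).
#' @export
drift_rate <- function(d) {
  fs <- signal_fs(d)
  mean(wrap_phase(diff(d$dphi))) * fs / (2 * pi)
}
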