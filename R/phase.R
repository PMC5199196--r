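# instantaneous-phase extraction and small signal utilities

# analytic signal via FFT: zero out negative frequencies, double positives
analytic_signal <- function(v) {
  n <- length(v)
  X <- fft(v)
  mult <- numeric(n)
  if (n %% 2 == 0) {
    mult[c(1, n / 2 + 1)] <- 1
    mult[2:(n / 2)] <- 2
  } else {
    mult[1] <- 1
    mult[2:((n + 1) / 2)] <- 2
  }
  fft(X * mult, inverse = TRUE) / n
}

#' Instantaneous phase and amplitude via the Hilbert transform
#'
#' Computes the analytic signal by FFT; the phase is its argument (wrapped
#' to `(-pi, pi]`, 0 at the peaks of a cosine, trough at +/- pi) and the
#' envelope its modulus. The input should already be band-limited
#' (see [bandpass()]); the phase of a broadband signal is not meaningful.
#'
#' @param x a band-limited signal tibble.
#' @return a phase-series tibble (`time`, `phase`, `envelope`).
#' @export
hilbert_phase <- function(x) {
  assert_signal(x)
  v <- x$value
  if (sd(v) == 0) abort("constant signal: instantaneous phase is undefined")
  a <- analytic_signal(v)
  ps <- new_phase_series(Arg(a), signal_fs(x), envelope = Mod(a),
                         t0 = x$time[1])
  attr(ps, "filter") <- attr(x, "filter")
  ps
}

#' Theta phase by waveform-landmark interpolation
#'
#' Estimates phase from waveform landmarks instead of the Hilbert
#' transform: each cycle is anchored at four points -- peak (phase 0),
#' descending zero-crossing (pi/2), trough (pi), ascending zero-crossing
#' (3*pi/2 = -pi/2) -- and phase is interpolated linearly between
#' consecutive anchors, so it advances faster on the shorter flank of an
#' asymmetric wave. Landmarks are located on the signal filtered in
#' `landmark_band`; peak/trough positions are refined on a lightly smoothed
#' copy of the raw trace.
#'
#' @param x raw signal tibble.
#' @param landmark_band band for landmark detection (default 4-20 Hz, wide
#'   enough to retain theta asymmetry).
#' @param refine_ms smoothing window (ms) for peak/trough refinement on the
#'   raw trace; `0` disables refinement.
#' @return a phase-series tibble (`time`, `phase`).
#' @export
waveform_theta_phase <- function(x, landmark_band = band(4, 20), refine_ms = 10) {
  assert_signal(x)
  fs <- signal_fs(x)
  xf <- bandpass(x, as_band(landmark_band))
  v <- xf$value
  n <- length(v)

  # fractional zero-crossing positions and their direction
  s <- sign(v)
  ic <- which(s[-n] * s[-1] < 0)
  if (length(ic) < 5) abort("too few cycles detected for interpolated phase")
  frac <- ic + v[ic] / (v[ic] - v[ic + 1])
  ascending <- v[ic] < 0

  # smoothed raw trace for extremum refinement
  vr <- x$value
  k <- max(1, round(refine_ms / 1000 * fs))
  if (k > 1) {
    sm <- stats::filter(vr, rep(1 / k, k), sides = 2)
    vr <- ifelse(is.na(sm), vr, as.numeric(sm))
  }

  # events: alternating zero-crossings with an extremum between each pair
  ev_pos <- numeric(0)
  ev_phase <- numeric(0)  # cumulative phase on a quarter-cycle lattice
  cum <- 0
  for (j in seq_along(ic)[-1]) {
    if (ascending[j] == ascending[j - 1]) next  # spurious double crossing
    lo <- ceiling(frac[j - 1]); hi <- floor(frac[j])
    if (hi <= lo) next
    seg <- lo:hi
    ext <- if (ascending[j - 1]) seg[which.max(vr[seg])] else seg[which.min(vr[seg])]
    # ascending crossing (-pi/2) -> peak (0) -> descending (pi/2) -> trough (pi)
    ph0 <- if (ascending[j - 1]) -pi / 2 else pi / 2
    base <- 2 * pi * cum
    ev_pos <- c(ev_pos, frac[j - 1], ext)
    ev_phase <- c(ev_phase, base + ph0, base + ph0 + pi / 2)
    if (!ascending[j - 1]) cum <- cum + 1  # full cycle completed at trough->asc
  }
  if (length(ev_pos) < 8) abort("too few cycles detected for interpolated phase")
  # enforce strictly increasing anchors
  keep <- c(TRUE, diff(ev_pos) > 0)
  ev_pos <- ev_pos[keep]; ev_phase <- ev_phase[keep]

  idx <- seq_len(n)
  ph <- approx(ev_pos, ev_phase, xout = idx, rule = 1)$y
  # extrapolate edges with the first/last inter-anchor slope
  sl1 <- (ev_phase[2] - ev_phase[1]) / (ev_pos[2] - ev_pos[1])
  sl2 <- (ev_phase[length(ev_phase)] - ev_phase[length(ev_phase) - 1]) /
         (ev_pos[length(ev_pos)] - ev_pos[length(ev_pos) - 1])
  before <- idx < ev_pos[1]; after <- idx > ev_pos[length(ev_pos)]
  ph[before] <- ev_phase[1] + (idx[before] - ev_pos[1]) * sl1
  ph[after] <- ev_phase[length(ev_phase)] + (idx[after] - ev_pos[length(ev_pos)]) * sl2
  new_phase_series(wrap_phase(ph), fs, t0 = x$time[1])
}

#' Instantaneous frequency from a phase series
#'
#' Forward difference of the unwrapped phase times `fs / (2*pi)`, in Hz.
#'
#' @param ps a phase-series tibble.
#' @return a signal tibble (`time`, `value` = frequency in Hz) with one
#'   fewer row than `ps`.
#' @export
instantaneous_frequency <- function(ps) {
  assert_phase(ps)
  fs <- signal_fs(ps)
  f <- wrap_phase(diff(ps$phase)) * fs / (2 * pi)
  new_signal(f, fs, t0 = ps$time[1])
}

#' Subsample a phase series
#'
#' Retains every k-th sample, `k = round(period_s * fs)`. Subsampling with
#' a period longer than one cycle of the filtered band breaks the
#' statistical dependence between neighboring phase samples that the filter
#' imposes; chance R_n:m bumps disappear under such subsampling.
#'
#' @param ps a phase-series tibble.
#' @param period_s new sampling period in seconds (>= `1/fs`).
#' @return the subsampled phase series, with `fs` updated to `fs / k`.
#' @export
subsample_phase <- function(ps, period_s) {
  assert_phase(ps)
  fs <- signal_fs(ps)
  k <- round(period_s * fs)
  if (k < 1) abort("`period_s` is shorter than one sample")
  out <- ps[seq(1, nrow(ps), by = k), ]
  attr(out, "fs") <- fs / k
  attr(out, "subsample_k") <- k
  class(out) <- class(ps)
  out
}

#' Current-source density from three adjacent channels
#'
#' Second spatial derivative `-A + 2B - C` of LFPs recorded at adjacent,
#' equally spaced probe sites; localizes transmembrane current relative to
#' the volume-conducted potential.
#'
#' @param a,b,c signal tibbles of equal length and sampling rate.
#' @return a signal tibble.
#' @export
csd <- function(a, b, c) {
  assert_signal(a); assert_signal(b); assert_signal(c)
  if (nrow(a) != nrow(b) || nrow(b) != nrow(c)) {
    abort("channels must have equal length")
  }
  fsa <- signal_fs(a)
  if (!isTRUE(all.equal(fsa, signal_fs(b))) ||
      !isTRUE(all.equal(fsa, signal_fs(c)))) {
    abort("channels must share the sampling rate")
  }
  new_signal(-a$value + 2 * b$value - c$value, fsa, t0 = a$time[1])
}

#' Oscillatory-burst mask from an amplitude envelope
#'
#' A burst is defined as the envelope exceeding its mean by
#' `threshold_sd` standard deviations, statistics taken over the whole
#' analyzed epoch (default 2 SD).
#'
#' @param envelope numeric envelope vector, or a phase-series tibble with
#'   an `envelope` column (as returned by [hilbert_phase()]).
#' @param threshold_sd threshold in SD units above the mean.
#' @return logical vector, `TRUE` during bursts.
#' @export
burst_mask <- function(envelope, threshold_sd = 2) {
  if (is.data.frame(envelope)) {
    if (!"envelope" %in% names(envelope)) {
      abort("phase series has no `envelope` column")
    }
    envelope <- envelope$envelope
  }
  if (any(envelope < 0)) abort("envelope must be non-negative")
  envelope > mean(envelope) + threshold_sd * sd(envelope)
}

#' Modal consecutive-sample phase step
#'
#' Histograms the wrapped phase difference between consecutive samples
#' (default bin width 0.01 rad, bins centered on multiples of the width)
#' and returns the modal bin center. For band-filtered signals -- even
#' white noise -- the distribution concentrates near `2*pi*f_c/fs`, the
#' step of a sinusoid at the filter center frequency: this is the
#' filtering-induced sinusoidality that creates chance n:m phase-locking.
#'
#' @param ps a phase-series tibble.
#' @param bin_width histogram bin width in radians.
#' @return modal bin center, radians.
#' @export
phase_step_mode <- function(ps, bin_width = 0.01) {
  assert_phase(ps)
  d <- wrap_phase(diff(ps$phase))
  ctr <- round(d / bin_width)
  tab <- table(ctr)
  as.numeric(names(tab)[which.max(tab)]) * bin_width
}
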