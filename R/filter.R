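# zero-phase band-pass filtering
#
# Default design follows the standard EEG protocol: a least-squares
# linear-phase FIR whose order is three times the sampling rate divided by
# the low cutoff, applied forward and then backward so the net phase
# response is zero. Transition bands span 15% of each cutoff.

# least-squares linear-phase FIR band-pass (Type I: even order, symmetric).
# Minimizes the integrated squared error of the amplitude response against a
# desired response of 1 on [low, high] and 0 outside the transition bands
# (transitions are don't-care). Closed-form normal equations in the cosine
# basis A(w) = a0 + sum a_k cos(kw).
fir_ls_design <- function(order, low, high, fs, trans = 0.15) {
  if (order %% 2 != 0) abort("FIR order must be even (Type I)")
  M <- order / 2
  nyq <- fs / 2
  bands <- rbind(
    c(0, (1 - trans) * low / nyq * pi, 0),
    c(low / nyq * pi, high / nyq * pi, 1),
    c(min((1 + trans) * high / nyq, 1) * pi, pi, 0)
  )
  k <- 0:M
  intcos <- function(nn, w1, w2) ifelse(nn == 0, w2 - w1,
                                        (sin(nn * w2) - sin(nn * w1)) / nn)
  Q <- matrix(0, M + 1, M + 1)
  b <- numeric(M + 1)
  dif <- abs(outer(k, k, "-")); sm <- outer(k, k, "+")
  for (r in seq_len(nrow(bands))) {
    w1 <- bands[r, 1]; w2 <- bands[r, 2]; d <- bands[r, 3]
    Q <- Q + 0.5 * (intcos(dif, w1, w2) + intcos(sm, w1, w2))
    if (d != 0) b <- b + d * intcos(k, w1, w2)
  }
  a <- solve(Q, b)
  c(rev(a[-1] / 2), a[1], a[-1] / 2)
}

# zero-phase FIR filtering: mirror-pad, convolve with conv(h, rev(h))
# (forward pass then time-reversed pass), trim the pads. Equivalent to
# filtfilt with reflection padding of one filter length.
fir_filtfilt <- function(x, h) {
  nh <- length(h)
  n <- length(x)
  pad <- nh
  if (n <= pad + 1) abort("epoch too short for the filter order")
  xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
          2 * x[n] - rev(x[(n - pad):(n - 1)]))
  g <- fft_conv(h, rev(h))
  y <- fft_conv(xp, g)
  y[(pad + nh):(pad + nh + n - 1)]
}

#' Band-pass filter a signal with zero phase distortion
#'
#' Default (`method = "fir"`): least-squares linear-phase FIR of order
#' `3 * fs / low` (rounded up to even), transition bands 15% of each
#' cutoff, applied forward and backward. Alternatives: a Butterworth IIR
#' (via \pkg{signal}, forward-backward) and convolution with a complex
#' Morlet wavelet centered on the band. The output has the same length as
#' the input; edge transients extend roughly one filter length, so trim
#' session edges (see [trim_edges()]) before phase-based analyses.
#'
#' @param x signal tibble.
#' @param band a [band()] object or `c(low, high)` in Hz.
#' @param method `"fir"` (default), `"butter"`, or `"wavelet"`.
#' @param order filter order; default `3 * fs / low` rounded up to even for
#'   FIR, 4 for Butterworth. Ignored for wavelet.
#' @param trans FIR transition-band fraction of each cutoff.
#' @param wavelet_cycles width of the Morlet wavelet, in cycles of the band
#'   center frequency.
#' @return a filtered signal tibble; attributes record the band, method and
#'   order (`attr(x, "filter")`).
#' @export
bandpass <- function(x, band, method = c("fir", "butter", "wavelet"),
                     order = NULL, trans = 0.15, wavelet_cycles = 7) {
  assert_signal(x)
  method <- match.arg(method)
  band <- as_band(band)
  fs <- signal_fs(x)
  if (band$high >= fs / 2) abort("band must lie below the Nyquist rate")
  v <- x$value
  if (method == "fir") {
    if (is.null(order)) {
      order <- 3 * floor(fs / band$low)
      if (order %% 2 == 1) order <- order + 1
    }
    if (length(v) <= 3 * order) {
      abort(sprintf(
        "epoch too short: %d samples for FIR order %d (need > 3 * order)",
        length(v), order))
    }
    h <- fir_ls_design(order, band$low, band$high, fs, trans)
    out <- fir_filtfilt(v, h)
  } else if (method == "butter") {
    if (is.null(order)) order <- 4
    bt <- signal::butter(order, c(band$low, band$high) / (fs / 2), type = "pass")
    out <- signal::filtfilt(bt, v)
  } else {
    # complex Morlet convolution; the real part is the band-passed signal
    order <- NA_integer_
    sd_t <- wavelet_cycles / (2 * pi * band$center)
    tt <- seq(-4 * sd_t, 4 * sd_t, by = 1 / fs)
    w <- exp(2i * pi * band$center * tt) * exp(-tt^2 / (2 * sd_t^2))
    w <- w / sum(abs(w))
    re <- fft_conv(v, Re(w))
    im <- fft_conv(v, Im(w))
    half <- (length(tt) - 1) / 2
    out <- 2 * re[(half + 1):(half + length(v))]
    attr(out, "imag") <- 2 * im[(half + 1):(half + length(v))]
  }
  y <- new_signal(as.numeric(out), fs, t0 = x$time[1])
  attr(y, "filter") <- list(method = method, band = band, order = order,
                            trans = if (method == "fir") trans else NA_real_)
  if (method == "wavelet") attr(y, "analytic_imag") <- attr(out, "imag")
  y
}
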