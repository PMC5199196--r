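# synthetic signal generators: white noise, sinusoids, jittered sawtooth
# waves, and coupled Kuramoto phase-oscillator pairs

#' Gaussian white noise
#'
#' I.i.d. standard-normal samples; the canonical negative control for
#' phase-phase coupling, since white noise has a flat spectrum and no
#' structured phase relationship between frequency bands.
#'
#' @param duration_s duration in seconds.
#' @param fs sampling rate, Hz.
#' @param seed optional integer; fixing it makes the draw bit-reproducible
#'   without touching the global RNG stream.
#' @return a signal tibble (`time`, `value`) with `fs` attribute.
#' @examples
#' x <- gen_white_noise(1, fs = 1000, seed = 1)
#' @export
gen_white_noise <- function(duration_s, fs = 1000, seed = NULL) {
  check_scalar(duration_s, "duration_s", positive = TRUE)
  check_scalar(fs, "fs", positive = TRUE)
  n <- round(duration_s * fs)
  if (n < 2) abort("duration_s * fs must be at least 2 samples")
  new_signal(with_seed_if(seed, rnorm(n)), fs)
}

#' Pure sinusoid
#'
#' Unit-amplitude cosine, `cos(2*pi*freq*t + phase0)`. With the cosine
#' convention the instantaneous phase is 0 at waveform peaks.
#'
#' @param freq frequency in Hz; must be below the Nyquist rate `fs/2`.
#' @param duration_s duration in seconds.
#' @param fs sampling rate, Hz.
#' @param phase0 initial phase in radians.
#' @return a signal tibble.
#' @export
gen_sinusoid <- function(freq, duration_s, fs = 1000, phase0 = 0) {
  check_scalar(freq, "freq", positive = TRUE)
  check_scalar(duration_s, "duration_s", positive = TRUE)
  if (freq >= fs / 2) abort("`freq` must be below the Nyquist rate fs/2")
  n <- round(duration_s * fs)
  t <- (0:(n - 1)) / fs
  new_signal(cos(2 * pi * freq * t + phase0), fs)
}

#' Sawtooth wave with per-cycle frequency jitter
#'
#' Piecewise-linear non-sinusoidal oscillation used to demonstrate harmonic
#' artifacts: each cycle's instantaneous frequency is drawn from
#' `N(mean_freq, freq_sigma)` (clamped below at `min_freq` so cycle lengths
#' stay positive), the waveform ramps linearly across the cycle, and
#' Gaussian noise of SD `noise_sigma` is added. Defaults are the
#' theta-asymmetry simulation conditions (8 Hz mean, 5 Hz jitter, 0.1
#' noise). With `freq_sigma = 0` the wave is strictly periodic and its
#' spectrum has peaks at the fundamental and all harmonics.
#'
#' @param duration_s duration in seconds.
#' @param mean_freq mean instantaneous frequency, Hz.
#' @param freq_sigma SD of the per-cycle Gaussian frequency jitter, Hz.
#' @param noise_sigma SD of additive Gaussian noise (signal units; the wave
#'   itself has unit peak-to-peak amplitude).
#' @param fs sampling rate, Hz; must exceed `2 * mean_freq`.
#' @param min_freq lower clamp for jittered frequency draws, Hz.
#' @param falling_edge if `TRUE` (default) the ramp ascends and drops
#'   sharply; `FALSE` flips the polarity.
#' @param seed optional integer for reproducibility.
#' @return a signal tibble.
#' @export
gen_sawtooth <- function(duration_s, mean_freq = 8, freq_sigma = 5,
                         noise_sigma = 0.1, fs = 1000, min_freq = 1,
                         falling_edge = TRUE, seed = NULL) {
  check_scalar(mean_freq, "mean_freq", positive = TRUE)
  check_scalar(duration_s, "duration_s", positive = TRUE)
  if (fs <= 2 * mean_freq) abort("`fs` must exceed 2 * mean_freq")
  if (freq_sigma < 0 || noise_sigma < 0) abort("sigmas must be non-negative")
  n <- round(duration_s * fs)
  with_seed_if(seed, {
    # draw enough cycles to cover the record, then synthesize the linear
    # instantaneous phase cycle by cycle (0 -> 2*pi within each cycle)
    n_cycles <- ceiling(duration_s * (mean_freq + 5 * freq_sigma)) + 2
    f <- pmax(rnorm(n_cycles, mean_freq, freq_sigma), min_freq)
    while (sum(1 / f) < duration_s + 1 / min_freq) {
      f <- c(f, pmax(rnorm(n_cycles, mean_freq, freq_sigma), min_freq))
    }
    t_edges <- c(0, cumsum(1 / f))          # cycle boundaries, seconds
    t <- (0:(n - 1)) / fs
    cyc <- findInterval(t, t_edges)
    frac <- (t - t_edges[cyc]) * f[cyc]     # position within cycle, [0, 1)
    v <- frac - 0.5
    if (!falling_edge) v <- -v
    if (noise_sigma > 0) v <- v + rnorm(n, 0, noise_sigma)
    new_signal(v, fs)
  })
}

#' Simulate a coupled pair of noisy Kuramoto phase oscillators
#'
#' Forward-Euler integration of two phase oscillators with sine coupling,
#' the standard generative model for n:m phase-locking:
#' \deqn{\dot\phi_\theta = \omega_\theta + \epsilon \sin(n\phi_\gamma - m\phi_\theta)}
#' \deqn{\dot\phi_\gamma = \omega_\gamma + \epsilon \sin(m\phi_\theta - n\phi_\gamma)}
#' At every step the natural frequencies are drawn independently from
#' Gaussians `N(2*pi*mean_freq, 2*pi*freq_sigma)` (white frequency noise),
#' so the instantaneous frequencies drift as in real rhythms. `epsilon` is
#' in rad/s. With the defaults (`epsilon = 10`, 1:5 ratio, 8 and 43 Hz,
#' `freq_sigma = 5` Hz, `dt` = 1 ms) the coupled oscillators pull their
#' mean frequencies onto the 1:5 ratio (8.5 and 42.5 Hz); with
#' `epsilon = 0` they run independently at 8 and 43 Hz.
#'
#' @param duration_s simulated duration in seconds (>= 1 s recommended for
#'   stable frequency estimates).
#' @param epsilon coupling strength, rad/s; `0` gives uncoupled oscillators.
#' @param n,m integer acceleration factors of the gamma and theta phases.
#' @param mean_freq_theta,mean_freq_gamma mean natural frequencies, Hz.
#' @param freq_sigma SD of the per-step Gaussian frequency jitter, Hz.
#' @param dt integration step, seconds (the sampling period of the output).
#' @param seed optional integer for reproducibility; initial phases are
#'   drawn uniformly on `(-pi, pi]`.
#' @return list with elements `theta` and `gamma`, each a phase-series
#'   tibble (`time`, `phase` wrapped to `(-pi, pi]`) sampled at `1/dt` Hz.
#' @examples
#' k <- simulate_kuramoto_pair(10, seed = 1)
#' @export
simulate_kuramoto_pair <- function(duration_s, epsilon = 10, n = 1, m = 5,
                                   mean_freq_theta = 8, mean_freq_gamma = 43,
                                   freq_sigma = 5, dt = 0.001, seed = NULL) {
  check_scalar(duration_s, "duration_s", positive = TRUE)
  check_scalar(n, "n", positive = TRUE, integerish = TRUE)
  check_scalar(m, "m", positive = TRUE, integerish = TRUE)
  if (epsilon < 0) abort("`epsilon` must be non-negative")
  if (dt <= 0) abort("`dt` must be positive")
  if (freq_sigma < 0) abort("`freq_sigma` must be non-negative")
  N <- round(duration_s / dt)
  with_seed_if(seed, {
    w_th <- 2 * pi * rnorm(N - 1, mean_freq_theta, freq_sigma)
    w_ga <- 2 * pi * rnorm(N - 1, mean_freq_gamma, freq_sigma)
    th <- numeric(N); ga <- numeric(N)
    th[1] <- runif(1, -pi, pi)
    ga[1] <- runif(1, -pi, pi)
    for (i in 2:N) {
      s <- sin(n * ga[i - 1] - m * th[i - 1])
      th[i] <- th[i - 1] + (w_th[i - 1] + epsilon * s) * dt
      ga[i] <- ga[i - 1] + (w_ga[i - 1] - epsilon * s) * dt
    }
    list(theta = new_phase_series(wrap_phase(th), fs = 1 / dt),
         gamma = new_phase_series(wrap_phase(ga), fs = 1 / dt))
  })
}
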