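# shared numeric helpers

#' Wrap angles to (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return numeric vector with every value in `(-pi, pi]`.
#' @examples
#' wrap_phase(c(0, pi, -pi, 3 * pi / 2))
#' @export
wrap_phase <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  # %% maps pi to -pi; keep the half-open interval (-pi, pi]
  w[w == -pi] <- pi
  w
}

#' Unwrap a wrapped phase series
#'
#' Inverts [wrap_phase()] up to the unknown global 2*pi offset by removing
#' jumps larger than pi between consecutive samples.
#'
#' @param x numeric vector of wrapped phases (radians).
#' @return numeric vector of cumulative (unwrapped) phases.
#' @export
unwrap_phase <- function(x) {
  if (length(x) < 2) return(x)
  d <- diff(x)
  x[1] + c(0, cumsum(wrap_phase(d)))
}

next_pow2 <- function(n) 2^ceiling(log2(max(n, 2)))

# linear convolution via FFT; returns the full length(x)+length(h)-1 result
fft_conv <- function(x, h) {
  nout <- length(x) + length(h) - 1
  L <- next_pow2(nout)
  y <- fft(fft(c(x, rep(0, L - length(x)))) * fft(c(h, rep(0, L - length(h)))),
           inverse = TRUE)
  Re(y[seq_len(nout)]) / L
}

# run code under a temporary RNG state when seed is given
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

check_scalar <- function(x, name, positive = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a finite numeric scalar.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be positive.", name))
  if (integerish && x != round(x)) abort(sprintf("`%s` must be an integer.", name))
  invisible(x)
}
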