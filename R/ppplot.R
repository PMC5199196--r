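# phase-phase plots: joint histograms of slow and fast phase

# circular 2D Gaussian smoothing by FFT convolution; kernel sums to 1 so
# total counts are preserved. Phases are circular on both axes, so the
# convolution wraps.
smooth_circular <- function(m, sigma_bins) {
  nb <- nrow(m)
  d <- c(0:floor(nb / 2), seq(ceiling(nb / 2) - 1, 1))
  k1 <- exp(-d^2 / (2 * sigma_bins^2))
  k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  out <- Re(fft(fft(m) * fft(K), inverse = TRUE)) / length(m)
  pmax(out, 0)
}

#' Phase-phase plot (joint phase histogram)
#'
#' Bins the simultaneous theta and gamma phases into an
#' `n_bins x n_bins` joint histogram (120 bins per axis by convention) and
#' smooths it with a circular Gaussian kernel (`sigma_bins = 10`).
#' Diagonal stripes in the plot indicate a maintained n:m phase
#' relationship -- but appear equally in filtered white noise and in single
#' surrogate runs, so stripes alone are not evidence of coupling.
#'
#' @param theta,gamma phase-series tibbles of equal length.
#' @param n_bins bins per axis.
#' @param sigma_bins SD of the smoothing kernel in bins; `0` disables
#'   smoothing.
#' @return an `nm_pp` object: raw `counts` (theta bins in rows, summing to
#'   N), `smoothed` counts (or `NULL`), bin `edges`, and metadata.
#' @export
phase_phase_histogram <- function(theta, gamma, n_bins = 120, sigma_bins = 10) {
  if (nrow(theta) != nrow(gamma)) abort("phase series must have equal length")
  check_scalar(n_bins, "n_bins", positive = TRUE, integerish = TRUE)
  it <- bin_index(theta$phase, n_bins)
  ig <- bin_index(gamma$phase, n_bins)
  counts <- matrix(tabulate((ig - 1L) * n_bins + it, nbins = n_bins * n_bins),
                   nrow = n_bins)
  structure(
    list(counts = counts,
         smoothed = if (sigma_bins > 0) smooth_circular(counts, sigma_bins) else NULL,
         edges = seq(-pi, pi, length.out = n_bins + 1),
         n_bins = n_bins, sigma_bins = sigma_bins, N = nrow(theta)),
    class = "nm_pp"
  )
}

#' @export
print.nm_pp <- function(x, ...) {
  cat(sprintf("<phase-phase plot> %d x %d bins, N = %d samples%s\n",
              x$n_bins, x$n_bins, x$N,
              if (is.null(x$smoothed)) "" else
                sprintf(", smoothed (sigma = %g bins)", x$sigma_bins)))
  invisible(x)
}

pp_bin_centers <- function(x) x$edges[-1] - pi / x$n_bins

#' Count diagonal stripes in a phase-phase plot
#'
#' Returns the m in `1..m_max` maximizing the histogram-weighted resultant
#' `|sum(counts * exp(i * (phi_gamma - m * phi_theta)))| / sum(counts)`
#' over bin centers. A 1:m phase relationship produces exactly m diagonal
#' stripes, so the argmax is the stripe count. Ties break toward smaller m.
#'
#' @param pp an `nm_pp` object with non-zero counts.
#' @param m_max largest m considered.
#' @return integer stripe count, with the per-m weighted resultant in
#'   attribute `profile` (a tibble `m`, `S`).
#' @export
count_stripes <- function(pp, m_max = 25) {
  stopifnot(inherits(pp, "nm_pp"))
  cnt <- pp$counts
  tot <- sum(cnt)
  if (tot == 0) abort("phase-phase plot has no counts")
  ctr <- pp_bin_centers(pp)
  # row i = theta bin, column j = gamma bin
  S <- purrr::map_dbl(seq_len(m_max), function(m) {
    Mod(sum(cnt * exp(1i * outer(-m * ctr, ctr, "+")))) / tot
  })
  best <- which.max(S)  # which.max takes the first (smallest m) on ties
  structure(as.integer(best), profile = tibble(m = seq_len(m_max), S = S))
}
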