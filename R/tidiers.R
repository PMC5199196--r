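# broom-style tidiers

#' Tidy a phase-phase plot into a long tibble
#'
#' @param x an `nm_pp` object.
#' @param ... unused.
#' @return tibble with `theta_center`, `gamma_center`, `count` and (when
#'   smoothing is on) `count_smoothed`, one row per bin.
#' @export
tidy.nm_pp <- function(x, ...) {
  ctr <- pp_bin_centers(x)
  out <- tibble(theta_center = rep(ctr, times = x$n_bins),
                gamma_center = rep(ctr, each = x$n_bins),
                count = as.vector(x$counts))
  if (!is.null(x$smoothed)) out$count_smoothed <- as.vector(x$smoothed)
  out
}

#' @export
glance.nm_pp <- function(x, ...) {
  tibble(n_bins = x$n_bins, N = x$N, sigma_bins = x$sigma_bins,
         max_count = max(x$counts), min_count = min(x$counts))
}

#' Tidy a significance map
#'
#' @param x an `nm_ppsig` object.
#' @param ... unused.
#' @return long tibble with per-bin `z`, `p`, `p_adj`, `significant`.
#' @export
tidy.nm_ppsig <- function(x, ...) {
  ctr <- x$edges[-1] - pi / x$n_bins
  tibble(theta_center = rep(ctr, times = x$n_bins),
         gamma_center = rep(ctr, each = x$n_bins),
         z = as.vector(x$z), p = as.vector(x$p),
         p_adj = as.vector(x$p_adj),
         significant = as.vector(x$significant))
}

#' @export
glance.nm_ppsig <- function(x, ...) {
  tibble(n_significant = x$n_significant, n_bins_total = x$n_bins^2,
         correction = x$correction, alpha = x$alpha, n_runs = x$n_runs,
         flagged_zero_sd = x$flagged_zero_sd, min_p = min(x$p))
}

#' @export
tidy.nm_curve <- function(x, ...) as_tibble(x)

#' Summary of an R_n:m curve: peak location and height
#' @param x an `nm_curve` tibble.
#' @param ... unused.
#' @return one-row tibble with `peak_m`, `peak_R`, `epoch_length_s`.
#' @export
glance.nm_curve <- function(x, ...) {
  i <- which.max(x$R)
  tibble(peak_m = x$m[i], peak_R = x$R[i],
         epoch_length_s = attr(x, "epoch_length_s") %||% NA_real_)
}
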