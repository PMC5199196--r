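# ggplot2 visualisations

#' Plot an R_n:m curve
#' @param object an `nm_curve` tibble from [rnm_curve()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.nm_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$m, y = .data$R)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "m (theta acceleration)", y = expression(R[n:m]),
                  title = sprintf("n = %d phase-locking curve", object$n[1])) +
    ggplot2::theme_minimal()
}

#' Plot a phase-phase histogram
#' @param object an `nm_pp` object.
#' @param smoothed plot the smoothed counts when available.
#' @param ... unused.
#' @return a ggplot raster of bin counts.
#' @export
autoplot.nm_pp <- function(object, smoothed = TRUE, ...) {
  d <- tidy(object)
  d$fill <- if (smoothed && !is.null(object$smoothed)) d$count_smoothed else d$count
  ggplot2::ggplot(d, ggplot2::aes(x = .data$theta_center,
                                  y = .data$gamma_center, fill = .data$fill)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "count") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "theta phase (rad)", y = "gamma phase (rad)") +
    ggplot2::theme_minimal()
}

#' Plot a bin-wise significance map
#' @param object an `nm_ppsig` object.
#' @param ... unused.
#' @return a ggplot raster of z values with significant bins outlined.
#' @export
autoplot.nm_ppsig <- function(object, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$theta_center,
                                       y = .data$gamma_center, fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(name = "z") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "theta phase (rad)", y = "gamma phase (rad)",
      title = sprintf("%s-corrected: %d significant bin(s)",
                      object$correction, object$n_significant)) +
    ggplot2::theme_minimal()
  if (any(d$significant)) {
    p <- p + ggplot2::geom_point(data = d[d$significant, ],
                                 color = "red", size = 0.3)
  }
  p
}

#' @importFrom rlang .data
NULL
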