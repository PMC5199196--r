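# frequency-band specifications

#' Frequency band specification
#'
#' @param low,high band edges in Hz, `0 < low < high`.
#' @param label optional band name.
#' @return an `nm_band` list with `low`, `high`, `center` (the midpoint,
#'   used to interpret filtering-induced phase velocities) and `label`.
#' @examples
#' band(30, 50, "gamma_slow")
#' @export
band <- function(low, high, label = NULL) {
  check_scalar(low, "low", positive = TRUE)
  check_scalar(high, "high", positive = TRUE)
  if (low >= high) abort("`low` must be less than `high`")
  structure(
    list(low = low, high = high, center = (low + high) / 2,
         label = label %||% sprintf("%g-%g Hz", low, high)),
    class = "nm_band"
  )
}

#' @export
print.nm_band <- function(x, ...) {
  cat(sprintf("<band> %s: %g-%g Hz (center %g Hz)\n",
              x$label, x$low, x$high, x$center))
  invisible(x)
}

#' Hippocampal band presets
#'
#' Conventional bands: theta 4-12 Hz (white-noise and simulation work),
#' theta 4-20 Hz (real LFPs, wide enough to capture theta-wave asymmetry),
#' slow gamma 30-50 Hz, middle gamma 50-90 Hz, fast gamma 90-150 Hz.
#'
#' @return named list of [band()] objects.
#' @export
hippocampal_bands <- function() {
  list(
    theta      = band(4, 12, "theta"),
    theta_lfp  = band(4, 20, "theta_lfp"),
    gamma_slow = band(30, 50, "gamma_slow"),
    gamma_mid  = band(50, 90, "gamma_mid"),
    gamma_fast = band(90, 150, "gamma_fast")
  )
}

as_band <- function(x) {
  if (inherits(x, "nm_band")) return(x)
  if (is.numeric(x) && length(x) == 2) return(band(x[1], x[2]))
  abort("expected a band() object or a numeric vector c(low, high)")
}
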