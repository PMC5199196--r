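# tidy containers for sampled signals and instantaneous-phase series
#
# A signal is a tibble with columns `time` (s) and `value` (arbitrary units);
# a phase series has `time` and `phase` (radians, wrapped to (-pi, pi]) and
# optionally `envelope` (non-negative amplitude). Both carry the sampling
# rate as the `fs` attribute; if dplyr verbs strip it, it is recovered from
# the time column.

new_signal <- function(value, fs, t0 = 0) {
  x <- tibble(time = t0 + (seq_along(value) - 1) / fs, value = as.double(value))
  attr(x, "fs") <- fs
  class(x) <- c("nm_signal", class(x))
  x
}

new_phase_series <- function(phase, fs, envelope = NULL, t0 = 0) {
  x <- tibble(time = t0 + (seq_along(phase) - 1) / fs, phase = as.double(phase))
  if (!is.null(envelope)) x$envelope <- as.double(envelope)
  attr(x, "fs") <- fs
  class(x) <- c("nm_phase", class(x))
  x
}

#' Sampling rate of a signal or phase series
#'
#' Returns the `fs` attribute if present, otherwise recovers it from the
#' median spacing of the `time` column.
#'
#' @param x a signal or phase-series tibble with a `time` column.
#' @return sampling rate in Hz.
#' @export
signal_fs <- function(x) {
  fs <- attr(x, "fs")
  if (!is.null(fs)) return(fs)
  if (!"time" %in% names(x) || nrow(x) < 2) {
    abort("cannot determine sampling rate: no `fs` attribute and no usable `time` column")
  }
  1 / median(diff(x$time))
}

assert_signal <- function(x) {
  if (!is.data.frame(x) || !all(c("time", "value") %in% names(x))) {
    abort("expected a signal data frame with columns `time` and `value`")
  }
  if (nrow(x) < 2) abort("signal must have at least 2 samples")
  if (anyNA(x$value) || any(!is.finite(x$value))) abort("signal values must be finite")
  invisible(x)
}

assert_phase <- function(x) {
  if (!is.data.frame(x) || !all(c("time", "phase") %in% names(x))) {
    abort("expected a phase series with columns `time` and `phase`")
  }
  invisible(x)
}

phase_vec <- function(x) {
  assert_phase(x)
  x$phase
}

#' Drop edge samples of a signal or phase series
#'
#' Forward-backward FIR filtering leaves transients at the two ends of a
#' record; analyses in this package conventionally discard 0.5 s per end of
#' a session before epochs are cut.
#'
#' @param x signal or phase-series tibble.
#' @param seconds duration to drop at each end (default 0.5 s).
#' @return the trimmed tibble (attributes preserved).
#' @export
trim_edges <- function(x, seconds = 0.5) {
  fs <- signal_fs(x)
  k <- round(seconds * fs)
  if (2 * k >= nrow(x)) abort("trim longer than the record")
  out <- x[(k + 1):(nrow(x) - k), ]
  attr(out, "fs") <- fs
  class(out) <- class(x)
  out
}

#' Extract an epoch by start time and duration
#'
#' @param x signal or phase-series tibble.
#' @param start_s epoch start, seconds from the first sample.
#' @param duration_s epoch duration in seconds.
#' @return tibble with `round(duration_s * fs)` rows.
#' @export
epoch_window <- function(x, start_s, duration_s) {
  fs <- signal_fs(x)
  i0 <- round(start_s * fs) + 1
  len <- round(duration_s * fs)
  if (i0 < 1 || i0 + len - 1 > nrow(x)) abort("epoch extends beyond the record")
  out <- x[i0:(i0 + len - 1), ]
  attr(out, "fs") <- fs
  class(out) <- class(x)
  out
}

#' Write a signal to disk with a JSON sidecar
#'
#' Writes the sample values as flat 64-bit little-endian binary (`.f64`),
#' flat 16-bit integer binary (`.i16`, values rounded), or single-column
#' delimited text (`.txt`), plus `<path>.json` recording the sampling rate
#' and any extra metadata.
#'
#' @param x signal tibble (columns `time`, `value`).
#' @param path output file path.
#' @param format one of `"f64"`, `"i16"`, `"txt"`.
#' @param meta named list of extra metadata for the sidecar.
#' @return `path`, invisibly.
#' @export
write_signal <- function(x, path, format = c("f64", "i16", "txt"), meta = list()) {
  assert_signal(x)
  format <- match.arg(format)
  fs <- signal_fs(x)
  v <- x$value
  if (format == "txt") {
    writeLines(format(v, digits = 17), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    if (format == "f64") {
      writeBin(as.double(v), con, size = 8, endian = "little")
    } else {
      writeBin(as.integer(round(v)), con, size = 2, endian = "little")
    }
  }
  side <- c(list(fs = fs, n = length(v), format = format), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a signal written by [write_signal()]
#'
#' @param path file path; `<path>.json` must exist and state `fs` and `format`.
#' @return a signal tibble.
#' @export
read_signal <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  v <- switch(side$format,
    txt = as.double(readLines(path)),
    f64 = readBin(path, "double", n = side$n, size = 8, endian = "little"),
    i16 = as.double(readBin(path, "integer", n = side$n, size = 2,
                            signed = TRUE, endian = "little")),
    abort(sprintf("unknown format '%s' in sidecar", side$format))
  )
  new_signal(v, side$fs)
}
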