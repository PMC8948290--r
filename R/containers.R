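#' Time-domain THz waveform
#'
#' @param t Time axis in ps, strictly increasing, uniform spacing.
#' @param amplitude Field amplitude samples (arbitrary units).
#' @param pixel_index Optional integer pair `c(row, col)`.
#' @param kind `"sample"` or `"reference"`.
#' @return Object of class `thz_waveform`.
#' @export
thz_waveform <- function(t, amplitude, pixel_index = NULL,
                         kind = c("sample", "reference")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(t), is.numeric(amplitude), length(t) == length(amplitude))
  dt <- diff(t)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9 * dt[1]) {
    stop("waveform time axis must be strictly increasing with uniform spacing")
  }
  structure(list(t = t, amplitude = amplitude, pixel_index = pixel_index,
                 kind = kind),
            class = "thz_waveform")
}

#' @export
print.thz_waveform <- function(x, ...) {
  cat(sprintf("<thz_waveform> %s, %d samples, dt = %.4g ps, span %.4g ps\n",
              x$kind, length(x$t), x$t[2] - x$t[1], diff(range(x$t))))
  invisible(x)
}

#' Complex (or amplitude) reflectivity spectrum on a frequency grid
#'
#' @param freq Frequency grid in THz, uniform ascending, `0 <= f <= Nyquist`.
#' @param value Complex reflectivity (or real amplitude) per frequency.
#' @param pixel_index Optional integer pair `c(row, col)`.
#' @return Object of class `spectral_trace`.
#' @export
spectral_trace <- function(freq, value, pixel_index = NULL) {
  stopifnot(is.numeric(freq), length(freq) == length(value), all(freq >= 0))
  if (length(freq) > 1 && any(diff(freq) <= 0)) {
    stop("spectral_trace frequency grid must be ascending")
  }
  structure(list(freq = freq, value = value, pixel_index = pixel_index),
            class = "spectral_trace")
}

#' Amplitude of a spectral trace
#' @param trace A [spectral_trace()].
#' @return Numeric vector `|value|`.
#' @export
trace_amplitude <- function(trace) {
  stopifnot(inherits(trace, "spectral_trace"))
  Mod(trace$value)
}

#' @export
print.spectral_trace <- function(x, ...) {
  cat(sprintf("<spectral_trace> %d bins, %.3g-%.3g THz\n",
              length(x$freq), min(x$freq), max(x$freq)))
  invisible(x)
}

# internal: pixel linear index (column-major over rows) used for waveform
# and spectra matrices
pixel_linear_index <- function(row, col, ny) (col - 1L) * ny + row

#' Extract one pixel waveform from a scan cube
#' @param scan A `thz_scan` (see [synth_scan()]).
#' @param row,col 1-based pixel indices.
#' @return A [thz_waveform()].
#' @export
get_waveform <- function(scan, row, col) {
  stopifnot(inherits(scan, "thz_scan"))
  idx <- pixel_linear_index(row, col, scan$ny)
  thz_waveform(scan$t, scan$waveforms[, idx], pixel_index = c(row, col))
}

#' @export
print.thz_scan <- function(x, ...) {
  cat(sprintf("<thz_scan> %d x %d px, %d samples/waveform, %d burn site(s), %d biopsy px\n",
              x$ny, x$nx, length(x$t), nrow(x$truth$sites), sum(x$truth$biopsy_mask)))
  invisible(x)
}
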