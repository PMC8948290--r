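#' Imaging window specification
#'
#' The scan geometry places a dielectric imaging window between the THz
#' optics and the tissue. Internal reflections inside the window generate
#' Fabry-Perot echoes of the main reflection, delayed by multiples of the
#' round-trip time `2 * n * thickness / c`. The window material is modelled
#' as lossless with a frequency-flat real refractive index.
#'
#' @param refractive_index Real index of the window material (> 1).
#' @param thickness Window thickness in metres.
#' @param n_echoes Number of Fabry-Perot round trips modelled (>= 1).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(refractive_index = 1.95, thickness = 4e-3, n_echoes = 2) {
  stopifnot(is.numeric(refractive_index), is.numeric(thickness))
  if (refractive_index <= 1) stop("window refractive_index must be > 1")
  if (thickness <= 0) stop("window thickness must be > 0")
  if (n_echoes < 1) stop("n_echoes must be >= 1 (mask detection requires an echo)")
  structure(list(refractive_index = refractive_index, thickness = thickness,
                 n_echoes = as.integer(n_echoes)),
            class = "window_spec")
}

#' Fabry-Perot round-trip time of the imaging window, in picoseconds
#' @param window A [window_spec()].
#' @return Round-trip delay `2 n d / c` in ps.
#' @export
round_trip_ps <- function(window) {
  c0 <- 299792458
  2 * window$refractive_index * window$thickness / c0 * 1e12
}

#' Reflection transfer function of a window-backed sample
#'
#' Complex transfer function of the layered sample seen from inside the
#' window: the primary window-medium Fresnel reflection plus `n_echoes`
#' Fabry-Perot terms, each delayed by an integer multiple of the round-trip
#' time and attenuated by one internal window-air reflection and one more
#' window-medium reflection per round trip:
#' \deqn{H(f) = r_b(f) \sum_{m=0}^{M} (r_t\, r_b(f))^m e^{+i 2\pi f m T}}
#' where \eqn{r_b} is the window-medium coefficient, \eqn{r_t} the internal
#' window-air coefficient at the top face and \eqn{T} the round trip.
#' Phases follow the `e^{-i w t}` physics convention of
#' [debye_permittivity()]; the common entry/exit transmission factor is
#' normalized out (it cancels in deconvolution against the reference).
#'
#' Echo orders whose delay `m T` falls at or beyond `time_window_ps` are
#' dropped rather than circularly wrapped, so a very thick window reduces
#' to the primary reflection alone.
#'
#' @param window A [window_spec()].
#' @param medium_eps Complex permittivity of the backing medium, scalar or
#'   one value per frequency.
#' @param freq_thz Frequency grid in THz (non-negative).
#' @param time_window_ps Optional record length in ps used to drop
#'   out-of-record echoes.
#' @return A [spectral_trace()] holding the complex transfer function.
#' @export
sample_response_spectrum <- function(window, medium_eps, freq_thz,
                                     time_window_ps = NULL) {
  stopifnot(inherits(window, "window_spec"))
  if (window$n_echoes < 1) stop("n_echoes must be >= 1")
  n_med <- refractive_index(medium_eps)
  n_w <- window$refractive_index
  r_b <- fresnel_reflection(n_w, n_med)      # window -> medium (bottom face)
  r_t <- fresnel_reflection(n_w, 1)          # window -> air (top face, internal)
  T_ps <- round_trip_ps(window)
  orders <- seq_len(window$n_echoes)
  if (!is.null(time_window_ps)) orders <- orders[orders * T_ps < time_window_ps]
  H <- r_b + 0i * freq_thz
  for (m in orders) {
    H <- H + r_b * (r_t * r_b)^m * exp(1i * 2 * pi * freq_thz * m * T_ps)
  }
  spectral_trace(freq_thz, H)
}
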