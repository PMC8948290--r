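#' Spectral signal-to-noise ratio of a reference waveform
#'
#' Per-frequency power SNR used to regularize Wiener deconvolution:
#' `SNR(f) = |S_ref(f)|^2 / P_noise(f)`, where `P_noise` is the smoothed
#' periodogram of the pre-pulse noise-window segment rescaled to the full
#' record length and interpolated onto the record's frequency grid. The SNR
#' is clipped to a finite ceiling so the noiseless limit stays usable, and
#' floored at a tiny positive value so it is strictly positive everywhere.
#'
#' @param reference A [thz_waveform()] containing the main pulse.
#' @param windows A [noise_windows()]; the pre window supplies the noise
#'   segment.
#' @param smooth_bins Width (bins) of the running-mean periodogram smoother.
#' @param ceiling Maximum SNR reported (default `1e6`).
#' @return Object of class `snr_spectrum`: `freq` (one-sided THz grid) and
#'   `snr`.
#' @export
estimate_snr_spectrum <- function(reference, windows = noise_windows(),
                                  smooth_bins = 5, ceiling = 1e6) {
  idx <- .noise_window_indices(reference, windows)
  n <- length(reference$amplitude)
  dt <- reference$t[2] - reference$t[1]
  freq <- (0:(n %/% 2)) / (n * dt)
  p_sig <- Mod(stats::fft(reference$amplitude))[seq_along(freq)]^2

  seg <- reference$amplitude[idx$pre]
  m <- length(seg)
  per <- Mod(stats::fft(seg))^2 * (n / m)  # scale to full record length
  nf_seg <- m %/% 2 + 1
  per <- per[1:nf_seg]
  if (smooth_bins > 1) {
    sm <- as.numeric(stats::filter(per, rep(1 / smooth_bins, smooth_bins),
                                   sides = 2))
    ok <- which(!is.na(sm))
    if (length(ok)) {
      sm[seq_len(ok[1] - 1)] <- sm[ok[1]]
      last <- ok[length(ok)]
      if (last < length(sm)) sm[(last + 1):length(sm)] <- sm[last]
      per <- sm
    }
  }
  f_seg <- (0:(nf_seg - 1)) / (m * dt)
  p_noise <- stats::approx(f_seg, per, xout = freq, rule = 2)$y

  snr <- ifelse(p_noise <= 0, ceiling, pmin(p_sig / p_noise, ceiling))
  snr <- pmax(snr, 1e-12)
  structure(list(freq = freq, snr = snr), class = "snr_spectrum")
}

#' Wiener deconvolution of a sample waveform against a reference
#'
#' Frequency-domain deconvolution regularized by the inverse SNR:
#' \deqn{R(f) = \frac{S_{samp}(f)\,\overline{S_{ref}(f)}}
#'                   {|S_{ref}(f)|^2 + 1/\mathrm{SNR}(f)}}
#' The `1/SNR` term keeps the estimate finite at reference spectral nulls,
#' avoiding the high-frequency spikes of the plain spectral ratio.
#'
#' @param sample,reference [thz_waveform()]s sharing the same time grid.
#' @param snr An `snr_spectrum` from [estimate_snr_spectrum()]; its grid
#'   must match the record's one-sided frequency grid.
#' @return A [spectral_trace()] with the complex reflectivity on the
#'   one-sided frequency grid.
#' @export
wiener_deconvolve <- function(sample, reference, snr) {
  stopifnot(inherits(sample, "thz_waveform"), inherits(reference, "thz_waveform"),
            inherits(snr, "snr_spectrum"))
  if (length(sample$t) != length(reference$t) ||
      max(abs(sample$t - reference$t)) > 1e-9) {
    stop("sample and reference must share the same time grid")
  }
  n <- length(sample$t)
  nf <- n %/% 2 + 1
  if (length(snr$snr) != nf) stop("SNR spectrum grid does not match the record")
  S <- stats::fft(sample$amplitude)
  R <- stats::fft(reference$amplitude)
  # expand one-sided SNR to the full two-sided grid
  snr_full <- numeric(n)
  snr_full[1:nf] <- snr$snr
  if (n %% 2 == 0) {
    if (nf > 2) snr_full[(nf + 1):n] <- snr$snr[(nf - 1):2]
  } else if (nf > 1) {
    snr_full[(nf + 1):n] <- snr$snr[nf:2]
  }
  W <- S * Conj(R) / (Mod(R)^2 + 1 / snr_full)
  dt <- sample$t[2] - sample$t[1]
  spectral_trace((0:(nf - 1)) / (n * dt), W[1:nf],
                 pixel_index = sample$pixel_index)
}

#' Plain (unregularized) spectral-ratio deconvolution
#'
#' Comparison mode: `R(f) = S_samp(f) / S_ref(f)` diverges at reference
#' spectral nulls, producing the high-frequency spikes the Wiener scheme
#' suppresses.
#'
#' @inheritParams wiener_deconvolve
#' @return A [spectral_trace()].
#' @export
naive_deconvolve <- function(sample, reference) {
  stopifnot(inherits(sample, "thz_waveform"), inherits(reference, "thz_waveform"))
  if (length(sample$t) != length(reference$t) ||
      max(abs(sample$t - reference$t)) > 1e-9) {
    stop("sample and reference must share the same time grid")
  }
  n <- length(sample$t)
  nf <- n %/% 2 + 1
  S <- stats::fft(sample$amplitude)[1:nf]
  R <- stats::fft(reference$amplitude)[1:nf]
  dt <- sample$t[2] - sample$t[1]
  spectral_trace((0:(nf - 1)) / (n * dt), S / R,
                 pixel_index = sample$pixel_index)
}

#' Denoise and deconvolve a whole scan cube
#'
#' Runs [modwt_denoise()] on every pixel, estimates the SNR spectrum from
#' the reference, and Wiener-deconvolves each denoised pixel against the
#' reference.
#'
#' @param scan A `thz_scan`.
#' @param windows A [noise_windows()].
#' @param wavelet,n_levels Denoising settings.
#' @param denoise Set `FALSE` to skip wavelet denoising.
#' @return Object of class `thz_spectra`: `freq` (one-sided THz grid),
#'   `value` (complex nf x npix matrix), `amplitude` (nf x npix), `nx`,
#'   `ny`, `snr`, and the scan's truth pass-through.
#' @export
preprocess_scan <- function(scan, windows = noise_windows(), wavelet = "sym8",
                            n_levels = 6, denoise = TRUE) {
  stopifnot(inherits(scan, "thz_scan"))
  if (denoise && !isTRUE(scan$denoised)) {
    scan <- denoise_scan(scan, windows, wavelet, n_levels)
  }
  snr <- estimate_snr_spectrum(scan$reference, windows)
  npix <- ncol(scan$waveforms)
  nf <- length(scan$t) %/% 2 + 1
  value <- matrix(0i, nf, npix)
  for (i in seq_len(npix)) {
    tr <- wiener_deconvolve(thz_waveform(scan$t, scan$waveforms[, i]),
                            scan$reference, snr)
    value[, i] <- tr$value
  }
  structure(list(freq = snr$freq, value = value, amplitude = Mod(value),
                 nx = scan$nx, ny = scan$ny, snr = snr,
                 truth = scan$truth, window = scan$window,
                 config = scan$config),
            class = "thz_spectra")
}

#' @export
print.thz_spectra <- function(x, ...) {
  cat(sprintf("<thz_spectra> %d x %d px, %d frequency bins (0-%.3g THz)\n",
              x$ny, x$nx, length(x$freq), max(x$freq)))
  invisible(x)
}
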