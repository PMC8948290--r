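test_that("SNR spectrum is clipped, positive and band-shaped", {
  sc <- noiseless_pixel_fixture(50)
  snr0 <- estimate_snr_spectrum(sc$reference, noise_windows())
  # noiseless reference -> clipped at the documented ceiling
  expect_true(all(snr0$snr <= 1e6))
  expect_equal(max(snr0$snr), 1e6)
  expect_true(all(snr0$snr > 0))
  # noisy reference: in-band SNR exceeds out-of-band SNR
  set.seed(10)
  ref_n <- thz_waveform(sc$t,
                        sc$reference$amplitude + rnorm(length(sc$t), sd = 1e-3),
                        kind = "reference")
  snr <- estimate_snr_spectrum(ref_n, noise_windows())
  inb <- snr$freq >= 0.1 & snr$freq <= 0.5
  oob <- snr$freq > 2 & snr$freq <= 5
  expect_gt(min(snr$snr[inb]), max(snr$snr[oob]))
})

test_that("SNR at 0.3 THz matches a direct periodogram computation", {
  set.seed(11)
  sc <- noiseless_pixel_fixture(50)
  ref_n <- thz_waveform(sc$t,
                        sc$reference$amplitude + rnorm(length(sc$t), sd = 1e-3),
                        kind = "reference")
  nw <- noise_windows()
  snr <- estimate_snr_spectrum(ref_n, nw, smooth_bins = 1)
  n <- length(sc$t); dt <- sc$t[2] - sc$t[1]
  k <- which.min(abs(snr$freq - 0.3))
  # signal power by direct DFT sum at bin k
  tt <- 0:(n - 1)
  ph <- exp(-2i * pi * (k - 1) * tt / n)
  p_sig <- Mod(sum(ref_n$amplitude * ph))^2
  # noise power: pre-window periodogram scaled to the record length,
  # linearly interpolated between the bracketing pre-window grid bins
  seg <- ref_n$amplitude[ref_n$t >= nw$pre[1] & ref_n$t <= nw$pre[2]]
  m <- length(seg)
  f_seg <- (0:(m %/% 2)) / (m * dt)
  per_at <- function(j) {
    pj <- exp(-2i * pi * (j - 1) * (0:(m - 1)) / m)
    Mod(sum(seg * pj))^2 * n / m
  }
  jlo <- max(which(f_seg <= snr$freq[k]))
  w <- (snr$freq[k] - f_seg[jlo]) / (f_seg[jlo + 1] - f_seg[jlo])
  p_noise <- (1 - w) * per_at(jlo) + w * per_at(jlo + 1)
  expect_equal(snr$snr[k], min(p_sig / p_noise, 1e6), tolerance = 1e-6)
})

test_that("self-deconvolution returns unit reflectivity in band", {
  sc <- noiseless_pixel_fixture(50)
  snr <- estimate_snr_spectrum(sc$reference, noise_windows())
  tr <- wiener_deconvolve(sc$reference, sc$reference, snr)
  inb <- tr$freq >= 0.1 & tr$freq <= 0.5
  expect_true(all(abs(trace_amplitude(tr)[inb] - 1) < 0.01))
  # zero sample -> zero reflectivity
  z <- thz_waveform(sc$t, numeric(length(sc$t)))
  expect_true(all(trace_amplitude(wiener_deconvolve(z, sc$reference, snr)) == 0))
})

test_that("deconvolution is linear in the sample argument", {
  sc <- noiseless_pixel_fixture(60)
  snr <- estimate_snr_spectrum(sc$reference, noise_windows())
  a <- thz_waveform(sc$t, sc$waveforms[, 1])
  b <- thz_waveform(sc$t, rev(sc$waveforms[, 1]))
  lin <- thz_waveform(sc$t, 2 * a$amplitude + 3 * b$amplitude)
  ra <- wiener_deconvolve(a, sc$reference, snr)$value
  rb <- wiener_deconvolve(b, sc$reference, snr)$value
  rl <- wiener_deconvolve(lin, sc$reference, snr)$value
  expect_equal(rl, 2 * ra + 3 * rb, tolerance = 1e-9)
})

test_that("Wiener regularization bounds the spectrum where naive division blows up", {
  set.seed(12)
  sc <- noiseless_pixel_fixture(60)
  noisy <- thz_waveform(sc$t, sc$waveforms[, 1] +
                          rnorm(length(sc$t), sd = 1e-3))
  ref_n <- thz_waveform(sc$t, sc$reference$amplitude +
                          rnorm(length(sc$t), sd = 1e-3), kind = "reference")
  snr <- estimate_snr_spectrum(ref_n, noise_windows())
  wie <- wiener_deconvolve(noisy, ref_n, snr)
  nai <- naive_deconvolve(noisy, ref_n)
  hi <- wie$freq > 5
  # the reference amplitude dies off at high frequency: plain division
  # diverges there while the Wiener estimate stays bounded
  expect_gt(max(trace_amplitude(nai)[hi]), 100 * max(trace_amplitude(wie)[hi]))
  expect_true(all(is.finite(trace_amplitude(wie))))
})

test_that("grid mismatch between sample and reference is rejected", {
  sc <- noiseless_pixel_fixture(50)
  snr <- estimate_snr_spectrum(sc$reference, noise_windows())
  short <- thz_waveform(sc$t[1:100], sc$waveforms[1:100, 1])
  expect_error(wiener_deconvolve(short, sc$reference, snr), "time grid")
})

test_that("denoising removes out-of-band spectral fluctuations", {
  set.seed(13)
  sc <- noiseless_pixel_fixture(50)
  x <- sc$waveforms[, 1] + rnorm(length(sc$t), sd = 0.02 / sqrt(20))
  wf <- thz_waveform(sc$t, x)
  den <- modwt_denoise(wf, noise_windows())
  f <- freq_axis(sc$config)
  oob <- f >= 2 & f <= 5
  amp <- function(v) Mod(stats::fft(v))[seq_along(f)]
  expect_lt(sd(amp(den$amplitude)[oob]), sd(amp(x)[oob]))
})
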