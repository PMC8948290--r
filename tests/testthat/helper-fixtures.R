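# Shared fixtures, built once per test session and memoised.

.fixture_env <- new.env(parent = emptyenv())

# tiny three-burn study (one scan per severity class) plus preprocessed
# spectra and detected masks
tiny_fixture <- function() {
  if (is.null(.fixture_env$tiny)) {
    scans <- tiny_study(master_seed = 1)
    spectra <- lapply(scans, preprocess_scan)
    masks <- lapply(scans, detect_biopsy_mask)
    .fixture_env$tiny <- list(scans = scans, spectra = spectra, masks = masks)
  }
  .fixture_env$tiny
}

# a single noiseless burn pixel and its scan (forward-model ground truth)
noiseless_pixel_fixture <- function(d = 60) {
  key <- paste0("px", d)
  if (is.null(.fixture_env[[key]])) {
    cf <- scan_config(nx = 1, ny = 1, noise_rms = 0, scatter_jitter = 0)
    ph <- phantom_spec(burn_sites = list(burn_site(c(1, 1), 0.6, d)))
    .fixture_env[[key]] <- synth_scan(ph, cf)
  }
  .fixture_env[[key]]
}

# Brute-force MODWT detail coefficients by direct time-domain circular
# convolution with explicitly upsampled filters (independent of the
# package's FFT-domain implementation).
brute_modwt_W <- function(x, wavelet, n_levels) {
  f <- wavelet_filters(wavelet)
  n <- length(x)
  v <- x
  W <- vector("list", n_levels)
  for (j in seq_len(n_levels)) {
    up <- 2^(j - 1)
    wj <- numeric(n)
    vj <- numeric(n)
    for (t in seq_len(n)) {
      aw <- 0; av <- 0
      for (l in seq_along(f$h)) {
        idx <- ((t - 1 - (l - 1) * up) %% n) + 1
        aw <- aw + f$h[l] * v[idx]
        av <- av + f$g[l] * v[idx]
      }
      wj[t] <- aw; vj[t] <- av
    }
    W[[j]] <- wj
    v <- vj
  }
  W
}

# per-level alignment delays recomputed from the brute-force transform of a
# unit impulse (independent of modwt_delays)
brute_modwt_delays <- function(wavelet, n, n_levels) {
  imp <- numeric(n); imp[1] <- 1
  W <- brute_modwt_W(imp, wavelet, n_levels)
  vapply(W, function(w) which.max(abs(w)) - 1L, integer(1))
}
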