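#' Noise-estimation time windows
#'
#' Two intervals of the time record used to estimate the noise floor: one
#' strictly before the main pulse and one after it (before the first window
#' echo). Per-level wavelet thresholds are set from the coefficients whose
#' time support falls inside these windows.
#'
#' The defaults match the default [scan_config()] layout (pulse at 30 ps,
#' first window echo at 82 ps): both windows keep more than 14 ps of
#' clearance from the pulse and echo supports, which exceeds the half-width
#' of the level-6 sym8 equivalent wavelet filter, so on a noiseless record
#' the window coefficients are exactly zero at every level.
#'
#' @param pre,post Numeric intervals `c(lo, hi)` in ps.
#' @return Object of class `noise_windows`.
#' @export
noise_windows <- function(pre = c(1, 13), post = c(47, 65)) {
  stopifnot(length(pre) == 2, length(post) == 2,
            pre[1] < pre[2], post[1] < post[2])
  if (pre[2] > post[1]) stop("pre window must precede the post window")
  structure(list(pre = pre, post = post), class = "noise_windows")
}

# internal: sample indices of a ps interval on a time axis
.window_indices <- function(t, interval) which(t >= interval[1] & t <= interval[2])

# internal: contiguous main-pulse support around the global |x| maximum
# (indices where |x| stays above frac * max, grown from the peak)
.pulse_support <- function(x, frac = 0.02) {
  a <- abs(x)
  peak <- which.max(a)
  thr <- frac * a[peak]
  lo <- peak
  while (lo > 1 && a[lo - 1] > thr) lo <- lo - 1
  hi <- peak
  while (hi < length(a) && a[hi + 1] > thr) hi <- hi + 1
  c(lo, hi)
}

# internal: validate windows against a waveform, return index sets
.noise_window_indices <- function(waveform, windows) {
  stopifnot(inherits(waveform, "thz_waveform"), inherits(windows, "noise_windows"))
  pre <- .window_indices(waveform$t, windows$pre)
  post <- .window_indices(waveform$t, windows$post)
  if (length(pre) < 32 || length(post) < 32) {
    stop("each noise window must contain at least 32 samples")
  }
  # enforce the pulse-overlap precondition only when a clear pulse exists
  # (peak well above the record's typical level); pure-noise records have no
  # pulse support to protect
  a <- abs(waveform$amplitude)
  if (max(a) > 0 && max(a) > 10 * stats::median(a)) {
    supp <- .pulse_support(waveform$amplitude)
    if (any(pre >= supp[1] & pre <= supp[2]) ||
        any(post >= supp[1] & post <= supp[2])) {
      stop("noise windows must not overlap the main pulse support")
    }
  }
  list(pre = pre, post = post)
}

#' Level-dependent wavelet thresholds from the noise windows
#'
#' For each decomposition level, the threshold is the maximum coefficient
#' magnitude over the (delay-compensated) coefficients whose time support
#' lies in the two noise windows. This "max rule" guarantees that hard
#' thresholding zeroes the noise windows at every detail level; it is
#' homogeneous of degree 1 in the noise amplitude. The per-level group
#' delay of the shift-invariant transform is compensated when selecting
#' window coefficients (see [modwt_delays()]).
#'
#' @param waveform A [thz_waveform()].
#' @param windows A [noise_windows()]; must not overlap the pulse support.
#' @param wavelet,n_levels Transform settings, see [modwt()].
#' @return Numeric vector of one non-negative threshold per level.
#' @export
level_thresholds <- function(waveform, windows, wavelet = "sym8", n_levels = 6) {
  idx <- .noise_window_indices(waveform, windows)
  w <- modwt(waveform$amplitude, wavelet, n_levels)
  delays <- modwt_delays(wavelet, w$n, n_levels)
  win <- c(idx$pre, idx$post)
  vapply(seq_len(n_levels), function(j) {
    sel <- ((win - 1L + delays[j]) %% w$n) + 1L
    max(abs(w$W[[j]][sel]))
  }, numeric(1))
}

#' Wavelet-shrinkage denoising of a THz waveform
#'
#' Maximal-overlap discrete wavelet transform with level-dependent *hard*
#' thresholding: at each detail level, coefficients with magnitude at or
#' below that level's [level_thresholds()] value are zeroed, all others kept
#' unchanged; the final-level scaling (approximation) coefficients are
#' untouched. The inverse transform returns the denoised time-domain
#' waveform on the original grid.
#'
#' @inheritParams level_thresholds
#' @return A denoised [thz_waveform()].
#' @export
modwt_denoise <- function(waveform, windows, wavelet = "sym8", n_levels = 6) {
  idx <- .noise_window_indices(waveform, windows)
  w <- modwt(waveform$amplitude, wavelet, n_levels)
  delays <- modwt_delays(wavelet, w$n, n_levels)
  win <- c(idx$pre, idx$post)
  for (j in seq_len(n_levels)) {
    sel <- ((win - 1L + delays[j]) %% w$n) + 1L
    thr <- max(abs(w$W[[j]][sel]))
    w$W[[j]][abs(w$W[[j]]) <= thr] <- 0
  }
  thz_waveform(waveform$t, imodwt(w), pixel_index = waveform$pixel_index,
               kind = waveform$kind)
}

#' Denoise every pixel waveform of a scan cube
#'
#' @param scan A `thz_scan`.
#' @param windows A [noise_windows()].
#' @param wavelet,n_levels Transform settings.
#' @return The scan with `waveforms` replaced by their denoised versions
#'   (the reference channel is left as acquired).
#' @export
denoise_scan <- function(scan, windows = noise_windows(), wavelet = "sym8",
                         n_levels = 6) {
  stopifnot(inherits(scan, "thz_scan"))
  for (i in seq_len(ncol(scan$waveforms))) {
    wf <- thz_waveform(scan$t, scan$waveforms[, i])
    scan$waveforms[, i] <- modwt_denoise(wf, windows, wavelet, n_levels)$amplitude
  }
  scan$denoised <- TRUE
  scan
}
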