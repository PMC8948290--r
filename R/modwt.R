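# Maximal overlap discrete wavelet transform (MODWT), implemented by exact
# circular filtering in the frequency domain (the filters at level j are the
# base filters upsampled by 2^(j-1); their DFTs are index-decimated copies of
# the base filter DFT). Perfect reconstruction holds to machine precision
# because the rescaled filters satisfy |G(f)|^2 + |H(f)|^2 = 1.

# Scaling (lowpass) filters in standard order h0..h_{L-1}; wavelet filter by
# quadrature mirror: h_l = (-1)^l g_{L-1-l}. MODWT rescaling (1/sqrt(2)) is
# applied in wavelet_filters().
.scaling_filters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db4 = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
          -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
          0.0328830116668852, -0.010597401785069032),
  sym8 = c(0.0018899503327594609, -0.0003029205147213668,
           -0.01495225833704823, 0.003808752013890615, 0.049137179673607506,
           -0.027219029917056003, -0.05194583810770904, 0.3644418948353314,
           0.7771857517005235, 0.4813596512583722, -0.061273359067658524,
           -0.1432942383508097, 0.007607487324917605, 0.03169508781149298,
           -0.0005421323317911481, -0.0033824159510061256)
)

#' MODWT filter pair
#' @param wavelet One of `"sym8"`, `"db4"`, `"haar"`.
#' @return List with rescaled scaling (`g`) and wavelet (`h`) filters.
#' @export
wavelet_filters <- function(wavelet = c("sym8", "db4", "haar")) {
  wavelet <- match.arg(wavelet)
  g <- .scaling_filters[[wavelet]]
  L <- length(g)
  h <- (-1)^(0:(L - 1)) * rev(g)
  list(g = g / sqrt(2), h = h / sqrt(2), name = wavelet)
}

# DFTs of the level-j filters on an N-point grid: base filter DFT sampled at
# indices (2^(j-1) * k) mod N. Memoised per (wavelet, n, n_levels) since the
# same grids recur for every pixel of a scan.
.dft_cache <- new.env(parent = emptyenv())

.level_filter_dfts <- function(filters, n, n_levels) {
  key <- paste(filters$name, n, n_levels, sep = "_")
  hit <- .dft_cache[[key]]
  if (!is.null(hit)) return(hit)
  Gh <- stats::fft(c(filters$g, rep(0, n - length(filters$g))))
  Hh <- stats::fft(c(filters$h, rep(0, n - length(filters$h))))
  k <- 0:(n - 1)
  out <- lapply(seq_len(n_levels), function(j) {
    idx <- ((2^(j - 1) * k) %% n) + 1
    list(G = Gh[idx], H = Hh[idx])
  })
  .dft_cache[[key]] <- out
  out
}

#' Maximal overlap discrete wavelet transform
#'
#' @param x Numeric signal (any length; circular boundary).
#' @param wavelet Filter family, see [wavelet_filters()].
#' @param n_levels Decomposition depth; must satisfy
#'   `n_levels <= floor(log2(length(x)))`.
#' @return List of class `modwt`: `W` (list of detail-coefficient vectors,
#'   one per level), `V` (final-level scaling coefficients), plus the
#'   transform settings.
#' @export
modwt <- function(x, wavelet = "sym8", n_levels = 6) {
  n <- length(x)
  if (n_levels < 1 || n_levels > floor(log2(n))) {
    stop(sprintf("n_levels must be in [1, %d] for a record of %d samples",
                 floor(log2(n)), n))
  }
  f <- wavelet_filters(wavelet)
  dfts <- .level_filter_dfts(f, n, n_levels)
  Vhat <- stats::fft(x)
  W <- vector("list", n_levels)
  for (j in seq_len(n_levels)) {
    W[[j]] <- Re(stats::fft(Vhat * dfts[[j]]$H, inverse = TRUE)) / n
    Vhat <- Vhat * dfts[[j]]$G
  }
  V <- Re(stats::fft(Vhat, inverse = TRUE)) / n
  structure(list(W = W, V = V, wavelet = wavelet, n_levels = n_levels, n = n),
            class = "modwt")
}

#' Inverse MODWT
#' @param w A [modwt()] object (possibly with modified coefficients).
#' @return Reconstructed signal of the original length.
#' @export
imodwt <- function(w) {
  stopifnot(inherits(w, "modwt"))
  f <- wavelet_filters(w$wavelet)
  dfts <- .level_filter_dfts(f, w$n, w$n_levels)
  Vhat <- stats::fft(w$V)
  for (j in rev(seq_len(w$n_levels))) {
    Vhat <- Conj(dfts[[j]]$G) * Vhat +
      Conj(dfts[[j]]$H) * stats::fft(w$W[[j]])
  }
  Re(stats::fft(Vhat, inverse = TRUE)) / w$n
}

#' Per-level time alignment of MODWT detail coefficients
#'
#' The level-j detail coefficients are delayed relative to the signal by the
#' group delay of the level's equivalent filter. The delay is obtained from
#' the equivalent filter's impulse response (index of its largest
#' magnitude), so a coefficient describing signal time `u` sits at index
#' `u + delay_j` (circularly).
#'
#' @param wavelet Filter family.
#' @param n Record length.
#' @param n_levels Depth.
#' @return Integer vector of per-level delays in samples.
#' @export
modwt_delays <- function(wavelet, n, n_levels) {
  key <- paste("delays", wavelet, n, n_levels, sep = "_")
  hit <- .dft_cache[[key]]
  if (!is.null(hit)) return(hit)
  f <- wavelet_filters(wavelet)
  dfts <- .level_filter_dfts(f, n, n_levels)
  Geq <- rep(1 + 0i, n)
  delays <- integer(n_levels)
  for (j in seq_len(n_levels)) {
    Heq <- Geq * dfts[[j]]$H
    h_eq <- Re(stats::fft(Heq, inverse = TRUE)) / n
    delays[j] <- which.max(abs(h_eq)) - 1L
    Geq <- Geq * dfts[[j]]$G
  }
  .dft_cache[[key]] <- delays
  delays
}
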