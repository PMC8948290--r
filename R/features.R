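#' Analysis frequency band
#'
#' @param f_lo,f_hi Band edges in THz; defaults 0.1 and 0.5, the in-band
#'   region where burn contrast is carried.
#' @return Object of class `band_spec`.
#' @export
band_spec <- function(f_lo = 0.1, f_hi = 0.5) {
  if (!(f_lo > 0 && f_lo < f_hi)) stop("band requires 0 < f_lo < f_hi")
  structure(list(f_lo = f_lo, f_hi = f_hi), class = "band_spec")
}

# internal: indices of in-band bins, endpoints inclusive (with a tolerance
# against floating-point grids)
band_bins <- function(freq, band) {
  tol <- 1e-9
  sel <- which(freq >= band$f_lo - tol & freq <= band$f_hi + tol)
  if (length(sel) < 2) stop("band contains fewer than 2 frequency bins")
  if (band$f_hi > max(freq) + tol) stop("band exceeds the Nyquist frequency")
  sel
}

#' Area under a spectral amplitude curve over the analysis band
#'
#' Trapezoidal integration of `|R(f)|` over the in-band bins (endpoints
#' inclusive). Units: THz x amplitude.
#'
#' @param trace A [spectral_trace()] (complex values are reduced by `Mod`),
#'   or a numeric amplitude vector with `freq` supplied.
#' @param band A [band_spec()].
#' @param freq Frequency grid if `trace` is a bare numeric vector.
#' @return Non-negative scalar for non-negative amplitude input.
#' @export
band_area <- function(trace, band = band_spec(), freq = NULL) {
  if (inherits(trace, "spectral_trace")) {
    freq <- trace$freq
    amp <- trace_amplitude(trace)
  } else {
    stopifnot(!is.null(freq))
    amp <- abs(trace)
  }
  sel <- band_bins(freq, band)
  f <- freq[sel]; a <- amp[sel]
  sum(diff(f) * (a[-1] + a[-length(a)]) / 2)
}

# internal: trapezoid quadrature weights on the in-band grid
.trapz_weights <- function(f) {
  n <- length(f)
  w <- numeric(n)
  d <- diff(f)
  w[1] <- d[1] / 2
  w[n] <- d[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (d[-1] + d[-(n - 1)]) / 2
  w
}

#' Spectral-band-area image of a scan
#'
#' Per-pixel area under the reflection spectral amplitude curve over the
#' analysis band, normalized to a maximum of 1 over the field of view.
#' Pixels flagged invalid are returned as `NaN`.
#'
#' @param spectra A `thz_spectra` from [preprocess_scan()].
#' @param band A [band_spec()].
#' @param invalid Optional logical ny x nx matrix of pixels to blank.
#' @return ny x nx numeric matrix with maximum 1.
#' @export
form_image <- function(spectra, band = band_spec(), invalid = NULL) {
  stopifnot(inherits(spectra, "thz_spectra"))
  sel <- band_bins(spectra$freq, band)
  w <- .trapz_weights(spectra$freq[sel])
  areas <- as.numeric(crossprod(spectra$amplitude[sel, , drop = FALSE], w))
  img <- matrix(areas, spectra$ny, spectra$nx)
  if (!is.null(invalid)) img[invalid] <- NaN
  mx <- max(img, na.rm = TRUE)
  if (is.finite(mx) && mx > 0) img <- img / mx
  img
}

#' Detect punch-biopsy pixels from the Fabry-Perot echo phase
#'
#' A punch biopsy leaves an air gap between the imaging window and the
#' tissue, which changes the phase of the window's internal Fabry-Perot
#' reflections: each round trip multiplies the field by \eqn{r_t\, r_b},
#' where \eqn{r_t} is the (real, positive) internal window-air coefficient
#' at the top face and \eqn{r_b} the window-backing coefficient at the
#' bottom face. For an air gap \eqn{r_b = r_t > 0}, so the first echo is in
#' phase with the pixel's primary reflection; for water-rich skin
#' \eqn{\mathrm{Re}(r_b) < 0} across the band, so the echo is phase-reversed
#' relative to the primary. The detector therefore gates the primary pulse
#' and the first-echo segment of each pixel and tests the sign of their
#' lag-one-round-trip correlation
#' \eqn{s = \langle w[\mathrm{echo\ gate}],\, w[\mathrm{primary\ gate}]\rangle}:
#' `s >= 0` (air-like echo phase) marks a biopsy pixel.
#'
#' @param scan A `thz_scan` (raw or denoised).
#' @param window A [window_spec()]; defaults to the scan's own.
#' @param gate_half_width_ps Half-width of the primary/echo gates in ps.
#' @param echo_order Which Fabry-Perot echo to gate (default 1).
#' @return Logical ny x nx matrix, `TRUE` at biopsy (air-gap) pixels.
#' @export
detect_biopsy_mask <- function(scan, window = NULL, gate_half_width_ps = 5,
                               echo_order = 1) {
  stopifnot(inherits(scan, "thz_scan"))
  if (is.null(window)) window <- scan$window
  dt <- scan$t[2] - scan$t[1]
  ref <- scan$reference$amplitude
  i0 <- which.max(abs(ref))
  hw <- round(gate_half_width_ps / dt)
  shift <- round(echo_order * round_trip_ps(window) / dt)
  n <- length(ref)
  if (i0 + shift + hw > n) {
    stop(sprintf(paste0("Fabry-Perot echo %d (round trip %.1f ps, window n = ",
                        "%.3g, thickness %.3g m) falls outside the time record"),
                 echo_order, round_trip_ps(window), window$refractive_index,
                 window$thickness))
  }
  gate_p <- max(1, i0 - hw):min(n, i0 + hw)
  gate_e <- gate_p + shift
  nrm <- sum(ref[gate_p]^2)
  s <- colSums(scan$waveforms[gate_e, , drop = FALSE] *
                 scan$waveforms[gate_p, , drop = FALSE]) / nrm
  matrix(s >= 0, scan$ny, scan$nx)
}

#' Admissible top-left positions for square ROI blocks
#'
#' A position is admissible when the whole `size x size` block lies inside
#' the grid, inside the allowed `region` (if given), and contains no masked
#' (biopsy) pixel.
#'
#' @param mask Logical ny x nx exclusion mask (`TRUE` = excluded pixel).
#' @param size Block side in pixels.
#' @param region Optional logical ny x nx matrix of allowed pixels.
#' @return Two-column integer matrix of (row, col) top-left positions.
#' @export
admissible_roi_positions <- function(mask, size = 4, region = NULL) {
  ny <- nrow(mask); nx <- ncol(mask)
  bad <- mask
  if (!is.null(region)) bad <- bad | !region
  out <- list()
  for (col in seq_len(nx - size + 1)) {
    for (row in seq_len(ny - size + 1)) {
      if (!any(bad[row:(row + size - 1), col:(col + size - 1)])) {
        out[[length(out) + 1]] <- c(row, col)
      }
    }
  }
  if (!length(out)) return(matrix(integer(), 0, 2))
  do.call(rbind, out)
}

#' Randomly sample square regions of interest
#'
#' Draws `k` distinct block positions uniformly from the admissible top-left
#' positions (blocks may overlap each other; they never contain a masked
#' pixel). Reproducible under `seed`.
#'
#' @inheritParams admissible_roi_positions
#' @param k Number of ROIs (default 15).
#' @param seed Integer seed.
#' @param iteration_id Identifier stored with the set.
#' @param disjoint If `TRUE`, blocks are additionally forced to be
#'   pairwise non-overlapping (greedy rejection).
#' @return Object of class `roi_set`: data frame `rois` (roi_id, row, col),
#'   plus `k`, `size`, `seed`, `iteration_id`.
#' @export
sample_rois <- function(mask, k = 15, size = 4, seed = 1L, region = NULL,
                        iteration_id = 1L, disjoint = FALSE) {
  pos <- admissible_roi_positions(mask, size, region)
  if (nrow(pos) < k) {
    stop(sprintf("only %d admissible ROI positions for k = %d", nrow(pos), k))
  }
  rng <- .seeded_rng(seed)
  if (!disjoint) {
    pick <- rng(function() sample.int(nrow(pos), k))
  } else {
    pick <- integer(0)
    order_all <- rng(function() sample.int(nrow(pos)))
    for (i in order_all) {
      ok <- TRUE
      for (j in pick) {
        if (abs(pos[i, 1] - pos[j, 1]) < size &&
            abs(pos[i, 2] - pos[j, 2]) < size) { ok <- FALSE; break }
      }
      if (ok) pick <- c(pick, i)
      if (length(pick) == k) break
    }
    if (length(pick) < k) {
      stop(sprintf("could not place %d disjoint ROIs (%d admissible positions)",
                   k, nrow(pos)))
    }
  }
  structure(list(rois = data.frame(roi_id = seq_len(k),
                                   row = pos[pick, 1], col = pos[pick, 2]),
                 k = k, size = size, seed = seed,
                 iteration_id = iteration_id),
            class = "roi_set")
}

# internal: run fn under a local RNG seed without disturbing the caller's RNG
.seeded_rng <- function(seed) {
  function(fn) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    fn()
  }
}

#' Build the ROI observation table
#'
#' One row per ROI: the feature vector is the arithmetic mean of the block's
#' 16 pixel amplitude spectra restricted to the in-band bins, and
#' `band_area` is the trapezoidal area of that mean spectrum over the band
#' (used for images and the ANOVA stage; the classifiers use the full
#' in-band spectrum).
#'
#' @param spectra A `thz_spectra`.
#' @param roi_set A [sample_rois()] result.
#' @param band A [band_spec()].
#' @param burn_id Burn identifier stored in every row.
#' @param d Dermal burn percentage of the burn (labels derive from it).
#' @return Data frame with columns `burn_id`, `roi_id`, `iteration_id`,
#'   `label`, `d`, `band_area`, then one `f_<THz>` column per in-band bin.
#' @export
build_observations <- function(spectra, roi_set, band = band_spec(),
                               burn_id = 1L, d = NA_real_) {
  stopifnot(inherits(spectra, "thz_spectra"), inherits(roi_set, "roi_set"))
  sel <- band_bins(spectra$freq, band)
  w <- .trapz_weights(spectra$freq[sel])
  size <- roi_set$size
  feats <- matrix(0, nrow(roi_set$rois), length(sel))
  for (i in seq_len(nrow(roi_set$rois))) {
    r0 <- roi_set$rois$row[i]; c0 <- roi_set$rois$col[i]
    px <- as.vector(outer(r0:(r0 + size - 1),
                          (c0:(c0 + size - 1) - 1) * spectra$ny, `+`))
    feats[i, ] <- rowMeans(spectra$amplitude[sel, px, drop = FALSE])
  }
  label <- assign_severity_label(rep(d, nrow(feats)))
  out <- data.frame(burn_id = burn_id, roi_id = roi_set$rois$roi_id,
                    iteration_id = roi_set$iteration_id,
                    label = label, d = d,
                    band_area = as.numeric(feats %*% w))
  feat_df <- as.data.frame(feats)
  names(feat_df) <- sprintf("f_%.4f", spectra$freq[sel])
  cbind(out, feat_df)
}

# internal: names of feature columns in an observation table
.feature_cols <- function(obs) grep("^f_[0-9]", names(obs), value = TRUE)

#' Write an observation table to CSV
#' @param obs Observation table from [build_observations()].
#' @param path Output file.
#' @export
write_observations <- function(obs, path) {
  data.table::fwrite(obs, path)
  invisible(path)
}

#' Export an image matrix as CSV and optionally a PNG preview
#' @param img Numeric matrix (e.g. from [form_image()]).
#' @param csv_path CSV output path.
#' @param png_path Optional PNG preview path.
#' @export
export_image <- function(img, csv_path, png_path = NULL) {
  data.table::fwrite(as.data.frame(img), csv_path, col.names = FALSE)
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 480, height = 480)
    on.exit(grDevices::dev.off())
    graphics::image(t(img[nrow(img):1, , drop = FALSE]), axes = FALSE,
                    col = grDevices::hcl.colors(64, "viridis"))
  }
  invisible(csv_path)
}
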