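#' Scan acquisition configuration
#'
#' Defaults emulate the handheld scanner study conditions: a 27 x 27 mm^2
#' field of view at 1 x 1 mm^2 pixels with 20 time averages per pixel. The
#' time grid is a 160 ps record at 0.025 ps sampling (Nyquist 20 THz) --
#' long enough to contain the analysis band (<= 1 THz) and two window
#' echoes, rather than the instrument's full unambiguous range, and laid
#' out so that the six-level wavelet coefficient supports of the pulse and
#' echoes stay clear of the noise-estimation windows (see
#' [noise_windows()]).
#'
#' @param nx,ny Pixels along x (columns) and y (rows).
#' @param pixel_size Pixel pitch in mm.
#' @param time_window Record length in ps.
#' @param dt Sampling interval in ps; must give a Nyquist frequency >= 2 THz.
#' @param n_averages Number of averaged acquisitions per pixel (>= 1).
#' @param noise_rms Single-shot additive noise RMS, in units of the unit
#'   incident pulse peak. Averaging scales the effective noise by
#'   `1/sqrt(n_averages)`.
#' @param seed Integer seed for the scan's noise and jitter draws.
#' @param pulse_delay Arrival time (ps) of the incident pulse peak.
#' @param pulse_width Gaussian width parameter sigma of the single-cycle
#'   pulse, in ps.
#' @param scatter_jitter Standard deviation of the per-pixel multiplicative
#'   reflectivity jitter emulating scattering heterogeneity of skin
#'   appendages (applied to tissue pixels only; 0 disables).
#' @return Object of class `scan_config`.
#' @export
scan_config <- function(nx = 27, ny = 27, pixel_size = 1,
                        time_window = 160, dt = 0.025,
                        n_averages = 20, noise_rms = 0.005, seed = 1L,
                        pulse_delay = 30, pulse_width = 0.25,
                        scatter_jitter = 0.03) {
  stopifnot(nx >= 1, ny >= 1, pixel_size > 0, time_window > 0, dt > 0)
  if (1 / (2 * dt) < 2) stop("dt too coarse: Nyquist frequency must be >= 2 THz")
  if (n_averages < 1) stop("n_averages must be >= 1")
  if (noise_rms < 0) stop("noise_rms must be >= 0")
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 pixel_size = pixel_size,
                 fov = c(nx * pixel_size, ny * pixel_size),
                 time_window = time_window, dt = dt,
                 n_averages = as.integer(n_averages), noise_rms = noise_rms,
                 seed = as.integer(seed),
                 pulse_delay = pulse_delay, pulse_width = pulse_width,
                 scatter_jitter = scatter_jitter),
            class = "scan_config")
}

#' Time axis of a scan configuration, in ps
#' @param config A [scan_config()].
#' @export
time_axis <- function(config) {
  n <- round(config$time_window / config$dt)
  seq(0, by = config$dt, length.out = n)
}

#' One-sided frequency axis (THz) of the scan's FFT grid
#' @param config A [scan_config()].
#' @export
freq_axis <- function(config) {
  n <- round(config$time_window / config$dt)
  (0:(n %/% 2)) / (n * config$dt)
}

#' A single scald burn site
#'
#' The wound footprint is a square of half-width `radius` (mm) centred on
#' `center` (the scald paddles produce compact wounds; a square footprint
#' guarantees admissible ROI block positions inside small wounds).
#'
#' @param center Integer pair `c(row, col)`, 1-based pixel indices.
#' @param radius Half-width of the square footprint in mm.
#' @param d Dermal burn percentage in `[0, 100]`.
#' @param hydration_delta Optional explicit hydration delta; default derives
#'   from `d` via [severity_to_hydration()].
#' @export
burn_site <- function(center, radius, d, hydration_delta = NULL) {
  stopifnot(length(center) == 2, radius > 0)
  if (d < 0 || d > 100) stop("dermal burn percentage d must lie in [0, 100]")
  list(center = as.integer(center), radius = radius, d = d,
       hydration_delta = hydration_delta)
}

#' Phantom specification: burn sites, biopsy disks, healthy background
#'
#' @param burn_sites List of [burn_site()]s; all must lie inside the FOV.
#' @param biopsy_disks List of `list(center = c(row, col), diameter = 4)`
#'   punch-biopsy air-gap disks (diameter in mm, default 4).
#' @param background_hydration Baseline hydration delta of healthy skin.
#' @export
phantom_spec <- function(burn_sites = list(), biopsy_disks = list(),
                         background_hydration = 0) {
  biopsy_disks <- lapply(biopsy_disks, function(b) {
    if (is.null(b$diameter)) b$diameter <- 4
    stopifnot(length(b$center) == 2, b$diameter > 0)
    b
  })
  structure(list(burn_sites = burn_sites, biopsy_disks = biopsy_disks,
                 background_hydration = background_hydration),
            class = "phantom_spec")
}

#' Map dermal burn percentage to a hydration delta
#'
#' Post-burn interstitial edema raises tissue water content, hence the
#' slow-relaxation dielectric amplitude. The mapping is linear in `d` with a
#' configurable maximum: `delta = max_delta * d / 100`. Any monotone map
#' satisfies the qualitative edema mechanism; linearity is the simplest
#' documented choice. The delta scales the Debye `eps_static - eps_mid`
#' amplitude (see [burned_skin_eps()]).
#'
#' @param d Dermal burn percentage in `[0, 100]` (vectorized).
#' @param max_delta Delta at `d = 100`; default 0.3 (raises `eps_static`
#'   from 60 towards the free-water value ~78).
#' @return Hydration delta, non-decreasing in `d`, 0 at `d = 0`.
#' @export
severity_to_hydration <- function(d, max_delta = 0.3) {
  if (any(d < 0 | d > 100)) stop("d must lie in [0, 100]")
  max_delta * d / 100
}

#' Permittivity of (possibly edematous) skin
#'
#' Applies a hydration delta to the slow-relaxation amplitude:
#' `eps_static` is replaced by `eps_static + delta * (eps_static - eps_mid)`.
#'
#' @param debye Healthy-skin [debye_params()].
#' @param delta Hydration delta (0 = healthy baseline).
#' @param freq_thz Frequency grid in THz.
#' @return Complex permittivity vector.
#' @export
burned_skin_eps <- function(debye, delta, freq_thz) {
  amp <- debye$eps_static - debye$eps_mid
  p <- debye_params(eps_static = debye$eps_static + delta * amp,
                    eps_mid = debye$eps_mid, eps_inf = debye$eps_inf,
                    tau1 = debye$tau1, tau2 = debye$tau2)
  debye_permittivity(p, freq_thz)
}

#' Synthetic incident THz pulse
#'
#' Deterministic single-cycle pulse (first derivative of a Gaussian),
#' normalized to unit peak, with its positive peak at `pulse_delay`. Its
#' amplitude spectrum covers 0.1-1.0 THz and integrates to ~zero (no DC).
#'
#' @param config A [scan_config()].
#' @return A [thz_waveform()] of kind `"reference"`.
#' @export
synth_reference_pulse <- function(config) {
  stopifnot(inherits(config, "scan_config"))
  t <- time_axis(config)
  s <- config$pulse_width
  u <- t - (config$pulse_delay + s)
  amp <- -(u / s) * exp(0.5 - u^2 / (2 * s^2))
  thz_waveform(t, amp, kind = "reference")
}

# internal: apply a one-sided physics-convention transfer function H(f>=0)
# to a real waveform via the FFT. The FFT synthesis kernel is e^{+i 2 pi f t},
# so positive-frequency bins are multiplied by Conj(H); negative bins follow
# by Hermitian symmetry, keeping the output real.
apply_response <- function(amplitude, H_onesided) {
  n <- length(amplitude)
  nh <- length(H_onesided)
  stopifnot(nh == n %/% 2 + 1)
  Hf <- complex(length.out = n)
  Hf[1:nh] <- Conj(H_onesided)
  if (n %% 2 == 0) {
    Hf[nh] <- Re(Hf[nh])  # Nyquist bin must be real
    if (nh > 2) Hf[(nh + 1):n] <- Conj(Hf[(nh - 1):2])
  } else if (nh > 1) {
    Hf[(nh + 1):n] <- Conj(Hf[nh:2])
  }
  Re(stats::fft(stats::fft(amplitude) * Hf, inverse = TRUE)) / n
}

# internal: rasterize phantom geometry onto the pixel grid.
# Returns site id map (0 healthy), biopsy mask, hydration map.
rasterize_phantom <- function(phantom, config, max_delta = 0.3) {
  ny <- config$ny; nx <- config$nx; ps <- config$pixel_size
  site_id <- matrix(0L, ny, nx)
  hydration <- matrix(phantom$background_hydration, ny, nx)
  rows <- matrix(seq_len(ny), ny, nx)
  cols <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  for (k in seq_along(phantom$burn_sites)) {
    s <- phantom$burn_sites[[k]]
    if (s$center[1] < 1 || s$center[1] > ny || s$center[2] < 1 || s$center[2] > nx) {
      stop("burn site center outside the field of view")
    }
    half_px <- s$radius / ps
    inside <- abs(rows - s$center[1]) <= half_px & abs(cols - s$center[2]) <= half_px
    site_id[inside] <- k
    delta <- if (!is.null(s$hydration_delta)) s$hydration_delta
             else severity_to_hydration(s$d, max_delta)
    hydration[inside] <- delta
  }
  mask <- matrix(FALSE, ny, nx)
  for (b in phantom$biopsy_disks) {
    r_px <- (b$diameter / 2) / ps
    inside <- (rows - b$center[1])^2 + (cols - b$center[2])^2 <= r_px^2
    full <- sum((matrix(seq(-ceiling(r_px), ceiling(r_px)), 2 * ceiling(r_px) + 1,
                        2 * ceiling(r_px) + 1)^2 +
                 matrix(seq(-ceiling(r_px), ceiling(r_px)), 2 * ceiling(r_px) + 1,
                        2 * ceiling(r_px) + 1, byrow = TRUE)^2) <= r_px^2)
    if (sum(inside) < full) {
      warning("biopsy disk clipped at the field-of-view edge")
    }
    mask <- mask | inside
  }
  list(site_id = site_id, biopsy_mask = mask, hydration = hydration)
}

#' Simulate a THz reflection scan cube
#'
#' Per-pixel forward model: incident pulse convolved with the window-backed
#' sample transfer function ([sample_response_spectrum()]). Biopsy-disk
#' pixels carry the window-air response (the punch leaves an air gap under
#' the window); all other pixels carry the window-skin response at the
#' pixel's hydration delta. Tissue pixels receive a multiplicative
#' reflectivity jitter (scattering heterogeneity), and every pixel receives
#' additive white noise of RMS `noise_rms / sqrt(n_averages)`. The reference
#' channel is the time-gated primary window-air reflection (flat Fresnel
#' coefficient times the incident pulse), as used for deconvolution.
#'
#' Identical `(phantom, config, window, debye)` and seed reproduce the cube
#' bit-for-bit.
#'
#' @param phantom A [phantom_spec()].
#' @param config A [scan_config()].
#' @param window A [window_spec()].
#' @param debye Healthy-skin [debye_params()].
#' @param max_delta Passed to [severity_to_hydration()] for sites specified
#'   by `d`.
#' @return Object of class `thz_scan`: fields `t`, `waveforms` (nt x npix
#'   matrix, pixels column-major over rows), `reference`, `nx`, `ny`,
#'   `config`, `window`, `debye`, `phantom` and `truth` (site table, site id
#'   map, biopsy mask, hydration map).
#' @export
synth_scan <- function(phantom, config = scan_config(),
                       window = window_spec(), debye = debye_params(),
                       max_delta = 0.3) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(config, "scan_config"))
  t <- time_axis(config)
  n <- length(t)
  freq <- freq_axis(config)
  pulse <- synth_reference_pulse(config)
  geom <- rasterize_phantom(phantom, config, max_delta)

  # unique media: air (biopsy gaps) + one per distinct hydration delta
  deltas <- sort(unique(geom$hydration[!geom$biopsy_mask]))
  H_air <- sample_response_spectrum(window, 1 + 0i, freq, config$time_window)
  w_air <- apply_response(pulse$amplitude, H_air$value)
  w_by_delta <- lapply(deltas, function(dl) {
    eps <- burned_skin_eps(debye, dl, freq)
    H <- sample_response_spectrum(window, eps, freq, config$time_window)
    apply_response(pulse$amplitude, H$value)
  })

  r_wa <- fresnel_reflection(window$refractive_index, 1)
  reference <- thz_waveform(t, Re(r_wa) * pulse$amplitude, kind = "reference")

  npix <- config$nx * config$ny
  set.seed(config$seed)
  jitter <- 1 + config$scatter_jitter * stats::rnorm(npix)
  sigma <- config$noise_rms / sqrt(config$n_averages)
  waveforms <- matrix(0, n, npix)
  for (col in seq_len(config$nx)) {
    for (row in seq_len(config$ny)) {
      idx <- pixel_linear_index(row, col, config$ny)
      if (geom$biopsy_mask[row, col]) {
        base <- w_air
      } else {
        dl <- geom$hydration[row, col]
        base <- jitter[idx] * w_by_delta[[match(dl, deltas)]]
      }
      waveforms[, idx] <- base + stats::rnorm(n, 0, sigma)
    }
  }

  sites <- if (length(phantom$burn_sites)) {
    data.frame(
      site = seq_along(phantom$burn_sites),
      row = vapply(phantom$burn_sites, function(s) s$center[1], 1L),
      col = vapply(phantom$burn_sites, function(s) s$center[2], 1L),
      radius = vapply(phantom$burn_sites, function(s) s$radius, 1),
      d = vapply(phantom$burn_sites, function(s) s$d, 1),
      label = assign_severity_label(vapply(phantom$burn_sites,
                                           function(s) s$d, 1))
    )
  } else {
    data.frame(site = integer(), row = integer(), col = integer(),
               radius = numeric(), d = numeric(),
               label = factor(character(), levels = severity_levels()))
  }

  structure(list(t = t, waveforms = waveforms, reference = reference,
                 nx = config$nx, ny = config$ny,
                 config = config, window = window, debye = debye,
                 phantom = phantom,
                 truth = list(sites = sites, site_id = geom$site_id,
                              biopsy_mask = geom$biopsy_mask,
                              hydration = geom$hydration)),
            class = "thz_scan")
}

#' Single-burn phantom over the default field of view
#'
#' One square scald wound centred in the FOV, optionally with one 4-mm
#' punch-biopsy air-gap disk inside the wound.
#'
#' @param d Dermal burn percentage of the wound.
#' @param nx,ny Grid size in pixels.
#' @param radius Wound half-width in mm.
#' @param biopsy Include a 4-mm biopsy disk?
#' @param biopsy_offset Biopsy center offset `c(row, col)` from the wound
#'   center; defaults to the wound's upper-right quadrant (where biopsies
#'   sit as imaging fiducials), scaled with the wound size.
#' @export
single_burn_phantom <- function(d, nx = 27, ny = 27, radius = 8,
                                biopsy = TRUE, biopsy_offset = NULL) {
  if (is.null(biopsy_offset)) {
    biopsy_offset <- c(-round(radius / 2), round(radius / 2))
  }
  center <- c((ny + 1) %/% 2, (nx + 1) %/% 2)
  disks <- if (biopsy) {
    list(list(center = center + biopsy_offset, diameter = 4))
  } else list()
  phantom_spec(burn_sites = list(burn_site(center, radius, d)),
               biopsy_disks = disks)
}

#' Default study: burn severities spanning the three grades
#'
#' Ten dermal-burn percentages covering SPT, DPT and FT, echoing the
#' study's ten scald burns (one wound per scan).
#'
#' @param gamma Hydration-separation scale: each `d` keeps its label but the
#'   hydration delta is scaled by `gamma` (1 = nominal physics, 0 = no
#'   severity contrast). Used for signal-recovery checks.
#' @export
default_study_d <- function() c(10, 22, 30, 45, 55, 65, 75, 85, 92, 97)

#' Build the phantoms + configs of a simulated study
#'
#' One single-burn scan per entry of `d`; scan seeds derive from
#' `seed + scan index`.
#'
#' @param d Dermal burn percentages, one scan each.
#' @param seed Master seed.
#' @param nx,ny,radius Geometry per scan.
#' @param gamma Hydration-separation scale in `[0, 1]` (see above).
#' @param biopsy Logical (recycled): include a biopsy disk per scan.
#' @param ... Passed to [scan_config()].
#' @return List of `list(phantom, config)` study members.
#' @export
study_spec <- function(d = default_study_d(), seed = 1L,
                       nx = 27, ny = 27, radius = 8, gamma = 1,
                       biopsy = TRUE, ...) {
  biopsy <- rep_len(biopsy, length(d))
  lapply(seq_along(d), function(i) {
    ph <- single_burn_phantom(d[i], nx = nx, ny = ny, radius = radius,
                              biopsy = biopsy[i])
    # keep the label from d but scale the physical hydration contrast
    ph$burn_sites[[1]]$hydration_delta <-
      gamma * severity_to_hydration(d[i])
    cf <- scan_config(nx = nx, ny = ny, seed = seed + i, ...)
    list(phantom = ph, config = cf)
  })
}

#' Simulate a full study of scan cubes
#' @param spec Output of [study_spec()].
#' @param window,debye Shared optics and dielectric model.
#' @return List of `thz_scan` cubes.
#' @export
synth_study <- function(spec, window = window_spec(), debye = debye_params()) {
  lapply(spec, function(m) synth_scan(m$phantom, m$config, window, debye))
}
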