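test_that("window response sums the Fabry-Perot series correctly", {
  win <- window_spec(refractive_index = 1.95, thickness = 4e-3, n_echoes = 1)
  f <- seq(0.1, 0.8, length.out = 8)
  eps <- debye_permittivity(debye_params(), f)
  tr <- sample_response_spectrum(win, eps, f)
  # hand-summed two-term series
  n_med <- sqrt(eps)
  r_b <- (win$refractive_index - n_med) / (win$refractive_index + n_med)
  r_t <- (win$refractive_index - 1) / (win$refractive_index + 1)
  T_ps <- 2 * win$refractive_index * win$thickness / 299792458 * 1e12
  oracle <- r_b + r_b * (r_t * r_b) * exp(1i * 2 * pi * f * T_ps)
  expect_equal(tr$value, oracle, tolerance = 1e-12)
})

test_that("echo amplitudes decay geometrically and sign tracks the medium", {
  win <- window_spec(n_echoes = 3)
  f <- 0.3
  H_air <- sample_response_spectrum(win, 1 + 0i, f)
  eps_skin <- debye_permittivity(debye_params(), f)
  r_t <- Re(fresnel_reflection(win$refractive_index, 1))
  r_air <- r_t  # window-air back face equals the internal top-face value
  # echo orders decay as (r_t r_b)^m
  expect_true(all(abs(r_air * (r_t * r_air)^(1:3)) <
                    abs(r_air * (r_t * r_air)^(0:2))))
  # primary reflection signs differ between air and skin backing
  r_skin <- fresnel_reflection(win$refractive_index,
                               refractive_index(eps_skin))
  expect_gt(Re(r_air), 0)
  expect_lt(Re(r_skin), 0)
  expect_error(window_spec(n_echoes = 0), "n_echoes")
})

test_that("echoes beyond the time record are dropped, not wrapped", {
  thick <- window_spec(thickness = 0.05, n_echoes = 2)  # 650 ps round trip
  f <- seq(0, 2, by = 0.1)
  tr <- sample_response_spectrum(thick, 1 + 0i, f, time_window_ps = 160)
  primary <- fresnel_reflection(thick$refractive_index, 1) + 0 * f
  expect_equal(tr$value, primary, tolerance = 1e-14)
})

test_that("synthetic reference pulse meets its bandwidth and shape contract", {
  cf <- scan_config()
  p <- synth_reference_pulse(cf)
  f <- freq_axis(cf)
  amp <- Mod(stats::fft(p$amplitude))[seq_along(f)]
  a03 <- amp[which.min(abs(f - 0.3))]
  a3 <- amp[which.min(abs(f - 3))]
  expect_gt(a03, 10 * a3)
  # single-cycle pulse has (nearly) zero DC content
  expect_lt(abs(sum(p$amplitude)), 1e-8 * sum(abs(p$amplitude)))
  # positive peak sits at the configured delay
  expect_equal(p$t[which.max(p$amplitude)], cf$pulse_delay)
  # deterministic
  expect_identical(p$amplitude, synth_reference_pulse(cf)$amplitude)
})

test_that("severity-to-hydration map is linear, monotone and anchored at 0", {
  expect_identical(severity_to_hydration(0), 0)
  expect_equal(severity_to_hydration(50, max_delta = 0.3), 0.15)
  d <- seq(0, 100, by = 5)
  expect_true(all(diff(severity_to_hydration(d)) >= 0))
  expect_error(severity_to_hydration(101), "\\[0, 100\\]")
})

test_that("scan synthesis is deterministic and spatially uniform when clean", {
  cf <- scan_config(nx = 4, ny = 4, noise_rms = 0, scatter_jitter = 0,
                    seed = 3)
  ph <- phantom_spec(burn_sites = list(burn_site(c(2, 2), 5, 50)))
  s1 <- synth_scan(ph, cf)
  s2 <- synth_scan(ph, cf)
  expect_identical(s1$waveforms, s2$waveforms)
  # uniform phantom, no noise -> all pixel waveforms identical
  ph0 <- phantom_spec()
  s0 <- synth_scan(ph0, cf)
  expect_true(all(apply(s0$waveforms, 1, function(r) diff(range(r)) == 0)))
})

test_that("full-thickness sites reflect more in-band than superficial ones", {
  cf <- scan_config(nx = 2, ny = 1, noise_rms = 0, scatter_jitter = 0)
  ph <- phantom_spec(burn_sites = list(burn_site(c(1, 1), 0.6, 10),
                                       burn_site(c(1, 2), 0.6, 95)))
  sp <- preprocess_scan(synth_scan(ph, cf), denoise = FALSE)
  sel <- sp$freq >= 0.1 & sp$freq <= 0.5
  spt <- mean(sp$amplitude[sel, 1])
  ft <- mean(sp$amplitude[sel, 2])
  expect_gt(ft, spt)
})

test_that("biopsy disks rasterize to the 4-mm footprint and clip with warning", {
  cf <- scan_config(nx = 9, ny = 9, noise_rms = 0)
  ph <- phantom_spec(biopsy_disks = list(list(center = c(5, 5), diameter = 4)))
  s <- synth_scan(ph, cf)
  # pixel centres within 2 mm of the disk centre on a 1-mm grid
  expect_identical(sum(s$truth$biopsy_mask), 13L)
  ph_edge <- phantom_spec(biopsy_disks = list(list(center = c(1, 1),
                                                   diameter = 4)))
  expect_warning(synth_scan(ph_edge, cf), "clipped")
})

test_that("pre-pulse noise variance scales as noise_rms^2 / n_averages", {
  var_pre <- function(n_avg, seeds) {
    vapply(seeds, function(sd_) {
      cf <- scan_config(nx = 1, ny = 1, time_window = 50, pulse_delay = 20,
                        n_averages = n_avg, noise_rms = 0.02, seed = sd_,
                        scatter_jitter = 0)
      s <- synth_scan(phantom_spec(), cf)
      stats::var(s$waveforms[s$t < 10, 1])
    }, numeric(1))
  }
  v1 <- mean(var_pre(1, 1:200))
  v16 <- mean(var_pre(16, 201:400))
  expect_equal(v1 / v16, 16, tolerance = 0.25)
  expect_equal(v1, 0.02^2, tolerance = 0.1)
})
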