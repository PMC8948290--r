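test_that("band area integrates amplitude over the analysis band", {
  cf <- scan_config()
  f <- freq_axis(cf)
  ones <- spectral_trace(f, rep(1, length(f)))
  expect_equal(band_area(ones), 0.4, tolerance = 1e-12)
  expect_identical(band_area(spectral_trace(f, rep(0, length(f)))), 0)
  # |R(f)| = f integrates to (0.5^2 - 0.1^2)/2 exactly (trapezoid is exact
  # for a linear integrand)
  expect_equal(band_area(spectral_trace(f, f)), 0.12, tolerance = 1e-12)
  expect_error(band_spec(0.5, 0.1), "f_lo < f_hi")
})

test_that("band-area images are normalized and rescale-invariant", {
  fix <- tiny_fixture()
  sp <- fix$spectra[[1]]
  img <- form_image(sp)
  expect_equal(dim(img), c(9, 9))
  expect_equal(max(img, na.rm = TRUE), 1)
  sp2 <- sp
  sp2$amplitude <- sp$amplitude * 37.5
  expect_equal(form_image(sp2), img, tolerance = 1e-12)
  # uniform phantom -> constant map of ones
  cfu <- scan_config(nx = 3, ny = 3, noise_rms = 0, scatter_jitter = 0)
  spu <- preprocess_scan(synth_scan(phantom_spec(), cfu), denoise = FALSE)
  expect_true(all(abs(form_image(spu) - 1) < 1e-12))
  # invalid pixels become NaN
  inv <- matrix(FALSE, 9, 9); inv[1, 1] <- TRUE
  expect_true(is.nan(form_image(sp, invalid = inv)[1, 1]))
})

test_that("the image maximum tracks the highest-hydration site", {
  cf <- scan_config(nx = 9, ny = 5, noise_rms = 0, scatter_jitter = 0)
  ph <- phantom_spec(burn_sites = list(burn_site(c(3, 2), 1, 20),
                                       burn_site(c(3, 7), 1, 95)))
  sp <- preprocess_scan(synth_scan(ph, cf), denoise = FALSE)
  img <- form_image(sp)
  peak <- which(img == 1, arr.ind = TRUE)
  expect_true(all(abs(peak[, "col"] - 7) <= 1))
})

test_that("echo-phase masking matches the simulated biopsy ground truth", {
  fix <- tiny_fixture()
  for (i in 1:3) {
    expect_identical(fix$masks[[i]], fix$scans[[i]]$truth$biopsy_mask)
  }
  # all-air scan (reference waveform everywhere, no echoes) is all air-like
  cf <- scan_config(nx = 2, ny = 2, noise_rms = 0, scatter_jitter = 0)
  ph <- phantom_spec(biopsy_disks = list(list(center = c(1, 1), diameter = 20)))
  expect_warning(sc_air <- synth_scan(ph, cf), "clipped")
  expect_true(all(detect_biopsy_mask(sc_air)))
  # echo outside the record is an explicit failure naming the window
  sc <- fix$scans[[1]]
  expect_error(detect_biopsy_mask(sc, window_spec(thickness = 0.02)),
               "outside the time record")
})

test_that("ROI sampling draws admissible positions reproducibly", {
  mask <- matrix(FALSE, 27, 27)
  expect_identical(nrow(admissible_roi_positions(mask, 4)), 576L)
  expect_error(sample_rois(matrix(TRUE, 27, 27)), "0 admissible")
  rs <- sample_rois(mask, k = 15, size = 4, seed = 42)
  expect_identical(nrow(rs$rois), 15L)
  expect_identical(rs$size * rs$size, 16)
  expect_identical(rs$rois, sample_rois(mask, k = 15, size = 4, seed = 42)$rois)
  # no sampled block may touch a masked pixel
  mask2 <- matrix(FALSE, 12, 12); mask2[5:7, 5:7] <- TRUE
  rs2 <- sample_rois(mask2, k = 10, size = 4, seed = 1)
  for (i in 1:10) {
    blk <- mask2[rs2$rois$row[i]:(rs2$rois$row[i] + 3),
                 rs2$rois$col[i]:(rs2$rois$col[i] + 3)]
    expect_false(any(blk))
  }
  # disjoint mode yields non-overlapping blocks
  rd <- sample_rois(mask, k = 8, size = 4, seed = 3, disjoint = TRUE)
  for (i in 1:7) for (j in (i + 1):8) {
    expect_true(abs(rd$rois$row[i] - rd$rois$row[j]) >= 4 ||
                  abs(rd$rois$col[i] - rd$rois$col[j]) >= 4)
  }
})

test_that("observation rows average the sixteen pixel spectra", {
  fix <- tiny_fixture()
  sp <- fix$spectra[[2]]
  rs <- sample_rois(fix$masks[[2]], k = 3, size = 4, seed = 9,
                    region = sp$truth$site_id == 1)
  obs <- build_observations(sp, rs, burn_id = 2, d = 60)
  expect_identical(nrow(obs), 3L)
  expect_true(all(obs$label == "DPT"))
  fc <- grep("^f_", names(obs), value = TRUE)
  sel <- sp$freq >= 0.1 & sp$freq <= 0.5
  expect_identical(length(fc), sum(sel))
  # brute-force re-averaging of the stored per-pixel spectra
  for (i in 1:3) {
    px <- as.vector(outer(rs$rois$row[i]:(rs$rois$row[i] + 3),
                          (rs$rois$col[i]:(rs$rois$col[i] + 3) - 1) * sp$ny,
                          `+`))
    oracle <- rowMeans(sp$amplitude[sel, px])
    expect_equal(as.numeric(obs[i, fc]), oracle, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # sixteen identical pixels -> feature equals any single pixel spectrum
  sp_u <- sp
  sp_u$amplitude <- matrix(sp$amplitude[, 1], nrow(sp$amplitude),
                           ncol(sp$amplitude))
  obs_u <- build_observations(sp_u, rs, burn_id = 2, d = 60)
  expect_equal(as.numeric(obs_u[1, fc]), sp$amplitude[sel, 1],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("ROI averaging reduces amplitude variance at in-band bins", {
  # repeated noise realizations of a uniform healthy scan, no jitter:
  # the 16-pixel ROI mean must beat a single pixel by at least 4x in variance
  cf0 <- function(seed) scan_config(nx = 4, ny = 4, seed = seed,
                                    scatter_jitter = 0)
  single <- NULL; roi <- NULL
  for (sd_ in 1:30) {
    sp <- preprocess_scan(synth_scan(phantom_spec(), cf0(sd_)),
                          denoise = FALSE)
    sel <- which(sp$freq >= 0.1 & sp$freq <= 0.5)[c(1, 20, 40)]
    single <- rbind(single, sp$amplitude[sel, 1])
    roi <- rbind(roi, rowMeans(sp$amplitude[sel, ]))
  }
  v_single <- apply(single, 2, stats::var)
  v_roi <- apply(roi, 2, stats::var)
  expect_true(all(v_roi <= v_single / 4))
})
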