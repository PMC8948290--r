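#' Write a scan cube to a plain-text container
#'
#' On-disk layout (one directory per scan): `meta.json` (config, window,
#' Debye model, phantom, truth site table), `time_axis.csv`,
#' `waveforms.csv` (nt x npix, pixels column-major over rows),
#' `reference.csv`, `truth_biopsy_mask.csv`, `truth_hydration.csv`,
#' `truth_site_id.csv`. Everything is plain text so containers diff and
#' checksum cleanly.
#'
#' @param scan A `thz_scan`.
#' @param dir Target directory (created; overwritten if it exists).
#' @export
write_scan <- function(scan, dir) {
  stopifnot(inherits(scan, "thz_scan"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    nx = scan$nx, ny = scan$ny,
    config = unclass(scan$config), window = unclass(scan$window),
    debye = unclass(scan$debye),
    phantom = rapply(unclass(scan$phantom), identity, how = "list"),
    sites = scan$truth$sites, denoised = isTRUE(scan$denoised))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  data.table::fwrite(data.frame(t = scan$t), file.path(dir, "time_axis.csv"))
  data.table::fwrite(as.data.frame(scan$waveforms),
                     file.path(dir, "waveforms.csv"), col.names = FALSE)
  data.table::fwrite(data.frame(reference = scan$reference$amplitude),
                     file.path(dir, "reference.csv"))
  data.table::fwrite(as.data.frame(scan$truth$biopsy_mask * 1L),
                     file.path(dir, "truth_biopsy_mask.csv"), col.names = FALSE)
  data.table::fwrite(as.data.frame(scan$truth$hydration),
                     file.path(dir, "truth_hydration.csv"), col.names = FALSE)
  data.table::fwrite(as.data.frame(scan$truth$site_id),
                     file.path(dir, "truth_site_id.csv"), col.names = FALSE)
  invisible(dir)
}

#' Read a scan cube from its plain-text container
#' @param dir Directory written by [write_scan()].
#' @return A `thz_scan`.
#' @export
read_scan <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = FALSE)
  t <- data.table::fread(file.path(dir, "time_axis.csv"))$t
  waveforms <- as.matrix(data.table::fread(file.path(dir, "waveforms.csv"),
                                           header = FALSE))
  dimnames(waveforms) <- NULL
  reference <- data.table::fread(file.path(dir, "reference.csv"))$reference
  mask <- as.matrix(data.table::fread(file.path(dir, "truth_biopsy_mask.csv"),
                                      header = FALSE)) == 1
  hyd <- as.matrix(data.table::fread(file.path(dir, "truth_hydration.csv"),
                                     header = FALSE))
  sid <- as.matrix(data.table::fread(file.path(dir, "truth_site_id.csv"),
                                     header = FALSE))
  dimnames(mask) <- dimnames(hyd) <- dimnames(sid) <- NULL
  cf <- do.call(scan_config,
                lapply(meta$config[setdiff(names(meta$config), "fov")], unlist))
  win <- do.call(window_spec, lapply(meta$window, unlist))
  dp <- do.call(debye_params, lapply(meta$debye, unlist))
  ph <- phantom_spec(
    burn_sites = lapply(meta$phantom$burn_sites, function(s)
      burn_site(unlist(s$center), unlist(s$radius), unlist(s$d),
                hydration_delta = unlist(s$hydration_delta))),
    biopsy_disks = lapply(meta$phantom$biopsy_disks, function(b)
      list(center = unlist(b$center), diameter = unlist(b$diameter))),
    background_hydration = unlist(meta$phantom$background_hydration))
  sites <- do.call(rbind, lapply(meta$sites, function(s)
    data.frame(site = as.integer(unlist(s$site)), row = as.integer(unlist(s$row)),
               col = as.integer(unlist(s$col)), radius = as.numeric(unlist(s$radius)),
               d = as.numeric(unlist(s$d)), label = unlist(s$label))))
  sites$label <- factor(sites$label, levels = severity_levels())
  structure(list(t = t, waveforms = waveforms,
                 reference = thz_waveform(t, reference, kind = "reference"),
                 nx = meta$nx, ny = meta$ny, config = cf, window = win,
                 debye = dp, phantom = ph,
                 truth = list(sites = sites, site_id = sid,
                              biopsy_mask = mask, hydration = hyd),
                 denoised = isTRUE(meta$denoised)),
            class = "thz_scan")
}

#' Pipeline configuration
#'
#' One nested list mirroring each stage's parameters, with a master seed
#' from which every stage seed derives deterministically. Serializes to
#' YAML and round-trips unchanged.
#'
#' @param out_dir Output directory for all artifacts.
#' @param master_seed Master seed.
#' @param study `list(d, nx, ny, radius, gamma, biopsy)` study geometry
#'   (see [study_spec()]).
#' @param simulate `list(noise_rms, n_averages, scatter_jitter, ...)`
#'   extra [scan_config()] settings.
#' @param preprocess `list(wavelet, n_levels, pre, post)` denoising and
#'   noise-window settings.
#' @param features `list(f_lo, f_hi, k_rois, roi_size)`.
#' @param classify `list(families, n_iterations, cv_folds, n_search_evals,
#'   inner_folds, burn_grouped)`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "thzburnmap-run", master_seed = 1L,
                            study = list(), simulate = list(),
                            preprocess = list(), features = list(),
                            classify = list()) {
  cfg <- list(
    out_dir = out_dir, master_seed = as.integer(master_seed),
    study = utils::modifyList(
      list(d = default_study_d(), nx = 27, ny = 27, radius = 8, gamma = 1,
           biopsy = TRUE), study),
    simulate = utils::modifyList(
      list(noise_rms = 0.005, n_averages = 20, scatter_jitter = 0.03),
      simulate),
    preprocess = utils::modifyList(
      list(wavelet = "sym8", n_levels = 6, pre = c(1, 13), post = c(47, 65)),
      preprocess),
    features = utils::modifyList(
      list(f_lo = 0.1, f_hi = 0.5, k_rois = 15, roi_size = 4), features),
    classify = utils::modifyList(
      list(families = classifier_families(), n_iterations = 10, cv_folds = 5,
           n_search_evals = 30, inner_folds = 3, burn_grouped = FALSE),
      classify))
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

#' Validate a pipeline configuration before any computation
#' @param cfg A configuration list.
#' @return The config, invisibly; errors on invalid settings.
#' @export
validate_pipeline_config <- function(cfg) {
  with(cfg$features, if (f_lo <= 0 || f_lo >= f_hi)
    stop("invalid band: need 0 < f_lo < f_hi"))
  if (any(cfg$study$d < 0 | cfg$study$d > 100)) {
    stop("study d values must lie in [0, 100]")
  }
  if (cfg$study$gamma < 0) stop("gamma must be >= 0")
  if (!all(cfg$classify$families %in% classifier_families())) {
    stop("unknown classifier family in config")
  }
  with(cfg$preprocess, noise_windows(pre, post))
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' @rdname read_pipeline_config
#' @param cfg A [pipeline_config()].
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# internal: stable hash of a config (via its canonical YAML string)
.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

# internal: manifest bookkeeping
.read_manifest <- function(out_dir) {
  p <- file.path(out_dir, "manifest.json")
  if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE) else list()
}

.write_manifest <- function(out_dir, manifest) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.stage_checksums <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Run the analysis pipeline
#'
#' Orchestrates the four stages over the configured study:
#' \describe{
#'   \item{simulate}{synthesize one scan cube per burn and write containers}
#'   \item{preprocess}{wavelet-denoise and Wiener-deconvolve every pixel,
#'     write spectra}
#'   \item{features}{echo-phase biopsy masks, band-area images, and the
#'     randomized-ROI observation tables for every iteration}
#'   \item{classify}{cross-validated one-vs-all evaluation of the
#'     configured families, metrics / ROC / summary outputs}
#' }
#' `"all"` runs them in order. Each completed stage records its config hash
#' and output checksums in `manifest.json`; rerunning a completed stage
#' with an unchanged config is a no-op unless `force = TRUE`. Reruns with
#' the same master seed reproduce identical observation tables.
#'
#' @param stage One of `"simulate"`, `"preprocess"`, `"features"`,
#'   `"classify"`, `"all"`.
#' @param config A [pipeline_config()], or a path to its YAML file.
#' @param force Rerun even if the stage is up to date.
#' @param quiet Suppress progress messages.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "preprocess", "features",
                                   "classify"),
                         config = pipeline_config(), force = FALSE,
                         quiet = FALSE) {
  stage <- match.arg(stage)
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  stages <- if (stage == "all") {
    c("simulate", "preprocess", "features", "classify")
  } else stage
  for (s in stages) .run_stage(s, config, force, quiet)
  invisible(.read_manifest(config$out_dir))
}

.run_stage <- function(stage, cfg, force, quiet) {
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- .read_manifest(out)
  hash <- .config_hash(cfg)
  done <- manifest$stages[[stage]]
  if (!force && !is.null(done) && identical(done$config_hash, hash)) {
    if (!quiet) message(sprintf("[%s] up to date, skipping (use force = TRUE to rerun)", stage))
    return(invisible(NULL))
  }
  if (!quiet) message(sprintf("[%s] running (master seed %d)", stage,
                              cfg$master_seed))
  paths <- switch(stage,
    simulate = .stage_simulate(cfg, quiet),
    preprocess = .stage_preprocess(cfg, quiet),
    features = .stage_features(cfg, quiet),
    classify = .stage_classify(cfg, quiet))
  manifest$config_hash <- hash
  manifest$master_seed <- cfg$master_seed
  manifest$package_version <- as.character(utils::packageVersion("thzburnmap"))
  if (is.null(manifest$stages)) manifest$stages <- list()
  manifest$stages[[stage]] <- list(config_hash = hash,
                                   completed = format(Sys.time(), tz = "UTC"),
                                   checksums = .stage_checksums(paths))
  .write_manifest(out, manifest)
  invisible(NULL)
}

.scan_dirs <- function(cfg) {
  file.path(cfg$out_dir, "scans",
            sprintf("scan_%02d", seq_along(cfg$study$d)))
}

.study_spec_of <- function(cfg) {
  do.call(study_spec, c(cfg$study[c("d", "nx", "ny", "radius", "gamma",
                                    "biopsy")],
                        list(seed = cfg$master_seed),
                        cfg$simulate))
}

.stage_simulate <- function(cfg, quiet) {
  spec <- .study_spec_of(cfg)
  dirs <- .scan_dirs(cfg)
  for (i in seq_along(spec)) {
    scan <- synth_scan(spec[[i]]$phantom, spec[[i]]$config)
    write_scan(scan, dirs[i])
  }
  file.path(dirs, "waveforms.csv")
}

.load_scans <- function(cfg) {
  dirs <- .scan_dirs(cfg)
  missing <- dirs[!file.exists(file.path(dirs, "meta.json"))]
  if (length(missing)) {
    stop("missing scan containers (run the `simulate` stage first): ",
         paste(basename(missing), collapse = ", "))
  }
  lapply(dirs, read_scan)
}

.pipeline_windows <- function(cfg) {
  noise_windows(cfg$preprocess$pre, cfg$preprocess$post)
}

.stage_preprocess <- function(cfg, quiet) {
  scans <- .load_scans(cfg)
  win <- .pipeline_windows(cfg)
  sp_dir <- file.path(cfg$out_dir, "spectra")
  dir.create(sp_dir, showWarnings = FALSE)
  out <- character(0)
  for (i in seq_along(scans)) {
    sp <- preprocess_scan(scans[[i]], win, cfg$preprocess$wavelet,
                          cfg$preprocess$n_levels)
    p <- file.path(sp_dir, sprintf("scan_%02d_amplitude.csv", i))
    data.table::fwrite(as.data.frame(sp$amplitude), p, col.names = FALSE)
    out <- c(out, p)
  }
  data.table::fwrite(data.frame(freq = freq_axis(scans[[1]]$config)),
                     file.path(sp_dir, "freq.csv"))
  c(out, file.path(sp_dir, "freq.csv"))
}

# internal: preprocess all scans in memory (spectra + detected masks)
.preprocessed_study <- function(cfg) {
  scans <- .load_scans(cfg)
  win <- .pipeline_windows(cfg)
  spectra <- lapply(scans, preprocess_scan, windows = win,
                    wavelet = cfg$preprocess$wavelet,
                    n_levels = cfg$preprocess$n_levels)
  masks <- lapply(scans, detect_biopsy_mask)
  list(scans = scans, spectra = spectra, masks = masks)
}

.stage_features <- function(cfg, quiet) {
  pre <- .preprocessed_study(cfg)
  band <- band_spec(cfg$features$f_lo, cfg$features$f_hi)
  img_dir <- file.path(cfg$out_dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  out <- character(0)
  for (i in seq_along(pre$spectra)) {
    img <- form_image(pre$spectra[[i]], band)
    p <- file.path(img_dir, sprintf("scan_%02d_band_area.csv", i))
    export_image(img, p, png_path = file.path(
      img_dir, sprintf("scan_%02d_band_area.png", i)))
    pm <- file.path(img_dir, sprintf("scan_%02d_biopsy_mask.csv", i))
    data.table::fwrite(as.data.frame(pre$masks[[i]] * 1L), pm,
                       col.names = FALSE)
    out <- c(out, p, pm)
  }
  obs_all <- list()
  for (it in seq_len(cfg$classify$n_iterations)) {
    for (b in seq_along(pre$spectra)) {
      sp <- pre$spectra[[b]]
      site <- sp$truth$sites[1, ]
      rs <- sample_rois(pre$masks[[b]], k = cfg$features$k_rois,
                        size = cfg$features$roi_size,
                        seed = cfg$master_seed + 7919L * it + b,
                        region = sp$truth$site_id == site$site,
                        iteration_id = it)
      obs_all[[length(obs_all) + 1]] <-
        build_observations(sp, rs, band = band, burn_id = b, d = site$d)
    }
  }
  p <- file.path(cfg$out_dir, "observations.csv")
  write_observations(do.call(rbind, obs_all), p)
  c(out, p)
}

.stage_classify <- function(cfg, quiet) {
  obs_path <- file.path(cfg$out_dir, "observations.csv")
  if (!file.exists(obs_path)) {
    stop("missing observations.csv (run the `features` stage first)")
  }
  obs <- as.data.frame(data.table::fread(obs_path))
  obs$label <- factor(obs$label, levels = severity_levels())
  results <- list()
  for (it in sort(unique(obs$iteration_id))) {
    oi <- obs[obs$iteration_id == it, ]
    for (fam in cfg$classify$families) {
      spec <- classifier_spec(fam,
                              n_search_evals = cfg$classify$n_search_evals,
                              cv_folds = cfg$classify$cv_folds,
                              inner_folds = cfg$classify$inner_folds)
      for (cls in severity_levels()) {
        ev <- crossval_evaluate(oi, spec, cls,
                                seed = cfg$master_seed + 17L * it,
                                burn_grouped = cfg$classify$burn_grouped)
        results[[length(results) + 1]] <- data.frame(
          family = fam, class = cls, iteration = it,
          metric = c("auc", "sensitivity", "specificity", "accuracy"),
          value = c(ev$auc, ev$sensitivity, ev$specificity, ev$accuracy))
      }
    }
  }
  results <- do.call(rbind, results)
  met_dir <- file.path(cfg$out_dir, "metrics")
  dir.create(met_dir, showWarnings = FALSE)
  data.table::fwrite(results, file.path(met_dir, "metrics.csv"))
  agg_mean <- stats::aggregate(value ~ family + class + metric, results, mean)
  agg_sd <- stats::aggregate(value ~ family + class + metric, results,
                             stats::sd)
  names(agg_mean)[4] <- "mean"
  agg_mean$sd <- ifelse(is.na(agg_sd$value), 0, agg_sd$value)
  anova_res <- anova_band_area(obs[obs$iteration_id == min(obs$iteration_id), ])
  jsonlite::write_json(
    list(metrics = agg_mean,
         anova = list(F = anova_res$F, p = anova_res$p,
                      pairwise = as.list(anova_res$pairwise),
                      alpha = anova_res$alpha)),
    file.path(met_dir, "summary.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.path(met_dir, c("metrics.csv", "summary.json"))
}

#' Built-in study fixtures
#'
#' `tiny`: three 9 x 9 single-burn scans (one per severity class, d = 20 /
#' 60 / 95, wound half-width 3 mm) with one 4-mm biopsy disk in the first
#' scan; 3 ROIs x 3 iterations; runs the whole suite in well under a
#' minute. `default`: the full 10-burn study at 27 x 27 pixels.
#'
#' @param size `"tiny"` or `"default"`.
#' @param out_dir Output directory of the returned config.
#' @param master_seed Master seed.
#' @return A [pipeline_config()].
#' @export
make_fixtures <- function(size = c("tiny", "default"),
                          out_dir = tempfile("thzburnmap-"),
                          master_seed = 1L) {
  size <- match.arg(size)
  if (size == "tiny") {
    pipeline_config(
      out_dir = out_dir, master_seed = master_seed,
      study = list(d = c(20, 60, 95), nx = 9, ny = 9, radius = 3,
                   biopsy = c(TRUE, FALSE, FALSE)),
      features = list(k_rois = 3),
      classify = list(n_iterations = 3, cv_folds = 3, n_search_evals = 6,
                      inner_folds = 2,
                      families = c("svm_gaussian", "lda")))
  } else {
    pipeline_config(out_dir = out_dir, master_seed = master_seed)
  }
}

#' Simulate the tiny fixture study in memory
#'
#' @param master_seed Master seed.
#' @param gamma Hydration-separation scale (see [study_spec()]).
#' @param noise_rms Single-shot noise level.
#' @return List of three `thz_scan` cubes (SPT, DPT, FT).
#' @export
tiny_study <- function(master_seed = 1L, gamma = 1, noise_rms = 0.005) {
  spec <- study_spec(d = c(20, 60, 95), seed = master_seed, nx = 9, ny = 9,
                     radius = 3, gamma = gamma,
                     biopsy = c(TRUE, FALSE, FALSE), noise_rms = noise_rms)
  synth_study(spec)
}
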