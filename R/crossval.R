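#' Classifier evaluation specification
#'
#' @param family One of [classifier_families()].
#' @param search_space Hyperparameter space; default per family.
#' @param n_search_evals Bayesian-search objective evaluations per fold.
#' @param cv_folds Outer cross-validation folds (default 5).
#' @param inner_folds Inner folds for the search objective (CV AUC on the
#'   training portion only).
#' @param n_iterations ROI-randomization iterations (default 10).
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(family, search_space = default_search_space(family),
                            n_search_evals = 30, cv_folds = 5,
                            inner_folds = 3, n_iterations = 10) {
  family <- match.arg(family, classifier_families())
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  structure(list(family = family, search_space = search_space,
                 n_search_evals = n_search_evals, cv_folds = cv_folds,
                 inner_folds = inner_folds, n_iterations = n_iterations),
            class = "classifier_spec")
}

#' Stratified (optionally group-aware) cross-validation folds
#'
#' Default mode stratifies by class at the observation level, so ROIs from
#' one burn may cross folds (matching the apparent study protocol). With
#' `groups` given, whole groups (burns) are assigned to folds,
#' stratified by the group's class — the leakage-safe alternative.
#'
#' @param y Binary labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param groups Optional group ids (e.g. burn ids), one per observation.
#' @return Integer fold assignment per observation.
#' @export
make_folds <- function(y, k, seed = 1L, groups = NULL) {
  y <- .as_binary(y)
  n <- length(y)
  run <- .seeded_rng(seed)
  fold <- integer(n)
  if (is.null(groups)) {
    for (cls in c(TRUE, FALSE)) {
      idx <- which(y == cls)
      idx <- run(function() sample(idx))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    gid <- unique(groups)
    gcls <- vapply(gid, function(g) mean(y[groups == g]) >= 0.5, TRUE)
    for (cls in c(TRUE, FALSE)) {
      gg <- gid[gcls == cls]
      gg <- run(function() sample(gg))
      gf <- rep_len(seq_len(k), length(gg))
      for (i in seq_along(gg)) fold[groups == gg[i]] <- gf[i]
    }
  }
  fold
}

#' Cross-validated one-vs-all evaluation of one classifier family
#'
#' Stratified k-fold cross-validation of `target_class` against the rest.
#' Within each fold, hyperparameters are chosen by [bayes_opt()] maximizing
#' inner-CV AUC on the training folds only; the tuned model is refit on the
#' whole training portion and scores the held-out fold. Test scores are
#' pooled across folds before the ROC is built. Because each fold may tune
#' different hyperparameters, raw score scales differ across folds; test
#' scores are therefore divided by a positive per-fold factor (the standard
#' deviation of the fold's training scores), which leaves each fold's
#' ranking and the sign of every score unchanged while making the pooled
#' scores comparable. Binary rates are computed at the native decision
#' boundary (score 0).
#'
#' @param obs Observation table from [build_observations()] (rows from one
#'   ROI iteration).
#' @param spec A [classifier_spec()].
#' @param target_class `"SPT"`, `"DPT"` or `"FT"`.
#' @param seed Integer seed for folds and search.
#' @param burn_grouped Keep all ROIs of a burn in one fold?
#' @return List: `roc`, `auc`, `sensitivity`, `specificity`, `accuracy`,
#'   `scores`, `truth`, `folds`, `best_params` (per fold).
#' @export
crossval_evaluate <- function(obs, spec, target_class, seed = 1L,
                              burn_grouped = FALSE) {
  stopifnot(inherits(spec, "classifier_spec"))
  target_class <- match.arg(target_class, severity_levels())
  x <- as.matrix(obs[, .feature_cols(obs), drop = FALSE])
  y <- obs$label == target_class
  if (sum(y) < 2 || sum(!y) < 2) {
    stop("need at least 2 observations per class for cross-validation")
  }
  groups <- if (burn_grouped) obs$burn_id else NULL
  fold <- make_folds(y, spec$cv_folds, seed = seed, groups = groups)
  scores <- numeric(nrow(obs))
  best_params <- vector("list", spec$cv_folds)
  for (f in seq_len(spec$cv_folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2) {
      stop(sprintf("stratification failure: a class is absent from the training portion of fold %d", f))
    }
    if (!any(!tr)) next
    tune <- .tune_fit(x[tr, , drop = FALSE], y[tr], spec,
                      seed = seed * 131L + f)
    best_params[[f]] <- tune$params
    scores[!tr] <- score_classifier(tune$model, x[!tr, , drop = FALSE])
  }
  roc <- roc_auc(scores, y)
  cm <- confusion_metrics(scores > 0, y)
  list(roc = roc, auc = roc$auc,
       sensitivity = cm$sensitivity, specificity = cm$specificity,
       accuracy = cm$accuracy, scores = scores, truth = y, folds = fold,
       best_params = best_params)
}

# internal: hyperparameter search + refit on full training set. The search
# objective is the inner-CV misclassification loss at the native decision
# boundary (minimized, i.e. accuracy maximized), with inner-CV AUC as a
# small tie-break so that among equally accurate settings the better-ranking
# one wins; loss-based selection also rejects degenerate constant-score
# models that an AUC-only objective cannot distinguish on separable folds.
.tune_fit <- function(xtr, ytr, spec, seed) {
  inner_k <- min(spec$inner_folds, sum(ytr), sum(!ytr))
  objective <- function(params) {
    fold <- make_folds(ytr, inner_k, seed = seed)
    sc <- rep(NA_real_, length(ytr))
    for (f in seq_len(inner_k)) {
      tr <- fold != f
      if (length(unique(ytr[tr])) < 2 || !any(!tr)) return(NA_real_)
      m <- fit_classifier(spec$family, xtr[tr, , drop = FALSE], ytr[tr], params)
      sc[!tr] <- score_classifier(m, xtr[!tr, , drop = FALSE])
    }
    ok <- !is.na(sc)
    if (length(unique(ytr[ok])) < 2) return(NA_real_)
    acc <- mean((sc[ok] > 0) == ytr[ok])
    acc + 1e-2 * roc_auc(sc[ok], ytr[ok])$auc
  }
  if (spec$n_search_evals >= 1 && length(spec$search_space) >= 1) {
    opt <- bayes_opt(objective, spec$search_space,
                     n_evals = spec$n_search_evals, seed = seed)
    params <- opt$best_params
  } else {
    params <- list()
  }
  list(model = fit_classifier(spec$family, xtr, ytr, params), params = params)
}

#' Evaluate the classifier suite over randomized-ROI iterations
#'
#' For each iteration a fresh seeded ROI set is drawn per burn, the
#' observation table is rebuilt, and every requested family is
#' cross-validated for each one-vs-all target class. The report aggregates
#' AUC, sensitivity, specificity and accuracy as mean +/- sd over the
#' iterations.
#'
#' @param spectra_list List of `thz_spectra` (one per burn scan), each with
#'   truth pass-through; masks are detected per scan unless `masks` given.
#' @param scans Optional list of `thz_scan` used for echo-phase mask
#'   detection (required when `masks` is `NULL` and biopsy disks exist).
#' @param families Character vector of [classifier_families()] entries.
#' @param k_rois ROIs per burn per iteration (default 15).
#' @param roi_size ROI side in pixels (default 4).
#' @param n_iterations ROI randomization iterations (default 10).
#' @param cv_folds,n_search_evals,inner_folds Cross-validation settings,
#'   see [classifier_spec()].
#' @param band A [band_spec()].
#' @param seed Master seed; all iteration/fold/search seeds derive from it.
#' @param burn_grouped Leakage-safe grouped folds (see [make_folds()]).
#' @param masks Optional list of logical exclusion masks per scan,
#'   overriding echo-phase detection.
#' @param permute_labels Null-calibration mode: permute labels across rows
#'   of each iteration's observation table (seeded) before evaluation.
#' @return Object of class `eval_report`: `results` (long data frame:
#'   family, class, iteration, metric, value), `summary` (mean, sd per
#'   family/class/metric), `rocs` (per family/class/iteration).
#' @export
evaluate_suite <- function(spectra_list, scans = NULL,
                           families = classifier_families(),
                           k_rois = 15, roi_size = 4, n_iterations = 10,
                           cv_folds = 5, n_search_evals = 30, inner_folds = 3,
                           band = band_spec(), seed = 1L,
                           burn_grouped = FALSE, masks = NULL,
                           permute_labels = FALSE) {
  families <- match.arg(families, classifier_families(), several.ok = TRUE)
  n_burns <- length(spectra_list)
  if (is.null(masks)) {
    if (is.null(scans)) stop("provide either `scans` (for mask detection) or `masks`")
    masks <- lapply(scans, detect_biopsy_mask)
  }
  if (n_iterations == 1) {
    message("single iteration: reported sd values are 0 by construction")
  }
  results <- list()
  rocs <- list()
  for (it in seq_len(n_iterations)) {
    obs <- do.call(rbind, lapply(seq_len(n_burns), function(b) {
      sp <- spectra_list[[b]]
      site <- sp$truth$sites[1, ]
      region <- sp$truth$site_id == site$site
      rs <- sample_rois(masks[[b]], k = k_rois, size = roi_size,
                        seed = seed + 7919L * it + b, region = region,
                        iteration_id = it)
      build_observations(sp, rs, band = band, burn_id = b, d = site$d)
    }))
    if (permute_labels) {
      perm <- .seeded_rng(seed + 104729L * it)(function() sample(nrow(obs)))
      obs$label <- obs$label[perm]
      obs$d <- obs$d[perm]
    }
    for (fam in families) {
      spec <- classifier_spec(fam, n_search_evals = n_search_evals,
                              cv_folds = cv_folds, inner_folds = inner_folds,
                              n_iterations = n_iterations)
      for (cls in severity_levels()) {
        ev <- crossval_evaluate(obs, spec, cls,
                                seed = seed + 17L * it, burn_grouped = burn_grouped)
        results[[length(results) + 1]] <- data.frame(
          family = fam, class = cls, iteration = it,
          metric = c("auc", "sensitivity", "specificity", "accuracy"),
          value = c(ev$auc, ev$sensitivity, ev$specificity, ev$accuracy))
        rocs[[paste(fam, cls, it, sep = ".")]] <- ev$roc
      }
    }
  }
  results <- do.call(rbind, results)
  agg_mean <- stats::aggregate(value ~ family + class + metric, results, mean)
  agg_sd <- stats::aggregate(value ~ family + class + metric, results, stats::sd)
  names(agg_mean)[4] <- "mean"
  agg_mean$sd <- ifelse(is.na(agg_sd$value), 0, agg_sd$value)
  structure(list(results = results, summary = agg_mean, rocs = rocs,
                 n_iterations = n_iterations, seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d iterations\n", x$n_iterations))
  auc <- x$summary[x$summary$metric == "auc", ]
  for (i in seq_len(nrow(auc))) {
    cat(sprintf("  %-13s %-3s AUC %.3f +/- %.3f\n", auc$family[i],
                auc$class[i], auc$mean[i], auc$sd[i]))
  }
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Long-format metrics CSV, a JSON summary of means +/- sd, and per
#' (family, class) ROC sample CSVs.
#'
#' @param report An `eval_report`.
#' @param dir Output directory (created if needed).
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(report$results, file.path(dir, "metrics.csv"))
  jsonlite::write_json(
    split(report$summary, paste(report$summary$family, report$summary$class,
                                sep = ".")),
    file.path(dir, "summary.json"), dataframe = "rows", auto_unbox = TRUE,
    digits = NA)
  roc_dir <- file.path(dir, "roc")
  dir.create(roc_dir, showWarnings = FALSE)
  for (nm in names(report$rocs)) {
    r <- report$rocs[[nm]]
    data.table::fwrite(data.frame(fpr = r$fpr, tpr = r$tpr),
                       file.path(roc_dir, paste0(nm, ".csv")))
  }
  invisible(dir)
}
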