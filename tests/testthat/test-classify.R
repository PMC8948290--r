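test_that("severity labels follow the dermal-burn-percentage thresholds", {
  expect_identical(as.character(assign_severity_label(22)), "SPT")
  expect_identical(as.character(assign_severity_label(50)), "DPT")
  expect_identical(as.character(assign_severity_label(95)), "FT")
  # boundary convention: 40 and 80 belong to DPT
  expect_identical(as.character(assign_severity_label(c(40, 80))),
                   c("DPT", "DPT"))
  expect_error(assign_severity_label(101), "\\[0, 100\\]")
})

test_that("ROC/AUC matches pair counting, ties and degenerate cases", {
  # worked 6-observation set: 8 of 9 pos-neg pairs concordant
  r <- roc_auc(c(0.1, 0.2, 0.35, 0.4, 0.7, 0.9), c(0, 0, 1, 0, 1, 1))
  expect_equal(r$auc, 8 / 9, tolerance = 1e-12)
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[length(r$fpr)], 1)
  expect_equal(r$tpr[length(r$tpr)], 1)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  # perfect separation and all-tied scores
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(1, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("ROC agrees with pROC on random tied instances", {
  skip_if_not_installed("pROC")
  set.seed(14)
  for (i in 1:25) {
    n <- sample(8:40, 1)
    sc <- round(runif(n), 1)
    y <- runif(n) > 0.5
    if (!any(y) || all(y)) y[sample(n, 2)] <- c(TRUE, FALSE)
    ours <- roc_auc(sc, y)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("confusion metrics implement the standard rates", {
  expect_equal(confusion_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0)),
               list(sensitivity = 1, specificity = 1, accuracy = 1))
  m <- confusion_metrics(rep(0, 6), c(1, 1, 0, 0, 0, 0))
  expect_equal(m$sensitivity, 0)
  expect_equal(m$specificity, 1)
  # TP=3, FN=1, TN=5, FP=1
  pred <- c(rep(1, 3), 0, rep(0, 5), 1)
  truth <- c(rep(1, 4), rep(0, 6))
  m2 <- confusion_metrics(pred, truth)
  expect_equal(m2$sensitivity, 0.75)
  expect_equal(m2$specificity, 5 / 6)
  expect_equal(m2$accuracy, 0.8)
  expect_error(confusion_metrics(c(1, 0), c(1, 1)), "both truth classes")
})

test_that("one-way ANOVA on band areas matches a hand-computed F", {
  g1 <- c(1.1, 1.3, 0.9, 1.2); g2 <- c(1.8, 2.1, 1.7, 2.0)
  g3 <- c(2.9, 3.2, 3.1, 2.8)
  obs <- data.frame(band_area = c(g1, g2, g3),
                    label = factor(rep(c("SPT", "DPT", "FT"), each = 4),
                                   levels = severity_levels()))
  res <- anova_band_area(obs)
  grand <- mean(obs$band_area)
  ssb <- 4 * sum((c(mean(g1), mean(g2), mean(g3)) - grand)^2)
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2) +
    sum((g3 - mean(g3))^2)
  f_oracle <- (ssb / 2) / (ssw / 9)
  expect_equal(res$F, f_oracle, tolerance = 1e-10)
  expect_lt(res$p, 0.001)
  expect_named(res$pairwise, c("DPT-SPT", "FT-SPT", "FT-DPT"))
  expect_equal(res$alpha, 0.05)
  # identical groups -> F = 0
  obs0 <- obs; obs0$band_area <- rep(c(1, 2, 3, 4), 3)
  expect_equal(anova_band_area(obs0)$F, 0, tolerance = 1e-10)
  expect_error(anova_band_area(obs[1:4, ]), "two severity groups")
})

test_that("regularized LDA at zero shrinkage matches MASS::lda ranking", {
  skip_if_not_installed("MASS")
  set.seed(15)
  n <- 60
  x <- rbind(matrix(rnorm(n * 3), n, 3),
             matrix(rnorm(n * 3, mean = 1), n, 3))
  y <- rep(c(FALSE, TRUE), each = n)
  m <- fit_classifier("lda", x, y, list(gamma = 0))
  ours <- score_classifier(m, x)
  ref <- MASS::lda(x, grouping = y)
  ref_scores <- as.numeric(predict(ref, x)$x[, 1])
  if (cor(ours, ref_scores) < 0) ref_scores <- -ref_scores
  expect_gt(cor(ours, ref_scores), 0.999999)
})

test_that("log-space naive Bayes agrees with e1071 class decisions", {
  set.seed(16)
  n <- 50
  x <- rbind(matrix(rnorm(n * 2, 0), n, 2), matrix(rnorm(n * 2, 2), n, 2))
  y <- rep(c(FALSE, TRUE), each = n)
  m <- fit_classifier("naive_bayes", x, y)
  ours <- score_classifier(m, x) > 0
  yf <- factor(ifelse(y, "pos", "neg"))
  ref <- predict(e1071::naiveBayes(x, yf), x) == "pos"
  expect_gt(mean(ours == ref), 0.97)
})

test_that("every family separates a linearly separable problem perfectly", {
  set.seed(17)
  x <- rbind(matrix(rnorm(24, -2, 0.2), 12, 2),
             matrix(rnorm(24, 2, 0.2), 12, 2))
  obs <- data.frame(label = factor(rep(c("SPT", "FT"), each = 12),
                                   levels = severity_levels()),
                    f_0.10 = x[, 1], f_0.20 = x[, 2])
  for (fam in classifier_families()) {
    spec <- classifier_spec(fam, n_search_evals = 4, cv_folds = 4,
                            inner_folds = 2)
    ev <- crossval_evaluate(obs, spec, "FT", seed = 2)
    expect_equal(ev$auc, 1, tolerance = 1e-9)
    expect_equal(ev$accuracy, 1, tolerance = 1e-9)
  }
})

test_that("stratified folds balance classes; grouped folds keep burns whole", {
  y <- rep(c(TRUE, FALSE), c(60, 90))
  f <- make_folds(y, 5, seed = 4)
  expect_identical(as.integer(table(f)), rep(30L, 5))
  expect_true(all(table(f[y]) == 12))
  burns <- rep(1:10, each = 15)
  yb <- burns <= 4
  fg <- make_folds(yb, 5, seed = 4, groups = burns)
  spread <- tapply(fg, burns, function(z) length(unique(z)))
  expect_true(all(spread == 1))
})

test_that("evaluation reports cover every family-class pair", {
  fix <- tiny_fixture()
  expect_message(
    rep1 <- evaluate_suite(fix$spectra, masks = fix$masks,
                           families = c("lda", "naive_bayes"),
                           k_rois = 3, n_iterations = 1, cv_folds = 3,
                           n_search_evals = 2, inner_folds = 2, seed = 3),
    "single iteration")
  auc <- rep1$summary[rep1$summary$metric == "auc", ]
  expect_identical(nrow(auc), 6L)  # 2 families x 3 classes
  expect_true(all(auc$sd == 0))
  expect_true(all(auc$mean >= 0 & auc$mean <= 1))
})

test_that("Bayesian search finds a near-optimal point on a smooth surface", {
  space <- list(a = list(type = "linear", lo = 0, hi = 1),
                b = list(type = "log", lo = 0.01, hi = 100))
  fn <- function(p) -(p$a - 0.3)^2 - (log10(p$b))^2
  out <- bayes_opt(fn, space, n_evals = 25, seed = 6)
  expect_gt(out$best_value, -0.05)
  expect_identical(nrow(out$history), 25L)
  # deterministic under seed
  out2 <- bayes_opt(fn, space, n_evals = 25, seed = 6)
  expect_identical(out$history$value, out2$history$value)
})
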