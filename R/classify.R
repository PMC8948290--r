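#' Severity label levels
#' @return Character vector `c("SPT", "DPT", "FT")`.
#' @export
severity_levels <- function() c("SPT", "DPT", "FT")

#' Assign a burn severity label from dermal burn percentage
#'
#' Histology grading: superficial partial-thickness (SPT) for `d < 40`,
#' deep partial-thickness (DPT) for `40 <= d <= 80`, full-thickness (FT)
#' for `d > 80`. The boundary values 40 and 80 are assigned to DPT (they
#' cannot occur with continuous simulated draws; the convention matters
#' only for exact inputs).
#'
#' @param d Dermal burn percentage(s) in `[0, 100]`.
#' @return Factor with levels SPT, DPT, FT.
#' @export
assign_severity_label <- function(d) {
  if (any(!is.na(d) & (d < 0 | d > 100))) stop("d must lie in [0, 100]")
  lab <- ifelse(d < 40, "SPT", ifelse(d <= 80, "DPT", "FT"))
  factor(lab, levels = severity_levels())
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores (descending),
#' accumulating true/false positive rates; tied scores move as one group,
#' which makes the trapezoidal area equal the Mann-Whitney concordance
#' probability with half credit for ties.
#'
#' @param scores Real-valued classifier scores (larger = more positive).
#' @param labels Binary ground truth: logical, 0/1, or a factor whose
#'   second level is the positive class.
#' @return List of class `roc_curve`: `fpr`, `tpr` (monotone from (0,0) to
#'   (1,1)), `thresholds`, `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- .as_binary(labels)
  stopifnot(length(scores) == length(y))
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) stop("roc_auc requires both classes present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  grp <- cumsum(c(TRUE, diff(s) != 0))
  tp <- as.numeric(tapply(yy, grp, sum))
  fp <- as.numeric(tapply(!yy, grp, sum))
  tpr <- c(0, cumsum(tp) / n_pos)
  fpr <- c(0, cumsum(fp) / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(fpr = fpr, tpr = tpr,
                 thresholds = c(Inf, s[!duplicated(grp)]), auc = auc),
            class = "roc_curve")
}

.as_binary <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) return(labels == levels(labels)[2])
  if (is.numeric(labels)) return(labels != 0)
  stop("labels must be logical, numeric or a two-level factor")
}

#' Sensitivity, specificity and accuracy of a binary prediction
#'
#' `sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)`,
#' `accuracy = (TP+TN)/N`.
#'
#' @param predicted,truth Binary vectors (logical or 0/1).
#' @return Named list with the three rates.
#' @export
confusion_metrics <- function(predicted, truth) {
  p <- .as_binary(predicted); y <- .as_binary(truth)
  stopifnot(length(p) == length(y), length(y) > 0)
  if (!any(y) || all(y)) {
    stop("confusion_metrics requires both truth classes present")
  }
  tp <- sum(p & y); fn <- sum(!p & y)
  tn <- sum(!p & !y); fp <- sum(p & !y)
  list(sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       accuracy = (tp + tn) / length(y))
}

#' One-way ANOVA on ROI band areas across severity groups
#'
#' Standard one-way analysis of variance of the scalar spectral band area
#' against the severity label, at the 0.05 significance level, with
#' Tukey-Kramer honest-significant-difference pairwise comparisons.
#'
#' @param obs Observation table (needs columns `band_area` and `label`)
#'   or a data frame with those columns.
#' @param alpha Significance level reported alongside (default 0.05).
#' @return List: `F` statistic, `p` overall, `pairwise` named vector of
#'   adjusted p-values (`DPT-SPT`, `FT-SPT`, `FT-DPT`), `alpha`, `fit`.
#' @export
anova_band_area <- function(obs, alpha = 0.05) {
  stopifnot(all(c("band_area", "label") %in% names(obs)))
  lab <- droplevels(factor(obs$label))
  if (nlevels(lab) < 2) stop("ANOVA needs at least two severity groups")
  if (any(table(lab) < 2)) stop("each group needs at least 2 observations")
  dat <- data.frame(band_area = obs$band_area, label = lab)
  fit <- stats::aov(band_area ~ label, data = dat)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$label
  pw <- tk[, "p adj"]
  names(pw) <- rownames(tk)
  list(F = tab[1, "F value"], p = tab[1, "Pr(>F)"],
       pairwise = pw, alpha = alpha, fit = fit)
}
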