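# Binary scoring learners behind a single fit/score interface. Scores are
# real-valued with the convention score > 0 => "pos"; the operating point
# for sensitivity/specificity/accuracy is score = 0 (the native decision
# boundary).

#' Classifier families of the evaluation harness
#' @return Character vector of family names.
#' @export
classifier_families <- function() {
  c("svm_linear", "svm_poly", "svm_gaussian", "naive_bayes", "lda",
    "adaboost_lda")
}

#' Hyperparameter search space of a classifier family
#'
#' Box-constraint and kernel scale on log-uniform ranges, polynomial degree
#' categorical \{2, 3, 4\}, naive-Bayes density model (Gaussian vs kernel)
#' categorical with a log-uniform bandwidth adjustment, LDA shrinkage on
#' `[0, 1]`, AdaBoost learner count on `[10, 200]` with log-uniform
#' learning rate.
#'
#' @param family One of [classifier_families()].
#' @return Named list of parameter descriptors used by [bayes_opt()].
#' @export
default_search_space <- function(family) {
  family <- match.arg(family, classifier_families())
  lg <- function(lo, hi) list(type = "log", lo = lo, hi = hi)
  ln <- function(lo, hi) list(type = "linear", lo = lo, hi = hi)
  int <- function(lo, hi) list(type = "int", lo = lo, hi = hi)
  cat_ <- function(...) list(type = "cat", values = c(...))
  switch(family,
    svm_linear = list(cost = lg(1e-3, 1e3)),
    svm_gaussian = list(cost = lg(1e-3, 1e3), kernel_scale = lg(1e-2, 1e2)),
    svm_poly = list(cost = lg(1e-3, 1e3), kernel_scale = lg(1e-2, 1e2),
                    degree = cat_(2, 3, 4)),
    naive_bayes = list(use_kernel = cat_(0, 1), bw_adjust = lg(0.25, 4)),
    lda = list(gamma = ln(0, 1)),
    adaboost_lda = list(n_learners = int(10, 200), learn_rate = lg(0.01, 1))
  )
}

# standardize columns by training statistics; constant columns get scale 1
.standardizer <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  list(center = ctr, scale = scl,
       apply = function(z) sweep(sweep(z, 2, ctr), 2, scl, "/"))
}

#' Fit a binary scoring classifier
#'
#' @param family One of [classifier_families()].
#' @param x Numeric feature matrix (rows = observations).
#' @param y Binary labels: logical or factor; `TRUE` / second level = "pos".
#' @param params Named list of hyperparameters for the family (see
#'   [default_search_space()]); missing entries take mid-range defaults.
#' @return Model object of class `thz_classifier`.
#' @export
fit_classifier <- function(family, x, y, params = list()) {
  family <- match.arg(family, classifier_families())
  x <- as.matrix(x)
  y <- .as_binary(y)
  if (all(y) || !any(y)) stop("training data must contain both classes")
  std <- .standardizer(x)
  xs <- std$apply(x)
  fit <- switch(family,
    svm_linear = .fit_svm(xs, y, kernel = "linear", params),
    svm_gaussian = .fit_svm(xs, y, kernel = "radial", params),
    svm_poly = .fit_svm(xs, y, kernel = "polynomial", params),
    naive_bayes = .fit_nb(xs, y, params),
    lda = .fit_rlda(xs, y, gamma = params$gamma %||% 0.5),
    adaboost_lda = .fit_adaboost(xs, y, params)
  )
  structure(list(family = family, fit = fit, std = std), class = "thz_classifier")
}

#' Score observations with a fitted classifier
#' @param model A `thz_classifier` from [fit_classifier()].
#' @param x Feature matrix.
#' @return Real scores; `> 0` means "pos".
#' @export
score_classifier <- function(model, x) {
  stopifnot(inherits(model, "thz_classifier"))
  xs <- model$std$apply(as.matrix(x))
  switch(model$family,
    svm_linear = , svm_gaussian = , svm_poly = .score_svm(model$fit, xs),
    naive_bayes = .score_nb(model$fit, xs),
    lda = .score_rlda(model$fit, xs),
    adaboost_lda = .score_adaboost(model$fit, xs)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- support vector machines (e1071) ----

.fit_svm <- function(xs, y, kernel, params) {
  yf <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  # kernel_scale s parameterizes K = exp(-||x - x'||^2 / s^2), i.e.
  # e1071's gamma = 1 / s^2; an explicit gamma overrides it
  gamma <- params$gamma %||%
    (if (!is.null(params$kernel_scale)) 1 / params$kernel_scale^2
     else 1 / ncol(xs))
  m <- e1071::svm(xs, yf, type = "C-classification", kernel = kernel,
                  cost = params$cost %||% 1, gamma = gamma,
                  degree = params$degree %||% 3, coef0 = 1, scale = FALSE)
  # decision values are signed towards the first label in m$labels
  first <- m$levels[m$labels[1]]
  list(model = m, sign = if (identical(first, "pos")) 1 else -1)
}

.score_svm <- function(fit, xs) {
  dv <- attr(stats::predict(fit$model, xs, decision.values = TRUE),
             "decision.values")[, 1]
  fit$sign * as.numeric(dv)
}

## ---- naive Bayes, scored in log space ----
# Gaussian or kernel-density class-conditional densities per feature;
# log-space scoring avoids the posterior saturation that 40+ correlated
# features produce in probability space.

.fit_nb <- function(xs, y, params) {
  use_kernel <- (params$use_kernel %||% 0) != 0
  bw_adjust <- params$bw_adjust %||% 1
  classes <- list(pos = xs[y, , drop = FALSE], neg = xs[!y, , drop = FALSE])
  prior <- c(pos = mean(y), neg = mean(!y))
  pooled_sd <- apply(xs, 2, stats::sd)
  pooled_sd[pooled_sd < 1e-8] <- 1e-8
  dens <- lapply(classes, function(xc) {
    lapply(seq_len(ncol(xc)), function(j) {
      v <- xc[, j]
      mu <- mean(v)
      sd <- max(stats::sd(v), 1e-3 * pooled_sd[j], 1e-8)
      if (!use_kernel || length(v) < 3) {
        list(type = "gauss", mu = mu, sd = sd)
      } else {
        bw <- max(stats::bw.nrd0(v), 1e-3 * pooled_sd[j]) * bw_adjust
        d <- stats::density(v, bw = bw, n = 256,
                            from = min(v) - 4 * bw, to = max(v) + 4 * bw)
        list(type = "kde", x = d$x, y = pmax(d$y, 1e-12), sd = sd)
      }
    })
  })
  list(dens = dens, prior = prior)
}

.score_nb <- function(fit, xs) {
  loglik <- function(class) {
    ll <- numeric(nrow(xs))
    for (j in seq_len(ncol(xs))) {
      dj <- fit$dens[[class]][[j]]
      if (dj$type == "gauss") {
        ll <- ll + stats::dnorm(xs[, j], dj$mu, dj$sd, log = TRUE)
      } else {
        v <- stats::approx(dj$x, dj$y, xout = xs[, j], rule = 2)$y
        ll <- ll + log(pmax(v, 1e-12))
      }
    }
    ll
  }
  (loglik("pos") + log(fit$prior["pos"])) -
    (loglik("neg") + log(fit$prior["neg"]))
}

## ---- regularized linear discriminant (shrinkage towards scaled identity) ----

.fit_rlda <- function(xs, y, gamma = 0.5, weights = NULL) {
  gamma <- min(max(gamma, 0), 1)
  n <- nrow(xs); p <- ncol(xs)
  w <- weights %||% rep(1 / n, n)
  w <- w / sum(w)
  wmean <- function(idx) colSums(xs[idx, , drop = FALSE] * w[idx]) / sum(w[idx])
  mu_p <- wmean(which(y)); mu_n <- wmean(which(!y))
  S <- matrix(0, p, p)
  for (cls in list(which(y), which(!y))) {
    xc <- sweep(xs[cls, , drop = FALSE], 2, wmean(cls))
    S <- S + crossprod(xc * sqrt(w[cls]), xc * sqrt(w[cls]))
  }
  S <- S / sum(w)
  tr_p <- sum(diag(S)) / p
  if (tr_p <= 0) tr_p <- 1
  Sg <- (1 - gamma) * S + (gamma * tr_p + 1e-8 * tr_p) * diag(p)
  wvec <- solve(Sg, mu_p - mu_n)
  b <- -sum(wvec * (mu_p + mu_n)) / 2 +
    log(sum(w[y]) / sum(w[!y]))
  list(w = wvec, b = b)
}

.score_rlda <- function(fit, xs) as.numeric(xs %*% fit$w + fit$b)

## ---- AdaBoost with regularized-LDA weak learners ----

.fit_adaboost <- function(xs, y, params) {
  n_learners <- round(params$n_learners %||% 50)
  lr <- params$learn_rate %||% 0.5
  gamma <- params$gamma %||% 0.2
  n <- nrow(xs)
  ysgn <- ifelse(y, 1, -1)
  w <- rep(1 / n, n)
  learners <- list()
  alphas <- numeric(0)
  for (t in seq_len(n_learners)) {
    f <- tryCatch(.fit_rlda(xs, y, gamma = gamma, weights = w),
                  error = function(e) NULL)
    if (is.null(f)) break
    pred <- sign(.score_rlda(f, xs))
    pred[pred == 0] <- 1
    err <- sum(w[pred != ysgn])
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- lr * 0.5 * log((1 - err) / err)
    learners[[length(learners) + 1]] <- f
    alphas <- c(alphas, alpha)
    if (err >= 0.5 || err <= 1e-9) break
    w <- w * exp(-alpha * ysgn * pred)
    w <- w / sum(w)
  }
  list(learners = learners, alphas = alphas)
}

.score_adaboost <- function(fit, xs) {
  s <- numeric(nrow(xs))
  for (t in seq_along(fit$learners)) {
    pred <- sign(.score_rlda(fit$learners[[t]], xs))
    pred[pred == 0] <- 1
    s <- s + fit$alphas[t] * pred
  }
  s
}
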