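# Compact Bayesian hyperparameter search: Gaussian-process surrogate
# (squared-exponential kernel on the unit cube) with expected-improvement
# acquisition over a random candidate pool. Deterministic under `seed`.

.encode_param <- function(desc, u) {
  switch(desc$type,
    log = exp(log(desc$lo) + u * (log(desc$hi) - log(desc$lo))),
    linear = desc$lo + u * (desc$hi - desc$lo),
    int = as.integer(round(desc$lo + u * (desc$hi - desc$lo))),
    cat = desc$values[[pmin(length(desc$values),
                            1 + floor(u * length(desc$values)))]]
  )
}

.decode_point <- function(space, u) {
  p <- lapply(seq_along(space), function(j) .encode_param(space[[j]], u[j]))
  names(p) <- names(space)
  p
}

#' Bayesian optimization of a black-box objective
#'
#' Maximizes `fn(params)` over the search space with a small
#' Gaussian-process surrogate: an initial space-filling random design,
#' then expected-improvement acquisition evaluated on a random candidate
#' pool. Intended for the handful-of-parameters, tens-of-evaluations regime
#' of classifier hyperparameter tuning.
#'
#' @param fn Objective taking a named parameter list, returning a scalar
#'   (larger is better; non-finite values are treated as failures).
#' @param space Named list of parameter descriptors
#'   (`list(type = "log"|"linear"|"int"|"cat", lo, hi, values)`), as
#'   produced by [default_search_space()].
#' @param n_evals Total number of objective evaluations (default 30).
#' @param seed Integer seed.
#' @param n_candidates Size of the acquisition candidate pool.
#' @return List: `best_params`, `best_value`, `history` data frame.
#' @export
bayes_opt <- function(fn, space, n_evals = 30, seed = 1L, n_candidates = 128) {
  stopifnot(length(space) >= 1, n_evals >= 1)
  d <- length(space)
  run <- .seeded_rng(seed)
  n_init <- max(min(4, n_evals), ceiling(n_evals / 3))
  U <- run(function() {
    # jittered latin-hypercube-style initial design + candidate pool draws
    init <- (apply(matrix(stats::runif(n_init * d), n_init, d), 2, rank) -
               stats::runif(n_init)) / n_init
    pools <- replicate(max(n_evals - n_init, 0),
                       matrix(stats::runif(n_candidates * d), n_candidates, d),
                       simplify = FALSE)
    list(init = init, pools = pools)
  })
  X <- matrix(numeric(0), 0, d)
  vals <- numeric(0)
  evaluate <- function(u) {
    v <- tryCatch(fn(.decode_point(space, u)), error = function(e) NA_real_)
    if (!is.finite(v)) v <- -Inf
    X <<- rbind(X, u)
    vals <<- c(vals, v)
  }
  for (i in seq_len(n_init)) evaluate(U$init[i, ])
  ell <- 0.3 * sqrt(d)
  for (i in seq_len(n_evals - n_init)) {
    cand <- U$pools[[i]]
    ok <- is.finite(vals)
    if (sum(ok) >= 2 && stats::sd(vals[ok]) > 0) {
      Xo <- X[ok, , drop = FALSE]
      yo <- vals[ok]
      mu0 <- mean(yo); sd0 <- stats::sd(yo)
      yn <- (yo - mu0) / sd0
      K <- exp(-0.5 * as.matrix(stats::dist(Xo))^2 / ell^2) +
        diag(1e-2 + 1e-8, nrow(Xo))
      Kinv_y <- solve(K, yn)
      Kc <- exp(-0.5 * .cross_dist2(cand, Xo) / ell^2)
      mu <- as.numeric(Kc %*% Kinv_y)
      var <- pmax(1 + 1e-2 - rowSums((Kc %*% solve(K)) * Kc), 1e-10)
      s <- sqrt(var)
      best <- max(yn)
      z <- (mu - best) / s
      ei <- s * (z * stats::pnorm(z) + stats::dnorm(z))
      u_next <- cand[which.max(ei), ]
    } else {
      u_next <- cand[1, ]
    }
    evaluate(u_next)
  }
  best <- which.max(vals)
  history <- as.data.frame(X)
  names(history) <- names(space)
  history$value <- vals
  list(best_params = .decode_point(space, X[best, ]),
       best_value = vals[best], history = history)
}

.cross_dist2 <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  pmax(outer(an, bn, "+") - 2 * A %*% t(B), 0)
}
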