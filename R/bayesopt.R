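## Gaussian-process Bayesian optimization with the UCB acquisition rule.

#' Hyperparameter search space
#'
#' @param ... dimension specifications: each a list or vector
#'   `(name, kind, lower, upper)` with kind one of `"continuous"`,
#'   `"log_continuous"` (bounds spanning decades, searched on log10 scale)
#'   or `"integer"` (continuous relaxation, rounded after proposal).
#' @return an object of class `search_space`.
#' @examples
#' search_space(list("lr", "log_continuous", 1e-6, 1e-3),
#'              list("dropout", "continuous", 0.1, 0.5),
#'              list("layers", "integer", 2, 6))
#' @export
search_space <- function(...) {
  dims <- lapply(list(...), function(d) {
    d <- as.list(d)
    names(d) <- c("name", "kind", "lower", "upper")
    d$lower <- as.numeric(d$lower); d$upper <- as.numeric(d$upper)
    if (!d$kind %in% c("continuous", "log_continuous", "integer"))
      stop("unknown dimension kind: ", d$kind)
    if (!(d$lower < d$upper)) stop("lower must be < upper for ", d$name)
    if (d$kind == "integer" &&
        (d$lower != round(d$lower) || d$upper != round(d$upper)))
      stop("integer bounds must be integral for ", d$name)
    d
  })
  structure(list(dimensions = dims), class = "search_space")
}

space_to_unit <- function(space, x) {
  vapply(seq_along(space$dimensions), function(i) {
    d <- space$dimensions[[i]]
    if (d$kind == "log_continuous")
      (log10(x[i]) - log10(d$lower)) / (log10(d$upper) - log10(d$lower))
    else (x[i] - d$lower) / (d$upper - d$lower)
  }, numeric(1))
}

space_from_unit <- function(space, u) {
  vapply(seq_along(space$dimensions), function(i) {
    d <- space$dimensions[[i]]
    v <- if (d$kind == "log_continuous")
      10^(log10(d$lower) + u[i] * (log10(d$upper) - log10(d$lower)))
    else d$lower + u[i] * (d$upper - d$lower)
    if (d$kind == "integer") round(v) else v
  }, numeric(1))
}

## Squared-exponential kernel with per-dimension lengthscales.
se_kernel <- function(A, B, ls, signal_var) {
  As <- sweep(A, 2L, ls, `/`); Bs <- sweep(B, 2L, ls, `/`)
  d2 <- outer(rowSums(As^2), rowSums(Bs^2), `+`) - 2 * tcrossprod(As, Bs)
  signal_var * exp(-0.5 * pmax(d2, 0))
}

#' Gaussian-process posterior at a query point
#'
#' Standard GP regression posterior with a squared-exponential kernel on
#' inputs normalized to the unit cube. A jitter of 1e-8 is added to the
#' kernel diagonal for numerical stability; the returned variance is clamped
#' at zero.
#'
#' @param x_train n x d matrix of observed inputs (unit cube).
#' @param y_train observed objective values.
#' @param x_query query point (length d) or m x d matrix.
#' @param lengthscale per-dimension lengthscales (recycled).
#' @param signal_var kernel signal variance.
#' @param noise_var observation noise variance.
#' @param prior_mean GP prior mean (default: mean of `y_train`).
#' @return list with `mean` and `var` (each length m).
#' @export
gp_posterior <- function(x_train, y_train, x_query, lengthscale = 0.3,
                         signal_var = 1, noise_var = 1e-6,
                         prior_mean = mean(y_train)) {
  x_train <- as.matrix(x_train)
  if (is.null(dim(x_query))) x_query <- matrix(x_query, nrow = 1L)
  d <- ncol(x_train)
  ls <- rep_len(lengthscale, d)
  K <- se_kernel(x_train, x_train, ls, signal_var) +
    diag(noise_var + 1e-8, nrow(x_train))
  ch <- tryCatch(chol(K), error = function(e)
    stop("kernel matrix singular after jitter"))
  Ks <- se_kernel(x_query, x_train, ls, signal_var)
  alpha <- backsolve(ch, forwardsolve(t(ch), y_train - prior_mean))
  mu <- prior_mean + as.numeric(Ks %*% alpha)
  z <- forwardsolve(t(ch), t(Ks))   # k*' K^{-1} k* = z'z with L z = k*
  var <- pmax(signal_var - colSums(z^2), 0)
  list(mean = mu, var = var)
}

#' Upper-confidence-bound acquisition
#'
#' `mu + kappa * sigma`: large `kappa` explores uncertain regions, small
#' `kappa` exploits regions already known to score well.
#'
#' @param mu posterior mean(s).
#' @param sigma posterior standard deviation(s) (>= 0).
#' @param kappa exploration constant (default 2).
#' @return acquisition value(s).
#' @export
ucb_acquisition <- function(mu, sigma, kappa = 2) {
  if (any(sigma < 0)) stop("sigma must be >= 0")
  mu + kappa * sigma
}

## Greedy per-dimension marginal-likelihood grid search for lengthscales
## and noise variance (y standardized to unit variance beforehand).
gp_fit_hyper <- function(X, y) {
  d <- ncol(X)
  ls <- rep(0.3, d)
  nv <- 1e-4
  loglik <- function(ls, nv) {
    K <- se_kernel(X, X, ls, 1) + diag(nv + 1e-8, nrow(X))
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    a <- backsolve(ch, forwardsolve(t(ch), y))
    -0.5 * sum(y * a) - sum(log(diag(ch)))
  }
  grid_ls <- c(0.05, 0.1, 0.2, 0.3, 0.5, 1, 2)
  grid_nv <- c(1e-6, 1e-4, 1e-2)
  for (j in seq_len(d)) {
    scores <- vapply(grid_ls, function(l) {
      ls2 <- ls; ls2[j] <- l; loglik(ls2, nv)
    }, numeric(1))
    ls[j] <- grid_ls[which.max(scores)]
  }
  scores <- vapply(grid_nv, function(v) loglik(ls, v), numeric(1))
  nv <- grid_nv[which.max(scores)]
  list(lengthscale = ls, signal_var = 1, noise_var = nv)
}

#' Bayesian optimization of a black-box objective
#'
#' Maximizes `objective` over the search space: 5 seeded Latin-hypercube
#' initial points, then UCB-maximizing proposals (inner maximization over
#' 1,000 seeded random candidates per iteration), for exactly `budget`
#' objective evaluations. An objective that raises an error is recorded as a
#' failed trial, excluded from the surrogate, and still consumes budget.
#'
#' @param objective function taking a named list of hyperparameter values
#'   and returning a scalar score (larger is better).
#' @param space a [search_space()].
#' @param budget total objective evaluations (>= 5).
#' @param kappa UCB exploration constant.
#' @param seed integer seed; the whole run, including the inner acquisition
#'   maximization, is deterministic given it.
#' @param n_init initial design size (default 5).
#' @param n_candidates inner-maximization candidate count (default 1000).
#' @return an object of class `trial_log`: `configs` (data frame of
#'   evaluated points), `scores` (NA for failures), `gp_hyperparams`,
#'   `best_config`, `best_score`.
#' @export
bo_optimize <- function(objective, space, budget = 50L, kappa = 2,
                        seed = 0L, n_init = 5L, n_candidates = 1000L) {
  if (budget < 5L) stop("budget must be >= 5")
  d <- length(space$dimensions)
  nm <- vapply(space$dimensions, `[[`, character(1), "name")
  with_seed(seed, {
    U <- lhs::randomLHS(n_init, d)
    configs <- matrix(NA_real_, budget, d, dimnames = list(NULL, nm))
    unit <- matrix(NA_real_, budget, d)
    scores <- rep(NA_real_, budget)
    eval_at <- function(u, i) {
      x <- space_from_unit(space, u)
      ## snap unit coords of integer dims so the surrogate sees the
      ## configuration actually evaluated
      unit[i, ] <<- space_to_unit(space, x)
      configs[i, ] <<- x
      scores[i] <<- tryCatch(
        as.numeric(objective(stats::setNames(as.list(x), nm))),
        error = function(e) NA_real_)
    }
    for (i in seq_len(min(n_init, budget))) eval_at(U[i, ], i)
    gp_hp <- NULL
    i <- n_init
    while (i < budget) {
      i <- i + 1L
      ok <- which(!is.na(scores[seq_len(i - 1L)]))
      if (length(ok) < 2L) {
        eval_at(stats::runif(d), i)
        next
      }
      Xo <- unit[ok, , drop = FALSE]
      yo <- scores[ok]
      mu_y <- mean(yo); sd_y <- max(stats::sd(yo), 1e-8)
      ys <- (yo - mu_y) / sd_y
      gp_hp <- gp_fit_hyper(Xo, ys)
      cand <- matrix(stats::runif(n_candidates * d), n_candidates, d)
      post <- gp_posterior(Xo, ys, cand, gp_hp$lengthscale,
                           gp_hp$signal_var, gp_hp$noise_var)
      acq <- ucb_acquisition(post$mean, sqrt(post$var), kappa)
      eval_at(cand[which.max(acq), ], i)
    }
    best <- which.max(scores)
    structure(list(configs = as.data.frame(configs), scores = scores,
                   gp_hyperparams = gp_hp,
                   best_config = stats::setNames(as.list(configs[best, ]), nm),
                   best_score = scores[best]),
              class = "trial_log")
  })
}

#' @export
print.trial_log <- function(x, ...) {
  cat("Bayesian optimization:", length(x$scores), "trials (",
      sum(is.na(x$scores)), "failed )\n")
  cat("  best score:", signif(x$best_score, 5), "at",
      paste(names(x$best_config), signif(unlist(x$best_config), 4),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}
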