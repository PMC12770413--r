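#' Negative log partial likelihood of the Cox model
#'
#' Breslow's convention for ties: tied event times share the same risk set
#' `R(t_i) = {j : t_j >= t_i}`. The value is invariant to adding a constant
#' to every score.
#'
#' @param risk_scores numeric vector of model scores `f(x_i)` (log hazard
#'   ratios).
#' @param times survival/censoring times.
#' @param events event indicators (1 observed, 0 censored); at least one
#'   event required.
#' @return scalar loss.
#' @export
neg_log_partial_likelihood <- function(risk_scores, times, events) {
  n <- length(risk_scores)
  if (length(times) != n || length(events) != n)
    stop("risk_scores, times and events must have equal lengths")
  if (sum(events) == 0)
    stop("partial likelihood undefined with zero events")
  s <- risk_scores - max(risk_scores)   # numerical stability; shift-invariant
  ord <- order(times, decreasing = TRUE)
  cs <- cumsum(exp(s[ord]))
  ## risk-set mass for each subject: include all tied times
  t_desc <- times[ord]
  last_tied <- cummax_by_ties(t_desc, cs)
  logW <- log(last_tied)[order(ord)]    # back to input order
  -sum((s - logW)[events == 1])
}

## For a descending time vector, return for each position the cumulative sum
## evaluated at the last index sharing the same time value.
cummax_by_ties <- function(t_desc, cs) {
  grp <- cumsum(!duplicated(t_desc))
  last_idx <- vapply(split(seq_along(grp), grp), max, numeric(1))
  cs[last_idx][grp]
}

## Gradient of the negative log partial likelihood w.r.t. the scores.
nlpl_gradient <- function(risk_scores, times, events) {
  s <- risk_scores - max(risk_scores)
  es <- exp(s)
  ord <- order(times, decreasing = TRUE)
  cs <- cumsum(es[ord])
  W_desc <- cummax_by_ties(times[ord], cs)
  W <- W_desc[order(ord)]               # risk-set mass per subject
  ## sum over events i with t_i <= t_k of 1/W_i, per subject k
  asc <- order(times)
  invW_ev <- ifelse(events[asc] == 1, 1 / W[asc], 0)
  cum_asc <- cumsum(invW_ev)
  ## subjects with tied times must all receive the full tied-group sum
  t_asc <- times[asc]
  grp <- cumsum(!duplicated(t_asc))
  last_idx <- vapply(split(seq_along(grp), grp), max, numeric(1))
  cum_tied <- cum_asc[last_idx][grp]
  cumsum_k <- numeric(length(s)); cumsum_k[asc] <- cum_tied
  -(events - es * cumsum_k)
}

## ---- risk network ----------------------------------------------------------

ds_init_params <- function(p, hidden) {
  layers <- list()
  prev <- p
  for (i in seq_along(hidden)) {
    layers[[paste0("h", i)]] <- nn_dense_init(prev, hidden[i])
    prev <- hidden[i]
  }
  layers$out <- nn_dense_init(prev, 1L)
  layers
}

ds_forward <- function(X, params, dropout = 0, train = FALSE) {
  caches <- list()
  h <- X
  nh <- length(params) - 1L
  for (i in seq_len(nh)) {
    dn <- nn_dense_forward(h, params[[paste0("h", i)]])
    rl <- nn_relu_forward(dn$out)
    h <- rl$out
    dmask <- NULL
    if (train && dropout > 0) {
      dmask <- matrix(stats::rbinom(length(h), 1, 1 - dropout) / (1 - dropout),
                      nrow(h))
      h <- h * dmask
    }
    caches[[paste0("h", i)]] <- list(dense = dn$cache, relu = rl$cache,
                                     dmask = dmask)
  }
  dn <- nn_dense_forward(h, params$out)
  caches$out <- dn$cache
  list(scores = as.numeric(dn$out), caches = caches)
}

ds_backward <- function(dscores, caches, params) {
  grads <- list()
  bk <- nn_dense_backward(matrix(dscores, ncol = 1L), caches$out)
  grads$out <- bk$grads
  dh <- bk$dx
  nh <- length(params) - 1L
  for (i in rev(seq_len(nh))) {
    key <- paste0("h", i)
    if (!is.null(caches[[key]]$dmask)) dh <- dh * caches[[key]]$dmask
    dh <- nn_relu_backward(dh, caches[[key]]$relu)
    bk <- nn_dense_backward(dh, caches[[key]]$dense)
    grads[[key]] <- bk$grads
    dh <- bk$dx
  }
  grads
}

#' Deep Cox proportional-hazards survival model
#'
#' Fits a risk network `f(x)` by full-batch Adam on the negative log partial
#' likelihood (Breslow ties), then computes the Breslow baseline cumulative
#' hazard on the training data. With `hidden = NULL` the risk network is
#' linear and the model coincides with a Cox regression fit by gradient
#' descent; with hidden layers it captures non-linear covariate
#' interactions. The hazard for covariates `x` is
#' `h(t | x) = h0(t) exp(f(x))`.
#'
#' @param formula model formula whose response is a [survival::Surv()]
#'   object, e.g. `Surv(time, event) ~ .`.
#' @param data data frame with the survival response and covariates.
#' @param hidden integer vector of hidden-layer sizes (ReLU); `NULL` for a
#'   linear risk model.
#' @param dropout dropout rate in \[0, 0.5\] applied to hidden layers during
#'   training.
#' @param epochs,lr full-batch Adam settings.
#' @param l2 L2 weight penalty (weights only, not biases).
#' @param standardize center/scale covariates internally (predictions are
#'   unaffected; coefficients are reported on the original scale).
#' @param seed integer seed (initialization and dropout).
#' @return an object of class `deepsurv` with components `params`,
#'   `baseline` (Breslow baseline table with `time` and `H0`), `history`
#'   (per-epoch loss), `input_spec`, and the training data summary. Methods:
#'   `print`, `summary`, `coef` (linear fits), `predict`, `plot`,
#'   `residuals` (martingale), `simulate`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 120, image_size = 32,
#'                                         seed = 1))
#' d <- data.frame(time = cohort_field(cohort, "time"),
#'                 event = cohort_field(cohort, "event"),
#'                 cohort_risk_matrix(cohort))
#' fit <- deepsurv(survival::Surv(time, event) ~ ., d, hidden = NULL,
#'                 epochs = 200, seed = 1)
#' coef(fit)
#' @export
deepsurv <- function(formula = survival::Surv(time, event) ~ ., data,
                     hidden = c(32L, 16L), dropout = 0, epochs = 300L,
                     lr = 0.02, l2 = 1e-4, standardize = TRUE, seed = 0L) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (!inherits(y, "Surv")) stop("the response must be a survival::Surv object")
  times <- as.numeric(y[, 1]); events <- as.numeric(y[, 2])
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (nrow(X) < 20L) stop("deepsurv requires at least 20 samples")
  if (sum(events) < 5L) stop("deepsurv requires at least 5 events")
  if (dropout < 0 || dropout > 0.5) stop("dropout must lie in [0, 0.5]")
  center <- if (standardize) colMeans(X) else rep(0, ncol(X))
  scale_ <- if (standardize) pmax(apply(X, 2L, stats::sd), 1e-8)
            else rep(1, ncol(X))
  Xs <- sweep(sweep(X, 2L, center), 2L, scale_, `/`)
  with_seed(seed, {
    params <- ds_init_params(ncol(Xs), hidden)
    opt <- adam_init(params)
    history <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      fw <- ds_forward(Xs, params, dropout, train = TRUE)
      loss <- neg_log_partial_likelihood(fw$scores, times, events) / nrow(Xs)
      ds <- nlpl_gradient(fw$scores, times, events) / nrow(Xs)
      gr <- ds_backward(ds, fw$caches, params)
      if (l2 > 0)
        gr <- Map(function(g, p) list(W = g$W + l2 * p$W, b = g$b),
                  gr[names(params)], params)
      st <- adam_step(params, gr, opt, lr = lr)
      params <- st$params; opt <- st$state
      history[ep] <- loss
    }
    scores <- ds_forward(Xs, params)$scores
    baseline <- breslow_baseline(scores, times, events)
    structure(list(params = params, hidden = hidden, dropout = dropout,
                   center = center, scale = scale_, formula = formula,
                   input_spec = colnames(X), baseline = baseline,
                   history = history, times = times, events = events,
                   train_scores = scores, seed = seed,
                   n = nrow(Xs), call = match.call()),
              class = "deepsurv")
  })
}

ds_predict_lp <- function(object, X) {
  Xs <- sweep(sweep(as.matrix(X), 2L, object$center), 2L, object$scale, `/`)
  ds_forward(Xs, object$params)$scores
}

newdata_matrix <- function(object, newdata) {
  tt <- stats::delete.response(stats::terms(object$formula,
                                            data = newdata))
  mf <- stats::model.frame(tt, newdata)
  X <- stats::model.matrix(tt, mf)
  X[, colnames(X) != "(Intercept)", drop = FALSE]
}

#' @export
print.deepsurv <- function(x, ...) {
  cat("Deep Cox proportional-hazards model\n")
  arch <- if (is.null(x$hidden)) "linear" else paste(x$hidden, collapse = "-")
  cat("  risk network:", arch, " covariates:", length(x$input_spec),
      " n:", x$n, " events:", sum(x$events), "\n")
  cat("  final loss:", signif(utils::tail(x$history, 1), 5), "\n")
  invisible(x)
}

#' @export
summary.deepsurv <- function(object, ...) {
  ci <- concordance_index(exp(object$train_scores), object$times,
                          object$events)
  out <- list(call = object$call, n = object$n,
              n_events = sum(object$events),
              train_cindex = ci,
              final_loss = utils::tail(object$history, 1),
              coefficients = if (is.null(object$hidden)) coef(object))
  class(out) <- "summary.deepsurv"
  out
}

#' @export
print.summary.deepsurv <- function(x, ...) {
  cat("Deep Cox proportional-hazards model\n  n =", x$n, ", events =",
      x$n_events, "\n  training concordance index:",
      round(x$train_cindex, 4), "\n")
  if (!is.null(x$coefficients)) {
    cat("  coefficients (original covariate scale):\n")
    print(round(x$coefficients, 4))
  }
  invisible(x)
}

#' @export
coef.deepsurv <- function(object, ...) {
  if (!is.null(object$hidden))
    stop("coefficients are only defined for linear risk networks (hidden = NULL)")
  stats::setNames(as.numeric(object$params$out$W) / object$scale,
                  object$input_spec)
}

#' Predictions from a deep Cox model
#'
#' @param object a fitted [deepsurv()] model.
#' @param newdata data frame of covariates (defaults to refitting data not
#'   being stored; `newdata` is required).
#' @param type `"lp"` (log hazard ratio `f(x)`), `"risk"` (hazard ratio
#'   `exp(f(x))`), `"cumhaz"` (`H(t|x)`) or `"survival"` (`exp(-H(t|x))`);
#'   the latter two need `times`.
#' @param times evaluation times for `"cumhaz"`/`"survival"`.
#' @param ... unused.
#' @return numeric vector, or a matrix (patients x times) for
#'   `"cumhaz"`/`"survival"`.
#' @export
predict.deepsurv <- function(object, newdata,
                             type = c("lp", "risk", "cumhaz", "survival"),
                             times = NULL, ...) {
  type <- match.arg(type)
  X <- newdata_matrix(object, newdata)
  lp <- ds_predict_lp(object, X)
  if (type == "lp") return(lp)
  if (type == "risk") return(exp(lp))
  if (is.null(times)) stop("'times' is required for cumulative hazard / survival")
  if (any(times < 0)) stop("times must be >= 0")
  H0 <- vapply(times, function(t) baseline_H0_at(object$baseline, t), numeric(1))
  H <- outer(exp(lp), H0)
  dimnames(H) <- list(NULL, paste0("t=", signif(times, 4)))
  if (type == "cumhaz") H else exp(-H)
}

#' @export
residuals.deepsurv <- function(object, newdata = NULL, ...) {
  ## martingale residuals: delta_i - H(t_i | x_i) on the training data
  H0 <- vapply(object$times, function(t) baseline_H0_at(object$baseline, t),
               numeric(1))
  object$events - H0 * exp(object$train_scores)
}

#' @export
plot.deepsurv <- function(x, ...) {
  graphics::plot(stats::stepfun(x$baseline$time, c(0, x$baseline$H0)),
                 do.points = FALSE, xlab = "time",
                 ylab = expression(H[0](t)),
                 main = "Breslow baseline cumulative hazard", ...)
  invisible(x)
}

#' @export
simulate.deepsurv <- function(object, nsim = 1L, seed = NULL, newdata, ...) {
  ## inverse-transform sampling from the step baseline; times beyond the
  ## last observed event time are right-censored there
  X <- newdata_matrix(object, newdata)
  hr <- exp(ds_predict_lp(object, X))
  tmax <- max(object$baseline$time)
  draw <- function() {
    E <- stats::rexp(length(hr))
    target <- E / hr
    idx <- findInterval(target, object$baseline$H0) + 1L
    ifelse(idx > nrow(object$baseline), tmax, object$baseline$time[idx])
  }
  if (!is.null(seed)) with_seed(seed, replicate(nsim, draw(), simplify = FALSE))
  else replicate(nsim, draw(), simplify = FALSE)
}

## ---- Breslow baseline ------------------------------------------------------

#' Breslow estimator of the baseline cumulative hazard
#'
#' At each distinct event time `t_(k)` the increment is
#' `d_(k) / sum_{j in R(t_(k))} exp(f(x_j))` with `d_(k)` the number of
#' events at `t_(k)`; the cumulative sum forms `H0`.
#'
#' @param risk_scores fitted scores `f(x_i)`.
#' @param times survival/censoring times.
#' @param events event indicators; at least one event required.
#' @return data frame with strictly increasing `time`, per-time `increment`
#'   and non-decreasing cumulative `H0`.
#' @export
breslow_baseline <- function(risk_scores, times, events) {
  if (sum(events) == 0) stop("no events: baseline hazard undefined")
  es <- exp(risk_scores)
  ev_times <- sort(unique(times[events == 1]))
  inc <- vapply(ev_times, function(t) {
    d <- sum(events == 1 & times == t)
    d / sum(es[times >= t])
  }, numeric(1))
  data.frame(time = ev_times, increment = inc, H0 = cumsum(inc))
}

## Right-continuous step interpolation of H0 at time t (H0(0) = 0).
baseline_H0_at <- function(baseline, t) {
  if (t < 0) stop("t must be >= 0")
  idx <- findInterval(t, baseline$time)
  if (idx == 0L) 0 else baseline$H0[idx]
}

#' Cumulative hazard for a fitted deep Cox model
#'
#' `H(t | x) = H0(t) exp(f(x))`, with the Breslow baseline step-interpolated
#' right-continuously and `H(0 | x) = 0`.
#'
#' @param state a fitted [deepsurv()] model.
#' @param x covariate row (data frame or named vector matching the model's
#'   input spec).
#' @param t non-negative evaluation time.
#' @return scalar cumulative hazard.
#' @export
cumulative_hazard <- function(state, x, t) {
  if (t < 0) stop("t must be >= 0")
  if (is.null(dim(x))) x <- as.data.frame(as.list(x))
  lp <- ds_predict_lp(state, newdata_matrix(state, x))
  baseline_H0_at(state$baseline, t) * exp(lp)
}

## ---- concordance index -----------------------------------------------------

#' Harrell's concordance index
#'
#' Over comparable pairs (the earlier subject must have an observed event
#' and a strictly shorter time), the fraction where the predicted hazard of
#' the earlier subject exceeds that of the later one; prediction ties count
#' 0.5.
#'
#' @param pred_hazard predicted hazards (any monotone risk score works).
#' @param times survival/censoring times.
#' @param events event indicators.
#' @return scalar in \[0, 1\].
#' @export
concordance_index <- function(pred_hazard, times, events) {
  n <- length(pred_hazard)
  if (length(times) != n || length(events) != n)
    stop("pred_hazard, times and events must have equal lengths")
  comp <- 0; conc <- 0
  ## vectorized pair enumeration: subject i usable when delta_i = 1, t_i < t_j
  ev <- which(events == 1)
  for (i in ev) {
    later <- times > times[i]
    m <- sum(later)
    if (m == 0) next
    comp <- comp + m
    conc <- conc + sum(pred_hazard[i] > pred_hazard[later]) +
      0.5 * sum(pred_hazard[i] == pred_hazard[later])
  }
  if (comp == 0) stop("no comparable pairs")
  conc / comp
}

## ---- risk stratification ---------------------------------------------------

#' Hazard-ratio cutpoints for risk stratification
#'
#' Defaults (1.0, 1.2) assign hazard ratios below 1.0 to the low-risk group,
#' \[1.0, 1.2) to medium and >= 1.2 to high.
#'
#' @param low_upper upper hazard-ratio bound of the low-risk group.
#' @param high_lower lower hazard-ratio bound of the high-risk group.
#' @return an object of class `risk_cutpoints`.
#' @export
risk_cutpoints <- function(low_upper = 1.0, high_lower = 1.2) {
  if (!(low_upper < high_lower)) stop("low_upper must be < high_lower")
  structure(list(low_upper = low_upper, high_lower = high_lower),
            class = "risk_cutpoints")
}

#' Tertile-based cutpoints from a set of hazard ratios
#'
#' Alternative to the fixed defaults: cutpoints at the 1/3 and 2/3 sample
#' quantiles of the supplied hazard ratios.
#'
#' @param hazard_ratios numeric vector of hazard ratios.
#' @return a [risk_cutpoints()] object.
#' @export
risk_cutpoints_tertiles <- function(hazard_ratios) {
  q <- stats::quantile(hazard_ratios, c(1 / 3, 2 / 3), names = FALSE)
  risk_cutpoints(q[1], q[2])
}

#' Stratify patients into risk groups by hazard ratio
#'
#' Low if below `low_upper`; medium in `[low_upper, high_lower)`; high at or
#' above `high_lower` (half-open convention: a hazard ratio exactly at
#' `low_upper` is medium).
#'
#' @param hazard_ratio positive hazard ratio(s) `exp(f(x))`.
#' @param cutpoints a [risk_cutpoints()] object.
#' @return factor with levels `low`, `medium`, `high`.
#' @export
stratify_risk <- function(hazard_ratio, cutpoints = risk_cutpoints()) {
  if (any(hazard_ratio <= 0)) stop("hazard ratios must be positive")
  grp <- ifelse(hazard_ratio < cutpoints$low_upper, "low",
                ifelse(hazard_ratio < cutpoints$high_lower, "medium", "high"))
  factor(grp, levels = c("low", "medium", "high"))
}
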