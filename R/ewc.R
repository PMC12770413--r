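## Elastic Weight Consolidation for incremental survival-model updates.

#' Diagonal empirical Fisher information of a deep Cox model
#'
#' Estimated as the mean over consecutive mini-batches of the squared
#' gradients of the negative log partial likelihood (per-sample normalized)
#' at the fitted parameters. All entries are non-negative; duplicating the
#' dataset leaves the estimate unchanged (it is a mean over batches, not a
#' sum).
#'
#' @param state a fitted [deepsurv()] model.
#' @param data previous-task data frame (same columns as the fitting data);
#'   must contain at least one event.
#' @param batch_size patients per mini-batch (default 50).
#' @return nested list matching the parameter structure, entries >= 0.
#' @export
estimate_fisher <- function(state, data, batch_size = 50L) {
  mf <- stats::model.frame(state$formula, data)
  y <- stats::model.response(mf)
  times <- as.numeric(y[, 1]); events <- as.numeric(y[, 2])
  if (sum(events) == 0) stop("all-censored data: Fisher estimate undefined")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  Xs <- sweep(sweep(X, 2L, state$center), 2L, state$scale, `/`)
  n <- nrow(Xs)
  starts <- seq(1L, n, by = batch_size)
  acc <- NULL
  n_used <- 0L
  for (s0 in starts) {
    idx <- s0:min(s0 + batch_size - 1L, n)
    if (sum(events[idx]) == 0) next  # batch contributes no likelihood
    fw <- ds_forward(Xs[idx, , drop = FALSE], state$params)
    ds <- nlpl_gradient(fw$scores, times[idx], events[idx]) / length(idx)
    gr <- ds_backward(ds, fw$caches, state$params)
    sq <- grad_square(gr[names(state$params)])
    acc <- if (is.null(acc)) sq else grad_add(acc, sq)
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("no batch contained an event")
  grad_scale(acc, 1 / n_used)
}

grad_square <- function(g) {
  if (is.list(g)) lapply(g, grad_square) else g * g
}

#' Elastic Weight Consolidation state
#'
#' Anchors the fitted parameters and their Fisher importances so later
#' updates can penalize drift on parameters important to the previous task.
#' The previous-task data is retained for retention reporting.
#'
#' @param fit a fitted [deepsurv()] model (the previous task).
#' @param data previous-task data frame.
#' @param lambda_ewc regularization strength (>= 0, default 100).
#' @param batch_size_new new patients per incremental update batch
#'   (default 50); also used for the Fisher mini-batches.
#' @return an object of class `ewc_state`.
#' @export
ewc_state <- function(fit, data, lambda_ewc = 100, batch_size_new = 50L) {
  if (lambda_ewc < 0) stop("lambda_ewc must be >= 0")
  structure(list(anchor_params = fit$params,
                 fisher_diag = estimate_fisher(fit, data, batch_size_new),
                 lambda_ewc = lambda_ewc,
                 batch_size_new = as.integer(batch_size_new),
                 old_data = data),
            class = "ewc_state")
}

ewc_penalty <- function(params, anchor, fisher, lambda) {
  pen <- function(p, a, f) {
    if (is.list(p)) sum(unlist(Map(pen, p, a[names(p)], f[names(p)])))
    else sum(f * (p - a)^2)
  }
  lambda / 2 * pen(params, anchor, fisher)
}

#' EWC-regularized loss on a new batch
#'
#' The negative log partial likelihood (per-sample normalized) of the
#' current parameters on the new batch, plus the quadratic anchor penalty
#' `lambda/2 * sum_i F_i (theta_i - theta_i*)^2`. Reduces exactly to the
#' plain new-batch loss at `lambda = 0`, and the penalty is exactly zero at
#' the anchor.
#'
#' @param current_params parameter structure (same shape as the anchor).
#' @param new_batch data frame of new patients (needs >= 1 event).
#' @param ewc a [ewc_state()].
#' @param fit the [deepsurv()] model supplying preprocessing and formula.
#' @return scalar loss.
#' @export
ewc_loss <- function(current_params, new_batch, ewc, fit) {
  mf <- stats::model.frame(fit$formula, new_batch)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  Xs <- sweep(sweep(X, 2L, fit$center), 2L, fit$scale, `/`)
  fw <- ds_forward(Xs, current_params)
  neg_log_partial_likelihood(fw$scores, as.numeric(y[, 1]),
                             as.numeric(y[, 2])) / nrow(Xs) +
    ewc_penalty(current_params, ewc$anchor_params, ewc$fisher_diag,
                ewc$lambda_ewc)
}

#' Incremental survival-model update with EWC
#'
#' Minimizes the EWC loss on the new batch by gradient descent with a
#' proximal (implicit) step on the quadratic anchor penalty:
#' `theta <- (theta - lr g_new + lr lambda F theta*) / (1 + lr lambda F)`.
#' The implicit step is unconditionally stable, reduces to plain gradient
#' descent at `lambda = 0`, and freezes the parameters at the anchor as
#' `lambda -> Inf`. The anchor is refreshed after the update.
#'
#' @param fit a fitted [deepsurv()] model.
#' @param ewc a [ewc_state()] built from the previous task.
#' @param new_batch data frame of new patients.
#' @param epochs,lr gradient-descent settings.
#' @param seed integer seed (kept for interface symmetry; the update itself
#'   is deterministic).
#' @return list with `fit` (updated model, baseline recomputed on the new
#'   batch), `ewc` (refreshed anchor) and `report` (old-task C-index before
#'   and after, new-task C-index, parameter shift in max-norm).
#' @export
incremental_update <- function(fit, ewc, new_batch, epochs = 200L, lr = 0.05,
                               seed = 0L) {
  if (nrow(new_batch) == 0L) stop("empty new batch")
  mf <- stats::model.frame(fit$formula, new_batch)
  y <- stats::model.response(mf)
  times <- as.numeric(y[, 1]); events <- as.numeric(y[, 2])
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  Xs <- sweep(sweep(X, 2L, fit$center), 2L, fit$scale, `/`)
  params <- fit$params
  lam <- ewc$lambda_ewc
  prox <- function(p, g, a, f) {
    if (is.list(p)) return(Map(prox, p, g[names(p)], a[names(p)], f[names(p)]))
    (p - lr * g + lr * lam * f * a) / (1 + lr * lam * f)
  }
  for (ep in seq_len(epochs)) {
    fw <- ds_forward(Xs, params)
    ds <- nlpl_gradient(fw$scores, times, events) / nrow(Xs)
    gr <- ds_backward(ds, fw$caches, params)
    params <- prox(params, gr[names(params)], ewc$anchor_params,
                   ewc$fisher_diag)
  }
  old_frame <- ewc$old_data
  oldX <- function(f) {
    lpold <- ds_predict_lp(f, newdata_matrix(f, old_frame))
    mfo <- stats::model.frame(f$formula, old_frame)
    yo <- stats::model.response(mfo)
    concordance_index(exp(lpold), as.numeric(yo[, 1]), as.numeric(yo[, 2]))
  }
  old_before <- oldX(fit)
  updated <- fit
  updated$params <- params
  scores_new <- ds_forward(Xs, params)$scores
  updated$baseline <- breslow_baseline(scores_new, times, events)
  updated$train_scores <- scores_new
  updated$times <- times; updated$events <- events; updated$n <- nrow(Xs)
  old_after <- oldX(updated)
  new_ci <- concordance_index(exp(scores_new), times, events)
  shift <- max_abs_diff(params, fit$params)
  ewc$anchor_params <- params
  ewc$old_data <- new_batch
  list(fit = updated, ewc = ewc,
       report = list(old_cindex_before = old_before,
                     old_cindex_after = old_after,
                     new_cindex = new_ci,
                     max_param_shift = shift))
}

max_abs_diff <- function(a, b) {
  if (is.list(a)) max(unlist(Map(max_abs_diff, a, b[names(a)])))
  else max(abs(a - b))
}
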