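## Shapley-value feature attribution: exact coalition enumeration for small
## feature sets, permutation sampling otherwise.

#' Model prediction with a feature coalition
#'
#' Features outside the coalition are replaced by their background means
#' (the interventional convention); the model is evaluated on the imputed
#' instance.
#'
#' @param model function mapping a 1-row matrix (or data frame row) of
#'   features to a scalar prediction.
#' @param x instance: named numeric vector.
#' @param subset integer indices of the features kept at their `x` values.
#' @param background reference rows (matrix/data frame) for imputation.
#' @return scalar model value `f(S)`.
#' @export
coalition_value <- function(model, x, subset, background) {
  if (is.null(dim(background)) || nrow(background) == 0L)
    stop("background must be a non-empty matrix of reference rows")
  bg <- colMeans(as.matrix(background))
  xi <- bg
  xi[subset] <- x[subset]
  as.numeric(model(matrix(xi, nrow = 1L,
                          dimnames = list(NULL, names(x) %||% colnames(background)))))
}

shapley_report <- function(feature_names, phi, baseline_value, full_value,
                           method, n_samples = NA_integer_, se = NULL,
                           seed = NA_integer_) {
  structure(list(feature_names = feature_names,
                 phi = stats::setNames(phi, feature_names),
                 baseline_value = baseline_value, full_value = full_value,
                 overall_score = sum(phi), method = method,
                 n_samples = n_samples, se = se, seed = seed),
            class = "shapley_report")
}

#' @export
print.shapley_report <- function(x, ...) {
  cat("Shapley attribution (", x$method, ")\n", sep = "")
  print(round(x$phi, 4))
  cat("  baseline", round(x$baseline_value, 4), "-> full",
      round(x$full_value, 4), "; overall score", round(x$overall_score, 4),
      "\n")
  invisible(x)
}

#' Exact Shapley values by coalition enumeration
#'
#' Full 2^n enumeration with the combinatorial weights
#' `|S|! (n - |S| - 1)! / n!`. Satisfies efficiency (attributions sum to
#' `f(N) - f(0)` within 1e-8), symmetry, dummy and linearity.
#'
#' @param model scalar-output model function (see [coalition_value()]).
#' @param x instance (named numeric vector).
#' @param background reference rows for imputation.
#' @param feature_names optional names (default from `x`/`background`).
#' @return a `shapley_report`.
#' @export
exact_shapley <- function(model, x, background, feature_names = NULL) {
  n <- length(x)
  if (n > 15L)
    stop("exact enumeration limited to 15 features; use permutation_shapley()")
  feature_names <- feature_names %||% names(x) %||%
    colnames(background) %||% paste0("f", seq_len(n))
  bg <- colMeans(as.matrix(background))
  vals <- numeric(2^n)
  for (mask in 0:(2^n - 1L)) {
    sub <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) > 0L)
    xi <- bg; xi[sub] <- x[sub]
    vals[mask + 1L] <- as.numeric(model(matrix(xi, 1L,
                                               dimnames = list(NULL, feature_names))))
  }
  fact <- factorial(0:n)
  phi <- numeric(n)
  for (i in seq_len(n)) {
    bit <- bitwShiftL(1L, i - 1L)
    for (mask in 0:(2^n - 1L)) {
      if (bitwAnd(mask, bit) > 0L) next
      s <- sum(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) > 0L)
      w <- fact[s + 1L] * fact[n - s] / fact[n + 1L]
      phi[i] <- phi[i] + w * (vals[bitwOr(mask, bit) + 1L] - vals[mask + 1L])
    }
  }
  shapley_report(feature_names, phi, baseline_value = vals[1L],
                 full_value = vals[2^n], method = "exact")
}

#' Permutation-sampling Shapley estimates
#'
#' Averages marginal contributions over uniformly random feature orderings:
#' an unbiased estimator of the exact Shapley values, with a per-feature
#' Monte-Carlo standard error.
#'
#' @param model scalar-output model function.
#' @param x instance (named numeric vector).
#' @param background reference rows for imputation.
#' @param n_samples number of random permutations (>= 10).
#' @param seed integer seed.
#' @return a `shapley_report` with `se` per feature.
#' @export
permutation_shapley <- function(model, x, background, n_samples = 200L,
                                seed = 0L) {
  if (n_samples < 10L) stop("n_samples must be >= 10")
  n <- length(x)
  feature_names <- names(x) %||% colnames(background) %||% paste0("f", seq_len(n))
  bg <- colMeans(as.matrix(background))
  evalx <- function(xi) as.numeric(model(matrix(xi, 1L,
                                                dimnames = list(NULL, feature_names))))
  base_val <- evalx(bg)
  full_val <- evalx(x)
  contrib <- matrix(0, n_samples, n)
  with_seed(seed, {
    for (s in seq_len(n_samples)) {
      perm <- sample.int(n)
      xi <- bg
      prev <- base_val
      for (i in perm) {
        xi[i] <- x[i]
        cur <- evalx(xi)
        contrib[s, i] <- cur - prev
        prev <- cur
      }
    }
  })
  phi <- colMeans(contrib)
  se <- apply(contrib, 2L, stats::sd) / sqrt(n_samples)
  rep_ <- shapley_report(feature_names, phi, base_val, full_val,
                         method = "permutation", n_samples = n_samples,
                         se = stats::setNames(se, feature_names), seed = seed)
  rep_
}

#' Overall attribution score of a Shapley report
#'
#' The default convention is the plain sum of the per-feature attribution
#' values (which, by efficiency, equals `f(N) - f(0)` for exact reports).
#' `"abs"` sums absolute attributions; `"normalized"` divides the plain sum
#' by `f(N) - f(0)` (1 for exact reports; a Monte-Carlo coverage diagnostic
#' for permutation estimates).
#'
#' @param report a `shapley_report`, or a bare numeric vector of
#'   per-feature attribution values.
#' @param method `"sum"` (default), `"abs"` or `"normalized"`.
#' @return scalar score.
#' @export
overall_score <- function(report, method = c("sum", "abs", "normalized")) {
  method <- match.arg(method)
  phi <- if (inherits(report, "shapley_report")) report$phi else as.numeric(report)
  switch(method,
    sum = sum(phi),
    abs = sum(abs(phi)),
    normalized = {
      denom <- if (inherits(report, "shapley_report"))
        report$full_value - report$baseline_value else sum(phi)
      sum(phi) / denom
    })
}

#' Model functions for attribution
#'
#' Wraps fitted package models as scalar-output functions for the Shapley
#' operators: for a [deepsurv()] fit the explained output is the log hazard
#' ratio `f(x)`; for a classifier the predicted-class probability of a
#' reference sample whose genomic vector is replaced by the explained
#' features.
#'
#' @param fit a fitted `deepsurv` model.
#' @return function mapping feature rows to scalars.
#' @export
shapley_model_deepsurv <- function(fit) {
  function(X) {
    X <- as.matrix(X)
    colnames(X) <- fit$input_spec
    ds_predict_lp(fit, X)
  }
}

#' @rdname shapley_model_deepsurv
#' @param clf a trained `oncosurv_classifier`.
#' @param sample cohort sample supplying the (fixed) image modality.
#' @param class explained class index 0/1/2 (default: the predicted class).
#' @export
shapley_model_classifier <- function(clf, sample, class = NULL) {
  f_img <- extract_image_features(sample$image, sample$mask, clf$params$cnn)
  if (is.null(class)) {
    probs <- feature_bundle(sample, clf)$subtype_probs
    class <- which.max(probs) - 1L
  }
  function(G) {
    G <- as.matrix(G)
    vapply(seq_len(nrow(G)), function(i) {
      f_gen <- extract_genomic_features(G[i, ], clf$params$mlp)
      fused <- fuse_features(f_img, f_gen, config = clf$config,
                             params = clf$params$attn)
      classify_subtype(as.numeric(fused), clf$params$head)[class + 1L]
    }, numeric(1))
  }
}
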