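linear_model <- function(w) function(X) as.numeric(as.matrix(X) %*% w)

centered_background <- function(n, p, seed = 2) {
  set.seed(seed)
  bg <- matrix(rnorm(n * p), n, p)
  sweep(bg, 2, colMeans(bg))  # exactly mean-zero
}

test_that("coalition values follow the mean-imputation convention", {
  w <- c(2, -1, 0.5)
  mod <- linear_model(w)
  bg <- centered_background(30, 3)
  x <- c(1, 2, -1)
  expect_equal(coalition_value(mod, x, 1:3, bg), sum(w * x))
  expect_equal(coalition_value(mod, x, integer(0), bg), 0, tolerance = 1e-12)
  ## linear model, mean-zero background: f(S) = sum_{i in S} w_i x_i
  expect_equal(coalition_value(mod, x, c(1, 3), bg), w[1] * x[1] + w[3] * x[3],
               tolerance = 1e-12)
  expect_error(coalition_value(mod, x, 1:3, bg[0, , drop = FALSE]),
               "background")
})

test_that("exact Shapley values satisfy the classic axioms", {
  w <- c(2, -1, 0.5, 0)
  mod <- linear_model(w)
  bg <- centered_background(25, 4)
  x <- c(1, 2, -1, 3)
  r <- exact_shapley(mod, x, bg)
  ## closed-form Shapley of a linear model with mean-zero background
  expect_equal(unname(r$phi), w * x, tolerance = 1e-10)
  ## dummy axiom: the ignored feature gets exactly zero
  expect_equal(unname(r$phi[4]), 0)
  ## efficiency to 1e-8
  expect_lt(abs(sum(r$phi) - (r$full_value - r$baseline_value)), 1e-8)
  ## symmetry: model depends on the sum of two features with equal values
  mods <- function(X) (as.matrix(X)[, 1] + as.matrix(X)[, 2])^2
  xs <- c(0.7, 0.7, 0.1)
  rs <- exact_shapley(mods, xs, centered_background(25, 3))
  expect_equal(unname(rs$phi[1]), unname(rs$phi[2]), tolerance = 1e-10)
  expect_error(exact_shapley(mod, rnorm(16), centered_background(5, 16)),
               "permutation_shapley")
})

test_that("exact enumeration equals the all-orders permutation-average oracle", {
  set.seed(9)
  for (trial in 1:6) {
    n <- sample(3:5, 1)
    A <- matrix(rnorm(n * n, sd = 0.5), n)
    w <- rnorm(n)
    mod <- function(X) {
      X <- as.matrix(X)
      as.numeric(X %*% w + rowSums((X %*% A) * X))  # quadratic, interacting
    }
    bg <- matrix(rnorm(10 * n), 10, n)
    x <- rnorm(n)
    r <- exact_shapley(mod, x, bg)
    oracle <- all_orders_shapley(mod, x, bg)
    expect_equal(unname(r$phi), oracle, tolerance = 1e-10)
  }
})

test_that("permutation sampling converges to the exact values with sqrt(n) errors", {
  w <- c(1.5, -2, 0.8, 0.3, -0.7, 1.1)
  A <- diag(0.3, 6); A[1, 2] <- 0.5
  mod <- function(X) {
    X <- as.matrix(X)
    as.numeric(X %*% w + rowSums((X %*% A) * X))
  }
  bg <- centered_background(40, 6, seed = 5)
  set.seed(6); x <- rnorm(6)
  ex <- exact_shapley(mod, x, bg)
  pm <- permutation_shapley(mod, x, bg, n_samples = 2000, seed = 0)
  expect_true(all(abs(pm$phi - ex$phi) <= 3 * pmax(pm$se, 1e-12)))
  ## doubling the sample count shrinks the standard error by about sqrt(2)
  pm2 <- permutation_shapley(mod, x, bg, n_samples = 4000, seed = 0)
  ratio <- mean(pm$se / pm2$se)
  expect_gt(ratio, sqrt(2) * 0.8)
  expect_lt(ratio, sqrt(2) * 1.25)
  ## determinism
  pm3 <- permutation_shapley(mod, x, bg, n_samples = 200, seed = 12)
  pm4 <- permutation_shapley(mod, x, bg, n_samples = 200, seed = 12)
  expect_identical(pm3$phi, pm4$phi)
  expect_error(permutation_shapley(mod, x, bg, n_samples = 5), "n_samples")
})

test_that("overall scores reproduce the printed per-patient sums", {
  for (row in shap_examples) {
    expect_equal(overall_score(row$phi), row$overall, tolerance = 1e-12)
  }
  expect_equal(overall_score(c(0, 0, 0)), 0)
  expect_equal(overall_score(c(-0.2, 0.5), method = "abs"), 0.7)
  r <- exact_shapley(linear_model(c(1, 2)), c(1, 1), centered_background(10, 2))
  expect_equal(overall_score(r, method = "normalized"), 1, tolerance = 1e-10)
})

test_that("fitted survival models can be explained end to end", {
  fit <- ph_fit()
  d <- ph_frame()
  x <- unlist(d[1, c("x1", "x2", "x3")])
  bg <- as.matrix(d[1:100, c("x1", "x2", "x3")])
  r <- exact_shapley(shapley_model_deepsurv(fit), x, bg)
  expect_lt(abs(sum(r$phi) - (r$full_value - r$baseline_value)), 1e-8)
  ## a linear risk net explained against its background mean is exactly
  ## beta_std * (x - mean(bg)) per feature
  beta <- coef(fit)
  expect_equal(unname(r$phi), unname(beta * (x - colMeans(bg))),
               tolerance = 1e-8)
})
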