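test_that("the partial likelihood matches its closed forms", {
  ## n = 2, equal scores: log 2 + log 1
  expect_equal(neg_log_partial_likelihood(c(0, 0), c(1, 2), c(1, 1)), log(2))
  ## general two-subject closed form
  a <- 0.7; b <- -1.2
  expect_equal(neg_log_partial_likelihood(c(a, b), c(1, 2), c(1, 1)),
               -(a - log(exp(a) + exp(b)) + b - log(exp(b))))
  ## equal scores, k events, distinct times, no censoring: sum log i
  k <- 7
  expect_equal(neg_log_partial_likelihood(rep(0.4, k), seq_len(k), rep(1, k)),
               sum(log(seq_len(k))))
  ## shift invariance (exact)
  set.seed(1)
  s <- rnorm(12); t <- runif(12); e <- rbinom(12, 1, 0.7); e[1] <- 1
  expect_equal(neg_log_partial_likelihood(s, t, e),
               neg_log_partial_likelihood(s + 5, t, e), tolerance = 1e-8)
  expect_error(neg_log_partial_likelihood(s, t, rep(0, 12)), "zero events")
})

test_that("the analytic score gradient matches central finite differences", {
  set.seed(11)
  n <- 15
  s <- rnorm(n); t <- round(runif(n, 1, 5)); e <- rbinom(n, 1, 0.8); e[1] <- 1
  g <- oncosurv:::nlpl_gradient(s, t, e)
  eps <- 1e-5
  gnum <- vapply(seq_len(n), function(i) {
    sp <- s; sm <- s
    sp[i] <- sp[i] + eps; sm[i] <- sm[i] - eps
    (neg_log_partial_likelihood(sp, t, e) -
       neg_log_partial_likelihood(sm, t, e)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(g - gnum)) / max(abs(gnum)), 1e-4)
})

test_that("the Breslow baseline matches hand evaluation and scaling identities", {
  bb <- breslow_baseline(c(0, 0, 0), c(1, 2, 3), c(1, 1, 1))
  expect_equal(bb$increment, c(1 / 3, 1 / 2, 1))
  expect_equal(bb$H0, c(1 / 3, 1 / 3 + 1 / 2, 1 / 3 + 1 / 2 + 1))
  expect_true(all(diff(bb$H0) >= 0))
  ## doubling every exp(f) halves every increment
  bb2 <- breslow_baseline(c(0, 0, 0) + log(2), c(1, 2, 3), c(1, 1, 1))
  expect_equal(bb2$increment, bb$increment / 2)
  expect_error(breslow_baseline(c(0, 0), c(1, 2), c(0, 0)), "no events")
})

test_that("cumulative hazard interpolates the baseline right-continuously", {
  fit <- ph_fit()
  nd <- ph_frame()[3, ]
  expect_equal(unname(predict(fit, nd, type = "cumhaz", times = 0)[1, 1]), 0)
  ## exp(f(x)) = 1 recovers H0 exactly: hand-built toy state
  bb <- breslow_baseline(c(0, 0, 0), c(1, 2, 3), c(1, 1, 1))
  expect_equal(oncosurv:::baseline_H0_at(bb, 2.5) * 2, 2 * 0.8333333,
               tolerance = 1e-6)
  ## H(t|x) non-decreasing, survival in [0,1]
  ts <- seq(0, 30, by = 2)
  H <- predict(fit, ph_frame()[1:5, ], type = "cumhaz", times = ts)
  expect_true(all(apply(H, 1, function(r) all(diff(r) >= 0))))
  S <- predict(fit, ph_frame()[1:5, ], type = "survival", times = ts)
  expect_true(all(S >= 0 & S <= 1))
})

test_that("concordance matches brute-force enumeration exactly", {
  ## spec'd 4-subject instance: 5 comparable pairs, 3 concordant
  expect_equal(concordance_index(c(4, 1, 3, 2), c(1, 2, 3, 4), c(1, 1, 0, 1)),
               brute_force_cindex(c(4, 1, 3, 2), c(1, 2, 3, 4), c(1, 1, 0, 1)))
  expect_equal(concordance_index(c(4, 1, 3, 2), c(1, 2, 3, 4), c(1, 1, 0, 1)),
               3 / 5)
  ## perfect anti-ordering and all-ties cases
  expect_equal(concordance_index(4:1, 1:4, rep(1, 4)), 1)
  expect_equal(concordance_index(rep(2, 4), 1:4, rep(1, 4)), 0.5)
  expect_error(concordance_index(1, 5, 0), "comparable")
  ## 200 random small instances, exact equality with the double loop
  set.seed(202)
  for (r in 1:200) {
    n <- sample(3:30, 1)
    pred <- sample(1:6, n, replace = TRUE)        # deliberate prediction ties
    t <- sample(1:10, n, replace = TRUE)          # deliberate time ties
    e <- rbinom(n, 1, 0.7)
    ok <- tryCatch(brute_force_cindex(pred, t, e), error = function(x) NULL)
    if (is.null(ok)) next
    expect_equal(concordance_index(pred, t, e), ok, tolerance = 1e-12)
  }
})

test_that("concordance agrees with survival::concordance on tie-free data", {
  set.seed(5)
  n <- 80
  pred <- rnorm(n); t <- rexp(n); e <- rbinom(n, 1, 0.7); e[1] <- 1
  cf <- survival::concordance(survival::Surv(t, e) ~ pred, reverse = TRUE)
  expect_equal(concordance_index(pred, t, e), as.numeric(cf$concordance),
               tolerance = 1e-12)
})

test_that("a linear risk network recovers the generating coefficients", {
  fit <- ph_fit()
  beta_hat <- coef(fit)
  beta_true <- c(1.0, -0.8, 0.5)
  expect_true(all(abs(beta_hat - beta_true) <= 0.25))
  expect_true(all(sign(beta_hat) == sign(beta_true)))
  ## cross-check against the canonical Cox fit
  cx <- survival::coxph(survival::Surv(time, event) ~ ., ph_frame())
  expect_equal(unname(beta_hat), unname(coef(cx)), tolerance = 0.01)
})

test_that("training is stable: loss decreases and is permutation invariant", {
  d <- ph_frame()[1:120, ]
  fit <- deepsurv(survival::Surv(time, event) ~ ., d, hidden = c(8),
                  epochs = 40, lr = 0.02, seed = 2)
  h <- fit$history
  ma <- stats::filter(h, rep(1 / 3, 3), sides = 1)[3:10]
  expect_true(all(diff(ma) < 0))
  ## permuting patient order leaves the final loss unchanged (full batch)
  perm <- sample(nrow(d))
  fit2 <- deepsurv(survival::Surv(time, event) ~ ., d[perm, ], hidden = c(8),
                   epochs = 40, lr = 0.02, seed = 2)
  expect_lt(abs(tail(fit$history, 1) - tail(fit2$history, 1)), 1e-6)
  ## determinism under identical seed and data
  fit3 <- deepsurv(survival::Surv(time, event) ~ ., d, hidden = c(8),
                   epochs = 40, lr = 0.02, seed = 2)
  expect_identical(fit$params, fit3$params)
})

test_that("model guards reject degenerate inputs", {
  d <- ph_frame()[1:30, ]
  d0 <- d; d0$event <- 0
  expect_error(deepsurv(survival::Surv(time, event) ~ ., d0), "events")
  expect_error(deepsurv(survival::Surv(time, event) ~ ., d[1:10, ]),
               "20 samples")
  expect_error(deepsurv(survival::Surv(time, event) ~ ., d, dropout = 0.9),
               "dropout")
})

test_that("risk stratification reproduces the printed hazard-ratio groups", {
  cp <- risk_cutpoints()  # defaults 1.0 / 1.2
  got <- as.character(stratify_risk(risk_group_examples$hazard_ratio, cp))
  expect_identical(got, risk_group_examples$group)
  ## boundary: exactly low_upper is medium (half-open convention)
  expect_identical(as.character(stratify_risk(1.0, cp)), "medium")
  expect_identical(as.character(stratify_risk(1.2, cp)), "high")
  expect_error(stratify_risk(-1, cp), "positive")
  expect_error(risk_cutpoints(1.5, 1.2), "low_upper")
  ## tertile alternative splits a sample into thirds
  hr <- exp(rnorm(99))
  g <- stratify_risk(hr, risk_cutpoints_tertiles(hr))
  expect_equal(as.numeric(table(g)), c(33, 33, 33))
})

test_that("martingale residuals sum to approximately zero on the training data", {
  fit <- ph_fit()
  r <- residuals(fit)
  expect_lt(abs(mean(r)), 0.02)
  expect_true(all(r <= 1))
})
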