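test_that("tumor mask geometry: zero irregularity gives an exact ellipse and noiseless images lift the tumor", {
  tp0 <- list(center = c(32, 32), radii = c(10, 6), irregularity = 0)
  out <- generate_image_with_mask(64, tp0, noise_sd = 0, seed = 1)
  gx <- matrix(rep(1:64, each = 64), 64)
  gy <- matrix(rep(1:64, times = 64), 64)
  ellipse <- matrix(as.numeric(((gx - 32) / 6)^2 + ((gy - 32) / 10)^2 <= 1), 64)
  expect_identical(out$mask, ellipse)
  ## noiseless image: every in-mask pixel beats the matched background value
  bg <- out$image - 0.30 * out$mask
  expect_true(all(out$image[out$mask == 1] > bg[out$mask == 1]))
  expect_true(all(out$image >= 0 & out$image <= 1))
})

test_that("image generation is deterministic and rejects out-of-bounds tumors", {
  tp <- list(center = c(20, 20), radii = c(8, 5), irregularity = 0.5)
  a <- generate_image_with_mask(48, tp, noise_sd = 0.05, seed = 11)
  b <- generate_image_with_mask(48, tp, noise_sd = 0.05, seed = 11)
  expect_identical(a, b)
  expect_error(
    generate_image_with_mask(32, list(center = c(3, 3), radii = c(8, 8),
                                      irregularity = 0)),
    "out of bounds")
})

test_that("exponential survival times match the closed-form mean and censoring calibrates", {
  sv <- sample_survival(rep(0, 10000), baseline_rate = 0.5,
                        censor_fraction = 0, seed = 4)
  expect_true(all(sv$event == 1))
  se <- 2 / sqrt(10000)  # exponential mean 1/lambda = 2, sd = mean
  expect_lt(abs(mean(sv$time) - 2), 3 * se)
  ## cohort-level calibration on heterogeneous risks
  set.seed(8)
  risks <- stats::rnorm(2000)
  svc <- sample_survival(risks, 0.1, censor_fraction = 0.3, seed = 3)
  expect_gte(mean(1 - svc$event), 0.25)
  expect_lte(mean(1 - svc$event), 0.35)
})

test_that("cohort generation is reproducible and validates its configuration", {
  cfg <- cohort_config(n_patients = 25, image_size = 32, seed = 9)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  expect_error(cohort_config(subtype_probs = c(0.5, 0.5, 0.5)),
               "subtype_probs")
  expect_error(cohort_config(censor_fraction = 0.95), "censor_fraction")
  expect_error(cohort_config(n_genomic = 2, n_mutation_flags = 5),
               "n_mutation_flags")
})

test_that("degenerate subtype probabilities collapse to one class", {
  ch <- generate_cohort(cohort_config(n_patients = 15, image_size = 32,
                                      subtype_probs = c(1, 0, 0), seed = 3))
  expect_true(all(vapply(ch, `[[`, numeric(1), "subtype") == 0))
})

test_that("the generating risk has chance-level concordance without signal and strong concordance with it", {
  ## no signal: beta = 0
  ch0 <- generate_cohort(cohort_config(n_patients = 1000, image_size = 16,
                                       beta_survival = c(0, 0, 0),
                                       censor_fraction = 0, seed = 21))
  tr <- vapply(ch0, `[[`, numeric(1), "true_risk")
  ci0 <- concordance_index(exp(tr + seq_along(tr) * 1e-12),  # break exact ties
                           vapply(ch0, `[[`, numeric(1), "time"),
                           vapply(ch0, `[[`, numeric(1), "event"))
  expect_lt(abs(ci0 - 0.5), 0.03)
  ## documented signal: oracle C-index of the generating linear predictor
  ch <- ph_cohort()
  ci <- concordance_index(exp(vapply(ch, `[[`, numeric(1), "true_risk")),
                          vapply(ch, `[[`, numeric(1), "time"),
                          vapply(ch, `[[`, numeric(1), "event"))
  expect_gte(ci, 0.75)
})

test_that("oracle concordance is non-decreasing in the signal magnitude", {
  cis <- vapply(c(0.25, 1, 4), function(s) {
    ch <- generate_cohort(cohort_config(n_patients = 400, image_size = 16,
                                        beta_survival = s * c(1.0, -0.8, 0.5),
                                        censor_fraction = 0.3, seed = 13))
    concordance_index(exp(vapply(ch, `[[`, numeric(1), "true_risk")),
                      vapply(ch, `[[`, numeric(1), "time"),
                      vapply(ch, `[[`, numeric(1), "event"))
  }, numeric(1))
  expect_true(all(diff(cis) >= 0))
})

test_that("mean intensity inside the mask exceeds outside for moderate noise", {
  ch <- small_cohort()
  ok <- vapply(ch, function(s) {
    mean(s$image[s$mask == 1]) > mean(s$image[s$mask == 0])
  }, logical(1))
  expect_true(all(ok))
})
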