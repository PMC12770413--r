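## Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

## Small desk-scale cohort shared across modules (32 px keeps training fast).
small_cohort <- function() {
  fixture("small_cohort", function()
    generate_cohort(cohort_config(n_patients = 40, image_size = 32,
                                  noise_sd = 0.05, seed = 5)))
}

## Segmenter trained on the small cohort (shallower than the shipped default
## but the same architecture family).
trained_segmenter <- function() {
  fixture("trained_segmenter", function()
    train_segmenter(small_cohort(),
                    segmenter_config(depth = 2, base_channels = 8,
                                     epochs = 12, batch_size = 8, seed = 0)))
}

## Proportional-hazards cohort matching the documented synthetic study
## conditions: n = 600, beta = (1, -0.8, 0.5), 30% censoring, seed 42.
ph_cohort <- function() {
  fixture("ph_cohort", function()
    generate_cohort(cohort_config(n_patients = 600, image_size = 32,
                                  beta_survival = c(1.0, -0.8, 0.5),
                                  baseline_rate = 0.1, censor_fraction = 0.3,
                                  seed = 42)))
}

ph_frame <- function(cohort = ph_cohort()) {
  Z <- do.call(rbind, lapply(cohort, `[[`, "risk_covariates"))
  data.frame(time = vapply(cohort, `[[`, numeric(1), "time"),
             event = vapply(cohort, `[[`, numeric(1), "event"),
             Z, check.names = FALSE)
}

## Linear deep Cox fit on the proportional-hazards cohort.
ph_fit <- function() {
  fixture("ph_fit", function()
    deepsurv(survival::Surv(time, event) ~ ., ph_frame(), hidden = NULL,
             epochs = 400, lr = 0.05, seed = 42))
}

## Independent O(n^2) double-loop concordance oracle (kept deliberately
## naive; the implementation must match it exactly).
brute_force_cindex <- function(pred, times, events) {
  conc <- 0; comp <- 0
  n <- length(pred)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (events[i] == 1 && times[i] < times[j]) {
        comp <- comp + 1
        if (pred[i] > pred[j]) conc <- conc + 1
        else if (pred[i] == pred[j]) conc <- conc + 0.5
      }
    }
  }
  if (comp == 0) stop("no comparable pairs")
  conc / comp
}

## All permutations of 1..n (for the all-orders Shapley oracle).
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

## Independent Shapley oracle: average marginal contribution over every
## one of the n! feature orderings.
all_orders_shapley <- function(model, x, background) {
  n <- length(x)
  bg <- colMeans(as.matrix(background))
  evalx <- function(xi) as.numeric(model(matrix(xi, 1L)))
  phi <- numeric(n)
  perms <- all_perms(n)
  for (perm in perms) {
    xi <- bg
    prev <- evalx(xi)
    for (i in perm) {
      xi[i] <- x[i]
      cur <- evalx(xi)
      phi[i] <- phi[i] + (cur - prev)
      prev <- cur
    }
  }
  phi / length(perms)
}

## Reference worked-example values (frozen published arithmetic the
## implementation must reproduce exactly).
fusion_examples <- list(
  P001 = list(img = c(0.56, 0.44, 0.78), gen = c(0.61, 0.75, 0.69),
              fused = c(1.17, 1.19, 1.47)),
  P002 = list(img = c(0.63, 0.52, 0.74), gen = c(0.58, 0.68, 0.71),
              fused = c(1.21, 1.20, 1.45)),
  P003 = list(img = c(0.68, 0.55, 0.81), gen = c(0.66, 0.79, 0.73),
              fused = c(1.34, 1.34, 1.54)),
  P004 = list(img = c(0.52, 0.47, 0.69), gen = c(0.57, 0.71, 0.64),
              fused = c(1.09, 1.18, 1.33)),
  P005 = list(img = c(0.75, 0.61, 0.88), gen = c(0.72, 0.81, 0.77),
              fused = c(1.47, 1.42, 1.65)))

risk_group_examples <- data.frame(
  hazard_ratio = c(1.43, 1.08, 1.55, 0.92, 1.67),
  group = c("high", "medium", "high", "low", "high"))

shap_examples <- list(
  P001 = list(phi = c(0.35, 0.28, 0.17), overall = 0.80),
  P002 = list(phi = c(0.31, 0.26, 0.18), overall = 0.75),
  P003 = list(phi = c(0.37, 0.31, 0.21), overall = 0.89),
  P004 = list(phi = c(0.28, 0.22, 0.15), overall = 0.65),
  P005 = list(phi = c(0.42, 0.33, 0.20), overall = 0.95))
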