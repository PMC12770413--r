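#' Configuration for a synthetic multimodal cohort
#'
#' Bundles every free parameter of the cohort simulator. The simulator
#' emulates the structure of a multimodal lung-tumor study: grayscale images
#' with ground-truth tumor masks, genomic vectors mixing binary mutation
#' flags (EGFR/KRAS/TP53-like profiles that depend on subtype) with
#' continuous expression values, clinical covariates, three histological
#' subtypes, and right-censored survival times drawn from a
#' proportional-hazards model with a known linear predictor.
#'
#' @param n_patients number of patients.
#' @param image_size pixels per side of the square images.
#' @param subtype_probs probabilities of the three subtypes
#'   (adenocarcinoma-like, squamous-like, large-cell-like); must sum to 1.
#' @param n_genomic total genomic features per patient.
#' @param n_mutation_flags how many of the genomic features are binary
#'   mutation flags (the rest are continuous expression values).
#' @param beta_survival true log-hazard coefficients of the generating
#'   proportional-hazards model (unitless).
#' @param baseline_rate exponential baseline hazard rate (events per time
#'   unit).
#' @param censor_fraction target fraction of censored patients, in
#'   \[0, 0.9\].
#' @param noise_sd standard deviation of additive Gaussian image noise.
#' @param risk_covariates `"gaussian"` (default) draws
#'   `length(beta_survival)` independent standard-normal covariates per
#'   patient; `"multimodal"` uses standardized age, a comorbidity flag,
#'   standardized tumor area from the mask, and the first mutation flag
#'   (then `beta_survival` must have length 4).
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 300L, image_size = 64L,
                          subtype_probs = c(0.45, 0.35, 0.20),
                          n_genomic = 8L, n_mutation_flags = 3L,
                          beta_survival = c(1.0, -0.8, 0.5),
                          baseline_rate = 0.1, censor_fraction = 0.3,
                          noise_sd = 0.05,
                          risk_covariates = c("gaussian", "multimodal"),
                          seed = 1L) {
  risk_covariates <- match.arg(risk_covariates)
  cfg <- list(n_patients = as.integer(n_patients),
              image_size = as.integer(image_size),
              subtype_probs = as.numeric(subtype_probs),
              n_genomic = as.integer(n_genomic),
              n_mutation_flags = as.integer(n_mutation_flags),
              beta_survival = as.numeric(beta_survival),
              baseline_rate = baseline_rate,
              censor_fraction = censor_fraction,
              noise_sd = noise_sd, risk_covariates = risk_covariates,
              seed = as.integer(seed))
  validate_fields(list(
    n_patients = cfg$n_patients > 0L,
    image_size = cfg$image_size >= 16L,
    subtype_probs = length(cfg$subtype_probs) == 3L &&
      all(cfg$subtype_probs >= 0) &&
      abs(sum(cfg$subtype_probs) - 1) < 1e-9,
    n_genomic = cfg$n_genomic > 0L,
    n_mutation_flags = cfg$n_mutation_flags > 0L &&
      cfg$n_mutation_flags <= cfg$n_genomic,
    beta_survival = length(cfg$beta_survival) >= 1L &&
      all(is.finite(cfg$beta_survival)),
    baseline_rate = is.numeric(cfg$baseline_rate) && cfg$baseline_rate > 0,
    censor_fraction = cfg$censor_fraction >= 0 && cfg$censor_fraction <= 0.9,
    noise_sd = cfg$noise_sd >= 0,
    risk_covariates = cfg$risk_covariates != "multimodal" ||
      length(cfg$beta_survival) == 4L))
  class(cfg) <- "cohort_config"
  cfg
}

#' Generate a tumor image with its ground-truth mask
#'
#' The mask is the noiseless support of a perturbed ellipse: at polar angle
#' \eqn{\phi} the boundary radius of the underlying unit ellipse is modulated
#' by a low-order random harmonic scaled by `irregularity`. The image is a
#' smooth background plus a constant intensity lift inside the mask plus
#' Gaussian noise, clipped to \[0, 1\].
#'
#' @param size image side length in pixels.
#' @param tumor_params list with `center` (length-2, pixels), `radii`
#'   (length-2 semi-axes, pixels) and `irregularity` in \[0, 1\].
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return list with `image` and `mask`, both `size` x `size` matrices;
#'   image values in \[0, 1\], mask values in \{0, 1\}.
#' @export
generate_image_with_mask <- function(size, tumor_params, noise_sd = 0.05,
                                     seed = 1L) {
  ctr <- tumor_params$center
  radii <- tumor_params$radii
  irr <- tumor_params$irregularity %||% 0
  if (irr < 0 || irr > 1) stop("irregularity must lie in [0, 1]")
  reach <- max(radii) * (1 + 0.5 * irr)
  if (any(ctr - reach < 1) || any(ctr + reach > size))
    stop("tumor out of bounds: center ", paste(round(ctr, 1), collapse = ","),
         " with effective radius ", round(reach, 1),
         " does not fit inside a ", size, "x", size, " image")
  with_seed(seed, {
    ## boundary modulation: low-order harmonics, amplitude capped at 0.5
    k <- 2:4
    ck <- stats::rnorm(length(k), 0, 1 / k)
    ph <- stats::runif(length(k), 0, 2 * pi)
    harm <- function(phi) {
      h <- rowSums(vapply(seq_along(k),
                          function(j) ck[j] * cos(k[j] * phi + ph[j]),
                          numeric(length(phi))))
      0.5 * h / max(1, max(abs(h)))
    }
    gx <- matrix(rep(seq_len(size), each = size), size)   # column (x) index
    gy <- matrix(rep(seq_len(size), times = size), size)  # row (y) index
    dx <- (gx - ctr[2]) / radii[2]
    dy <- (gy - ctr[1]) / radii[1]
    phi <- atan2(dy, dx)
    r <- sqrt(dx^2 + dy^2)
    bnd <- 1 + irr * harm(as.vector(phi))
    mask <- matrix(as.numeric(r <= matrix(bnd, size)), size)
    ## smooth background: gentle ramps + one large-scale wave, kept <= 0.55
    bgx <- (gx - 1) / (size - 1); bgy <- (gy - 1) / (size - 1)
    background <- 0.22 + 0.10 * bgx + 0.08 * bgy +
      0.05 * sin(2 * pi * bgx) * cos(2 * pi * bgy)
    image <- background + 0.30 * mask +
      matrix(stats::rnorm(size * size, 0, noise_sd), size)
    image <- pmin(pmax(image, 0), 1)
    list(image = image, mask = mask)
  })
}

#' Sample right-censored survival times from a proportional-hazards model
#'
#' Event times are exponential with rate `baseline_rate * exp(true_risk)`.
#' Censoring is independent exponential; its single rate is calibrated
#' (numerically, over the supplied risk distribution) so that the expected
#' censored fraction equals `censor_fraction`, keeping censoring
#' non-informative.
#'
#' @param true_risk numeric vector of linear predictors (log hazard ratios).
#' @param baseline_rate exponential baseline hazard rate (> 0).
#' @param censor_fraction target censored fraction in \[0, 1).
#' @param seed integer seed.
#' @return list with numeric vectors `time` (> 0) and `event` (1 = observed,
#'   0 = censored).
#' @export
sample_survival <- function(true_risk, baseline_rate, censor_fraction = 0,
                            seed = 1L) {
  if (baseline_rate <= 0) stop("baseline_rate must be > 0")
  if (censor_fraction < 0 || censor_fraction >= 1)
    stop("censor_fraction must lie in [0, 1)")
  lam <- baseline_rate * exp(true_risk)
  with_seed(seed, {
    t_event <- stats::rexp(length(lam), rate = lam)
    if (censor_fraction == 0)
      return(list(time = t_event, event = rep(1, length(lam))))
    ## P(C < T_i) = rc / (rc + lambda_i); solve mean over cohort = target
    cens_prob <- function(rc) mean(rc / (rc + lam)) - censor_fraction
    hi <- max(lam) * censor_fraction / (1 - censor_fraction) + 1e-12
    rc <- stats::uniroot(cens_prob, lower = 1e-12, upper = hi + 1,
                         extendInt = "upX", tol = 1e-12)$root
    t_cens <- stats::rexp(length(lam), rate = rc)
    list(time = pmin(t_event, t_cens),
         event = as.numeric(t_event <= t_cens))
  })
}

## Subtype-specific shape and genomic conventions (documented mapping):
##   subtype 0 adenocarcinoma-like : round, low irregularity, EGFR-like flag
##   subtype 1 squamous-like       : elongated, medium irregularity, KRAS-like
##   subtype 2 large-cell-like     : small, high irregularity, TP53-like
subtype_shape_params <- function(subtype, size) {
  s <- size
  switch(as.character(subtype),
    "0" = list(radii = stats::runif(1, 0.16, 0.21) * s * c(1, stats::runif(1, 0.9, 1.1)),
               irregularity = stats::runif(1, 0.05, 0.25)),
    "1" = list(radii = c(stats::runif(1, 0.22, 0.27), stats::runif(1, 0.09, 0.13)) * s,
               irregularity = stats::runif(1, 0.20, 0.35)),
    "2" = list(radii = stats::runif(1, 0.08, 0.12) * s * c(1, stats::runif(1, 0.85, 1.15)),
               irregularity = stats::runif(1, 0.55, 0.80)))
}

## Mutation-flag probabilities per subtype for the first three flags
## (EGFR-like, KRAS-like, TP53-like); further flags are background-rate 0.2.
mutation_flag_probs <- function(subtype, n_flags) {
  profile <- rbind(c(0.70, 0.15, 0.30),
                   c(0.15, 0.65, 0.35),
                   c(0.20, 0.20, 0.80))
  p <- rep(0.2, n_flags)
  k <- min(3L, n_flags)
  p[seq_len(k)] <- profile[subtype + 1L, seq_len(k)]
  p
}

#' Generate a seeded synthetic multimodal cohort
#'
#' Draws each patient's subtype, then a subtype-dependent tumor shape and
#' mutation profile, a smooth image with ground-truth mask, clinical
#' covariates (age in years, one comorbidity flag), a genomic vector, and a
#' right-censored survival time whose true linear predictor
#' (`true_risk = beta_survival . z`) is retained as simulator-only ground
#' truth.
#'
#' @param config a [cohort_config()].
#' @return an object of class `oncosurv_cohort`: a list of patient records,
#'   each with `patient_id`, `image`, `mask`, `genomic`, `clinical`
#'   (age, comorbidity), `risk_covariates`, `subtype` (0/1/2), `time`,
#'   `event` and `true_risk`. The config is attached as an attribute.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  n <- config$n_patients
  with_seed(config$seed, {
    subtype <- sample(0:2, n, replace = TRUE, prob = config$subtype_probs)
    age <- stats::rnorm(n, 65, 10)
    comorbidity <- stats::rbinom(n, 1, 0.4)
    image_seeds <- sample.int(2^31 - 2, n)
    expr_shift <- rbind(c(0.8, -0.5, 0.0),
                        c(-0.6, 0.7, 0.3),
                        c(0.0, 0.2, -0.9))
    samples <- vector("list", n)
    for (i in seq_len(n)) {
      shp <- subtype_shape_params(subtype[i], config$image_size)
      reach <- max(shp$radii) * 1.5 + 2
      ctr <- stats::runif(2, reach, config$image_size - reach + 1)
      im <- generate_image_with_mask(
        config$image_size,
        list(center = ctr, radii = shp$radii, irregularity = shp$irregularity),
        noise_sd = config$noise_sd, seed = image_seeds[i])
      pflag <- mutation_flag_probs(subtype[i], config$n_mutation_flags)
      flags <- stats::rbinom(config$n_mutation_flags, 1, pflag)
      n_expr <- config$n_genomic - config$n_mutation_flags
      expr <- if (n_expr > 0) {
        mu <- rep(0, n_expr)
        k <- min(3L, n_expr)
        mu[seq_len(k)] <- expr_shift[subtype[i] + 1L, seq_len(k)]
        stats::rnorm(n_expr, mu, 1)
      } else numeric(0)
      samples[[i]] <- list(
        patient_id = sprintf("P%04d", i),
        image = im$image, mask = im$mask,
        genomic = c(flags, expr),
        clinical = list(age = age[i], comorbidity = comorbidity[i]),
        subtype = subtype[i])
    }
    ## ground-truth linear predictor
    if (config$risk_covariates == "gaussian") {
      k <- length(config$beta_survival)
      Z <- matrix(stats::rnorm(n * k), n, k,
                  dimnames = list(NULL, paste0("x", seq_len(k))))
    } else {
      area <- vapply(samples, function(s) sum(s$mask), numeric(1))
      Z <- cbind(age = as.numeric(scale(age)),
                 comorbidity = comorbidity,
                 tumor_area = as.numeric(scale(area)),
                 mutation1 = vapply(samples, function(s) s$genomic[1], numeric(1)))
    }
    true_risk <- as.numeric(Z %*% config$beta_survival)
    surv_seed <- sample.int(2^31 - 2, 1)
    sv <- sample_survival(true_risk, config$baseline_rate,
                          config$censor_fraction, seed = surv_seed)
    for (i in seq_len(n)) {
      samples[[i]]$risk_covariates <- Z[i, ]
      samples[[i]]$true_risk <- true_risk[i]
      samples[[i]]$time <- sv$time[i]
      samples[[i]]$event <- sv$event[i]
    }
    structure(samples, class = "oncosurv_cohort", config = config)
  })
}

#' @export
print.oncosurv_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("Synthetic multimodal cohort:", length(x), "patients,",
      cfg$image_size, "x", cfg$image_size, "images\n")
  cat("  subtypes:", paste(table(factor(vapply(x, `[[`, numeric(1), "subtype"),
                                        levels = 0:2)), collapse = "/"),
      " censored:", round(mean(1 - vapply(x, `[[`, numeric(1), "event")), 3), "\n")
  invisible(x)
}

#' Cohort accessors
#'
#' Column-wise views of an `oncosurv_cohort`: `cohort_field()` extracts one
#' numeric per-patient field (`"time"`, `"event"`, `"true_risk"`, ...),
#' `cohort_risk_matrix()` stacks the latent risk covariates,
#' `cohort_genomic_matrix()` the genomic vectors, and `cohort_subtypes()`
#' returns the 0/1/2 subtype labels.
#'
#' @param cohort an `oncosurv_cohort`.
#' @param field name of a numeric per-patient field.
#' @return vector or matrix with one row/entry per patient.
#' @export
cohort_field <- function(cohort, field) {
  vapply(cohort, `[[`, numeric(1), field)
}

#' @rdname cohort_field
#' @export
cohort_risk_matrix <- function(cohort) {
  do.call(rbind, lapply(cohort, `[[`, "risk_covariates"))
}

#' @rdname cohort_field
#' @export
cohort_genomic_matrix <- function(cohort) {
  do.call(rbind, lapply(cohort, `[[`, "genomic"))
}

#' @rdname cohort_field
#' @export
cohort_subtypes <- function(cohort) {
  vapply(cohort, `[[`, numeric(1), "subtype")
}
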