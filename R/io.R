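## Cohort I/O, splitting and cross-validation: the evaluation harness.

cohort_subset <- function(cohort, idx) {
  structure(unclass(cohort)[idx], class = "oncosurv_cohort",
            config = attr(cohort, "config"))
}

#' Write a cohort to its on-disk layout
#'
#' Layout: `images/{id}.png` (8-bit grayscale), `masks/{id}.png` (0/255),
#' `genomic.csv` (`patient_id`, `g1..gK`), `clinical.csv` (`patient_id`,
#' `age`, `comorbidity`, plus any latent risk covariates `x1..xk`),
#' `outcomes.csv` (`patient_id`, `subtype`, `time`, `event`) and, for
#' simulated cohorts, `truth.csv` (`patient_id`, `true_risk`).
#'
#' @param cohort an `oncosurv_cohort`.
#' @param path output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  dir.create(file.path(path, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "masks"), recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(cohort, `[[`, character(1), "patient_id")
  if (anyDuplicated(ids)) stop("duplicate patient ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ","))
  for (s in cohort) {
    png::writePNG(s$image, file.path(path, "images", paste0(s$patient_id, ".png")))
    png::writePNG(s$mask, file.path(path, "masks", paste0(s$patient_id, ".png")))
  }
  gm <- cohort_genomic_matrix(cohort)
  colnames(gm) <- paste0("g", seq_len(ncol(gm)))
  utils::write.csv(data.frame(patient_id = ids, gm, check.names = FALSE),
                   file.path(path, "genomic.csv"), row.names = FALSE)
  rc <- cohort_risk_matrix(cohort)
  clin <- data.frame(patient_id = ids,
                     age = vapply(cohort, function(s) s$clinical$age, numeric(1)),
                     comorbidity = vapply(cohort, function(s) s$clinical$comorbidity,
                                          numeric(1)))
  if (!is.null(rc)) clin <- cbind(clin, as.data.frame(rc))
  utils::write.csv(clin, file.path(path, "clinical.csv"), row.names = FALSE)
  utils::write.csv(data.frame(patient_id = ids,
                              subtype = cohort_subtypes(cohort),
                              time = cohort_field(cohort, "time"),
                              event = cohort_field(cohort, "event")),
                   file.path(path, "outcomes.csv"), row.names = FALSE)
  tr <- try(cohort_field(cohort, "true_risk"), silent = TRUE)
  if (!inherits(tr, "try-error"))
    utils::write.csv(data.frame(patient_id = ids, true_risk = tr),
                     file.path(path, "truth.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a cohort from its on-disk layout
#'
#' Validates that every patient appears in every table; masks stored as
#' 0/255 PNG are read back as \{0, 1\}. Round-trips [write_cohort()] output
#' up to 8-bit image quantization.
#'
#' @param path cohort directory.
#' @return an `oncosurv_cohort`.
#' @export
read_cohort <- function(path) {
  req <- c("genomic.csv", "clinical.csv", "outcomes.csv")
  for (f in req) if (!file.exists(file.path(path, f)))
    stop("missing cohort table: ", f)
  genomic <- utils::read.csv(file.path(path, "genomic.csv"))
  clinical <- utils::read.csv(file.path(path, "clinical.csv"))
  outcomes <- utils::read.csv(file.path(path, "outcomes.csv"))
  for (tb in list(genomic, clinical, outcomes))
    if (!"patient_id" %in% names(tb)) stop("malformed CSV header: missing patient_id")
  truth <- if (file.exists(file.path(path, "truth.csv")))
    utils::read.csv(file.path(path, "truth.csv"))
  ids <- sort(unique(c(genomic$patient_id, clinical$patient_id,
                       outcomes$patient_id)))
  for (nm in c("genomic", "clinical", "outcomes")) {
    tb <- get(nm)
    if (anyDuplicated(tb$patient_id))
      stop("duplicate patient ids in ", nm, ".csv")
    miss <- setdiff(ids, tb$patient_id)
    if (length(miss))
      stop("patient ", paste(miss, collapse = ","), " missing from ", nm, ".csv")
  }
  imgdir <- file.path(path, "images"); mskdir <- file.path(path, "masks")
  xcols <- setdiff(names(clinical), c("patient_id", "age", "comorbidity"))
  samples <- lapply(ids, function(id) {
    ipath <- file.path(imgdir, paste0(id, ".png"))
    mpath <- file.path(mskdir, paste0(id, ".png"))
    if (!file.exists(ipath)) stop("patient ", id, " missing image file")
    if (!file.exists(mpath)) stop("patient ", id, " missing mask file")
    image <- png::readPNG(ipath)
    mask <- round(png::readPNG(mpath))
    if (!identical(dim(image), dim(mask)))
      stop("image/mask shape mismatch for patient ", id)
    ge <- genomic[genomic$patient_id == id, -1, drop = FALSE]
    cl <- clinical[clinical$patient_id == id, , drop = FALSE]
    oc <- outcomes[outcomes$patient_id == id, , drop = FALSE]
    s <- list(patient_id = id, image = image, mask = mask,
              genomic = as.numeric(ge),
              clinical = list(age = cl$age, comorbidity = cl$comorbidity),
              subtype = oc$subtype, time = oc$time, event = oc$event)
    if (length(xcols))
      s$risk_covariates <- stats::setNames(as.numeric(cl[, xcols]), xcols)
    if (!is.null(truth))
      s$true_risk <- truth$true_risk[truth$patient_id == id]
    s
  })
  structure(samples, class = "oncosurv_cohort")
}

#' Stratified train/validation/test split
#'
#' Splits the cohort into disjoint, exhaustive parts whose per-class
#' proportions match the requested fractions within one sample per class
#' (largest-remainder allocation within each stratum).
#'
#' @param cohort an `oncosurv_cohort`.
#' @param fractions length-3 non-negative vector (train, val, test) summing
#'   to 1.
#' @param seed integer seed.
#' @param strata stratification labels (default: subtype).
#' @return list with `train`, `val` and `test` cohorts.
#' @export
stratified_split <- function(cohort, fractions = c(0.70, 0.15, 0.15),
                             seed = 0L, strata = NULL) {
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be three non-negative numbers summing to 1")
  strata <- strata %||% cohort_subtypes(cohort)
  assign_part <- integer(length(cohort))
  with_seed(seed, {
    for (g in unique(strata)) {
      idx <- which(strata == g)
      pos <- fractions > 0
      if (length(idx) < sum(pos))
        stop("stratum ", g, " too small (", length(idx), " members) for the split")
      idx <- sample(idx)
      exact <- fractions * length(idx)
      base <- floor(exact)
      rem <- length(idx) - sum(base)
      if (rem > 0) {
        extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1L
      }
      parts <- rep(1:3, times = base)
      assign_part[idx] <- parts
    }
  })
  list(train = cohort_subset(cohort, assign_part == 1L),
       val = cohort_subset(cohort, assign_part == 2L),
       test = cohort_subset(cohort, assign_part == 3L))
}

#' Stratified k-fold cross-validation
#'
#' Every sample is validated exactly once; folds are stratified on subtype.
#' The `stage` decides what is fit per fold: `"classify"` trains the
#' multimodal subtype classifier, `"survival"` fits the deep Cox model on
#' the latent risk covariates.
#'
#' @param cohort an `oncosurv_cohort`.
#' @param k number of folds (>= 2).
#' @param stage `"classify"` or `"survival"`.
#' @param config stage configuration ([fusion_config()] or a list of
#'   [deepsurv()] arguments).
#' @param seed integer seed.
#' @param ... further stage arguments (e.g. `epochs` for the classifier).
#' @return list with `folds` (per-fold metric rows), `mean` and `sd`.
#' @export
cross_validate <- function(cohort, k = 5L, stage = c("classify", "survival"),
                           config = NULL, seed = 0L, ...) {
  stage <- match.arg(stage)
  if (k < 2L) stop("k must be >= 2")
  strata <- cohort_subtypes(cohort)
  if (k > min(table(strata)))
    stop("k exceeds the smallest class count (", min(table(strata)), ")")
  fold_id <- integer(length(cohort))
  with_seed(derive_seed(seed, "cv"), {
    for (g in unique(strata)) {
      idx <- sample(which(strata == g))
      fold_id[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  rows <- lapply(seq_len(k), function(f) {
    tr <- cohort_subset(cohort, fold_id != f)
    va <- cohort_subset(cohort, fold_id == f)
    if (stage == "classify") {
      clf <- train_classifier(tr, config %||% fusion_config(),
                              val_fraction = 0.15,
                              seed = derive_seed(seed + f, "fuse"), ...)
      probs <- t(vapply(va, function(s) feature_bundle(s, clf)$subtype_probs,
                        numeric(3)))
      pred <- max.col(probs) - 1L
      c(accuracy = mean(pred == cohort_subtypes(va)))
    } else {
      args <- c(list(data = surv_frame(tr),
                     seed = derive_seed(seed + f, "survival")),
                config %||% list())
      fit <- do.call(deepsurv, args)
      lp <- predict(fit, newdata = surv_frame(va), type = "lp")
      c(cindex = concordance_index(exp(lp), cohort_field(va, "time"),
                                   cohort_field(va, "event")))
    }
  })
  m <- do.call(rbind, rows)
  list(folds = m, mean = colMeans(m), sd = apply(m, 2L, stats::sd))
}

## Data frame of survival response + latent risk covariates for deepsurv().
surv_frame <- function(cohort) {
  Z <- cohort_risk_matrix(cohort)
  data.frame(time = cohort_field(cohort, "time"),
             event = cohort_field(cohort, "event"), Z, check.names = FALSE)
}
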