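## The umbrella evaluation harness: run configuration, stage chaining,
## metrics report.

#' Pipeline run configuration
#'
#' Bundles the per-stage configurations, the train/validation/test split,
#' the cross-validation fold count and the single global seed from which
#' every stage seed is derived (see [derive_seed()]).
#'
#' @param simulate named list of [cohort_config()] arguments.
#' @param segment named list of [segmenter_config()] arguments, plus
#'   `n_train`/`n_eval` caps for the segmentation stage.
#' @param fuse named list of [fusion_config()] arguments, plus `epochs`.
#' @param survival named list of [deepsurv()] arguments.
#' @param split train/val/test fractions, positive, summing to 1.
#' @param cv_folds cross-validation folds (>= 2).
#' @param seed global seed.
#' @param out_dir output directory for reports and logs (`NULL`: nothing
#'   written).
#' @param log_level `"info"` or `"quiet"`.
#' @return an object of class `run_config`.
#' @export
run_config <- function(simulate = list(), segment = list(), fuse = list(),
                       survival = list(), split = c(0.70, 0.15, 0.15),
                       cv_folds = 5L, seed = 0L, out_dir = NULL,
                       log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  cfg <- list(simulate = simulate, segment = segment, fuse = fuse,
              survival = survival, split = as.numeric(split),
              cv_folds = as.integer(cv_folds), seed = as.integer(seed),
              out_dir = out_dir, log_level = log_level)
  validate_fields(list(
    split = length(cfg$split) == 3L && all(cfg$split > 0) &&
      abs(sum(cfg$split) - 1) < 1e-9,
    cv_folds = cfg$cv_folds >= 2L))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose top-level keys are [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

tab2mat <- function(t) {
  matrix(as.numeric(t), nrow(t), ncol(t), dimnames = dimnames(t))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

## Modality-derived survival feature frames mirroring the covariate-set
## combinations: clinical only / + imaging / + genomic / all.
survival_feature_sets <- function(cohort) {
  age <- vapply(cohort, function(s) s$clinical$age, numeric(1))
  com <- vapply(cohort, function(s) s$clinical$comorbidity, numeric(1))
  area <- vapply(cohort, function(s) sum(s$mask), numeric(1))
  inten <- vapply(cohort, function(s) {
    m <- s$mask == 1
    if (any(m)) mean(s$image[m]) else 0
  }, numeric(1))
  G <- cohort_genomic_matrix(cohort)
  nm <- min(3L, ncol(G))
  base <- data.frame(time = cohort_field(cohort, "time"),
                     event = cohort_field(cohort, "event"))
  clinical <- data.frame(age = age, comorbidity = com)
  imaging <- data.frame(tumor_area = area, tumor_intensity = inten)
  genomic <- as.data.frame(G[, seq_len(nm), drop = FALSE])
  list(clinical = cbind(base, clinical),
       imaging_clinical = cbind(base, clinical, imaging),
       genomic_clinical = cbind(base, clinical, genomic),
       all = cbind(base, clinical, imaging, genomic))
}

#' Run the full multimodal pipeline
#'
#' Chains simulate, segmenter training + evaluation, classifier training +
#' evaluation, survival fits over the covariate-set combinations (clinical
#' only, + imaging, + genomic, all), risk stratification against simulator
#' truth, and Shapley attribution for one test patient; writes a metrics
#' report (JSON) and a log when `out_dir` is set.
#'
#' @param config a [run_config()].
#' @return an object of class `oncosurv_metrics` (also serialized to
#'   `metrics.json` under `out_dir`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  t_start <- Sys.time()
  log_lines <- character(0)
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    log_lines <<- c(log_lines, line)
    if (config$log_level == "info") message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }
  ## simulate ---------------------------------------------------------------
  cohort <- stage("simulate", {
    sim_args <- utils::modifyList(
      list(risk_covariates = "multimodal",
           beta_survival = c(0.5, 0.4, 0.7, 0.6)),
      config$simulate)
    sim_args$seed <- sim_args$seed %||% derive_seed(config$seed, "simulate")
    ccfg <- do.call(cohort_config, sim_args)
    logmsg("simulate: n=", ccfg$n_patients, " image ", ccfg$image_size, "px")
    generate_cohort(ccfg)
  })
  sp <- stratified_split(cohort, config$split,
                         seed = derive_seed(config$seed, "split"))
  trainval <- structure(c(unclass(sp$train), unclass(sp$val)),
                        class = "oncosurv_cohort",
                        config = attr(cohort, "config"))
  ## segment ----------------------------------------------------------------
  seg_metrics <- stage("segment", {
    sargs <- config$segment
    n_train <- sargs$n_train %||% 40L
    n_eval <- sargs$n_eval %||% 20L
    sargs$n_train <- NULL; sargs$n_eval <- NULL
    sargs$seed <- sargs$seed %||% derive_seed(config$seed, "segment")
    scfg <- do.call(segmenter_config, sargs)
    seg <- train_segmenter(cohort_subset(sp$train,
                                         seq_len(min(n_train, length(sp$train)))),
                           scfg)
    eval_idx <- seq_len(min(n_eval, length(sp$test)))
    outs <- lapply(sp$test[eval_idx], function(s)
      refine_segment(seg, s$image, ref_mask = s$mask))
    dice <- vapply(seq_along(outs), function(i)
      dice_coefficient(outs[[i]]$final_mask, sp$test[[eval_idx[i]]]$mask),
      numeric(1))
    iters <- vapply(outs, `[[`, numeric(1), "iterations_run")
    logmsg("segment: mean test Dice ", round(mean(dice), 3))
    list(mean_dice = mean(dice), mean_iterations = mean(iters),
         n_eval = length(dice))
  })
  ## fuse / classify --------------------------------------------------------
  clf_metrics <- stage("fuse", {
    fargs <- config$fuse
    epochs <- fargs$epochs %||% 25L
    fargs$epochs <- NULL
    fargs$seed <- fargs$seed %||% derive_seed(config$seed, "fuse")
    fcfg <- do.call(fusion_config, fargs)
    clf <- train_classifier(trainval, fcfg, epochs = epochs,
                            seed = fcfg$seed)
    probs <- t(vapply(sp$test, function(s)
      feature_bundle(s, clf)$subtype_probs, numeric(3)))
    y <- cohort_subtypes(sp$test)
    pred <- max.col(probs) - 1L
    auc <- vapply(0:2, function(k) {
      resp <- factor(y == k, levels = c(FALSE, TRUE))
      if (length(unique(resp)) < 2L) return(NA_real_)
      as.numeric(pROC::auc(pROC::roc(resp, probs[, k + 1L], quiet = TRUE,
                                     direction = "<",
                                     levels = c(FALSE, TRUE))))
    }, numeric(1))
    logmsg("classify: test accuracy ", round(mean(pred == y), 3))
    list(accuracy = mean(pred == y), auc_per_class = auc,
         confusion = tab2mat(table(truth = factor(y, levels = 0:2),
                                   predicted = factor(pred, levels = 0:2))))
  })
  ## survival ---------------------------------------------------------------
  surv_metrics <- stage("survival", {
    fs_train <- survival_feature_sets(trainval)
    fs_test <- survival_feature_sets(sp$test)
    sargs <- config$survival
    sargs$seed <- sargs$seed %||% derive_seed(config$seed, "survival")
    cidx <- lapply(names(fs_train), function(nm) {
      fit <- do.call(deepsurv, c(list(data = fs_train[[nm]]), sargs))
      hr <- predict(fit, fs_test[[nm]], type = "risk")
      list(fit = fit, hr = hr,
           cindex = concordance_index(hr, fs_test[[nm]]$time,
                                      fs_test[[nm]]$event))
    })
    names(cidx) <- names(fs_train)
    ## risk stratification vs simulator truth (tertile cutpoints each)
    hr_all <- cidx$all$hr
    truth_hr <- exp(cohort_field(sp$test, "true_risk"))
    grp_pred <- stratify_risk(hr_all, risk_cutpoints_tertiles(hr_all))
    grp_true <- stratify_risk(truth_hr, risk_cutpoints_tertiles(truth_hr))
    logmsg("survival: test C-index (all) ", round(cidx$all$cindex, 3))
    list(cindex = lapply(cidx, `[[`, "cindex"),
         risk_confusion = tab2mat(table(truth = grp_true,
                                        predicted = grp_pred)),
         fit_all = cidx$all$fit, test_features = fs_test$all)
  })
  ## explain ----------------------------------------------------------------
  shap_metrics <- stage("explain", {
    fit <- surv_metrics$fit_all
    feats <- surv_metrics$test_features
    x <- unlist(feats[1L, !(names(feats) %in% c("time", "event"))])
    bg <- as.matrix(feats[, !(names(feats) %in% c("time", "event")),
                          drop = FALSE])
    rep_ <- exact_shapley(shapley_model_deepsurv(fit), x, bg)
    logmsg("explain: overall score ", round(rep_$overall_score, 3))
    list(patient_id = sp$test[[1L]]$patient_id,
         phi = as.list(rep_$phi), overall_score = rep_$overall_score)
  })
  surv_metrics$fit_all <- NULL
  surv_metrics$test_features <- NULL
  report <- structure(list(
    segmentation = seg_metrics, classification = clf_metrics,
    survival = surv_metrics, explanation = shap_metrics,
    config_hash = config_hash(config),
    seed = config$seed,
    started = format(t_start, "%Y-%m-%d %H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    class = "oncosurv_metrics")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(config$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(config$out_dir, "pipeline.log"))
  }
  report
}

#' @export
print.oncosurv_metrics <- function(x, ...) {
  cat("Pipeline metrics (config ", substr(x$config_hash, 1, 8), ")\n", sep = "")
  cat("  mean Dice:", round(x$segmentation$mean_dice, 3),
      " subtype accuracy:", round(x$classification$accuracy, 3), "\n")
  cat("  C-index:", paste(names(x$survival$cindex),
                          round(unlist(x$survival$cindex), 3),
                          sep = "=", collapse = "  "), "\n")
  invisible(x)
}
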