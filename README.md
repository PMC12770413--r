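# oncosurv

Desk-scale, fully seeded R implementation of an integrated multimodal
analysis pipeline for lung tumors: iterative tumor segmentation, fusion of
imaging and genomic features for subtype classification, deep Cox
proportional-hazards survival modelling with risk stratification, continual
model updates without catastrophic forgetting, Gaussian-process
hyperparameter optimization, and exact Shapley-value attribution. Every
neural component is written in base R, trains in seconds to minutes on one
CPU, and is deterministic given a seed.

The package is aimed at methodologists who want to study, test and extend
this class of multimodal pipeline on synthetic cohorts with known ground
truth — not at clinical use. A built-in simulator generates cohorts with the
statistical structure the pipeline assumes: grayscale images with
ground-truth tumor masks, genomic vectors mixing binary mutation flags
(EGFR/KRAS/TP53-like, subtype-dependent) with continuous expression values,
clinical covariates, three histological subtypes (adenocarcinoma-,
squamous- and large-cell-like), and right-censored survival times drawn
from a proportional-hazards model.

## The models

**Segmentation.** An encoder–decoder convolutional network with skip
connections produces a soft tumor mask, trained with the combined loss

    L(S, y) = CE(S, y) + α (1 − Dice(S, y)),
    Dice(S, y) = 2 Σ S·y / (Σ S + Σ y)

wrapped in an iterative refinement loop: iteration 1 is the plain forward
pass; iteration *t + 1* feeds the image and the previous soft mask back
through the network and adds a λ-scaled correction to the previous logits.
The loop stops when the relative Dice improvement falls below 0.5 % or the
loss change below 0.001 for two consecutive iterations, or after 6
iterations.

**Fusion and classification.** A small CNN embeds the masked image, an MLP
with sigmoid output embeds the genomic vector, and the modalities are fused
by concatenation, element-wise sum, or multi-head cross-attention
(`softmax(QKᵀ/√d_k)` with modality-specific projections; each modality is
one token). A softmax head predicts the subtype.

**Survival.** `deepsurv()` fits a risk network f(x) under the Cox model
h(t|x) = h₀(t) exp(f(x)) by minimizing the negative log partial likelihood
(Breslow ties), with the Breslow estimator for the baseline cumulative
hazard H₀(t). It is a classic R modelling function — formula + data in, an
S3 object out, with `print`, `summary`, `coef`, `predict`, `plot`,
`residuals` and `simulate` methods. With `hidden = NULL` the model is a
Cox regression fit by gradient descent (and matches `survival::coxph` to
three decimals on simulated data); with hidden layers it captures
non-linear interactions. Patients are stratified into low/medium/high risk
groups by hazard-ratio cutpoints (defaults 1.0 and 1.2; tertiles
available). Ranking accuracy is measured by Harrell's concordance index.

**Continual learning.** `incremental_update()` fits new patient batches
(default 50) under the Elastic Weight Consolidation penalty
(λ/2) Σᵢ Fᵢ(θᵢ − θᵢ*)², with a diagonal empirical Fisher estimate and a
proximal update that is exact in the limits λ = 0 (plain descent) and
λ → ∞ (parameter freeze).

**Hyperparameter search.** `bo_optimize()` maximizes a black-box objective
with a squared-exponential GP surrogate and the UCB acquisition µ + κσ.

**Attribution.** `exact_shapley()` enumerates all 2ⁿ coalitions with the
Shapley weights |S|!(n−|S|−1)!/n!; `permutation_shapley()` scales beyond 15
features with an unbiased sampling estimator and per-feature standard
errors.

## Worked example

```r
library(oncosurv)
library(survival)

cohort <- generate_cohort(cohort_config(n_patients = 200, image_size = 32,
                                        seed = 7))
#> Synthetic multimodal cohort: 200 patients, 32 x 32 images
#>   subtypes: 83/78/39  censored: 0.295

d <- data.frame(time  = cohort_field(cohort, "time"),
                event = cohort_field(cohort, "event"),
                cohort_risk_matrix(cohort))
fit <- deepsurv(Surv(time, event) ~ ., d, hidden = NULL, epochs = 300,
                seed = 7)
summary(fit)
#> Deep Cox proportional-hazards model
#>   n = 200 , events = 141
#>   training concordance index: 0.7909
#>   coefficients (original covariate scale):
#>      x1      x2      x3
#>  1.0440 -0.8115  0.4985
```

The simulator drew survival times with true log-hazard coefficients
(1.0, −0.8, 0.5); the fitted coefficients recover them to two decimals, and
the training concordance of 0.79 says the fitted risk ranks patients
correctly in 79 % of comparable pairs. Hazard ratios stratify patients into
risk groups, and exact Shapley values decompose each patient's log hazard
ratio into additive per-feature contributions:

```r
hr <- predict(fit, d[1:5, ], type = "risk")
round(hr, 2)
#> [1] 0.34 0.13 0.14 2.93 0.17
stratify_risk(hr)
#> [1] low  low  low  high low

x <- unlist(d[1, c("x1", "x2", "x3")])
exact_shapley(shapley_model_deepsurv(fit), x,
              as.matrix(d[, c("x1", "x2", "x3")]))
#> Shapley attribution (exact)
#>      x1      x2      x3
#>  0.2036 -1.2675 -0.0011
#>   baseline 0 -> full -1.065 ; overall score -1.065
```

The attributions sum exactly to the difference between the patient's log
hazard ratio and the cohort-average baseline (the efficiency axiom).

`run_pipeline(run_config(...))` chains every stage — simulate, segment,
classify, survival fits over covariate-set combinations, Shapley
attribution — and writes a JSON metrics report; `inst/cli/oncosurv`
exposes each stage as a shell subcommand.

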