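---
title: "Models and design choices in oncosurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in oncosurv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

oncosurv implements a multimodal tumor-analysis pipeline — segmentation,
imaging/genomic fusion, subtype classification, deep Cox survival
modelling, continual updates, hyperparameter search and Shapley
attribution — entirely in base R, at a scale where every stage trains in
seconds to minutes on one CPU. This vignette records the models, their
assumptions, the numerical choices, and the places where the design was
genuinely open, so a maintainer can tell deliberate conventions from
accidents.

## The synthetic cohort: what it emulates and what it does not

All development and testing runs on cohorts from `generate_cohort()`, which
emulates the *structure* of a multimodal lung-cancer study:

* **Images.** 2-D grayscale images (default 64×64 px) containing one tumor
  per image: a perturbed ellipse whose boundary radius is modulated by
  low-order random harmonics scaled by an `irregularity` parameter in
  [0, 1], on a smooth background with additive Gaussian noise
  (`noise_sd`, default 0.05 on a [0, 1] intensity scale). The noiseless
  tumor support is the ground-truth mask.
* **Subtypes.** Three classes with distinct shape conventions — subtype 0
  (adenocarcinoma-like) round with low irregularity, subtype 1
  (squamous-like) elongated, subtype 2 (large-cell-like) small with high
  irregularity — so the image modality carries class signal.
* **Genomics.** The first `n_mutation_flags` features are Bernoulli
  mutation flags whose probabilities depend on subtype (EGFR-like flag
  enriched in subtype 0, KRAS-like in subtype 1, TP53-like in subtype 2);
  remaining features are unit-variance Gaussians with small subtype-
  dependent mean shifts on the first three. Both modalities therefore carry
  learnable, partially redundant class signal.
* **Survival.** Event times are exponential with rate
  `baseline_rate · exp(true_risk)`; `true_risk = β · z` is retained as
  ground truth. By default `z` is three independent standard-normal
  covariates with β = (1.0, −0.8, 0.5) — the documented operating point at
  which a well-specified fit reaches a concordance index in the 0.75–0.80
  band. The alternative `risk_covariates = "multimodal"` ties the risk to
  standardized age, a comorbidity flag, standardized tumor area from the
  mask, and the first mutation flag, which is the configuration the
  end-to-end pipeline uses so that its covariate-set comparisons (clinical
  / +imaging / +genomic / all) are meaningful.
* **Censoring.** Independent exponential, with a single cohort-level rate
  solved numerically (`uniroot`) so the expected censored fraction hits
  `censor_fraction` (default 0.3). Censoring is therefore non-informative
  by construction — the standard survival-simulation convention.

What the simulator does **not** emulate: 3-D acquisition, scanner physics,
histopathology texture, realistic RNA-seq count distributions, correlated
comorbidity structure, or informative censoring. Passing tests on these
cohorts show that the algorithms are implemented correctly and behave as
their theory predicts under their own assumptions; they say nothing about
performance on real clinical data.

## Segmentation

The segmenter is an encoder–decoder network with skip connections: per
level one 3×3 convolution + ReLU, 2×2 average pooling down, nearest-
neighbour upsampling and skip concatenation up, and a 1×1 output head.
Defaults are depth 3 and 16 base channels (doubled per level), chosen as
the smallest architecture that saturates Dice on simulator images; tests
use depth 2 / 8 channels for speed. The loss is pixel-mean binary
cross-entropy plus `alpha_loss · (1 − soft Dice)` with `alpha_loss = 1` —
the two terms are of comparable magnitude on blob-like masks, and the
weight is exposed for imbalanced cases. Probabilities are clipped at 1e-7
before the log; the Dice smoothing constant is 1e-6.

**Iterative refinement.** The network takes two input channels: the image
and the previous soft mask (a neutral 0.5 at iteration 1, so iteration 1
is exactly the plain forward pass). Refinement adds a
`lambda_refine`-scaled (default 0.5) correction to the previous logits:
`z_{t+1} = z_t + λ · net(image, S_t)`. A formulation that adds a parameter-
space gradient directly to a segmentation map is dimensionally
inconsistent, so the refinement operator here is a *learned recurrent
residual*: well-posed at inference (no labels needed), trained by taking a
second gradient step per batch with the network's own prediction fed back
as the previous-mask channel. Stopping follows two rules checked from
iteration 2 on: relative Dice improvement below `dice_improve_tol`
(default 0.005, i.e. 0.5 %) or absolute loss change below `loss_delta_tol`
(default 0.001), either sustained for `patience = 2` consecutive
iterations, with a hard cap `max_iterations = 6`. With a reference mask
the traces are computed against it; at inference without labels the same
rules run on self-consistency between consecutive masks (Dice of
consecutive hard masks; cross-entropy of the current soft mask against the
previous one), because a label-dependent criterion would be undefined.
Hard masks use threshold 0.5.

## Fusion and classification

The image extractor masks the image (element-wise product — pixels outside
the mask provably cannot influence the features), applies three
convolution blocks (defaults 16→32→64 filters; tests use smaller), global
average pooling, and a linear projection to `feature_dim` (default 16).
The genomic MLP uses ReLU hidden layers (defaults 64/32) and a **sigmoid
output embedding**, so genomic features live in (0, 1); placing the
saturating activation at the embedding rather than the hidden layers keeps
training well-conditioned while preserving a bounded embedding.

Three fusion modes are selectable: `concat`, element-wise `sum` (requires
equal embedding lengths), and the default `attention`. Cross-attention
treats each modality embedding as a single token: per head,
`softmax(q·k/√d_k)` over the available auxiliary modalities, head-averaged
weights, and `fused = f_img + a_gen · f_genomic (+ a_hist · f_hist)`.
Query/key projections are modality-specific (`share_projections = FALSE`).
Two consequences are worth recording: with a single auxiliary modality the
softmax is over one token, the attention weight is identically 1, and the
attention projections receive exactly zero gradient during end-to-end
training — the mode then coincides with sum fusion plus the image term.
Attention only differentiates modalities when at least two are present
(e.g. with a histopathology channel). The histopathology channel is
optional and all its terms drop when absent, which is the simulator's
default.

Multi-head defaults (4 heads) follow the convention of keeping per-head
dimension `feature_dim / n_heads`; `feature_dim` must be divisible by
`n_heads`. The classifier head is a single softmax layer trained by
cross-entropy with mini-batch Adam (defaults: 30 epochs, lr 2e-3, batch
32, stratified 80/20 split). Held-out metrics are accuracy, one-vs-rest
AUC per class (via pROC) and the confusion matrix.

## Deep Cox survival model

`deepsurv()` follows the classic R modelling idiom (formula + data,
S3 methods) because the survival model is the package's central estimator.
The risk network is a dense ReLU network (defaults 32/16; `hidden = NULL`
gives the linear special case); dropout in [0, 0.5] is available for the
hidden layers. Training is full-batch Adam on the negative log partial
likelihood normalized per sample, plus a small L2 penalty (1e-4) on
weights only. Covariates are standardized internally; `coef()` maps linear
weights back to the original scale.

Numerical and statistical conventions:

* **Ties: Breslow.** Tied event times share a risk set, consistent with
  the Breslow baseline estimator; the Efron correction is a possible
  extension, not implemented.
* **Baseline hazard: Breslow estimator**, increments
  `d_k / Σ_{R(t_k)} exp(f(x_j))`, cumulated into a right-continuous step
  function with H₀(0) = 0.
* **Stability.** Scores are max-shifted before exponentiation (the loss is
  shift-invariant, asserted exactly in tests); the analytic score gradient
  is verified against central finite differences at 1e-4 relative
  tolerance.
* **Concordance.** Harrell's convention: a pair is comparable when the
  earlier subject has an observed event and a strictly shorter time;
  prediction ties count 0.5. The implementation is checked for exact
  agreement with a naive double-loop oracle and with
  `survival::concordance` on tie-free data.
* **Risk groups.** Hazard-ratio cutpoints default to 1.0 and 1.2 with the
  half-open convention (a ratio exactly 1.0 is medium); these reproduce
  the reference worked examples this package tests against. Because
  absolute hazard ratios depend on the covariate centering, tertile-based
  cutpoints (`risk_cutpoints_tertiles()`) are offered for cohort-relative
  stratification, and the pipeline uses them when comparing predicted
  groups against simulator truth.

## Elastic weight consolidation

`ewc_state()` snapshots the fitted parameters θ* and a **diagonal
empirical Fisher**: the mean over consecutive mini-batches (default 50
patients, matching the incremental batch size) of squared gradients of the
per-sample-normalized partial-likelihood loss at θ*. The mean (not sum)
makes the estimate invariant to dataset duplication. The update minimizes
`L_new(θ) + (λ/2) Σ F_i (θ_i − θ_i*)²` with a **proximal (implicit) step**
on the quadratic penalty:
`θ ← (θ − lr·g_new + lr·λ·F·θ*) / (1 + lr·λ·F)`. A first-order explicit
step would oscillate or diverge for large λ·F; the implicit step is
unconditionally stable and exact in both limits — plain gradient descent
at λ = 0 and a parameter freeze as λ → ∞ — which is precisely what the
limit-behaviour tests assert. The default λ = 100 retains old-task
concordance on distribution-shifted batches in the seeded forgetting
experiment; λ is exposed and tunable via `bo_optimize()`. The anchor
policy is single-anchor (most recent task), modelling a rolling clinical
stream rather than discrete named tasks.

## Bayesian optimization

The surrogate is GP regression with a squared-exponential kernel on inputs
normalized to the unit cube; observations are standardized. Per-dimension
lengthscales and the noise variance are chosen by a greedy grid search on
the log marginal likelihood (grids 0.05–2 and 1e-6–1e-2) — adequate for
the ≤ 4-dimensional spaces used here and free of optimizer dependencies.
A jitter of 1e-8 guards the Cholesky factorization; posterior variances
are clamped at zero. Acquisition is UCB `µ + κσ` with κ = 2 by default
(balanced exploration); the initial design is 5 seeded Latin-hypercube
points (via lhs) and the inner acquisition maximization scans 1,000 seeded
uniform candidates, keeping the whole run deterministic given one seed.
Integer dimensions use continuous relaxation with rounding after proposal
(adequate for layer counts 2–6); learning-rate-like dimensions use a
log10 scale. Failed objective evaluations are recorded as NA, excluded
from the surrogate, and still consume budget.

## Shapley attribution

`f(S)` is the model's prediction with out-of-coalition features replaced
by background means (the interventional convention; deterministic given
the background sample). Exact enumeration covers up to 15 features;
beyond that `permutation_shapley()` averages marginal contributions over
uniformly random orderings and reports per-feature Monte-Carlo standard
errors. The explained scalar is the log hazard ratio f(x) for survival
models and the predicted-class probability for the classifier (with the
image modality held fixed); both choices are conventions, recorded here
because the attributed quantity must be stated for attributions to be
interpretable. The default overall score is the plain sum of per-feature
attributions — by efficiency, exactly `f(N) − f(∅)` for exact reports —
with absolute-sum and normalized variants available. The efficiency,
dummy, symmetry and linearity axioms, and exact agreement with an
independent all-orderings oracle, are asserted in the test suite.

## Evaluation harness

`stratified_split()` uses largest-remainder allocation within each
stratum, so per-class proportions match the requested (0.70, 0.15, 0.15)
fractions within one sample. `cross_validate()` runs stratified k-fold
(default 5) with every sample validated exactly once.
One global seed determines every stage seed through a fixed affine map
(`derive_seed()`), making whole-pipeline runs reproducible; the metrics
report carries an MD5 hash of the serialized configuration. Masks are
stored as 0/255 PNG and read back as {0, 1}; images are 8-bit grayscale
PNG (round-trips are exact for masks and within 1/255 for images);
coordinates are row-major with the origin at the top-left.

## Problem sizes

The shipped defaults (64×64 images, cohorts of a few hundred) are sized
for interactive desk use. The test suite runs smaller instances chosen as
the smallest sizes at which each property is cleanly observable: 32×32
images, segmenter depth 2 with 8 base channels on 40 images, classifier
cohorts of 240, survival cohorts of 600 (n = 600 with β = (1.0, −0.8, 0.5)
and 30 % censoring is the documented operating point for the concordance
band and coefficient recovery), EWC tasks of 200 + 50 patients, and
optimizer budgets of 15–30.

## Known limitations

* Single-tumor, single-channel 2-D images; no multi-class masks.
* The attention fusion is degenerate (weight ≡ 1) with one auxiliary
  modality; its benefit over sum fusion only materializes with ≥ 2
  auxiliary modalities.
* Breslow ties only; no time-varying covariates or competing risks.
* The GP surrogate fits hyperparameters by grid search and proposes one
  point at a time; no batch or multi-fidelity proposals.
* Exact Shapley cost grows as 2ⁿ; the permutation estimator's error decays
  as n_samples^(−1/2).
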