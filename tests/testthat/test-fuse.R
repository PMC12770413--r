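test_that("genomic MLP outputs stay in (0,1) and match a hand evaluation", {
  cfg <- fusion_config(feature_dim = 4, mlp_hidden = c(5), seed = 2)
  st <- init_feature_extractors(cfg, n_genomic = 6)
  out <- extract_genomic_features(rnorm(6), st$mlp)
  expect_true(all(out > 0 & out < 1))
  expect_length(out, 4)
  ## zero weights, zero biases -> sigmoid(0) = 0.5 everywhere
  zero <- lapply(st$mlp, function(l) list(W = l$W * 0, b = l$b * 0))
  expect_equal(extract_genomic_features(rnorm(6), zero), rep(0.5, 4))
  ## two-feature toy with hand-set weights: one hidden ReLU unit, sigmoid out
  toy <- list(h1 = list(W = matrix(c(1, -2), 2, 1), b = 0.5),
              out = list(W = matrix(3, 1, 1), b = -1))
  g <- c(0.8, 0.1)
  hidden <- max(0, 1 * 0.8 - 2 * 0.1 + 0.5)
  hand <- 1 / (1 + exp(-(3 * hidden - 1)))
  expect_equal(extract_genomic_features(g, toy), hand)
  expect_error(extract_genomic_features(rnorm(3), st$mlp), "does not match")
})

test_that("image features are invariant to content outside the mask", {
  cfg <- fusion_config(feature_dim = 8, cnn_channels = c(4, 8, 8), seed = 3)
  st <- init_feature_extractors(cfg, n_genomic = 4)
  ch <- small_cohort()
  s <- ch[[1]]
  f1 <- extract_image_features(s$image, s$mask, st$cnn)
  outside <- s$image
  outside[s$mask == 0] <- runif(sum(s$mask == 0))
  f2 <- extract_image_features(outside, s$mask, st$cnn)
  expect_equal(f1, f2, tolerance = 1e-12)
  expect_identical(f1, extract_image_features(s$image, s$mask, st$cnn))
  ## all-zero mask annihilates the input: equals the stack on a zero image
  zmask <- s$mask * 0
  expect_equal(extract_image_features(s$image, zmask, st$cnn),
               extract_image_features(s$image * 0, zmask + 1, st$cnn),
               tolerance = 1e-12)
})

test_that("cross-attention weights are proper distributions with hand-checkable scores", {
  cfg <- fusion_config(feature_dim = 8, n_heads = 2, d_k = 3, seed = 4)
  st <- init_feature_extractors(cfg, n_genomic = 4)
  par <- oncosurv:::attn_init(cfg, 8, 8)
  q <- rnorm(8)
  ## single key position: weight exactly 1 regardless of parameters
  ca1 <- cross_attention(q, rnorm(8), par, n_heads = 2)
  expect_equal(as.numeric(ca1$attention), c(1, 1))
  ## identical keys at all positions: uniform 1/m
  kv <- matrix(rep(rnorm(8), 3), 3, byrow = TRUE)
  ca3 <- cross_attention(q, kv, par, n_heads = 2)
  expect_equal(as.numeric(ca3$attention), rep(1 / 3, 6), tolerance = 1e-12)
  expect_equal(rowSums(ca3$attention), c(1, 1))
  ## two-position toy: weights match softmax(q.k / sqrt(d_k)) by hand
  kv2 <- matrix(rnorm(16), 2)
  ca2 <- cross_attention(q, kv2, par, n_heads = 2)
  d_k <- 3
  for (h in 1:2) {
    ik <- (h - 1) * d_k + seq_len(d_k)
    qh <- as.numeric(q %*% par$Wq)[ik]
    Kh <- (kv2 %*% par$Wk)[, ik, drop = FALSE]
    sc <- as.numeric(Kh %*% qh) / sqrt(d_k)
    expect_equal(ca2$attention[h, ], exp(sc - max(sc)) / sum(exp(sc - max(sc))),
                 tolerance = 1e-12)
  }
})

test_that("fusion modes reproduce printed arithmetic and preserve structure", {
  r <- fusion_examples$P001
  cfg_sum <- fusion_config(mode = "sum", feature_dim = 3)
  expect_equal(fuse_features(r$img, r$gen, config = cfg_sum), r$fused,
               tolerance = 1e-12)
  ## sum fusion is commutative in its modality arguments
  expect_equal(fuse_features(r$img, r$gen, config = cfg_sum),
               fuse_features(r$gen, r$img, config = cfg_sum))
  expect_error(fuse_features(r$img, c(1, 2), config = cfg_sum), "equal")
  ## concat preserves every component in order
  cfg_cat <- fusion_config(mode = "concat", feature_dim = 3)
  expect_identical(fuse_features(r$img, r$gen, config = cfg_cat),
                   c(r$img, r$gen))
  ## attention with weights forced to zero degenerates to the image features
  cfg_att <- fusion_config(mode = "attention", feature_dim = 3, n_heads = 1)
  fz <- fuse_features(r$img, r$gen, config = cfg_att, weights = 0)
  expect_equal(as.numeric(fz), r$img)
})

test_that("the softmax head is a proper classifier", {
  head0 <- list(W = matrix(0, 4, 3), b = rep(0, 3))
  expect_equal(classify_subtype(rnorm(4), head0), rep(1 / 3, 3))
  crafted <- list(W = matrix(0, 2, 3), b = c(10, 0, 0))
  p <- classify_subtype(c(1, 1), crafted)
  expect_gt(p[1], 0.99)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  ## hand-set 2-D case
  head2 <- list(W = matrix(c(1, 0, 0, 1, -1, 0.5), 2, 3), b = c(0.1, -0.2, 0))
  f <- c(0.4, -0.3)
  z <- as.numeric(f %*% head2$W) + head2$b
  expect_equal(classify_subtype(f, head2), exp(z) / sum(exp(z)))
  expect_error(classify_subtype(rnorm(5), head0), "does not match")
})

test_that("permuting genomic inputs together with first-layer weights leaves the MLP unchanged", {
  cfg <- fusion_config(feature_dim = 4, mlp_hidden = c(6), seed = 7)
  st <- init_feature_extractors(cfg, n_genomic = 5)
  g <- rnorm(5)
  perm <- c(3, 1, 5, 2, 4)
  st_p <- st$mlp
  st_p$h1$W <- st_p$h1$W[perm, , drop = FALSE]
  expect_equal(extract_genomic_features(g[perm], st_p),
               extract_genomic_features(g, st$mlp), tolerance = 1e-12)
})

test_that("end-to-end training separates the subtypes well above chance", {
  ch <- fixture("clf_cohort", function()
    generate_cohort(cohort_config(n_patients = 240, image_size = 32, seed = 7)))
  clf <- fixture("clf_fit", function()
    train_classifier(ch, fusion_config(mode = "attention", feature_dim = 16,
                                       cnn_channels = c(8, 16, 16), seed = 0),
                     epochs = 15, seed = 3))
  expect_gte(clf$metrics$accuracy, 0.85)
  expect_true(all(clf$metrics$auc > 0.9, na.rm = TRUE))
  ## confusion matrix rows sum to the per-class held-out counts
  sp <- stratified_split(ch, c(0.8, 0, 0.2), seed = derive_seed(3, "split"))
  counts <- table(factor(vapply(sp$test, `[[`, numeric(1), "subtype"),
                         levels = 0:2))
  expect_equal(as.numeric(rowSums(clf$metrics$confusion)), as.numeric(counts))
})

test_that("shuffled labels drive held-out accuracy to chance", {
  ch <- fixture("clf_cohort", function()
    generate_cohort(cohort_config(n_patients = 240, image_size = 32, seed = 7)))
  set.seed(41)
  y <- vapply(ch, `[[`, numeric(1), "subtype")
  ysh <- sample(y)
  shuffled <- ch
  for (i in seq_along(shuffled)) shuffled[[i]]$subtype <- ysh[i]
  clf <- train_classifier(shuffled,
                          fusion_config(mode = "sum", feature_dim = 8,
                                        cnn_channels = c(4, 8, 8), seed = 0),
                          epochs = 6, val_fraction = 0.4, seed = 9)
  expect_lt(abs(clf$metrics$accuracy - 1 / 3), 0.1)
})

test_that("a class missing from the training split is reported by name", {
  ch <- fixture("clf_cohort", function()
    generate_cohort(cohort_config(n_patients = 240, image_size = 32, seed = 7)))
  only01 <- structure(Filter(function(s) s$subtype != 2, unclass(ch)),
                      class = "oncosurv_cohort")
  expect_error(
    train_classifier(only01, fusion_config(), epochs = 1, seed = 1),
    "class 2 absent")
})
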