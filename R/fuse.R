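#' Multimodal fusion configuration
#'
#' Settings for feature extraction and fusion of the imaging and genomic
#' modalities. Three fusion modes are supported: `"concat"` (stacked
#' per-modality vectors), `"sum"` (element-wise sum, requiring equal
#' lengths), and `"attention"` (the default: cross-attention weights from the
#' imaging query over the auxiliary modalities, each modality treated as a
#' single token). Query/key projections are modality-specific
#' (`share_projections = FALSE`) so attention learning stays
#' modality-specific.
#'
#' @param mode fusion mode: `"attention"`, `"concat"` or `"sum"`.
#' @param n_heads parallel attention heads (default 4).
#' @param d_k key dimensionality per head.
#' @param feature_dim per-modality embedding size; must be divisible by
#'   `n_heads` in attention mode.
#' @param share_projections share query/key projections across modalities.
#' @param cnn_channels filters of the three convolutional blocks of the
#'   image feature extractor.
#' @param mlp_hidden hidden-layer sizes of the genomic MLP (ReLU hidden
#'   activations; sigmoid output embedding).
#' @param seed integer seed for parameter initialization.
#' @return an object of class `fusion_config`.
#' @export
fusion_config <- function(mode = c("attention", "concat", "sum"),
                          n_heads = 4L, d_k = 8L, feature_dim = 16L,
                          share_projections = FALSE,
                          cnn_channels = c(16L, 32L, 64L),
                          mlp_hidden = c(64L, 32L), seed = 0L) {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, n_heads = as.integer(n_heads),
              d_k = as.integer(d_k), feature_dim = as.integer(feature_dim),
              share_projections = isTRUE(share_projections),
              cnn_channels = as.integer(cnn_channels),
              mlp_hidden = as.integer(mlp_hidden), seed = as.integer(seed))
  validate_fields(list(
    d_k = cfg$d_k > 0L,
    n_heads = cfg$n_heads > 0L,
    feature_dim = cfg$feature_dim > 0L &&
      (mode != "attention" || cfg$feature_dim %% cfg$n_heads == 0L)))
  class(cfg) <- "fusion_config"
  cfg
}

## ---- image CNN -------------------------------------------------------------

cnn_init <- function(config) {
  ch <- config$cnn_channels
  list(conv1 = nn_conv_init(1L, ch[1]),
       conv2 = nn_conv_init(ch[1], ch[2]),
       conv3 = nn_conv_init(ch[2], ch[3]),
       proj = nn_dense_init(ch[3], config$feature_dim))
}

cnn_forward <- function(x, par) {
  c1 <- nn_conv_forward(x, par$conv1); r1 <- nn_relu_forward(c1$out)
  p1 <- nn_pool2_forward(r1$out)
  c2 <- nn_conv_forward(p1, par$conv2); r2 <- nn_relu_forward(c2$out)
  p2 <- nn_pool2_forward(r2$out)
  c3 <- nn_conv_forward(p2, par$conv3); r3 <- nn_relu_forward(c3$out)
  g <- nn_gap_forward(r3$out)
  pj <- nn_dense_forward(g, par$proj)
  list(out = pj$out,
       cache = list(c1 = c1$cache, r1 = r1$cache, d1 = dim(r1$out),
                    c2 = c2$cache, r2 = r2$cache, d2 = dim(r2$out),
                    c3 = c3$cache, r3 = r3$cache, d3 = dim(r3$out),
                    proj = pj$cache))
}

cnn_backward <- function(dout, cc) {
  bkp <- nn_dense_backward(dout, cc$proj)
  grads <- list(proj = bkp$grads)
  dh <- nn_gap_backward(bkp$dx, cc$d3)
  dh <- nn_relu_backward(dh, cc$r3)
  bk3 <- nn_conv_backward(dh, cc$c3); grads$conv3 <- bk3$grads
  dh <- nn_pool2_backward(bk3$dx, cc$d2)
  dh <- nn_relu_backward(dh, cc$r2)
  bk2 <- nn_conv_backward(dh, cc$c2); grads$conv2 <- bk2$grads
  dh <- nn_pool2_backward(bk2$dx, cc$d1)
  dh <- nn_relu_backward(dh, cc$r1)
  bk1 <- nn_conv_backward(dh, cc$c1); grads$conv1 <- bk1$grads
  grads
}

#' Extract spatial features from a segmented image
#'
#' Applies the mask (element-wise product), then a three-block convolutional
#' stack with ReLU activations and pooling, global average pooling, and a
#' linear projection to a fixed-length feature vector. Pixels outside the
#' mask cannot influence the output.
#'
#' @param image square image matrix.
#' @param mask binary mask of the same shape.
#' @param cnn_state CNN parameters (from [init_feature_extractors()] or a
#'   trained classifier).
#' @return numeric feature vector of length `feature_dim`.
#' @export
extract_image_features <- function(image, mask, cnn_state) {
  if (!identical(dim(image), dim(mask)))
    stop("image and mask must have identical shapes")
  x <- array(image * mask, c(1L, nrow(image), ncol(image), 1L))
  as.numeric(cnn_forward(x, cnn_state)$out)
}

## ---- genomic MLP ------------------------------------------------------------

mlp_init <- function(n_in, config) {
  hs <- config$mlp_hidden
  layers <- list()
  prev <- n_in
  for (i in seq_along(hs)) {
    layers[[paste0("h", i)]] <- nn_dense_init(prev, hs[i])
    prev <- hs[i]
  }
  layers$out <- nn_dense_init(prev, config$feature_dim)
  layers
}

mlp_forward <- function(g, par) {
  caches <- list()
  h <- g
  nh <- length(par) - 1L
  for (i in seq_len(nh)) {
    dn <- nn_dense_forward(h, par[[paste0("h", i)]])
    rl <- nn_relu_forward(dn$out)
    caches[[paste0("h", i)]] <- list(dense = dn$cache, relu = rl$cache)
    h <- rl$out
  }
  dn <- nn_dense_forward(h, par$out)
  sg <- nn_sigmoid_forward(dn$out)
  caches$out <- list(dense = dn$cache, sig = sg$cache)
  list(out = sg$out, cache = caches)
}

mlp_backward <- function(dout, cc, par) {
  grads <- list()
  dh <- nn_sigmoid_backward(dout, cc$out$sig)
  bk <- nn_dense_backward(dh, cc$out$dense)
  grads$out <- bk$grads
  dh <- bk$dx
  nh <- length(par) - 1L
  for (i in rev(seq_len(nh))) {
    key <- paste0("h", i)
    dr <- nn_relu_backward(dh, cc[[key]]$relu)
    bk <- nn_dense_backward(dr, cc[[key]]$dense)
    grads[[key]] <- bk$grads
    dh <- bk$dx
  }
  grads
}

#' Extract biological features from a genomic vector
#'
#' Fully connected layers with ReLU hidden activations and a sigmoid output
#' embedding, so every output component lies strictly in (0, 1).
#'
#' @param g genomic feature vector.
#' @param mlp_state MLP parameters.
#' @return numeric feature vector of length `feature_dim`, entries in (0, 1).
#' @export
extract_genomic_features <- function(g, mlp_state) {
  n_in <- nrow(mlp_state[[1]]$W)
  if (length(g) != n_in)
    stop("genomic vector length ", length(g), " does not match MLP input ", n_in)
  as.numeric(mlp_forward(matrix(g, 1L), mlp_state)$out)
}

## ---- cross-attention --------------------------------------------------------

attn_init <- function(config, d_query, d_kv) {
  dk_total <- config$n_heads * config$d_k
  fd <- config$feature_dim
  list(Wq = he_init(c(d_query, dk_total), d_query),
       Wk = he_init(c(d_kv, dk_total), d_kv),
       Wv = he_init(c(d_kv, fd), d_kv),
       Wo = he_init(c(fd, fd), fd),
       bo = numeric(fd))
}

#' Scaled dot-product cross-attention between modalities
#'
#' The query vector comes from one modality; keys and values from another
#' (`f_key_value` may be a matrix with one token per row). Per head, the
#' attention weights are `softmax(q . k / sqrt(d_k))` over key positions;
#' head outputs are concatenated, normalized (zero mean, unit variance) and
#' passed through a feed-forward projection.
#'
#' @param f_query query feature vector.
#' @param f_key_value key/value tokens: a vector (single token) or a matrix
#'   with tokens in rows.
#' @param params attention parameters (`Wq`, `Wk`, `Wv`, `Wo`, `bo`).
#' @param n_heads number of attention heads; must divide the value dimension.
#' @return list with `attended` (the output vector) and `attention`
#'   (`n_heads` x m weight matrix; every row sums to 1).
#' @export
cross_attention <- function(f_query, f_key_value, params, n_heads = 4L) {
  if (is.null(dim(f_key_value))) f_key_value <- matrix(f_key_value, nrow = 1L)
  m <- nrow(f_key_value)
  dk_total <- ncol(params$Wq)
  if (dk_total %% n_heads != 0L) stop("n_heads must divide the key dimension")
  d_k <- dk_total %/% n_heads
  if (length(f_query) != nrow(params$Wq) || ncol(f_key_value) != nrow(params$Wk))
    stop("dimension mismatch between features and attention projections")
  q <- as.numeric(f_query %*% params$Wq)          # dk_total
  K <- f_key_value %*% params$Wk                  # m x dk_total
  V <- f_key_value %*% params$Wv                  # m x fd
  fd <- ncol(V)
  if (fd %% n_heads != 0L) stop("n_heads must divide the value dimension")
  dv <- fd %/% n_heads
  A <- matrix(0, n_heads, m)
  out <- numeric(fd)
  for (h in seq_len(n_heads)) {
    ik <- (h - 1L) * d_k + seq_len(d_k)
    iv <- (h - 1L) * dv + seq_len(dv)
    scores <- as.numeric(K[, ik, drop = FALSE] %*% q[ik]) / sqrt(d_k)
    A[h, ] <- softmax(scores)
    out[iv] <- as.numeric(A[h, ] %*% V[, iv, drop = FALSE])
  }
  mu <- mean(out); sd_ <- stats::sd(out)
  normed <- (out - mu) / (sd_ + 1e-8)
  attended <- as.numeric(normed %*% params$Wo) + params$bo
  list(attended = attended, attention = A)
}

#' Fuse per-modality feature vectors
#'
#' `"concat"` stacks the vectors (imaging first), `"sum"` adds them
#' element-wise (equal lengths required), and `"attention"` computes
#' cross-attention weights from the imaging query over the auxiliary
#' modalities (each one token) and returns
#' `a_genomic * f_genomic + a_hist * f_hist + f_img`, where each `a` is the
#' head-averaged attention weight of that modality.
#'
#' @param f_img imaging feature vector.
#' @param f_genomic genomic feature vector.
#' @param f_hist optional second-image (histopathology) feature vector; its
#'   term is dropped when absent.
#' @param config a [fusion_config()].
#' @param params attention parameters (attention mode only).
#' @param weights optional fixed modality weights overriding the learned
#'   attention (diagnostic use; e.g. all-zero weights reduce the fusion to
#'   `f_img`).
#' @return fused numeric vector; in attention mode the modality weight
#'   vector is attached as attribute `"attention"`.
#' @export
fuse_features <- function(f_img, f_genomic, f_hist = NULL,
                          config = fusion_config(), params = NULL,
                          weights = NULL) {
  switch(config$mode,
    concat = c(f_img, f_genomic, f_hist),
    sum = {
      if (length(f_img) != length(f_genomic) ||
          (!is.null(f_hist) && length(f_hist) != length(f_img)))
        stop("sum fusion requires equal feature lengths")
      f_img + f_genomic + if (is.null(f_hist)) 0 else f_hist
    },
    attention = {
      kv <- rbind(f_genomic, if (!is.null(f_hist)) f_hist)
      if (is.null(weights)) {
        if (is.null(params)) {
          params <- with_seed(config$seed,
                              attn_init(config, length(f_img), ncol(kv)))
        }
        ca <- cross_attention(f_img, kv, params, config$n_heads)
        abar <- colMeans(ca$attention)
      } else abar <- rep_len(weights, nrow(kv))
      fused <- f_img + abar[1] * f_genomic +
        if (is.null(f_hist)) 0 else abar[2] * f_hist
      attr(fused, "attention") <- abar
      fused
    })
}

#' Subtype probabilities from a fused feature vector
#'
#' Softmax over a single fully connected layer: `softmax(W f + b)`.
#'
#' @param f_fusion fused feature vector.
#' @param head_params list with `W` (d x 3) and `b` (length 3).
#' @return probability 3-vector summing to 1.
#' @export
classify_subtype <- function(f_fusion, head_params) {
  if (length(f_fusion) != nrow(head_params$W))
    stop("fused vector length does not match classifier head")
  softmax(as.numeric(f_fusion %*% head_params$W) + head_params$b)
}

#' Initialize untrained feature extractors
#'
#' Seeded random CNN, MLP and (in attention mode) attention parameters, used
#' for feature extraction before or without end-to-end training.
#'
#' @param config a [fusion_config()].
#' @param n_genomic genomic input length.
#' @return list with `cnn`, `mlp`, optionally `attn`, and `head` parameters.
#' @export
init_feature_extractors <- function(config, n_genomic) {
  with_seed(config$seed, {
    fused_dim <- if (config$mode == "concat") 2L * config$feature_dim
                 else config$feature_dim
    list(cnn = cnn_init(config),
         mlp = mlp_init(n_genomic, config),
         attn = if (config$mode == "attention")
           attn_init(config, config$feature_dim, config$feature_dim),
         head = nn_dense_init(fused_dim, 3L))
  })
}

## ---- end-to-end classifier training ----------------------------------------

#' Train the multimodal subtype classifier
#'
#' End-to-end training of the image CNN, genomic MLP, fusion and softmax head
#' by cross-entropy on a stratified train/held-out split. Images enter
#' masked by their ground-truth masks (or segmenter outputs, if the caller
#' substitutes them into the cohort).
#'
#' @param cohort an `oncosurv_cohort` with subtype labels.
#' @param config a [fusion_config()].
#' @param epochs,lr,batch_size training-loop settings.
#' @param val_fraction held-out fraction (stratified by subtype).
#' @param seed integer seed.
#' @return an object of class `oncosurv_classifier` with trained parameter
#'   states and held-out `metrics` (accuracy, one-vs-rest AUC per class,
#'   confusion matrix).
#' @export
train_classifier <- function(cohort, config = fusion_config(), epochs = 30L,
                             lr = 2e-3, batch_size = 32L,
                             val_fraction = 0.2, seed = 0L) {
  y_all <- cohort_subtypes(cohort)
  sp <- stratified_split(cohort, c(1 - val_fraction, 0, val_fraction),
                         seed = derive_seed(seed, "split"))
  train <- sp$train; val <- sp$test
  y_tr <- cohort_subtypes(train)
  missing_cls <- setdiff(0:2, unique(y_tr))
  if (length(missing_cls))
    stop("subtype class ", paste(missing_cls, collapse = ","),
         " absent from the training split")
  H <- nrow(train[[1]]$image)
  stack_x <- function(set) {
    x <- array(0, c(length(set), H, H, 1L))
    for (i in seq_along(set)) x[i, , , 1] <- set[[i]]$image * set[[i]]$mask
    x
  }
  x_tr <- stack_x(train); g_tr <- cohort_genomic_matrix(train)
  x_va <- stack_x(val); g_va <- cohort_genomic_matrix(val)
  y_va <- cohort_subtypes(val)
  n <- length(train)
  with_seed(seed, {
    params <- init_feature_extractors(config, ncol(g_tr))
    trainable <- params[!vapply(params, is.null, logical(1))]
    trainable$attn <- NULL  # single-token attention passes no gradient
    opt <- adam_init(trainable)
    history <- numeric(epochs)
    fwd <- function(xb, gb) {
      cf <- cnn_forward(xb, params$cnn)
      mf <- mlp_forward(gb, params$mlp)
      fused <- switch(config$mode,
        concat = cbind(cf$out, mf$out),
        sum = cf$out + mf$out,
        attention = {
          ab <- t(vapply(seq_len(nrow(cf$out)), function(i)
            colMeans(cross_attention(cf$out[i, ], mf$out[i, , drop = FALSE],
                                     params$attn, config$n_heads)$attention),
            numeric(1)))
          cf$out + as.numeric(ab) * mf$out
        })
      hd <- nn_dense_forward(fused, params$head)
      list(cf = cf, mf = mf, fused = fused, hd = hd,
           probs = softmax_rows(hd$out))
    }
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      ep_loss <- 0
      for (bi in batches) {
        xb <- x_tr[bi, , , , drop = FALSE]
        gb <- g_tr[bi, , drop = FALSE]
        yb <- y_tr[bi]
        fw <- fwd(xb, gb)
        nb <- length(bi)
        Y <- matrix(0, nb, 3L); Y[cbind(seq_len(nb), yb + 1L)] <- 1
        ep_loss <- ep_loss -
          sum(log(pmax(fw$probs[cbind(seq_len(nb), yb + 1L)], 1e-12)))
        dlogits <- (fw$probs - Y) / nb
        bk_head <- nn_dense_backward(dlogits, fw$hd$cache)
        dfused <- bk_head$dx
        fd <- config$feature_dim
        dimg <- switch(config$mode,
          concat = dfused[, seq_len(fd), drop = FALSE],
          sum = dfused, attention = dfused)
        dgen <- switch(config$mode,
          concat = dfused[, fd + seq_len(fd), drop = FALSE],
          sum = dfused,
          attention = dfused)  # modality weight is 1 for a single kv token
        gr <- list(cnn = cnn_backward(dimg, fw$cf$cache),
                   mlp = mlp_backward(dgen, fw$mf$cache, params$mlp),
                   head = bk_head$grads)
        st <- adam_step(trainable, gr, opt, lr = lr)
        trainable <- st$params; opt <- st$state
        params[names(trainable)] <- trainable
      }
      history[ep] <- ep_loss / n
    }
    fw_va <- fwd(x_va, g_va)
    pred <- max.col(fw_va$probs) - 1L
    acc <- mean(pred == y_va)
    auc <- vapply(0:2, function(k) {
      resp <- factor(y_va == k, levels = c(FALSE, TRUE))
      if (length(unique(resp)) < 2L) return(NA_real_)
      as.numeric(pROC::auc(pROC::roc(resp, fw_va$probs[, k + 1L],
                                     quiet = TRUE, direction = "<",
                                     levels = c(FALSE, TRUE))))
    }, numeric(1))
    confusion <- table(truth = factor(y_va, levels = 0:2),
                       predicted = factor(pred, levels = 0:2))
    structure(list(params = params, config = config, history = history,
                   metrics = list(accuracy = acc, auc = auc,
                                  confusion = confusion),
                   n_genomic = ncol(g_tr), image_size = H),
              class = "oncosurv_classifier")
  })
}

#' @export
print.oncosurv_classifier <- function(x, ...) {
  cat("Multimodal subtype classifier (", x$config$mode, " fusion)\n", sep = "")
  cat("  held-out accuracy:", round(x$metrics$accuracy, 3),
      " AUC:", paste(round(x$metrics$auc, 3), collapse = "/"), "\n")
  invisible(x)
}

#' Full multimodal feature bundle for one patient
#'
#' Runs both extractors, fusion and the classifier head for a single sample
#' and returns every intermediate representation.
#'
#' @param sample one cohort sample (image, mask, genomic).
#' @param clf a trained `oncosurv_classifier` (or the output of
#'   [init_feature_extractors()] wrapped with a `fusion_config`).
#' @return list with `f_img`, `f_genomic`, `attention` (attention mode
#'   only), `f_fusion` and `subtype_probs`.
#' @export
feature_bundle <- function(sample, clf) {
  f_img <- extract_image_features(sample$image, sample$mask, clf$params$cnn)
  f_gen <- extract_genomic_features(sample$genomic, clf$params$mlp)
  fused <- fuse_features(f_img, f_gen, config = clf$config,
                         params = clf$params$attn)
  probs <- classify_subtype(as.numeric(fused), clf$params$head)
  list(f_img = f_img, f_genomic = f_gen,
       attention = attr(fused, "attention"),
       f_fusion = as.numeric(fused), subtype_probs = probs)
}
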