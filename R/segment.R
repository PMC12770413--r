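#' Segmenter configuration
#'
#' Architecture and refinement-loop settings for the encoder-decoder tumor
#' segmenter. Iterative refinement stops once the relative Dice improvement
#' falls below `dice_improve_tol` (default 0.5\%) or the absolute loss change
#' falls below `loss_delta_tol` for `patience` consecutive iterations, or at
#' `max_iterations` (default 6, matching the 5-6 cycles after which the
#' refinement typically stabilizes).
#'
#' @param depth encoder levels (each halves the resolution).
#' @param base_channels convolution filters at the first level; doubled per
#'   level.
#' @param lambda_refine step size of the refinement correction (unitless).
#' @param alpha_loss weight of the Dice term in the combined loss.
#' @param max_iterations refinement iteration cap (>= 1).
#' @param dice_improve_tol relative Dice-improvement stopping threshold.
#' @param loss_delta_tol absolute loss-change stopping threshold.
#' @param patience consecutive below-threshold iterations before stopping.
#' @param epochs,lr,batch_size training-loop settings.
#' @param seed integer seed governing initialization and batch order.
#' @return an object of class `segmenter_config`.
#' @export
segmenter_config <- function(depth = 3L, base_channels = 16L,
                             lambda_refine = 0.5, alpha_loss = 1.0,
                             max_iterations = 6L, dice_improve_tol = 0.005,
                             loss_delta_tol = 0.001, patience = 2L,
                             epochs = 20L, lr = 3e-3, batch_size = 8L,
                             seed = 0L) {
  cfg <- list(depth = as.integer(depth), base_channels = as.integer(base_channels),
              lambda_refine = lambda_refine, alpha_loss = alpha_loss,
              max_iterations = as.integer(max_iterations),
              dice_improve_tol = dice_improve_tol,
              loss_delta_tol = loss_delta_tol, patience = as.integer(patience),
              epochs = as.integer(epochs), lr = lr,
              batch_size = as.integer(batch_size), seed = as.integer(seed))
  validate_fields(list(
    depth = cfg$depth >= 1L, base_channels = cfg$base_channels >= 1L,
    max_iterations = cfg$max_iterations >= 1L,
    dice_improve_tol = cfg$dice_improve_tol > 0,
    alpha_loss = cfg$alpha_loss >= 0,
    patience = cfg$patience >= 1L))
  class(cfg) <- "segmenter_config"
  cfg
}

#' Dice similarity coefficient
#'
#' Overlap measure `(2 * sum(pred * ref) + smooth) / (sum(pred) + sum(ref) +
#' smooth)` between a predicted (binary or soft) mask and a reference binary
#' mask. Equals `2|A n B| / (|A| + |B|)` for hard masks.
#'
#' @param pred_mask predicted mask (values in \[0, 1\]).
#' @param ref_mask reference binary mask, same shape.
#' @param smooth small smoothing constant (default 1e-6).
#' @return scalar in \[0, 1\].
#' @export
dice_coefficient <- function(pred_mask, ref_mask, smooth = 1e-6) {
  if (!identical(dim(pred_mask), dim(ref_mask)))
    stop("pred_mask and ref_mask must have identical shapes")
  if (smooth < 0) stop("smooth must be >= 0")
  (2 * sum(pred_mask * ref_mask) + smooth) /
    (sum(pred_mask) + sum(ref_mask) + smooth)
}

#' Combined cross-entropy + Dice segmentation loss
#'
#' Pixel-mean binary cross-entropy plus `alpha * (1 - soft Dice)`.
#' Probabilities are clipped to \[1e-7, 1 - 1e-7\] so both terms stay finite.
#'
#' @param probs soft prediction grid in \[0, 1\].
#' @param ref_mask binary reference grid, same shape.
#' @param alpha non-negative Dice-term weight.
#' @param smooth Dice smoothing constant.
#' @return scalar loss (>= 0).
#' @export
combined_loss <- function(probs, ref_mask, alpha = 1, smooth = 1e-6) {
  if (alpha < 0) stop("alpha must be >= 0")
  if (!identical(dim(probs), dim(ref_mask)))
    stop("probs and ref_mask must have identical shapes")
  p <- pmin(pmax(probs, 1e-7), 1 - 1e-7)
  ce <- -mean(ref_mask * log(p) + (1 - ref_mask) * log(1 - p))
  ce + alpha * (1 - dice_coefficient(p, ref_mask, smooth))
}

## ---- network ---------------------------------------------------------------

seg_init_params <- function(config) {
  ch <- config$base_channels * 2^(seq_len(config$depth) - 1L)
  enc <- vector("list", config$depth)
  cin <- 2L  # image + previous-soft-mask channel
  for (d in seq_len(config$depth)) {
    enc[[d]] <- nn_conv_init(cin, ch[d])
    cin <- ch[d]
  }
  bott <- nn_conv_init(ch[config$depth], ch[config$depth])
  dec <- vector("list", config$depth)
  up_ch <- ch[config$depth]
  for (d in rev(seq_len(config$depth))) {
    dec[[d]] <- nn_conv_init(up_ch + ch[d], ch[d])
    up_ch <- ch[d]
  }
  head <- nn_dense_init(ch[1], 1L)  # 1x1 convolution as a per-pixel dense map
  list(enc = enc, bott = bott, dec = dec, head = head)
}

## Forward pass. x: (N, H, W, 2). Returns logits (N, H, W) and caches.
seg_forward <- function(params, x) {
  depth <- length(params$enc)
  caches <- list(enc = vector("list", depth), dec = vector("list", depth))
  skips <- vector("list", depth)
  h <- x
  for (d in seq_len(depth)) {
    cv <- nn_conv_forward(h, params$enc[[d]])
    rl <- nn_relu_forward(cv$out)
    skips[[d]] <- rl$out
    caches$enc[[d]] <- list(conv = cv$cache, relu = rl$cache,
                            in_dim = dim(h), out_dim = dim(rl$out))
    h <- nn_pool2_forward(rl$out)
  }
  cvb <- nn_conv_forward(h, params$bott)
  rlb <- nn_relu_forward(cvb$out)
  caches$bott <- list(conv = cvb$cache, relu = rlb$cache, in_dim = dim(h))
  h <- rlb$out
  for (d in rev(seq_len(depth))) {
    hu <- nn_upsample2_forward(h)
    cat_in <- array(c(hu, skips[[d]]),
                    dim = c(dim(hu)[1:3], dim(hu)[4] + dim(skips[[d]])[4]))
    cv <- nn_conv_forward(cat_in, params$dec[[d]])
    rl <- nn_relu_forward(cv$out)
    caches$dec[[d]] <- list(conv = cv$cache, relu = rl$cache,
                            up_in_dim = dim(h), n_up = dim(hu)[4])
    h <- rl$out
  }
  d4 <- dim(h)
  hm <- matrix(h, nrow = prod(d4[1:3]), ncol = d4[4])
  hd <- nn_dense_forward(hm, params$head)
  caches$head <- list(dense = hd$cache, d4 = d4)
  list(logits = array(hd$out, d4[1:3]), caches = caches)
}

## Backward pass from dlogits (N, H, W); returns gradient structure.
seg_backward <- function(params, caches, dlogits) {
  depth <- length(params$enc)
  grads <- list(enc = vector("list", depth), dec = vector("list", depth))
  d4 <- caches$head$d4
  dhm <- matrix(dlogits, nrow = prod(d4[1:3]), ncol = 1L)
  bk <- nn_dense_backward(dhm, caches$head$dense)
  grads$head <- bk$grads
  dh <- array(bk$dx, d4)
  dskips <- vector("list", depth)
  for (d in seq_len(depth)) {
    cc <- caches$dec[[d]]
    drelu <- nn_relu_backward(dh, cc$relu)
    bk <- nn_conv_backward(drelu, cc$conv)
    grads$dec[[d]] <- bk$grads
    n_up <- cc$n_up
    dcat <- bk$dx
    dhu <- dcat[, , , seq_len(n_up), drop = FALSE]
    dskips[[d]] <- dcat[, , , n_up + seq_len(dim(dcat)[4] - n_up), drop = FALSE]
    dh <- nn_upsample2_backward(dhu, cc$up_in_dim)
  }
  drelu <- nn_relu_backward(dh, caches$bott$relu)
  bk <- nn_conv_backward(drelu, caches$bott$conv)
  grads$bott <- bk$grads
  dh <- bk$dx
  for (d in rev(seq_len(depth))) {
    cc <- caches$enc[[d]]
    dpost <- nn_pool2_backward(dh, cc$out_dim) + dskips[[d]]
    drelu <- nn_relu_backward(dpost, cc$relu)
    bk <- nn_conv_backward(drelu, cc$conv)
    grads$enc[[d]] <- bk$grads
    dh <- bk$dx
  }
  grads
}

## Gradient of the combined loss w.r.t. logits; per-sample Dice, batch mean.
seg_loss_grad <- function(logits, refs, alpha, smooth = 1e-6) {
  n <- dim(logits)[1]
  npix <- prod(dim(logits)[2:3])
  p <- 1 / (1 + exp(-logits))
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  dlog <- array(0, dim(logits))
  total <- 0
  for (i in seq_len(n)) {
    pi_ <- pc[i, , ]
    yi <- refs[i, , ]
    ce <- -mean(yi * log(pi_) + (1 - yi) * log(1 - pi_))
    A <- 2 * sum(pi_ * yi) + smooth
    B <- sum(pi_) + sum(yi) + smooth
    total <- total + ce + alpha * (1 - A / B)
    dce_dp <- (pi_ - yi) / (pi_ * (1 - pi_)) / npix
    ddice_dp <- -(2 * yi * B - A) / B^2
    dp <- dce_dp + alpha * ddice_dp
    dlog[i, , ] <- dp * pi_ * (1 - pi_)
  }
  list(loss = total / n, dlogits = dlog / n)
}

#' Train the tumor segmenter
#'
#' Fits the encoder-decoder network (skip connections between matching
#' encoder and decoder levels) by mini-batch Adam on the combined
#' cross-entropy + Dice loss. Each batch takes two gradient steps: one with a
#' neutral previous-mask channel (the plain forward pass) and one feeding the
#' network its own prediction back in, which trains the refinement operator
#' used by [refine_segment()].
#'
#' @param cohort an `oncosurv_cohort` (or list of samples with `image` and
#'   `mask`).
#' @param config a [segmenter_config()].
#' @return an object of class `oncosurv_segmenter` with trained parameters
#'   and the per-epoch loss history.
#' @export
train_segmenter <- function(cohort, config = segmenter_config()) {
  if (length(cohort) < 1L) stop("empty cohort")
  sizes <- vapply(cohort, function(s) dim(s$image), integer(2))
  if (length(unique(sizes[1, ])) > 1L || length(unique(sizes[2, ])) > 1L ||
      any(sizes[1, ] != sizes[2, ]))
    stop("all images must be square and of uniform size")
  n <- length(cohort)
  H <- sizes[1, 1]
  imgs <- array(0, c(n, H, H))
  refs <- array(0, c(n, H, H))
  for (i in seq_len(n)) {
    imgs[i, , ] <- cohort[[i]]$image
    refs[i, , ] <- cohort[[i]]$mask
  }
  with_seed(config$seed, {
    params <- seg_init_params(config)
    opt <- adam_init(params)
    history <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      for (bi in batches) {
        xb <- array(0, c(length(bi), H, H, 2L))
        xb[, , , 1] <- imgs[bi, , , drop = FALSE]
        xb[, , , 2] <- 0.5
        yb <- array(refs[bi, , , drop = FALSE], c(length(bi), H, H))
        fw <- seg_forward(params, xb)
        lg <- seg_loss_grad(fw$logits, yb, config$alpha_loss)
        gr <- seg_backward(params, fw$caches, lg$dlogits)
        st <- adam_step(params, gr, opt, lr = config$lr)
        params <- st$params; opt <- st$state
        ## refinement pass: previous soft mask as extra channel
        xb[, , , 2] <- 1 / (1 + exp(-fw$logits))
        fw2 <- seg_forward(params, xb)
        lg2 <- seg_loss_grad(fw2$logits, yb, config$alpha_loss)
        gr2 <- seg_backward(params, fw2$caches, lg2$dlogits)
        st <- adam_step(params, gr2, opt, lr = config$lr)
        params <- st$params; opt <- st$state
        ep_loss <- ep_loss + (lg$loss + lg2$loss) / 2 * length(bi)
      }
      history[ep] <- ep_loss / n
    }
    structure(list(params = params, config = config, history = history,
                   image_size = H, trained = TRUE),
              class = "oncosurv_segmenter")
  })
}

#' @export
print.oncosurv_segmenter <- function(x, ...) {
  cat("Encoder-decoder segmenter: depth", x$config$depth, ", base",
      x$config$base_channels, "channels,", x$image_size, "px input\n")
  cat("  final training loss:", signif(utils::tail(x$history, 1), 4), "\n")
  invisible(x)
}

#' Iteratively refine a segmentation
#'
#' Iteration 1 is the plain forward pass (neutral previous-mask channel).
#' Each later iteration feeds the image together with the previous soft mask
#' through the network and adds a `lambda_refine`-scaled correction to the
#' previous logits. The loop stops when the relative Dice improvement drops
#' below `dice_improve_tol` or the absolute loss change drops below
#' `loss_delta_tol` for `patience` consecutive iterations, or at
#' `max_iterations`. With a reference mask, Dice and loss are computed
#' against it; without one, self-consistency between consecutive soft masks
#' is used.
#'
#' @param state a trained `oncosurv_segmenter`.
#' @param image square image matrix (values in \[0, 1\]).
#' @param ref_mask optional reference binary mask.
#' @param config optional [segmenter_config()] overriding the training-time
#'   refinement settings.
#' @return an object of class `segmentation_output`: list with `soft_masks`
#'   (one probability grid per iteration), `final_mask` (binary, threshold
#'   0.5), `dice_trace`, `loss_trace`, `iterations_run` and `stop_reason`
#'   (`converged_dice`, `converged_loss` or `max_iterations`).
#' @export
refine_segment <- function(state, image, ref_mask = NULL, config = NULL) {
  if (!inherits(state, "oncosurv_segmenter") || !isTRUE(state$trained))
    stop("refine_segment requires a trained segmenter state")
  cfg <- config %||% state$config
  H <- nrow(image)
  x <- array(0, c(1L, H, H, 2L))
  x[1, , , 1] <- image
  x[1, , , 2] <- 0.5
  z <- seg_forward(state$params, x)$logits[1, , ]
  soft <- list(1 / (1 + exp(-z)))
  trace_dice <- numeric(0)
  trace_loss <- numeric(0)
  measure <- function(t) {
    st <- soft[[t]]
    if (!is.null(ref_mask)) {
      trace_dice[t] <<- dice_coefficient(matrix(as.numeric(st > 0.5), H),
                                         ref_mask)
      trace_loss[t] <<- combined_loss(st, ref_mask, cfg$alpha_loss)
    } else if (t == 1L) {
      trace_dice[t] <<- 0
      trace_loss[t] <<- Inf
    } else {
      prev <- soft[[t - 1L]]
      trace_dice[t] <<- dice_coefficient(matrix(as.numeric(st > 0.5), H),
                                         matrix(as.numeric(prev > 0.5), H))
      p <- pmin(pmax(st, 1e-7), 1 - 1e-7)
      trace_loss[t] <<- -mean(prev * log(p) + (1 - prev) * log(1 - p))
    }
  }
  measure(1L)
  stop_reason <- "max_iterations"
  below <- 0L
  t <- 1L
  while (t < cfg$max_iterations) {
    x[1, , , 2] <- soft[[t]]
    corr <- seg_forward(state$params, x)$logits[1, , ]
    z <- z + cfg$lambda_refine * corr
    t <- t + 1L
    soft[[t]] <- 1 / (1 + exp(-z))
    measure(t)
    rel_impr <- (trace_dice[t] - trace_dice[t - 1L]) /
      max(abs(trace_dice[t - 1L]), 1e-8)
    cond_dice <- is.finite(rel_impr) && rel_impr < cfg$dice_improve_tol
    dloss <- abs(trace_loss[t] - trace_loss[t - 1L])
    cond_loss <- is.finite(dloss) && dloss < cfg$loss_delta_tol
    if (cond_dice || cond_loss) {
      below <- below + 1L
      if (below >= cfg$patience) {
        stop_reason <- if (cond_dice) "converged_dice" else "converged_loss"
        break
      }
    } else below <- 0L
  }
  structure(list(soft_masks = soft,
                 final_mask = matrix(as.numeric(soft[[t]] > 0.5), H),
                 dice_trace = trace_dice, loss_trace = trace_loss,
                 iterations_run = t, stop_reason = stop_reason),
            class = "segmentation_output")
}

#' @export
print.segmentation_output <- function(x, ...) {
  cat("Segmentation:", x$iterations_run, "iteration(s), stop:",
      x$stop_reason, "\n")
  cat("  dice trace:", paste(signif(x$dice_trace, 4), collapse = " "), "\n")
  invisible(x)
}
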