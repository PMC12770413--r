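## Minimal neural-network primitives used by the segmenter, the multimodal
## classifier and the survival risk network. Everything operates on batches
## in NHWC layout (images) or N x d matrices (vectors), with hand-written
## backward passes; heavy lifting is delegated to BLAS matrix products.
## All functions are internal.

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)
}

## ---- im2col convolution (3x3, stride 1, zero padding) ----------------------

nn_conv_init <- function(cin, cout, k = 3L) {
  list(W = he_init(c(k, k, cin, cout), fan_in = k * k * cin),
       b = numeric(cout))
}

## Unfold a padded batch into the (N*H*W) x (k*k*C) patch matrix.
## Rows: sample fastest, then output position (row-major within the image
## following R's column-major array layout). Columns: kernel offset fastest
## (di before dj), then input channel -- matching matrix(W, k*k*cin, cout).
conv_im2col <- function(x, k, pad) {
  d <- dim(x); N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  xp <- array(0, c(N, Hp, Wp, C))
  xp[, (pad + 1L):(pad + H), (pad + 1L):(pad + W), ] <- x
  oi <- rep(seq_len(k), times = k); oj <- rep(seq_len(k), each = k)
  pi_ <- rep(seq_len(H), times = W); pj <- rep(seq_len(W), each = H)
  K <- k * k
  rr <- outer(oi - 1L, pi_, `+`)
  cc <- outer(oj - 1L, pj, `+`)
  idx <- rr + (cc - 1L) * Hp                      # K x (H*W), offset fastest
  xp2 <- array(xp, c(N, Hp * Wp, C))
  colarr <- xp2[, as.vector(idx), , drop = FALSE] # N x (K*HW) x C
  colarr <- array(colarr, c(N, K, H * W, C))
  colarr <- aperm(colarr, c(1L, 3L, 2L, 4L))      # N x HW x K x C
  list(mat = matrix(colarr, nrow = N * H * W), idx = idx,
       dims = c(N = N, H = H, W = W, C = C, Hp = Hp, Wp = Wp, K = K))
}

nn_conv_forward <- function(x, par, pad = 1L) {
  k <- dim(par$W)[1]
  ic <- conv_im2col(x, k, pad)
  cout <- dim(par$W)[4]
  Wmat <- matrix(par$W, nrow = k * k * dim(par$W)[3], ncol = cout)
  y <- ic$mat %*% Wmat
  y <- sweep(y, 2L, par$b, `+`)
  d <- ic$dims
  list(out = array(y, c(d[["N"]], d[["H"]], d[["W"]], cout)),
       cache = list(ic = ic, par = par, pad = pad))
}

nn_conv_backward <- function(dout, cache) {
  ic <- cache$ic; par <- cache$par; pad <- cache$pad
  d <- ic$dims
  k <- dim(par$W)[1]; cin <- dim(par$W)[3]; cout <- dim(par$W)[4]
  dY <- matrix(dout, nrow = d[["N"]] * d[["H"]] * d[["W"]], ncol = cout)
  dW <- array(crossprod(ic$mat, dY), dim = dim(par$W))
  db <- colSums(dY)
  Wmat <- matrix(par$W, nrow = k * k * cin, ncol = cout)
  dcol <- tcrossprod(dY, Wmat)                    # (N*HW) x (K*cin)
  dcolA <- array(dcol, c(d[["N"]], d[["H"]] * d[["W"]], d[["K"]], cin))
  dcolA <- aperm(dcolA, c(1L, 3L, 2L, 4L))        # N x K x HW x cin
  dxp2 <- array(0, c(d[["N"]], d[["Hp"]] * d[["Wp"]], cin))
  for (o in seq_len(d[["K"]])) {
    tgt <- ic$idx[o, ]
    dxp2[, tgt, ] <- dxp2[, tgt, ] + dcolA[, o, , ]
  }
  dxp <- array(dxp2, c(d[["N"]], d[["Hp"]], d[["Wp"]], cin))
  dx <- dxp[, (pad + 1L):(pad + d[["H"]]), (pad + 1L):(pad + d[["W"]]), ,
            drop = FALSE]
  list(dx = dx, grads = list(W = dW, b = db))
}

## ---- 2x2 average pooling and nearest-neighbour upsampling ------------------

nn_pool2_forward <- function(x) {
  d <- dim(x); N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  xr <- array(x, c(N, 2L, H %/% 2L, 2L, W %/% 2L, C))
  y <- (xr[, 1L, , 1L, , , drop = FALSE] + xr[, 2L, , 1L, , , drop = FALSE] +
        xr[, 1L, , 2L, , , drop = FALSE] + xr[, 2L, , 2L, , , drop = FALSE]) / 4
  array(y, c(N, H %/% 2L, W %/% 2L, C))
}

nn_pool2_backward <- function(dy, in_dim) {
  N <- in_dim[1]; H <- in_dim[2]; W <- in_dim[3]; C <- in_dim[4]
  dyq <- array(dy / 4, c(N, 1L, H %/% 2L, 1L, W %/% 2L, C))
  dxr <- array(0, c(N, 2L, H %/% 2L, 2L, W %/% 2L, C))
  for (a in 1:2) for (b in 1:2) dxr[, a, , b, , ] <- dyq
  array(dxr, c(N, H, W, C))
}

nn_upsample2_forward <- function(x) {
  d <- dim(x); N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  yr <- array(0, c(N, 2L, H, 2L, W, C))
  xa <- array(x, c(N, 1L, H, 1L, W, C))
  for (a in 1:2) for (b in 1:2) yr[, a, , b, , ] <- xa
  array(yr, c(N, 2L * H, 2L * W, C))
}

nn_upsample2_backward <- function(dy, in_dim) {
  N <- in_dim[1]; H <- in_dim[2]; W <- in_dim[3]; C <- in_dim[4]
  dyr <- array(dy, c(N, 2L, H, 2L, W, C))
  array(dyr[, 1L, , 1L, , ] + dyr[, 2L, , 1L, , ] +
        dyr[, 1L, , 2L, , ] + dyr[, 2L, , 2L, , ], c(N, H, W, C))
}

nn_gap_forward <- function(x) {
  d <- dim(x)
  m <- aperm(array(x, c(d[1], d[2] * d[3], d[4])), c(2L, 1L, 3L))
  colMeans(array(m, c(d[2] * d[3], d[1] * d[4]))) |>
    matrix(nrow = d[1], ncol = d[4])
}

nn_gap_backward <- function(dy, in_dim) {
  N <- in_dim[1]; H <- in_dim[2]; W <- in_dim[3]; C <- in_dim[4]
  g <- array(0, c(N, H, W, C))
  scale <- 1 / (H * W)
  for (h in seq_len(H)) for (w in seq_len(W)) g[, h, w, ] <- dy * scale
  g
}

## ---- dense layers and activations ------------------------------------------

nn_dense_init <- function(din, dout) {
  list(W = he_init(c(din, dout), fan_in = din), b = numeric(dout))
}

nn_dense_forward <- function(x, par) {
  list(out = sweep(x %*% par$W, 2L, par$b, `+`), cache = list(x = x, par = par))
}

nn_dense_backward <- function(dout, cache) {
  list(dx = tcrossprod(dout, cache$par$W),
       grads = list(W = crossprod(cache$x, dout), b = colSums(dout)))
}

nn_relu_forward <- function(x) list(out = pmax(x, 0), cache = x > 0)
nn_relu_backward <- function(dout, cache) dout * cache

nn_sigmoid_forward <- function(x) {
  s <- 1 / (1 + exp(-x))
  list(out = s, cache = s)
}
nn_sigmoid_backward <- function(dout, cache) dout * cache * (1 - cache)

## ---- Adam optimizer over arbitrarily nested parameter lists ----------------

adam_init <- function(params) {
  zero <- function(p) if (is.list(p)) lapply(p, zero) else array(0, dim = dim(p) %||% length(p))
  list(m = zero(params), v = zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      if (!is.null(names(p)) && !is.null(names(g))) g <- g[names(p)]
      out <- Map(upd, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  if (!is.null(names(params)) && !is.null(names(grads)))
    grads <- grads[names(params)]
  out <- Map(upd, params, grads, state$m, state$v)
  list(params = lapply(out, `[[`, "p"),
       state = list(m = lapply(out, `[[`, "m"), v = lapply(out, `[[`, "v"),
                    t = t))
}

## Sum two gradient structures of identical shape (used for shared params).
grad_add <- function(a, b) {
  if (is.list(a)) Map(grad_add, a, b) else a + b
}

grad_scale <- function(a, s) {
  if (is.list(a)) lapply(a, grad_scale, s = s) else a * s
}
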