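# Differentiable network primitives. Tensors are H x W x C x B arrays
# (column-major, as R stores them); images are H x W x 3 in [0, 1].
# Every *_fwd returns list(out, cache); every *_bwd consumes that cache and
# the upstream gradient and returns list(gx, grads) where grads mirrors the
# parameter list. Backward passes are verified against finite differences
# in the test suite.

as_batch <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

nn_conv_init <- function(kh, kw, cin, cout, gain = sqrt(2)) {
  list(w = array(rnorm(kh * kw * cin * cout, sd = gain / sqrt(kh * kw * cin)),
                 dim = c(kh, kw, cin, cout)),
       b = numeric(cout))
}

# im2col + BLAS matmul; the patch matrix is recomputed in the backward
# pass rather than cached, trading a cheap C++ pass for memory.
nn_conv_fwd <- function(p, x, stride = 1L, pad = 0L) {
  x <- as_batch(x)
  d <- dim(x)
  wd <- dim(p$w)
  if (wd[3] != d[3]) {
    stop(sprintf("conv2d: input has %d channels, kernel expects %d",
                 d[3], wd[3]))
  }
  cols <- im2col_cpp(x, d, wd[1], wd[2], as.integer(stride),
                     as.integer(pad))
  wm <- matrix(p$w, ncol = wd[4])               # (kh*kw*Ci) x Co
  om <- crossprod(wm, cols) + p$b               # Co x (Ho*Wo*B)
  Ho <- (d[1] + 2 * pad - wd[1]) %/% stride + 1
  Wo <- (d[2] + 2 * pad - wd[2]) %/% stride + 1
  out <- aperm(array(om, c(wd[4], Ho, Wo, d[4])), c(2, 3, 1, 4))
  list(out = out, cache = list(x = x, stride = stride, pad = pad))
}

nn_conv_bwd <- function(p, cache, gout) {
  d <- dim(cache$x)
  wd <- dim(p$w)
  gm <- matrix(aperm(gout, c(3, 1, 2, 4)), nrow = wd[4])  # Co x (Ho*Wo*B)
  cols <- im2col_cpp(cache$x, d, wd[1], wd[2], as.integer(cache$stride),
                     as.integer(cache$pad))
  gw <- array(tcrossprod(cols, gm), wd)
  gcols <- matrix(p$w, ncol = wd[4]) %*% gm
  gx <- col2im_cpp(gcols, d, wd[1], wd[2], as.integer(cache$stride),
                   as.integer(cache$pad))
  list(gx = gx, grads = list(w = gw, b = rowSums(gm)))
}

nn_relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
nn_relu_bwd <- function(cache, gout) gout * cache

# ---- batch normalization over channels of a 4-D tensor -------------------

nn_bn_init <- function(C) {
  rs <- new.env(parent = emptyenv())
  rs$mean <- numeric(C)
  rs$var <- rep(1, C)
  list(gamma = rep(1, C), beta = numeric(C), rs = rs)
}

.bn_eps <- 1e-5

# x as (M, C) matrix with per-channel columns
.bn_core_fwd <- function(p, xm, training, momentum = 0.1) {
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    p$rs$mean <- (1 - momentum) * p$rs$mean + momentum * mu
    p$rs$var <- (1 - momentum) * p$rs$var + momentum * v
  } else {
    mu <- p$rs$mean
    v <- p$rs$var
  }
  istd <- 1 / sqrt(v + .bn_eps)
  n <- nrow(xm)
  xhat <- (xm - rep(mu, each = n)) * rep(istd, each = n)
  outm <- xhat * rep(p$gamma, each = n) + rep(p$beta, each = n)
  list(out = outm, cache = list(xhat = xhat, istd = istd, training = training))
}

.bn_core_bwd <- function(p, cache, gm) {
  n <- nrow(gm)
  xhat <- cache$xhat
  ggamma <- colSums(gm * xhat)
  gbeta <- colSums(gm)
  gxhat <- gm * rep(p$gamma, each = n)
  if (cache$training) {
    gx <- (gxhat - rep(colMeans(gxhat), each = n) -
             xhat * rep(colMeans(gxhat * xhat), each = n)) *
      rep(cache$istd, each = n)
  } else {
    gx <- gxhat * rep(cache$istd, each = n)
  }
  list(gx = gx, grads = list(gamma = ggamma, beta = gbeta))
}

nn_bn_fwd <- function(p, x, training) {
  x <- as_batch(x)
  d <- dim(x)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  r <- .bn_core_fwd(p, xm, training)
  out <- aperm(array(r$out, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(out = out, cache = c(r$cache, list(d = d)))
}

nn_bn_bwd <- function(p, cache, gout) {
  d <- cache$d
  gm <- matrix(aperm(gout, c(1, 2, 4, 3)), ncol = d[3])
  r <- .bn_core_bwd(p, cache, gm)
  gx <- aperm(array(r$gx, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(gx = gx, grads = r$grads)
}

# 1-D variant for (features, batch) matrices: channels are rows.
nn_bn1d_fwd <- function(p, x, training) {
  r <- .bn_core_fwd(p, t(x), training)
  list(out = t(r$out), cache = r$cache)
}

nn_bn1d_bwd <- function(p, cache, gout) {
  r <- .bn_core_bwd(p, cache, t(gout))
  list(gx = t(r$gx), grads = r$grads)
}

# ---- linear --------------------------------------------------------------

nn_linear_init <- function(fin, fout, gain = sqrt(2)) {
  list(w = matrix(rnorm(fout * fin, sd = gain / sqrt(fin)), fout, fin),
       b = numeric(fout))
}

nn_linear_fwd <- function(p, x) {
  list(out = p$w %*% x + p$b, cache = list(x = x))
}

nn_linear_bwd <- function(p, cache, gout) {
  list(gx = crossprod(p$w, gout),
       grads = list(w = tcrossprod(gout, cache$x), b = rowSums(gout)))
}

# ---- average pooling by an integer factor --------------------------------

nn_pool_fwd <- function(x, f) {
  x <- as_batch(x)
  d <- dim(x)
  s1 <- colMeans(array(x, c(f, d[1] / f, d[2], d[3], d[4])))
  s2 <- colMeans(aperm(array(s1, c(d[1] / f, f, d[2] / f, d[3], d[4])),
                       c(2, 1, 3, 4, 5)))
  list(out = s2, cache = list(d = d, f = f))
}

nn_pool_bwd <- function(cache, gout) {
  d <- cache$d; f <- cache$f
  g <- gout / f^2
  # expand along W then H by repetition
  gw <- aperm(array(rep(aperm(g, c(2, 1, 3, 4)), each = f),
                    c(f, d[2] / f, d[1] / f, d[3], d[4])),
              c(3, 1, 2, 4, 5))
  dim(gw) <- c(d[1] / f, d[2], d[3], d[4])
  gh <- array(rep(gw, each = f), c(f, d[1] / f, d[2], d[3], d[4]))
  dim(gh) <- d
  gh
}

# Adaptive average resampling to a coarser dyadic grid (used by fusion).
nn_resample_fwd <- function(x, target_hw) {
  x <- as_batch(x)
  f <- dim(x)[1] / target_hw
  if (f == 1) return(list(out = x, cache = list(identity = TRUE)))
  stopifnot(f == round(f))
  r <- nn_pool_fwd(x, as.integer(f))
  list(out = r$out, cache = list(identity = FALSE, pool = r$cache))
}

nn_resample_bwd <- function(cache, gout) {
  if (cache$identity) return(gout)
  nn_pool_bwd(cache$pool, gout)
}

# ---- sub-pixel rearrangement (pixel shuffle), upscale factor r -----------
# Input channel co * r^2 + dh * r + dw maps to output channel co at spatial
# offset (dh, dw) inside each r x r block: the r^2 slots of one block are
# filled from consecutive input channels in row-major (dh, dw) scan order.

nn_pixel_shuffle_fwd <- function(x, r = 2L) {
  x <- as_batch(x)
  d <- dim(x)
  stopifnot(d[3] %% (r * r) == 0)
  co <- d[3] %/% (r * r)
  xr <- array(x, c(d[1], d[2], r, r, co, d[4]))   # H W dw dh co b
  xp <- aperm(xr, c(4, 1, 3, 2, 5, 6))            # dh H dw W co b
  out <- array(xp, c(d[1] * r, d[2] * r, co, d[4]))
  list(out = out, cache = list(d = d, r = r, co = co))
}

nn_pixel_shuffle_bwd <- function(cache, gout) {
  d <- cache$d; r <- cache$r
  gr <- array(gout, c(r, d[1], r, d[2], cache$co, d[4]))  # dh H dw W co b
  gx <- aperm(gr, c(2, 4, 3, 1, 5, 6))                    # H W dw dh co b
  array(gx, d)
}

# ---- global average pooling (student head) -------------------------------

nn_gap_fwd <- function(x) {
  x <- as_batch(x)
  d <- dim(x)
  xm <- matrix(aperm(x, c(3, 4, 1, 2)), nrow = d[3] * d[4])
  list(out = matrix(rowMeans(xm), d[3], d[4]), cache = list(d = d))
}

nn_gap_bwd <- function(cache, gout) {
  d <- cache$d
  g <- array(rep(as.numeric(gout), each = d[1] * d[2]) / (d[1] * d[2]), d)
  g
}

# ---- softmax / cross-entropy ---------------------------------------------

softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(z))
}

# labels: integer vector in 1..N, logits (N, B). Returns mean CE and the
# gradient w.r.t. logits.
ce_loss <- function(logits, labels) {
  p <- softmax_cols(logits)
  B <- ncol(logits)
  idx <- cbind(labels, seq_len(B))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  g <- p
  g[idx] <- g[idx] - 1
  list(loss = loss, grad = g / B)
}

mse_loss <- function(a, b) {
  d <- a - b
  list(loss = mean(d^2), grad = 2 * d / length(d))
}
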