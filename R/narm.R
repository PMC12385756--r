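#' NARM configuration
#'
#' Shapes of one Noise Adaptive Recognition Module: the ARU branch (FTM
#' feature transform, EGCP pooling, SCM classification head) and the RTU
#' branch (PRM progressive upsampling restoration plus the LFS shallow
#' supplement on the noisy input).
#'
#' @param in_channels Channels C of the tapped backbone feature.
#' @param feature_channels Channels D after the FTM (covariance size).
#' @param mid_channels FTM bottleneck width; default `feature_channels / 2`.
#' @param head_hidden Hidden width D' of the SCM head.
#' @param restore_channels Width D'' of the LFS supplement convolutions.
#' @param num_classes Number of classes N.
#' @param stage_size Spatial side of the tapped feature map.
#' @param target_size Restored image side H' = W'; must equal
#'   `stage_size * 2^upsample_stages`.
#' @return An object of class `narm_config`.
#' @export
narm_config <- function(in_channels, feature_channels, num_classes,
                        stage_size, target_size,
                        mid_channels = max(1L, feature_channels %/% 2L),
                        head_hidden = feature_channels,
                        restore_channels = 8L) {
  up <- log2(target_size / stage_size)
  if (abs(up - round(up)) > 1e-9 || up < 1) {
    stop("target_size must be stage_size times a positive power of 2")
  }
  cfg <- list(in_channels = as.integer(in_channels),
              feature_channels = as.integer(feature_channels),
              mid_channels = as.integer(mid_channels),
              head_hidden = as.integer(head_hidden),
              restore_channels = as.integer(restore_channels),
              num_classes = as.integer(num_classes),
              stage_size = as.integer(stage_size),
              target_size = as.integer(target_size),
              upsample_stages = as.integer(round(up)))
  stopifnot(all(vapply(cfg, function(v) v >= 1, logical(1))))
  structure(cfg, class = "narm_config")
}

# channel plan of the PRM chain: after each x2 shuffle channels drop by 4,
# each module's conv then sets the next width (kept a multiple of 4 while
# further shuffles remain).
prm_channel_plan <- function(cfg) {
  ch <- cfg$in_channels
  plan <- integer(0)
  for (k in seq_len(cfg$upsample_stages)) {
    if (ch %% 4L != 0L) stop("PRM input channels must be divisible by 4")
    post <- ch %/% 4L
    nxt <- if (k < cfg$upsample_stages) max(4L, 4L * (post %/% 2L)) else max(2L, post)
    plan <- c(plan, nxt)
    ch <- nxt
  }
  plan
}

init_narm <- function(cfg) {
  plan <- prm_channel_plan(cfg)
  prm <- list()
  ch <- cfg$in_channels
  for (k in seq_along(plan)) {
    prm[[paste0("m", k)]] <- nn_conv_init(3, 3, ch %/% 4L, plan[k])
    ch <- plan[k]
  }
  # restoration starts near the identity mapping: the PRM projection is
  # initialised close to zero and the LFS convolutions close to a
  # pass-through, so the initial restored image is approximately the noisy
  # input and training improves on it rather than first un-learning a
  # random restorer
  prm$out <- nn_conv_init(3, 3, ch, 3, gain = 0.05)
  lfs <- list(conv1 = nn_conv_init(3, 3, 3, cfg$restore_channels,
                                   gain = 0.05),
              conv2 = nn_conv_init(3, 3, cfg$restore_channels, 3,
                                   gain = 0.05))
  for (c in seq_len(min(3L, cfg$restore_channels))) {
    lfs$conv1$w[2, 2, c, c] <- 1
    lfs$conv2$w[2, 2, c, c] <- 1
  }
  list(
    ftm = list(conv1 = nn_conv_init(1, 1, cfg$in_channels, cfg$mid_channels),
               bn = nn_bn_init(cfg$mid_channels),
               conv2 = nn_conv_init(3, 3, cfg$mid_channels,
                                    cfg$feature_channels)),
    scm = list(fc1 = nn_linear_init(cfg$feature_channels^2, cfg$head_hidden),
               bn = nn_bn_init(cfg$head_hidden),
               fc2 = nn_linear_init(cfg$head_hidden, cfg$num_classes,
                                    gain = 1)),
    prm = prm,
    lfs = lfs
  )
}

#' Feature Transformation Module forward pass
#'
#' `conv 1x1 (C -> mid) -> BatchNorm -> ReLU -> conv 3x3 (mid -> D)`,
#' spatial size preserved.
#'
#' @param x H x W x C (x B) activation array.
#' @param cfg A [narm_config()].
#' @param params FTM parameter list (from the module initialiser).
#' @param training Logical; use batch statistics in BatchNorm when `TRUE`.
#' @return List with `out` (H x W x D x B) and a backward `cache`.
#' @export
ftm_forward <- function(x, cfg, params, training = FALSE) {
  x <- as_batch(x)
  if (dim(x)[3] != cfg$in_channels) {
    stop(sprintf("FTM expects %d input channels, got %d",
                 cfg$in_channels, dim(x)[3]))
  }
  c1 <- nn_conv_fwd(params$conv1, x, 1, 0)
  bn <- nn_bn_fwd(params$bn, c1$out, training)
  rl <- nn_relu_fwd(bn$out)
  c2 <- nn_conv_fwd(params$conv2, rl$out, 1, 1)
  list(out = c2$out, cache = list(c1 = c1$cache, bn = bn$cache,
                                  rl = rl$cache, c2 = c2$cache))
}

ftm_backward <- function(params, cache, gout) {
  b2 <- nn_conv_bwd(params$conv2, cache$c2, gout)
  gr <- nn_relu_bwd(cache$rl, b2$gx)
  bb <- nn_bn_bwd(params$bn, cache$bn, gr)
  b1 <- nn_conv_bwd(params$conv1, cache$c1, bb$gx)
  list(gx = b1$gx, grads = list(conv1 = b1$grads, bn = bb$grads,
                                conv2 = b2$grads))
}

#' Semantic Classification Module head
#'
#' Treats the flattened EGCP matrix as a D^2-channel 1 x 1 map:
#' `linear D^2 -> D' -> BatchNorm -> ReLU -> linear D' -> N` logits.
#'
#' @param A_flat Length-D^2 vector, or a D^2 x B matrix for a batch.
#' @param cfg A [narm_config()].
#' @param params SCM parameter list.
#' @param training Logical BatchNorm mode.
#' @return List with `logits` (N x B) and a backward `cache`.
#' @export
scm_classify <- function(A_flat, cfg, params, training = FALSE) {
  if (is.null(dim(A_flat))) A_flat <- matrix(A_flat, ncol = 1)
  if (nrow(A_flat) != cfg$feature_channels^2) {
    stop(sprintf("SCM expects input length %d, got %d",
                 cfg$feature_channels^2, nrow(A_flat)))
  }
  f1 <- nn_linear_fwd(params$fc1, A_flat)
  bn <- nn_bn1d_fwd(params$bn, f1$out, training)
  rl <- nn_relu_fwd(bn$out)
  f2 <- nn_linear_fwd(params$fc2, rl$out)
  list(logits = f2$out, cache = list(f1 = f1$cache, bn = bn$cache,
                                     rl = rl$cache, f2 = f2$cache))
}

scm_backward <- function(params, cache, gout) {
  b2 <- nn_linear_bwd(params$fc2, cache$f2, gout)
  gr <- nn_relu_bwd(cache$rl, b2$gx)
  bb <- nn_bn1d_bwd(params$bn, cache$bn, gr)
  b1 <- nn_linear_bwd(params$fc1, cache$f1, bb$gx)
  list(gx = b1$gx, grads = list(fc1 = b1$grads, bn = bb$grads,
                                fc2 = b2$grads))
}

#' Restorative Transformation Unit
#'
#' PRM: a chain of `ReLU(Conv(PixelShuffle(x)))` x2 upsampling modules from
#' the tapped stage feature up to the image resolution, then a 3x3
#' projection to 3 channels (no ReLU). LFS: two 3x3 convolutions
#' (3 -> D'' -> 3) on the noisy input image. The restored image is their
#' pixel-wise sum.
#'
#' @param x Tapped stage feature, H x W x C (x B).
#' @param I_noisy Noisy input image(s), H' x W' x 3 (x B).
#' @param cfg A [narm_config()].
#' @param params RTU parameters (`prm`, `lfs`).
#' @return List with `I_PRM`, `I_LFS`, `I_restored` (each H' x W' x 3 x B)
#'   and a backward `cache`.
#' @export
rtu_restore <- function(x, I_noisy, cfg, params) {
  x <- as_batch(x)
  I_noisy <- as_batch(I_noisy)
  if (dim(x)[1] * 2^cfg$upsample_stages != cfg$target_size) {
    stop("stage size times 2^upsample_stages must equal target_size")
  }
  caches <- list()
  h <- x
  for (k in seq_len(cfg$upsample_stages)) {
    ps <- nn_pixel_shuffle_fwd(h, 2L)
    cv <- nn_conv_fwd(params$prm[[paste0("m", k)]], ps$out, 1, 1)
    rl <- nn_relu_fwd(cv$out)
    caches[[k]] <- list(ps = ps$cache, cv = cv$cache, rl = rl$cache)
    h <- rl$out
  }
  po <- nn_conv_fwd(params$prm$out, h, 1, 1)
  I_PRM <- po$out
  l1 <- nn_conv_fwd(params$lfs$conv1, I_noisy, 1, 1)
  l2 <- nn_conv_fwd(params$lfs$conv2, l1$out, 1, 1)
  I_LFS <- l2$out
  if (!identical(dim(I_PRM), dim(I_LFS))) {
    stop("PRM and LFS outputs disagree in shape")
  }
  list(I_PRM = I_PRM, I_LFS = I_LFS, I_restored = I_PRM + I_LFS,
       cache = list(mods = caches, po = po$cache, l1 = l1$cache,
                    l2 = l2$cache, n_up = cfg$upsample_stages))
}

rtu_backward <- function(params, cache, g_restored) {
  # LFS path (gradient does not reach the backbone)
  bl2 <- nn_conv_bwd(params$lfs$conv2, cache$l2, g_restored)
  bl1 <- nn_conv_bwd(params$lfs$conv1, cache$l1, bl2$gx)
  # PRM path
  bpo <- nn_conv_bwd(params$prm$out, cache$po, g_restored)
  g <- bpo$gx
  prm_grads <- list()
  for (k in rev(seq_len(cache$n_up))) {
    cc <- cache$mods[[k]]
    gr <- nn_relu_bwd(cc$rl, g)
    bcv <- nn_conv_bwd(params$prm[[paste0("m", k)]], cc$cv, gr)
    prm_grads[[paste0("m", k)]] <- bcv$grads
    g <- nn_pixel_shuffle_bwd(cc$ps, bcv$gx)
  }
  prm_grads$out <- bpo$grads
  list(gx = g, grads = list(prm = prm_grads,
                            lfs = list(conv1 = bl1$grads, conv2 = bl2$grads)))
}

#' Full NARM forward pass
#'
#' Runs both branches from the same tapped feature: ARU
#' (`ftm_forward` -> `egcp_transform` -> `scm_classify`) for class logits
#' and RTU (`rtu_restore`) for the restored image.
#'
#' @inheritParams rtu_restore
#' @param ecfg An [egcp_config()].
#' @param training Logical BatchNorm mode.
#' @return List with `logits`, the image triplet fields of [rtu_restore()],
#'   and a backward `cache`.
#' @export
narm_forward <- function(x, I_noisy, cfg, params, ecfg = egcp_config(),
                         training = FALSE) {
  ftm <- ftm_forward(x, cfg, params$ftm, training)
  eg <- egcp_fwd(ftm$out, ecfg)
  scm <- scm_classify(eg$out, cfg, params$scm, training)
  rtu <- rtu_restore(x, I_noisy, cfg, params)
  list(logits = scm$logits, I_PRM = rtu$I_PRM, I_LFS = rtu$I_LFS,
       I_restored = rtu$I_restored,
       cache = list(ftm = ftm$cache, eg = eg$cache, scm = scm$cache,
                    rtu = rtu$cache))
}

# Backward of the full module given gradients on logits and restored image.
# Returns the gradient w.r.t. the tapped stage feature plus parameter grads.
narm_backward <- function(params, cfg, cache, g_logits, g_restored) {
  bs <- scm_backward(params$scm, cache$scm, g_logits)
  g_d2 <- egcp_bwd(cache$eg, bs$gx)
  bf <- ftm_backward(params$ftm, cache$ftm, g_d2)
  br <- rtu_backward(params, cache$rtu, g_restored)
  list(gx = bf$gx + br$gx,
       grads = list(ftm = bf$grads, scm = bs$grads,
                    prm = br$grads$prm, lfs = br$grads$lfs))
}

#' NARM joint loss
#'
#' `L_rec` is the softmax cross-entropy of the logits against the labels;
#' `L_mse` the mean squared pixel error between restored and clean images;
#' `L_NARM = alpha * L_rec + beta * L_mse`.
#'
#' @param p Logits, length-N vector or N x B matrix.
#' @param label Integer class labels in `1..N` (length B).
#' @param I_restored,I_clean Image arrays of identical shape.
#' @param alpha,beta Balancing weights; defaults follow the loss-weight
#'   sensitivity analysis (0.6 / 0.4).
#' @return List of class `narm_loss_bundle` with `L_rec`, `L_mse`, `alpha`,
#'   `beta`, `L_NARM`, and gradients `g_logits`, `g_restored` of `L_NARM`.
#' @export
narm_loss <- function(p, label, I_restored, I_clean, alpha = 0.6,
                      beta = 0.4) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 1)
  if (any(label < 1 | label > nrow(p))) {
    stop(sprintf("labels must lie in 1..%d", nrow(p)))
  }
  if (!identical(dim(as_batch(I_restored)), dim(as_batch(I_clean)))) {
    stop("restored and clean images must share a shape")
  }
  ce <- ce_loss(p, as.integer(label))
  ms <- mse_loss(as_batch(I_restored), as_batch(I_clean))
  structure(list(L_rec = ce$loss, L_mse = ms$loss, alpha = alpha,
                 beta = beta,
                 L_NARM = alpha * ce$loss + beta * ms$loss,
                 g_logits = alpha * ce$grad, g_restored = beta * ms$grad),
            class = "narm_loss_bundle")
}
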