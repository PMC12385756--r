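#' Fusion configuration
#'
#' Weights and projection width for Weighted Multi-Granularity Fusion:
#' `x* = sum_i beta_i * proj_i(x_i)` over the tapped backbone stages,
#' after 1x1 projection to a common width and average-resampling to the
#' deepest tapped grid.
#'
#' @param betas Nonnegative stage weights, shallow to deep. The default
#'   (0.2, 0.35, 0.45) favours deeper stages and sums to 1.
#' @param projection_channels Common channel width after projection.
#' @return Object of class `fusion_config`.
#' @export
fusion_config <- function(betas = c(0.2, 0.35, 0.45),
                          projection_channels = 32L) {
  if (any(betas < 0)) stop("fusion betas must be nonnegative")
  structure(list(betas = betas,
                 projection_channels = as.integer(projection_channels)),
            class = "fusion_config")
}

#' Training configuration
#'
#' @param lr0 Initial learning rate (SGD). Default 0.002.
#' @param epochs Number of epochs.
#' @param batch_size Minibatch size. Default 32.
#' @param momentum SGD momentum. Default 0.9.
#' @param horizon Cosine annealing horizon in epochs (default `epochs`).
#' @param lr_floor Final learning rate of the cosine schedule.
#' @param seed Root seed for parameter init, shuffling and noise draws.
#' @param alpha,beta NARM loss weights (classification / restoration).
#' @param stop_at_train_acc Optional early stop once training top-1 reaches
#'   this fraction.
#' @return Object of class `train_config`.
#' @export
train_config <- function(lr0 = 0.002, epochs = 30L, batch_size = 32L,
                         momentum = 0.9, horizon = epochs, lr_floor = 0,
                         seed = 1L, alpha = 0.6, beta = 0.4,
                         stop_at_train_acc = NULL) {
  stopifnot(lr0 > 0, epochs >= 1)
  structure(list(lr0 = lr0, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), momentum = momentum,
                 horizon = horizon, lr_floor = lr_floor,
                 seed = as.integer(seed), alpha = alpha, beta = beta,
                 stop_at_train_acc = stop_at_train_acc),
            class = "train_config")
}

#' Cosine annealing learning rate
#'
#' `lr(t) = floor + (lr0 - floor)/2 * (1 + cos(pi t / horizon))`.
#'
#' @param t Epoch in `[0, horizon]`.
#' @param tc A [train_config()].
#' @return The learning rate at epoch `t`.
#' @export
cosine_lr <- function(t, tc) {
  if (t < 0 || t > tc$horizon) stop("epoch out of schedule range")
  tc$lr_floor + 0.5 * (tc$lr0 - tc$lr_floor) * (1 + cos(pi * t / tc$horizon))
}

# internal config for a fusion ARU head (FTM + EGCP + SCM, no RTU)
aru_config <- function(in_channels, feature_channels, num_classes,
                       stage_size, head_hidden = feature_channels) {
  narm_config(in_channels = in_channels,
              feature_channels = feature_channels,
              num_classes = num_classes, stage_size = stage_size,
              target_size = stage_size * 2L, head_hidden = head_hidden)
}

#' Assemble a teacher model
#'
#' Builds the full architecture: a stage-tapped backbone, one NARM per
#' tapped stage (restoring to the input resolution), and the fusion head
#' (per-stage 1x1 projections plus a fusion ARU).
#'
#' @param spec A [backbone_spec()].
#' @param num_classes Number of classes.
#' @param image_size Input image side (square images).
#' @param feature_channels EGCP channel count D inside every ARU.
#' @param fc A [fusion_config()]; `betas` must have one entry per tap.
#' @param ecfg An [egcp_config()].
#' @param restore_channels LFS width D'' of every NARM.
#' @return Object of class `narm_teacher`.
#' @export
init_teacher_model <- function(spec, num_classes, image_size,
                               feature_channels = 16L,
                               fc = NULL, ecfg = egcp_config(),
                               restore_channels = 8L) {
  S <- length(spec$taps)
  if (is.null(fc)) {
    betas <- if (S == 3L) c(0.2, 0.35, 0.45) else seq_len(S) / sum(seq_len(S))
    fc <- fusion_config(betas = betas,
                        projection_channels = spec$channels[max(spec$taps)])
  }
  if (length(fc$betas) != S) stop("need one fusion beta per tapped stage")
  narm_cfgs <- lapply(spec$taps, function(s) {
    narm_config(in_channels = spec$channels[s],
                feature_channels = feature_channels,
                num_classes = num_classes,
                stage_size = stage_side(spec, s, image_size),
                target_size = image_size,
                restore_channels = restore_channels)
  })
  deep_side <- stage_side(spec, max(spec$taps), image_size)
  acfg <- aru_config(fc$projection_channels, feature_channels, num_classes,
                     deep_side)
  params <- list(
    backbone = init_backbone(spec),
    narms = lapply(narm_cfgs, init_narm),
    fusion = list(
      proj = lapply(spec$taps, function(s) {
        nn_conv_init(1, 1, spec$channels[s], fc$projection_channels)
      }),
      aru = list(ftm = init_narm(acfg)$ftm, scm = init_narm(acfg)$scm)
    )
  )
  audit <- new.env(parent = emptyenv())
  audit$backwards <- character(0)
  structure(list(spec = spec, image_size = as.integer(image_size),
                 num_classes = as.integer(num_classes),
                 feature_channels = as.integer(feature_channels),
                 narm_cfgs = narm_cfgs, aru_cfg = acfg, fusion_cfg = fc,
                 ecfg = ecfg, params = params, audit = audit),
            class = "narm_teacher")
}

record_backward <- function(model, label) {
  model$audit$backwards <- c(model$audit$backwards, label)
  invisible(NULL)
}

#' Weighted multi-granularity feature fusion
#'
#' Projects each tapped stage feature to a common width with a 1x1
#' convolution, average-resamples to the deepest tapped grid, and forms the
#' weighted sum `x* = sum_i beta_i x_i'`.
#'
#' @param feats List of stage feature arrays, shallow to deep.
#' @param fc A [fusion_config()] with `length(feats)` betas.
#' @param params List of 1x1 projection conv parameters (same length);
#'   `NULL` entries mean identity (features already at the common width).
#' @return List with the fused map `out` and a backward `cache`.
#' @export
fuse_features <- function(feats, fc, params = NULL) {
  S <- length(feats)
  if (length(fc$betas) != S) stop("need one beta per stage feature")
  feats <- lapply(feats, as_batch)
  target <- min(vapply(feats, function(f) dim(f)[1], numeric(1)))
  out <- NULL
  caches <- vector("list", S)
  for (i in seq_len(S)) {
    h <- feats[[i]]
    pc <- NULL
    if (!is.null(params) && !is.null(params[[i]])) {
      cv <- nn_conv_fwd(params[[i]], h, 1, 0)
      h <- cv$out
      pc <- cv$cache
    }
    rs <- nn_resample_fwd(h, target)
    caches[[i]] <- list(proj = pc, rs = rs$cache)
    contrib <- fc$betas[i] * rs$out
    out <- if (is.null(out)) contrib else out + contrib
  }
  list(out = out, cache = list(caches = caches, betas = fc$betas))
}

fuse_backward <- function(params, cache, gout) {
  S <- length(cache$caches)
  gfeats <- vector("list", S)
  pgrads <- vector("list", S)
  for (i in seq_len(S)) {
    g <- cache$betas[i] * nn_resample_bwd(cache$caches[[i]]$rs, gout)
    if (!is.null(params) && !is.null(params[[i]])) {
      b <- nn_conv_bwd(params[[i]], cache$caches[[i]]$proj, g)
      g <- b$gx
      pgrads[[i]] <- b$grads
    }
    gfeats[[i]] <- g
  }
  list(gfeats = gfeats, pgrads = pgrads)
}

# fusion ARU forward: FTM -> EGCP -> SCM on the fused map
aru_forward <- function(x, cfg, params, ecfg, training = FALSE) {
  ftm <- ftm_forward(x, cfg, params$ftm, training)
  eg <- egcp_fwd(ftm$out, ecfg)
  scm <- scm_classify(eg$out, cfg, params$scm, training)
  list(logits = scm$logits,
       cache = list(ftm = ftm$cache, eg = eg$cache, scm = scm$cache))
}

aru_backward <- function(params, cache, g_logits) {
  bs <- scm_backward(params$scm, cache$scm, g_logits)
  gd <- egcp_bwd(cache$eg, bs$gx)
  bf <- ftm_backward(params$ftm, cache$ftm, gd)
  list(gx = bf$gx, grads = list(ftm = bf$grads, scm = bs$grads))
}

# ---- SGD with momentum ---------------------------------------------------

sgd_init <- function(params) nl_zero_like(params)

sgd_step <- function(params, grads, velocity, lr, momentum) {
  velocity <- nl_map2(velocity, grads, function(v, g) momentum * v + g)
  params <- nl_map2(params, velocity, function(p, v) p - lr * v)
  list(params = params, velocity = velocity)
}

#' One WMF training step (Algorithm of the S+1-step procedure)
#'
#' For each of the S NARMs in stage order, computes
#' `L_NARM(i) = alpha L_rec(i) + beta L_mse(i)` and backpropagates it; then
#' computes the fused-head classification loss `L_cls` on
#' `x* = sum beta_i x_i` and backpropagates it. Gradients from all S+1
#' backward passes are accumulated and a single SGD update is applied.
#'
#' @param batch List with `x` (noisy input images, H x W x 3 x B), `clean`
#'   (targets for restoration) and `labels` (integers in 1..N).
#' @param model A [init_teacher_model()] teacher.
#' @param tc A [train_config()].
#' @param opt Optimizer state (`sgd_init(model$params)` at first call).
#' @param lr Learning rate for this step.
#' @return List with updated `model`, `opt`, and the ordered numeric vector
#'   `losses` (`L_NARM_1..S`, `L_cls`).
#' @export
wmf_train_step <- function(batch, model, tc, opt, lr = tc$lr0) {
  S <- length(model$spec$taps)
  fwd <- backbone_forward(model$params$backbone, model$spec, batch$x,
                          training = TRUE)
  total <- NULL
  losses <- numeric(0)
  # S per-NARM passes
  for (i in seq_len(S)) {
    s <- model$spec$taps[i]
    nf <- narm_forward(fwd$stages[[s]], batch$x, model$narm_cfgs[[i]],
                       model$params$narms[[i]], model$ecfg, training = TRUE)
    lb <- narm_loss(nf$logits, batch$labels, nf$I_restored, batch$clean,
                    tc$alpha, tc$beta)
    if (!is.finite(lb$L_NARM)) {
      stop(sprintf("non-finite loss in NARM step %d", i))
    }
    nb <- narm_backward(model$params$narms[[i]], model$narm_cfgs[[i]],
                        nf$cache, lb$g_logits, lb$g_restored)
    sg <- vector("list", length(model$spec$channels))
    sg[[s]] <- nb$gx
    bb <- backbone_backward(model$params$backbone, model$spec, fwd$cache, sg)
    gtree <- list(backbone = bb$grads,
                  narms = local({ l <- vector("list", S); l[[i]] <- nb$grads; l }))
    total <- nl_add(total, gtree)
    losses <- c(losses, lb$L_NARM)
    record_backward(model, paste0("narm_", i))
  }
  # fusion pass
  fu <- fuse_features(fwd$stages[model$spec$taps], model$fusion_cfg,
                      model$params$fusion$proj)
  ar <- aru_forward(fu$out, model$aru_cfg, model$params$fusion$aru,
                    model$ecfg, training = TRUE)
  ce <- ce_loss(ar$logits, batch$labels)
  if (!is.finite(ce$loss)) stop("non-finite loss in fusion step")
  ab <- aru_backward(model$params$fusion$aru, ar$cache, ce$grad)
  fb <- fuse_backward(model$params$fusion$proj, fu$cache, ab$gx)
  sg <- vector("list", length(model$spec$channels))
  for (i in seq_len(S)) sg[[model$spec$taps[i]]] <- fb$gfeats[[i]]
  bb <- backbone_backward(model$params$backbone, model$spec, fwd$cache, sg)
  total <- nl_add(total, list(backbone = bb$grads,
                              fusion = list(proj = fb$pgrads,
                                            aru = ab$grads)))
  losses <- c(losses, ce$loss)
  record_backward(model, "fusion")
  # single optimizer update
  st <- sgd_step(model$params, total, opt, lr, tc$momentum)
  model$params <- st$params
  list(model = model, opt = st$velocity, losses = losses)
}

# forward-only fused prediction; returns fused logits and per-NARM logits
predict_teacher <- function(model, x, chunk = 32L) {
  x <- as_batch(x)
  B <- dim(x)[4]
  S <- length(model$spec$taps)
  fused <- matrix(0, model$num_classes, B)
  stage_logits <- lapply(seq_len(S), function(i) matrix(0, model$num_classes, B))
  for (from in seq(1, B, by = chunk)) {
    to <- min(from + chunk - 1L, B)
    xb <- x[, , , from:to, drop = FALSE]
    fwd <- backbone_forward(model$params$backbone, model$spec, xb, FALSE)
    for (i in seq_len(S)) {
      s <- model$spec$taps[i]
      ftm <- ftm_forward(fwd$stages[[s]], model$narm_cfgs[[i]],
                         model$params$narms[[i]]$ftm, FALSE)
      eg <- egcp_fwd(ftm$out, model$ecfg)
      sc <- scm_classify(eg$out, model$narm_cfgs[[i]],
                         model$params$narms[[i]]$scm, FALSE)
      stage_logits[[i]][, from:to] <- sc$logits
    }
    fu <- fuse_features(fwd$stages[model$spec$taps], model$fusion_cfg,
                        model$params$fusion$proj)
    ar <- aru_forward(fu$out, model$aru_cfg, model$params$fusion$aru,
                      model$ecfg, FALSE)
    fused[, from:to] <- ar$logits
  }
  list(logits = fused, stage_logits = stage_logits)
}

#' Restore images through a trained NARM
#'
#' Runs the restoration branch (PRM + LFS) of one NARM on a batch of
#' (typically noisy) images. Outputs are clamped to [0, 1] by default, as
#' at evaluation time; the training loss itself uses unclamped values.
#'
#' @param model A trained `narm_teacher`.
#' @param x Image array, H x W x 3 (x B).
#' @param which Index of the NARM (1 = shallowest tapped stage).
#' @param chunk Minibatch size for inference.
#' @param clamp Clamp outputs to the valid pixel range.
#' @return Restored images, H x W x 3 x B.
#' @export
restore_images <- function(model, x, which = 1L, chunk = 16L,
                           clamp = TRUE) {
  x <- as_batch(x)
  B <- dim(x)[4]
  out <- NULL
  for (from in seq(1, B, by = chunk)) {
    to <- min(from + chunk - 1L, B)
    xb <- x[, , , from:to, drop = FALSE]
    fwd <- backbone_forward(model$params$backbone, model$spec, xb, FALSE)
    s <- model$spec$taps[which]
    rt <- rtu_restore(fwd$stages[[s]], xb, model$narm_cfgs[[which]],
                      model$params$narms[[which]])
    if (is.null(out)) out <- array(0, c(dim(rt$I_restored)[1:3], B))
    out[, , , from:to] <- rt$I_restored
  }
  if (clamp) out <- pmin(pmax(out, 0), 1)
  out
}

#' Train a teacher model with the S+1-step WMF procedure
#'
#' SGD with momentum under a cosine learning-rate schedule. Training images
#' are the (optionally noise-injected) inputs; clean images are the
#' restoration targets. Per-epoch records include every loss, the fused
#' train/validation top-1, and the per-NARM validation accuracies p_i.
#'
#' @param data A loaded dataset from [load_dataset()].
#' @param model A [init_teacher_model()] teacher.
#' @param tc A [train_config()].
#' @param noise A [noise_spec()] applied to training inputs only (clean
#'   targets and evaluation splits stay untouched), or `NULL` for none.
#' @param stop_check Optional `function(model, row)` evaluated after each
#'   epoch; returning `TRUE` stops training early.
#' @return List with the trained `model`, optimizer state, and the `log`
#'   data frame.
#' @export
train_teacher <- function(data, model, tc, noise = NULL,
                          stop_check = NULL) {
  n_train <- sum(data$split == "train")
  if (n_train == 0) stop("dataset has no training images")
  set.seed(tc$seed)
  idx_train <- which(data$split == "train")
  clean <- data$images[, , , idx_train, drop = FALSE]
  xin <- clean
  if (!is.null(noise) && noise$sigma > 0) {
    xin <- inject_gaussian_noise(clean, noise)
  }
  labels <- data$labels[idx_train]
  S <- length(model$spec$taps)
  opt <- sgd_init(model$params)
  log <- NULL
  for (epoch in seq_len(tc$epochs)) {
    lr <- cosine_lr(epoch - 1, tc)
    ord <- sample(n_train)
    loss_acc <- numeric(S + 1)
    nb <- 0
    for (from in seq(1, n_train, by = tc$batch_size)) {
      to <- min(from + tc$batch_size - 1L, n_train)
      sel <- ord[from:to]
      batch <- list(x = xin[, , , sel, drop = FALSE],
                    clean = clean[, , , sel, drop = FALSE],
                    labels = labels[sel])
      st <- wmf_train_step(batch, model, tc, opt, lr)
      model <- st$model
      opt <- st$opt
      loss_acc <- loss_acc + st$losses
      nb <- nb + 1
    }
    tr <- predict_teacher(model, xin)
    train_top1 <- mean(apply(tr$logits, 2, which.max) == labels)
    row <- data.frame(epoch = epoch, lr = lr,
                      t(setNames(loss_acc / nb,
                                 c(paste0("L_NARM_", seq_len(S)), "L_cls"))),
                      train_top1 = train_top1)
    idx_val <- which(data$split == "val")
    if (length(idx_val)) {
      pv <- predict_teacher(model, data$images[, , , idx_val, drop = FALSE])
      row$val_top1 <- mean(apply(pv$logits, 2, which.max) ==
                             data$labels[idx_val])
      for (i in seq_len(S)) {
        row[[paste0("p", i)]] <- mean(apply(pv$stage_logits[[i]], 2,
                                            which.max) == data$labels[idx_val])
      }
    }
    log <- rbind(log, row)
    if (!is.null(tc$stop_at_train_acc) &&
        train_top1 >= tc$stop_at_train_acc) break
    if (!is.null(stop_check) && isTRUE(stop_check(model, row))) break
  }
  list(model = model, opt = opt, log = log)
}
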