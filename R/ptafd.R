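#' Distillation configuration
#'
#' @param alpha Weight of the distillation term in
#'   `L = alpha * L_distillation + (1 - alpha) * L_student`; default 0.5.
#' @param T_start,T_end Temperature schedule endpoints for the distillation
#'   phase. The default rises from 0.5 (sharp, high-confidence teacher
#'   labels early) to 2.0 (smoothed labels exposing inter-class structure
#'   late); set `T_start > T_end` for the falling variant.
#' @param phase_1_epochs Distillation-phase epochs.
#' @param phase_2_epochs Plain cross-entropy fine-tuning epochs.
#' @param feature_align_weight Weight of the per-stage feature alignment
#'   term (0 disables it).
#' @return Object of class `distill_config`.
#' @export
distill_config <- function(alpha = 0.5, T_start = 0.5, T_end = 2.0,
                           phase_1_epochs = 8L, phase_2_epochs = 2L,
                           feature_align_weight = 0.1) {
  stopifnot(alpha >= 0, alpha <= 1, T_start > 0, T_end > 0,
            phase_1_epochs >= 0, phase_2_epochs >= 0,
            feature_align_weight >= 0)
  structure(list(alpha = alpha, T_start = T_start, T_end = T_end,
                 phase_1_epochs = as.integer(phase_1_epochs),
                 phase_2_epochs = as.integer(phase_2_epochs),
                 feature_align_weight = feature_align_weight),
            class = "distill_config")
}

#' Temperature-scaled softmax
#'
#' `softmax(logits / T)`: temperatures below 1 sharpen the distribution,
#' above 1 smooth it.
#'
#' @param logits Numeric vector or K x B matrix.
#' @param T Positive temperature.
#' @return Probabilities of the same shape (columns sum to 1).
#' @export
soften_logits <- function(logits, T = 1) {
  if (T <= 0) stop("temperature must be positive")
  v <- is.null(dim(logits))
  z <- if (v) matrix(logits, ncol = 1) else logits
  p <- softmax_cols(z / T)
  if (v) as.numeric(p) else p
}

#' Soft-label distillation loss
#'
#' `-sum_i yhat_teacher,i * log(yhat_student,i)` with both distributions
#' softened at the same temperature (mean over a batch). No T^2
#' compensation factor is applied.
#'
#' @param teacher_logits,student_logits Equal-shaped logit vectors or
#'   K x B matrices.
#' @param T Positive temperature.
#' @return List with `loss` and `grad` (gradient w.r.t. student logits).
#' @export
distillation_loss <- function(teacher_logits, student_logits, T = 1) {
  if (!identical(dim(teacher_logits) %||% length(teacher_logits),
                 dim(student_logits) %||% length(student_logits))) {
    stop("teacher and student logits must have matching shapes")
  }
  tl <- if (is.null(dim(teacher_logits))) matrix(teacher_logits, ncol = 1)
        else teacher_logits
  sl <- if (is.null(dim(student_logits))) matrix(student_logits, ncol = 1)
        else student_logits
  pt <- soften_logits(tl, T)
  ps <- soften_logits(sl, T)
  B <- ncol(sl)
  loss <- -sum(pt * log(pmax(ps, 1e-12))) / B
  grad <- (ps - pt) / (T * B)
  list(loss = loss, grad = grad)
}

#' Combined distillation objective
#'
#' `L_student` is the plain (T = 1) cross-entropy of the student against
#' the hard labels; `L_total = alpha * L_distillation + (1 - alpha) *
#' L_student`.
#'
#' @param teacher_logits,student_logits K x B logit matrices (or vectors).
#' @param y Integer labels in 1..K.
#' @param dc A [distill_config()].
#' @param T Temperature for the distillation term.
#' @return List of class `distill_loss_bundle` with `L_distillation`,
#'   `L_student`, `L_total` and `grad` (w.r.t. student logits).
#' @export
combined_loss <- function(teacher_logits, student_logits, y, dc, T = 1) {
  sl <- if (is.null(dim(student_logits))) matrix(student_logits, ncol = 1)
        else student_logits
  if (any(y < 1 | y > nrow(sl))) stop("labels out of range")
  dl <- distillation_loss(teacher_logits, student_logits, T)
  ce <- ce_loss(sl, as.integer(y))
  structure(list(L_distillation = dl$loss, L_student = ce$loss,
                 L_total = dc$alpha * dl$loss + (1 - dc$alpha) * ce$loss,
                 grad = dc$alpha * dl$grad + (1 - dc$alpha) * ce$grad),
            class = "distill_loss_bundle")
}

#' Temperature schedule
#'
#' Piecewise-linear from `T_start` (epoch 0) to `T_end` (last
#' distillation-phase epoch); constant 1 during the fine-tuning phase.
#' Clamped at the phase boundaries.
#'
#' @param epoch Zero-based epoch.
#' @param dc A [distill_config()].
#' @return The temperature.
#' @export
temperature_at <- function(epoch, dc) {
  if (dc$phase_1_epochs <= 0) return(1)
  if (epoch >= dc$phase_1_epochs) return(1)
  frac <- if (dc$phase_1_epochs == 1L) 1 else
    min(1, max(0, epoch / (dc$phase_1_epochs - 1)))
  dc$T_start + frac * (dc$T_end - dc$T_start)
}

# L2-normalize a flattened tensor; returns value and a closure-free cache
l2n <- function(v) {
  n <- sqrt(sum(v^2))
  list(out = if (n > 0) v / n else v, norm = n)
}

#' Per-stage feature alignment loss
#'
#' Mean over stages of the MSE between teacher and student stage features
#' after (optional) 1x1 projection of the student to the teacher width and
#' global L2 normalization of both, making the distance scale-invariant.
#'
#' @param teacher_stage_feats,student_stage_feats Lists (equal length) of
#'   stage feature arrays.
#' @param proj Optional list of 1x1 conv parameters projecting each student
#'   stage to the teacher width; `NULL` entries mean identity.
#' @return List with `loss`, per-stage gradients `gfeats` (w.r.t. student
#'   features) and `pgrads` (w.r.t. projections).
#' @export
feature_alignment_loss <- function(teacher_stage_feats, student_stage_feats,
                                   proj = NULL) {
  S <- length(teacher_stage_feats)
  if (length(student_stage_feats) != S) {
    stop("teacher and student must expose the same number of stages")
  }
  loss <- 0
  gfeats <- vector("list", S)
  pgrads <- vector("list", S)
  for (i in seq_len(S)) {
    tf <- as_batch(teacher_stage_feats[[i]])
    sf <- as_batch(student_stage_feats[[i]])
    pc <- NULL
    h <- sf
    if (!is.null(proj) && !is.null(proj[[i]])) {
      cv <- nn_conv_fwd(proj[[i]], sf, 1, 0)
      h <- cv$out
      pc <- cv$cache
    }
    if (!identical(dim(h), dim(tf))) {
      stop("stage feature shapes disagree after projection")
    }
    tn <- l2n(tf)
    sn <- l2n(h)
    d <- sn$out - tn$out
    loss <- loss + mean(d^2)
    g <- 2 * d / length(d)                       # d loss_i / d sn$out
    gh <- if (sn$norm > 0) {
      (g - sn$out * sum(sn$out * g)) / sn$norm
    } else g
    if (!is.null(pc)) {
      b <- nn_conv_bwd(proj[[i]], pc, gh)
      gfeats[[i]] <- b$gx / S
      pgrads[[i]] <- nl_map(b$grads, function(x) x / S)
    } else {
      gfeats[[i]] <- gh / S
    }
  }
  list(loss = loss / S, gfeats = gfeats, pgrads = pgrads)
}

# ---- student model -------------------------------------------------------

#' Assemble a plain student model
#'
#' A conventional backbone of the same family as the teacher, followed by
#' global average pooling and a linear classifier.
#'
#' @param spec A [backbone_spec()] (same stage count as the teacher).
#' @param num_classes Number of classes.
#' @return Object of class `narm_student`.
#' @export
init_student_model <- function(spec, num_classes) {
  params <- list(backbone = init_backbone(spec),
                 head = nn_linear_init(spec$channels[length(spec$channels)],
                                       num_classes, gain = 1))
  structure(list(spec = spec, num_classes = as.integer(num_classes),
                 params = params),
            class = "narm_student")
}

student_forward <- function(model, x, training = FALSE) {
  fwd <- backbone_forward(model$params$backbone, model$spec, x, training)
  deep <- fwd$stages[[length(model$spec$channels)]]
  gp <- nn_gap_fwd(deep)
  hd <- nn_linear_fwd(model$params$head, gp$out)
  list(logits = hd$out, stages = fwd$stages,
       cache = list(bb = fwd$cache, gap = gp$cache, head = hd$cache))
}

student_backward <- function(model, cache, g_logits, stage_grads = NULL) {
  bh <- nn_linear_bwd(model$params$head, cache$head, g_logits)
  gdeep <- nn_gap_bwd(cache$gap, bh$gx)
  n <- length(model$spec$channels)
  sg <- stage_grads %||% vector("list", n)
  sg[[n]] <- if (is.null(sg[[n]])) gdeep else sg[[n]] + gdeep
  bb <- backbone_backward(model$params$backbone, model$spec, cache$bb, sg)
  list(grads = list(backbone = bb$grads, head = bh$grads))
}

predict_student <- function(model, x, chunk = 64L) {
  x <- as_batch(x)
  B <- dim(x)[4]
  out <- matrix(0, model$num_classes, B)
  for (from in seq(1, B, by = chunk)) {
    to <- min(from + chunk - 1L, B)
    out[, from:to] <- student_forward(
      model, x[, , , from:to, drop = FALSE], FALSE)$logits
  }
  out
}

# teacher-side inference for distillation: fused logits + stage features
teacher_soft_targets <- function(teacher, x) {
  fwd <- backbone_forward(teacher$params$backbone, teacher$spec, x, FALSE)
  fu <- fuse_features(fwd$stages[teacher$spec$taps], teacher$fusion_cfg,
                      teacher$params$fusion$proj)
  ar <- aru_forward(fu$out, teacher$aru_cfg, teacher$params$fusion$aru,
                    teacher$ecfg, FALSE)
  list(logits = ar$logits, stages = fwd$stages)
}

#' Train a student by progressive temperature-aware distillation
#'
#' Phase 1 minimizes `alpha * L_distillation + (1 - alpha) * L_student +
#' feature_align_weight * L_feature` under the scheduled temperature, with
#' the teacher frozen throughout; phase 2 fine-tunes with plain
#' cross-entropy only.
#'
#' @param teacher A trained [init_teacher_model()] (frozen).
#' @param student A [init_student_model()] with the same stage count.
#' @param data A loaded dataset from [load_dataset()].
#' @param dc A [distill_config()].
#' @param tc A [train_config()] (epochs are taken from `dc` phases).
#' @param noise Optional [noise_spec()] for training inputs.
#' @return List with the trained `student` and the per-epoch `log`
#'   (phase, temperature, losses, train/val top-1).
#' @export
distill_student <- function(teacher, student, data, dc = distill_config(),
                            tc = train_config(), noise = NULL) {
  if (length(teacher$spec$channels) != length(student$spec$channels)) {
    stop("teacher and student must have the same stage count")
  }
  set.seed(tc$seed)
  idx_train <- which(data$split == "train")
  clean <- data$images[, , , idx_train, drop = FALSE]
  xin <- if (!is.null(noise) && noise$sigma > 0) {
    inject_gaussian_noise(clean, noise)
  } else clean
  labels <- data$labels[idx_train]
  n_train <- length(idx_train)
  nstage <- length(student$spec$channels)
  proj <- NULL
  if (dc$feature_align_weight > 0) {
    proj <- lapply(seq_len(nstage), function(s) {
      if (teacher$spec$channels[s] == student$spec$channels[s]) NULL
      else nn_conv_init(1, 1, student$spec$channels[s],
                        teacher$spec$channels[s])
    })
  }
  params_all <- list(model = student$params, proj = proj)
  opt <- sgd_init(params_all)
  log <- NULL
  total_epochs <- dc$phase_1_epochs + dc$phase_2_epochs
  for (epoch in seq_len(total_epochs)) {
    phase1 <- epoch <= dc$phase_1_epochs
    Tcur <- if (phase1) temperature_at(epoch - 1, dc) else 1
    lr <- cosine_lr(min(epoch - 1, tc$horizon), tc)
    ord <- sample(n_train)
    acc_losses <- c(distill = 0, student = 0, feature = 0)
    nb <- 0
    for (from in seq(1, n_train, by = tc$batch_size)) {
      to <- min(from + tc$batch_size - 1L, n_train)
      sel <- ord[from:to]
      xb <- xin[, , , sel, drop = FALSE]
      yb <- labels[sel]
      sf <- student_forward(student, xb, training = TRUE)
      stage_grads <- NULL
      pgrads <- NULL
      if (phase1) {
        tt <- teacher_soft_targets(teacher, xb)
        lb <- combined_loss(tt$logits, sf$logits, yb, dc, Tcur)
        g_logits <- lb$grad
        lf <- 0
        if (dc$feature_align_weight > 0) {
          fa <- feature_alignment_loss(tt$stages, sf$stages, proj)
          lf <- fa$loss
          stage_grads <- lapply(fa$gfeats, function(g) {
            if (is.null(g)) NULL else dc$feature_align_weight * g
          })
          pgrads <- lapply(fa$pgrads, function(g) {
            if (is.null(g)) NULL
            else nl_map(g, function(x) dc$feature_align_weight * x)
          })
        }
        acc_losses <- acc_losses +
          c(lb$L_distillation, lb$L_student, lf)
      } else {
        ce <- ce_loss(sf$logits, yb)
        g_logits <- ce$grad
        acc_losses <- acc_losses + c(0, ce$loss, 0)
      }
      sb <- student_backward(student, sf$cache, g_logits, stage_grads)
      gall <- list(model = sb$grads, proj = pgrads)
      st <- sgd_step(params_all, gall, opt, lr, tc$momentum)
      params_all <- st$params
      opt <- st$velocity
      student$params <- params_all$model
      proj <- params_all$proj
      nb <- nb + 1
    }
    row <- data.frame(epoch = epoch, phase = if (phase1) 1L else 2L,
                      temperature = Tcur, lr = lr,
                      L_distill = acc_losses[1] / nb,
                      L_student = acc_losses[2] / nb,
                      L_feature = acc_losses[3] / nb)
    tr <- predict_student(student, xin)
    row$train_top1 <- mean(apply(tr, 2, which.max) == labels)
    log <- rbind(log, row)
  }
  list(student = student, log = log)
}
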