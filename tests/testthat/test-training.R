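test_that("backbone presets obey the stride bookkeeping", {
  # resnet50-like: five stages halving resolution, 448 input
  spec <- backbone_spec("resnet50-like")
  sides <- vapply(seq_along(spec$channels),
                  function(s) narmnet:::stage_side(spec, s, 448), integer(1))
  expect_equal(sides, c(224L, 112L, 56L, 28L, 14L))
  expect_equal(spec$channels[spec$taps], c(512L, 1024L, 2048L))
  expect_equal(sides[spec$taps], c(56L, 28L, 14L))
  # tiny: strictly decreasing spatial size
  tiny <- backbone_spec("tiny")
  set.seed(20)
  bb <- build_backbone(tiny)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  stages <- bb$forward(x)
  hs <- vapply(stages, function(s) dim(s)[1], numeric(1))
  expect_true(all(diff(hs) < 0))
  expect_equal(vapply(stages, function(s) dim(s)[3], numeric(1)),
               as.numeric(tiny$channels))
  # same seed twice -> identical initial parameters
  set.seed(20)
  bb2 <- build_backbone(tiny)
  expect_identical(narmnet:::nl_leaves(bb$params),
                   narmnet:::nl_leaves(bb2$params))
  expect_error(backbone_spec("vgg"), "arg")
})

test_that("fuse_features is a weighted projection with exact reductions", {
  set.seed(21)
  feats <- list(array(rnorm(16 * 16 * 4), c(16, 16, 4, 1)),
                array(rnorm(8 * 8 * 6), c(8, 8, 6, 1)),
                array(rnorm(4 * 4 * 8), c(4, 4, 8, 1)))
  proj <- list(narmnet:::nn_conv_init(1, 1, 4, 8),
               narmnet:::nn_conv_init(1, 1, 6, 8),
               narmnet:::nn_conv_init(1, 1, 8, 8))
  # one-hot betas recover the projected deepest feature
  fc1 <- fusion_config(betas = c(0, 0, 1), projection_channels = 8)
  r1 <- fuse_features(feats, fc1, proj)
  deep <- narmnet:::nn_conv_fwd(proj[[3]], feats[[3]], 1, 0)$out
  expect_equal(r1$out, deep, tolerance = 1e-12)
  # identical projected features with weights summing to 1 reproduce f
  f0 <- array(rnorm(4 * 4 * 8), c(4, 4, 8, 1))
  fc2 <- fusion_config(betas = c(0.2, 0.35, 0.45), projection_channels = 8)
  r2 <- fuse_features(list(f0, f0, f0), fc2, NULL)
  expect_equal(r2$out, f0, tolerance = 1e-12)
  # homogeneity: doubling betas doubles the output
  fc3 <- fusion_config(betas = 2 * fc2$betas, projection_channels = 8)
  r3a <- fuse_features(feats, fc2, proj)
  r3b <- fuse_features(feats, fc3, proj)
  expect_equal(r3b$out, 2 * r3a$out, tolerance = 1e-12)
  # accumulation order does not matter beyond numerical noise
  perm <- c(3, 1, 2)
  fcp <- fusion_config(betas = fc2$betas[perm], projection_channels = 8)
  rp <- fuse_features(feats[perm], fcp, proj[perm])
  expect_lt(max(abs(rp$out - r3a$out)), 1e-6)
  expect_error(fuse_features(feats[1:2], fc2, proj[1:2]), "beta")
})

test_that("cosine_lr matches the closed form over the horizon", {
  tc <- train_config(lr0 = 0.002, epochs = 10, horizon = 10, lr_floor = 0)
  expect_equal(cosine_lr(0, tc), 0.002)
  expect_equal(cosine_lr(10, tc), 0)
  expect_equal(cosine_lr(5, tc), 0.001)
  expect_error(cosine_lr(11, tc), "range")
  # non-increasing over the schedule
  lrs <- vapply(0:10, cosine_lr, numeric(1), tc = tc)
  expect_true(all(diff(lrs) <= 1e-15))
  # floor honoured
  tcf <- train_config(lr0 = 0.002, epochs = 4, horizon = 4,
                      lr_floor = 5e-4)
  expect_equal(cosine_lr(4, tcf), 5e-4)
})

test_that("wmf_train_step performs S+1 ordered backward passes and updates everything", {
  data <- toy_dataset()
  model <- tiny_teacher(data, seed = 30)
  S <- length(model$spec$taps)
  tc <- train_config(lr0 = 0.01, epochs = 1, batch_size = 6, seed = 30)
  batch <- list(x = data$images[, , , 1:6], clean = data$images[, , , 1:6],
                labels = data$labels[1:6])
  opt <- narmnet:::sgd_init(model$params)
  before <- narmnet:::nl_leaves(model$params)
  st <- wmf_train_step(batch, model, tc, opt)
  expect_length(st$losses, S + 1)
  expect_true(all(is.finite(st$losses)))
  expect_equal(st$model$audit$backwards,
               c(paste0("narm_", seq_len(S)), "fusion"))
  # every NARM and fusion-head parameter moved (nonzero gradient flow)
  after <- narmnet:::nl_leaves(st$model$params)
  moved <- mapply(function(a, b) max(abs(a - b)) > 0, before, after)
  paths <- names(before)
  expect_true(all(moved[grepl("^narms/", paths)]))
  expect_true(all(moved[grepl("^fusion/", paths)]))
  expect_true(all(moved[grepl("^backbone/", paths)]))
})

test_that("with zero restoration weight each L_NARM reduces to L_rec", {
  data <- toy_dataset()
  model <- tiny_teacher(data, seed = 31)
  tc <- train_config(lr0 = 0.01, epochs = 1, batch_size = 5, seed = 31,
                     alpha = 0.6, beta = 0)
  batch <- list(x = data$images[, , , 1:5], clean = data$images[, , , 1:5],
                labels = data$labels[1:5])
  st <- wmf_train_step(batch, model, tc, narmnet:::sgd_init(model$params))
  # recompute L_rec directly at the pre-update parameters
  fwd <- narmnet:::backbone_forward(model$params$backbone, model$spec,
                                    batch$x, TRUE)
  for (i in seq_along(model$spec$taps)) {
    s <- model$spec$taps[i]
    nf <- narm_forward(fwd$stages[[s]], batch$x, model$narm_cfgs[[i]],
                       model$params$narms[[i]], model$ecfg, training = TRUE)
    lb <- narm_loss(nf$logits, batch$labels, nf$I_restored, batch$clean,
                    0.6, 0)
    expect_equal(st$losses[i], 0.6 * lb$L_rec, tolerance = 1e-8)
  }
})

test_that("single-stage WMF with beta = 1 decomposes into its two heads", {
  data <- toy_dataset()
  set.seed(32)
  spec <- backbone_spec("tiny", n_taps = 1)
  model <- init_teacher_model(spec, length(data$classes), 32,
                              feature_channels = 8,
                              fc = fusion_config(betas = 1,
                                                 projection_channels = 32))
  tc <- train_config(lr0 = 0.01, epochs = 1, batch_size = 5, seed = 32)
  batch <- list(x = data$images[, , , 1:5], clean = data$images[, , , 1:5],
                labels = data$labels[1:5])
  st <- wmf_train_step(batch, model, tc, narmnet:::sgd_init(model$params))
  expect_length(st$losses, 2)
  fwd <- narmnet:::backbone_forward(model$params$backbone, spec, batch$x,
                                    TRUE)
  s <- spec$taps[1]
  nf <- narm_forward(fwd$stages[[s]], batch$x, model$narm_cfgs[[1]],
                     model$params$narms[[1]], model$ecfg, training = TRUE)
  lb <- narm_loss(nf$logits, batch$labels, nf$I_restored, batch$clean,
                  tc$alpha, tc$beta)
  expect_equal(st$losses[1], lb$L_NARM, tolerance = 1e-8)
  fu <- fuse_features(fwd$stages[spec$taps], model$fusion_cfg,
                      model$params$fusion$proj)
  ar <- narmnet:::aru_forward(fu$out, model$aru_cfg,
                              model$params$fusion$aru, model$ecfg, TRUE)
  expect_equal(st$losses[2], narmnet:::ce_loss(ar$logits, batch$labels)$loss,
               tolerance = 1e-8)
})

test_that("train_teacher logs every epoch and is seed-deterministic", {
  data <- toy_dataset()
  run <- function() {
    model <- tiny_teacher(data, seed = 33)
    tc <- train_config(lr0 = 0.01, epochs = 2, batch_size = 12, seed = 33)
    train_teacher(data, model, tc, noise = noise_spec(0.1, seed = 9))
  }
  f1 <- run()
  f2 <- run()
  S <- length(f1$model$spec$taps)
  expect_equal(nrow(f1$log), 2)
  expect_true(all(c(paste0("L_NARM_", seq_len(S)), "L_cls", "train_top1",
                    "val_top1", paste0("p", seq_len(S))) %in%
                    colnames(f1$log)))
  expect_equal(f1$log, f2$log, tolerance = 1e-12)
  expect_error(train_teacher(list(images = data$images,
                                  labels = data$labels,
                                  split = rep("test", length(data$split))),
                             tiny_teacher(data), train_config(epochs = 1)),
               "no training images")
})
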