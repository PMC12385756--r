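toy_cfg <- function() {
  narm_config(in_channels = 8, feature_channels = 8, num_classes = 3,
              stage_size = 16, target_size = 64, mid_channels = 4,
              restore_channels = 8)
}

test_that("narm_config validates the geometry", {
  expect_error(narm_config(8, 8, 3, stage_size = 16, target_size = 48),
               "power of 2")
  cfg <- toy_cfg()
  expect_equal(cfg$upsample_stages, 2L)
  expect_equal(cfg$mid_channels, 4L)
})

test_that("ftm_forward honours shape and linearity-through-zero", {
  cfg <- toy_cfg()
  set.seed(10)
  params <- narmnet:::init_narm(cfg)
  x0 <- array(0, c(16, 16, 8, 2))
  # zero input, zero biases -> zero output (BN in inference mode with
  # fresh running stats is the identity up to gamma/beta)
  r0 <- ftm_forward(x0, cfg, params$ftm, training = FALSE)
  expect_equal(max(abs(r0$out)), 0)
  x <- array(rnorm(16 * 16 * 8 * 2), c(16, 16, 8, 2))
  r <- ftm_forward(x, cfg, params$ftm, training = TRUE)
  expect_equal(dim(r$out), c(16, 16, 8, 2))
  expect_error(ftm_forward(array(0, c(16, 16, 5, 1)), cfg, params$ftm),
               "channels")
})

test_that("scm_classify reduces to an explicit linear-algebra oracle", {
  cfg <- toy_cfg()
  set.seed(11)
  params <- narmnet:::init_narm(cfg)
  a <- rnorm(cfg$feature_channels^2)
  r <- scm_classify(a, cfg, params$scm, training = FALSE)
  expect_equal(dim(r$logits), c(3L, 1L))
  # inference-mode oracle: fc2(relu(gamma*fc1(a) + beta)) with unit
  # running stats
  h <- params$scm$fc1$w %*% a + params$scm$fc1$b
  h <- h / sqrt(1 + 1e-5)   # fresh running var = 1
  h <- pmax(params$scm$bn$gamma * h + params$scm$bn$beta, 0)
  expect_equal(as.numeric(r$logits),
               as.numeric(params$scm$fc2$w %*% h + params$scm$fc2$b),
               tolerance = 1e-10)
  # zero input with zero biases gives zero logits
  p0 <- params$scm
  p0$fc1$b[] <- 0; p0$fc2$b[] <- 0; p0$bn$beta[] <- 0
  expect_equal(max(abs(scm_classify(numeric(64), cfg, p0)$logits)), 0)
  # one-class degenerate head
  cfg1 <- narm_config(8, 8, 1, 16, 64)
  set.seed(12)
  p1 <- narmnet:::init_narm(cfg1)
  l1 <- scm_classify(rnorm(64), cfg1, p1$scm)$logits
  expect_length(l1, 1)
  expect_equal(soften_logits(as.numeric(l1)), 1)
  expect_error(scm_classify(numeric(10), cfg, params$scm), "length")
})

test_that("rtu_restore upsamples to the target size and fuses additively", {
  cfg <- toy_cfg()
  set.seed(13)
  params <- narmnet:::init_narm(cfg)
  x <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  r <- rtu_restore(x, img, cfg, params)
  expect_equal(dim(r$I_PRM), c(64, 64, 3, 1))
  expect_equal(r$I_restored, r$I_PRM + r$I_LFS)
  # zeroed PRM means restored == LFS exactly
  pz <- params
  pz$prm <- narmnet:::nl_map(pz$prm, function(w) w * 0)
  rz <- rtu_restore(x, img, cfg, pz)
  expect_equal(max(abs(rz$I_PRM)), 0)
  expect_equal(rz$I_restored, rz$I_LFS)
})

test_that("a four-module PRM recovers 448 from a 28-pixel stage", {
  cfg <- narm_config(in_channels = 16, feature_channels = 8,
                     num_classes = 2, stage_size = 28, target_size = 448,
                     restore_channels = 4)
  expect_equal(cfg$upsample_stages, 4L)
  set.seed(14)
  params <- narmnet:::init_narm(cfg)
  x <- array(rnorm(28 * 28 * 16), c(28, 28, 16))
  img <- array(runif(448 * 448 * 3), c(448, 448, 3))
  r <- rtu_restore(x, img, cfg, params)
  expect_equal(dim(r$I_PRM)[1:2], c(448L, 448L))
})

test_that("narm_forward meets the shape contract and is deterministic", {
  cfg <- narm_config(in_channels = 8, feature_channels = 8, num_classes = 3,
                     stage_size = 16, target_size = 64)
  set.seed(15)
  params <- narmnet:::init_narm(cfg)
  x <- array(rnorm(16 * 16 * 8 * 2), c(16, 16, 8, 2))
  img <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  r1 <- narm_forward(x, img, cfg, params)
  r2 <- narm_forward(x, img, cfg, params)
  expect_equal(dim(r1$logits), c(3L, 2L))
  expect_equal(dim(r1$I_restored), c(64, 64, 3, 2))
  expect_identical(r1$logits, r2$logits)
  expect_identical(r1$I_restored, r2$I_restored)
})

test_that("narm_loss composes the weighted bundle and validates inputs", {
  set.seed(16)
  p <- matrix(rnorm(8), 4, 2)
  imgs <- array(runif(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  # perfect restoration
  lb <- narm_loss(p, c(1L, 3L), imgs, imgs, alpha = 0.7, beta = 0.3)
  expect_equal(lb$L_mse, 0)
  expect_equal(lb$L_NARM, 0.7 * lb$L_rec)
  # uniform logits over 4 classes
  lb2 <- narm_loss(matrix(0, 4, 1), 2L, imgs[, , , 1], imgs[, , , 1])
  expect_equal(lb2$L_rec, log(4), tolerance = 1e-12)
  # reference weighting 0.6/0.4 reproduces the affine combination
  noisy <- pmin(pmax(imgs + 0.1, 0), 1)
  lb3 <- narm_loss(p, c(1L, 3L), noisy, imgs, alpha = 0.6, beta = 0.4)
  expect_equal(lb3$L_NARM, 0.6 * lb3$L_rec + 0.4 * lb3$L_mse)
  expect_error(narm_loss(p, c(0L, 2L), imgs, imgs), "labels")
  expect_error(narm_loss(p, c(1L, 2L), imgs[, , , 1], imgs), "shape")
})

test_that("loss bundle is affine in (alpha, beta) with pure-task reductions", {
  set.seed(17)
  p <- matrix(rnorm(6), 3, 2)
  a <- array(runif(48), c(4, 4, 3))
  b <- array(runif(48), c(4, 4, 3))
  full <- function(al, be) narm_loss(p, c(2L, 1L), a, b, al, be)$L_NARM
  l10 <- full(1, 0)
  l01 <- full(0, 1)
  expect_equal(l10, narm_loss(p, c(2L, 1L), a, b)$L_rec)
  expect_equal(l01, narm_loss(p, c(2L, 1L), a, b)$L_mse)
  expect_equal(full(0.6, 0.4), 0.6 * l10 + 0.4 * l01, tolerance = 1e-12)
  expect_equal(full(0.5, 0.5), 0.5 * l10 + 0.5 * l01, tolerance = 1e-12)
})

test_that("gradient of L_NARM w.r.t. input pixels matches finite differences", {
  cfg <- narm_config(in_channels = 4, feature_channels = 4, num_classes = 3,
                     stage_size = 4, target_size = 8, restore_channels = 4)
  set.seed(18)
  params <- narmnet:::init_narm(cfg)
  x <- array(rnorm(4 * 4 * 4), c(4, 4, 4, 1))
  img <- array(runif(8 * 8 * 3), c(8, 8, 3, 1))
  clean <- array(runif(8 * 8 * 3), c(8, 8, 3, 1))
  loss_of <- function(xx) {
    r <- narm_forward(xx, img, cfg, params, training = FALSE)
    narm_loss(r$logits, 2L, r$I_restored, clean)$L_NARM
  }
  r <- narm_forward(x, img, cfg, params, training = FALSE)
  lb <- narm_loss(r$logits, 2L, r$I_restored, clean)
  bw <- narmnet:::narm_backward(params, cfg, r$cache, lb$g_logits,
                                lb$g_restored)
  ng <- num_grad(loss_of, x, h = 1e-5)
  expect_lt(relerr(bw$gx, ng), 1e-3)
})
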