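test_that("normalize_features centers and scales each channel", {
  cfg <- egcp_config(1e-12)
  # constant channel: variance guard leaves zeros
  x <- array(5, c(3, 3, 1))
  expect_equal(normalize_features(x, cfg)$values, array(0, c(3, 3, 1)))
  # symmetric pair
  x2 <- array(c(-1, 1), c(2, 1, 1))
  expect_equal(as.numeric(normalize_features(x2, cfg)$values), c(-1, 1),
               tolerance = 1e-6)
  # random map against a direct loop oracle
  set.seed(21)
  x3 <- rand_fmap(3, 3, 4)
  nf <- normalize_features(x3, egcp_config(1e-5))
  for (d in 1:4) {
    ch <- as.numeric(x3[, , d])
    mu <- mean(ch)
    v <- mean((ch - mu)^2)
    expect_lt(abs(mean(nf$values[, , d])), 1e-9)
    expect_equal(mean((nf$values[, , d] - mean(nf$values[, , d]))^2),
                 v / (v + 1e-5), tolerance = 1e-8)
    expect_equal(nf$mu[d], mu)
    expect_equal(nf$weights[d], 1 / (v + 1e-5))
  }
  # non-finite input names the offending channel
  xb <- x3; xb[1, 1, 3] <- NaN
  expect_error(normalize_features(xb, cfg), "channel\\(s\\) 3")
})

test_that("weighted_covariance matches the double-loop definition", {
  cfg <- egcp_config(1e-5)
  # single spatial position: centering annihilates the sample
  x1 <- array(rnorm(3), c(1, 1, 3))
  expect_equal(unclass(weighted_covariance(normalize_features(x1, cfg))),
               matrix(0, 3, 3), ignore_attr = TRUE)
  # duplicated channels give a rank-1 block scaled by sqrt(w1 w2)
  set.seed(3)
  base <- rnorm(8)
  x2 <- array(c(base, base), c(4, 2, 2))
  nf <- normalize_features(x2, cfg)
  P2 <- weighted_covariance(nf)
  expect_equal(P2[1, 1], P2[2, 2], tolerance = 1e-12)
  expect_equal(P2[1, 2], P2[2, 1], tolerance = 1e-12)
  # explicit outer-product oracle: both channels share the centred
  # normalized vector xt, so P = sqrt(w1 w2) * mean(xt^2) * ones(2, 2)
  xt <- as.numeric(nf$values[, , 1])
  xt <- xt - mean(xt)
  expect_equal(P2[1, 2], sqrt(nf$weights[1] * nf$weights[2]) * mean(xt^2),
               tolerance = 1e-10)
  expect_equal(P2[1, 1], nf$weights[1] * mean(xt^2), tolerance = 1e-10)
  expect_equal(qr(P2)$rank, 1L)
  # random map equals the brute-force loops entrywise
  set.seed(9)
  x3 <- rand_fmap(8, 8, 6)
  P3 <- weighted_covariance(normalize_features(x3, cfg))
  expect_lt(max(abs(P3 - egcp_oracle(x3, 1e-5)$P)), 1e-10)
})

test_that("regularization, decomposition and the eigenvalue floor behave", {
  cfg <- egcp_config(1e-5)
  es <- regularize_and_decompose(diag(3), cfg)
  expect_equal(es$lambdas_reg, rep(1 + 1e-5, 3))
  expect_lt(max(abs(crossprod(es$U) - diag(3))), 1e-6)
  es2 <- regularize_and_decompose(diag(c(2, 0.5)), cfg)
  expect_equal(sort(es2$lambdas_reg), sort(c(2 + 1e-5, 0.5 + 1e-5)))
  # reconstruction of a random symmetric matrix
  set.seed(4)
  M <- crossprod(matrix(rnorm(25), 5))
  es3 <- regularize_and_decompose(M, cfg)
  Preg <- M + diag(1e-5, 5)
  rec <- es3$U %*% (es3$lambdas_reg * t(es3$U))
  expect_lt(norm(rec - Preg, "F") / norm(Preg, "F"), 1e-6)
  # floor across random inputs
  for (i in 1:100) {
    S <- matrix(rnorm(16), 4)
    es4 <- regularize_and_decompose(S + t(S), cfg)
    expect_gte(min(es4$lambdas_reg), 1e-5)
  }
  # asymmetry is refused
  A <- matrix(rnorm(9), 3)
  expect_error(regularize_and_decompose(A, cfg), "asymmetric")
})

test_that("eigenvalue enhancement is the log transform and amplifies small values", {
  expect_equal(enhance_eigenvalues(0), 0)
  expect_equal(enhance_eigenvalues(exp(1) - 1), 1)
  expect_equal(enhance_eigenvalues(1), log(2))
  expect_error(enhance_eigenvalues(-0.1), "nonnegative")
  # relative amplification: log(1+l)/l strictly decreasing on a 10^3 grid
  grid <- exp(seq(log(1e-4), log(50), length.out = 1000))
  ratio <- enhance_eigenvalues(grid) / grid
  expect_true(all(diff(ratio) < 0))
})

test_that("dynamic scaling matches its closed form and limits", {
  # zero enhanced spectrum
  r0 <- dynamic_scaling(diag(3), rep(0, 3))
  expect_equal(r0$S_mat, diag(3))
  expect_equal(r0$S_F, 0)
  expect_equal(max(abs(r0$Q_cross)), 0)
  # scalar case
  r1 <- dynamic_scaling(matrix(1), 1)
  expect_equal(r1$S_F, exp(-1), tolerance = 1e-12)
  # explicit 2x2 assembly
  r2 <- dynamic_scaling(diag(2), c(1, 1))
  Q <- diag(sqrt(c(1, 1)) * exp(-c(1, 1)))
  expect_equal(r2$S_F, sqrt(sum(Q^2)), tolerance = 1e-12)
  expect_equal(r2$S_F, sqrt(2 * exp(-2)), tolerance = 1e-12)
  expect_error(dynamic_scaling(diag(2), c(-1, 1)), "nonnegative")
})

test_that("closed-form scaling identity holds on random eigenstates", {
  set.seed(42)
  for (i in 1:100) {
    D <- sample(2:6, 1)
    U <- qr.Q(qr(matrix(rnorm(D * D), D)))
    len <- abs(rnorm(D))
    ds <- dynamic_scaling(U, len)
    expect_lt(abs(ds$S_F - sqrt(sum(len * exp(-2 * len)))), 1e-8)
  }
})

test_that("egcp_transform reproduces the all-zero hand trace", {
  eps <- 1e-5
  r <- egcp_transform(array(0, c(4, 4, 3)), egcp_config(eps))
  len <- log(1 + eps)
  SF <- sqrt(3 * len * exp(-2 * len))
  expect_equal(r$S_F, SF, tolerance = 1e-10)
  expect_equal(r$A, (SF + 1) * sqrt(len) * diag(3), tolerance = 1e-10)
  expect_lt(max(abs(r$P_en - len * diag(3))), 1e-12)
})

test_that("egcp_transform agrees with the loop-based oracle", {
  set.seed(77)
  for (i in 1:50) {
    D <- sample(2:8, 1)
    H <- sample(2:8, 1)
    W <- sample(2:8, 1)
    x <- rand_fmap(H, W, D, sd = runif(1, 0.5, 2))
    r <- egcp_transform(x, egcp_config(1e-5))
    o <- egcp_oracle(x, 1e-5)
    expect_lt(relerr(r$a_flat, o$a_flat), 1e-6)
    expect_lt(relerr(r$S_F, o$S_F), 1e-6)
    expect_lt(relerr(r$P_en, o$P_en), 1e-6)
  }
})

test_that("egcp_transform is invariant under spatial replication", {
  set.seed(12)
  x <- rand_fmap(4, 4, 3)
  x2 <- array(0, c(8, 4, 3))
  x2[1:4, , ] <- x
  x2[5:8, , ] <- x
  r1 <- egcp_transform(x)
  r2 <- egcp_transform(x2)
  expect_lt(max(abs(r1$A - r2$A)), 1e-10)
})

test_that("structural invariants: symmetry, PSD, conjugation equivariance", {
  set.seed(31)
  for (i in 1:20) {
    x <- rand_fmap(5, 5, 4)
    r <- egcp_transform(x)
    expect_lt(max(abs(r$A - t(r$A))), 1e-6)
    expect_lt(max(abs(r$P_en - t(r$P_en))), 1e-6)
    expect_gte(min(eigen(r$A, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
    expect_gte(min(eigen(r$P_en, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-8)
  }
  # orthogonal conjugation of P propagates to A, S_F unchanged
  cfg <- egcp_config(1e-5)
  spectral_tail <- function(P) {
    es <- regularize_and_decompose(P, cfg)
    len <- enhance_eigenvalues(es$lambdas_reg)
    ds <- dynamic_scaling(es$U, len)
    list(A = (ds$S_F + 1) * es$U %*% (sqrt(len) * t(es$U)), S_F = ds$S_F)
  }
  for (i in 1:10) {
    P <- crossprod(matrix(rnorm(25), 5)) / 5
    R <- qr.Q(qr(matrix(rnorm(25), 5)))
    a <- spectral_tail(P)
    b <- spectral_tail(R %*% P %*% t(R))
    expect_lt(max(abs(b$A - R %*% a$A %*% t(R))), 1e-6)
    expect_lt(abs(a$S_F - b$S_F), 1e-6)
  }
})

test_that("the internal batched EGCP matches egcp_transform and its gradient", {
  set.seed(55)
  cfg <- egcp_config(1e-5)
  x <- array(rnorm(6 * 6 * 5 * 2), c(6, 6, 5, 2))
  fe <- narmnet:::egcp_fwd(x, cfg)
  for (b in 1:2) {
    expect_equal(fe$out[, b], egcp_transform(x[, , , b], cfg)$a_flat,
                 tolerance = 1e-10)
  }
  ge <- matrix(rnorm(length(fe$out)), nrow(fe$out))
  gx <- narmnet:::egcp_bwd(fe$cache, ge)
  f <- function(xx) sum(narmnet:::egcp_fwd(xx, cfg)$out * ge)
  expect_lt(relerr(gx, num_grad(f, x)), 1e-3)
})
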