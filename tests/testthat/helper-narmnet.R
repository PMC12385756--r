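# Shared test helpers: finite-difference gradients, a loop-based EGCP
# reference, and memoised toy datasets/models reused across test files.

relerr <- function(a, b) {
  max(abs(a - b)) / max(1e-12, max(abs(a)), max(abs(b)))
}

num_grad <- function(f, x, h = 1e-5) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

`%||%` <- function(x, y) if (is.null(x)) y else x

rand_fmap <- function(H, W, D, sd = 1) array(rnorm(H * W * D, sd = sd), c(H, W, D))

# Independent brute-force EGCP reference: every step as explicit loops and
# a dense eigendecomposition, kept free of the package's internal path.
egcp_oracle <- function(x, eps) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; D <- d[3]; N <- H * W
  mu <- numeric(D); v <- numeric(D)
  for (dd in seq_len(D)) {
    s <- 0
    for (h in seq_len(H)) for (w in seq_len(W)) s <- s + x[h, w, dd]
    mu[dd] <- s / N
    s2 <- 0
    for (h in seq_len(H)) for (w in seq_len(W)) {
      s2 <- s2 + (x[h, w, dd] - mu[dd])^2
    }
    v[dd] <- s2 / N
  }
  xt <- array(0, d)
  for (dd in seq_len(D)) {
    xt[, , dd] <- (x[, , dd] - mu[dd]) / sqrt(v[dd] + eps)
  }
  wgt <- 1 / (v + eps)
  P <- matrix(0, D, D)
  for (i in seq_len(D)) for (j in seq_len(D)) {
    s <- 0
    for (h in seq_len(H)) for (w in seq_len(W)) {
      s <- s + xt[h, w, i] * xt[h, w, j]
    }
    P[i, j] <- sqrt(wgt[i] * wgt[j]) * s / N
  }
  e <- eigen(P + diag(eps, D), symmetric = TRUE)
  lam <- pmax(e$values, eps)
  len <- log(1 + lam)
  U <- e$vectors
  P_en <- U %*% diag(len, D) %*% t(U)
  S_mat <- U %*% diag(exp(-len), D) %*% t(U)
  Q <- (U %*% diag(sqrt(len), D) %*% t(U)) %*% S_mat
  S_F <- sqrt(sum(Q^2))
  A <- (S_F + 1) * (U %*% diag(sqrt(len), D) %*% t(U))
  list(P = P, P_en = P_en, S_mat = S_mat, Q_cross = Q, S_F = S_F, A = A,
       a_flat = as.numeric(t(A)))
}

# memoised fixtures shared across test files (built once per session)
.fix <- new.env(parent = emptyenv())

toy_dataset <- function(key = "mini", n_classes = 3, per_class = 20,
                        image_size = 32, seed = 101) {
  if (is.null(.fix[[key]])) {
    dir <- file.path(tempdir(), paste0("narmnet-", key))
    man <- generate_toy_dataset(n_classes, per_class, image_size, seed, dir)
    .fix[[key]] <- load_dataset(man)
  }
  .fix[[key]]
}

tiny_teacher <- function(data, seed = 5, feature_channels = 12) {
  set.seed(seed)
  init_teacher_model(backbone_spec("tiny"), length(data$classes),
                     dim(data$images)[1], feature_channels = feature_channels)
}
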