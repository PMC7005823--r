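# Exact (non-approximate) t-SNE.
#
# Implemented in-package: deterministic PCA initialisation (sign-fixed
# loadings), per-point perplexity calibration by binary search, early
# exaggeration, momentum + adaptive gains gradient descent. Exact pairwise
# gradients are quadratic in n, which is comfortably fast at screen scale
# (hundreds to low thousands of images).

tsne_probabilities <- function(D2, perplexity, tol = 1e-5, max_iter = 50L) {
  n <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1
    beta_lo <- -Inf; beta_hi <- Inf
    di <- D2[i, -i]
    for (it in seq_len(max_iter)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { h <- 0; pr <- w }
      else {
        pr <- w / sw
        h <- log(sw) + beta * sum(di * w) / sw
      }
      diff <- h - target
      if (abs(diff) < tol) break
      if (diff > 0) { beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else { beta_hi <- beta
        beta <- if (is.finite(beta_lo)) (beta + beta_lo) / 2 else beta / 2
      }
    }
    P[i, -i] <- pr
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, .Machine$double.xmin)
}

pca_scores <- function(X, k) {
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$x))
  S <- pc$x[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-magnitude loading of each PC is positive
  for (j in seq_len(k)) {
    ld <- pc$rotation[, j]
    if (ld[which.max(abs(ld))] < 0) S[, j] <- -S[, j]
  }
  S
}

tsne_exact <- function(X, perplexity = 30, n_iter = 750L, eta = NULL,
                       exaggeration = 12, exag_iter = 250L, seed = 0L) {
  n <- nrow(X)
  # auto learning rate; large fixed rates make small embeddings diverge
  if (is.null(eta)) eta <- max(n / (4 * exaggeration), 50)
  if (ncol(X) > 50) X <- pca_scores(X, 50L)
  D2 <- as.matrix(stats::dist(X))^2
  P <- tsne_probabilities(D2, perplexity)
  init <- pca_scores(X, 2L)
  if (ncol(init) < 2L) init <- cbind(init, 0)
  sdev <- sd(init[, 1])
  Y <- if (sdev > 0) init / sdev * 1e-4 else
    with_seed(seed, matrix(rnorm(n * 2, sd = 1e-4), n, 2))
  V <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  Pex <- P * exaggeration
  for (iter in seq_len(n_iter)) {
    Puse <- if (iter <= exag_iter) Pex else P
    sqd <- as.matrix(stats::dist(Y))^2
    W <- 1 / (1 + sqd)
    diag(W) <- 0
    Z <- sum(W)
    Q <- pmax(W / Z, .Machine$double.xmin)
    L <- (Puse - Q) * W
    G <- 4 * (rowSums(L) * Y - L %*% Y)
    mom <- if (iter <= exag_iter) 0.5 else 0.8
    gains <- pmax(ifelse(sign(G) != sign(V), gains + 0.2, gains * 0.8), 0.01)
    V <- mom * V - eta * gains * G
    Y <- Y + V
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
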