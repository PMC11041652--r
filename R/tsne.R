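# Exact (O(n^2)) t-distributed stochastic neighbor embedding, used for the
# 2-D visualization of spontaneous-activity features. Cohorts here are a
# few hundred neurons, so the exact gradient is cheap and fully
# deterministic given the seed.

tsne_affinities <- function(D2, perplexity) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    d <- D2[i, -i]
    beta_lo <- 0; beta_hi <- Inf; beta <- 1
    for (iter in 1:64) {
      w <- exp(-d * beta)
      sw <- sum(w)
      if (sw <= 0) { beta <- beta / 2; next }
      H <- log(sw) + beta * sum(d * w) / sw
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else { beta_hi <- beta; beta <- (beta + beta_lo) / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

tsne_exact <- function(X, seed, perplexity = 30, max_iter = 500,
                       eta = 200, exaggeration = 12, exag_iter = 100) {
  X <- as.matrix(X)
  n <- nrow(X)
  assert_that(n >= 4, "too few points for an embedding")
  perp <- min(perplexity, floor((n - 1) / 3))
  if (perp < perplexity)
    warning(sprintf("perplexity reduced to %d for n = %d", perp, n), call. = FALSE)
  D2 <- as.matrix(stats::dist(X))^2
  P <- tsne_affinities(D2, perp)
  with_seed(seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    inc <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    for (it in seq_len(max_iter)) {
      Pe <- if (it <= exag_iter) P * exaggeration else P
      num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (Pe - Q) * num
      grad <- 4 * (diag(rowSums(L)) %*% Y - L %*% Y)
      momentum <- if (it < 250) 0.5 else 0.8
      gains <- pmax(0.01, ifelse(sign(grad) != sign(inc),
                                 gains + 0.2, gains * 0.8))
      inc <- momentum * inc - eta * gains * grad
      Y <- Y + inc
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}
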