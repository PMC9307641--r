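# Exact t-SNE (O(n^2)), sufficient for the few hundred patch embeddings the
# latent export handles; seeded and deterministic. Standard ingredients:
# per-point binary search for the target perplexity, symmetrized affinities,
# early exaggeration, momentum gradient descent on the Student-t low-D
# affinities.

tsne_perplexity_probs <- function(d2, perplexity, tol = 1e-5, max_iter = 50) {
  n <- nrow(d2)
  p <- matrix(0, n, n)
  log_u <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; beta_min <- -Inf; beta_max <- Inf
    di <- d2[i, -i]
    for (iter in seq_len(max_iter)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { h <- 0; pi_row <- w } else {
        pi_row <- w / sw
        h <- -sum(pi_row[pi_row > 0] * log(pi_row[pi_row > 0]))
      }
      diff <- h - log_u
      if (abs(diff) < tol) break
      if (diff > 0) { beta_min <- beta; beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2 }
      else { beta_max <- beta; beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2 }
    }
    p[i, -i] <- pi_row
  }
  p
}

tsne_embed <- function(x, dims = 2L, perplexity = 10, seed = 1L,
                       max_iter = 300L, eta = 100) {
  n <- nrow(x)
  perplexity <- max(2, min(perplexity, (n - 1) / 3))
  sq <- rowSums(x^2)
  d2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(x), 0)
  p <- tsne_perplexity_probs(d2, perplexity)
  p <- (p + t(p)) / (2 * n)
  p <- pmax(p, 1e-12)
  with_local_seed(seed, {
    y <- matrix(rnorm(n * dims, sd = 1e-4), n, dims)
    inc <- matrix(0, n, dims)
    exaggeration <- 4
    for (iter in seq_len(max_iter)) {
      pe <- if (iter <= 100) p * exaggeration else p
      sqy <- rowSums(y^2)
      num <- 1 / (1 + pmax(outer(sqy, sqy, "+") - 2 * tcrossprod(y), 0))
      diag(num) <- 0
      q <- pmax(num / sum(num), 1e-12)
      mult <- (pe - q) * num
      grad <- 4 * (diag(rowSums(mult)) - mult) %*% y
      momentum <- if (iter <= 20) 0.5 else 0.8
      inc <- momentum * inc - eta * grad
      y <- y + inc
      y <- sweep(y, 2, colMeans(y))
    }
    y
  })
}
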