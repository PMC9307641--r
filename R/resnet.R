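# Forward pass of the 34-layer residual network used by the "resnet34" backbone
# preset: 7x7/2 stem (64 channels), 3x3/2 max pool, four stages of basic
# blocks [3, 4, 6, 3] at 64/128/256/512 channels with stride-2 stage entries,
# global average pooling. Activations are channel-normalized in place of
# batch statistics so the frozen forward pass is well-scaled for any weights.

init_resnet34_weights <- function(feature_dim = 512L) {
  stages <- list(c(64L, 3L), c(128L, 4L), c(256L, 6L), c(512L, 3L))
  blocks <- list()
  cin <- 64L
  for (s in seq_along(stages)) {
    cout <- stages[[s]][1]
    for (b in seq_len(stages[[s]][2])) {
      stride <- if (s > 1 && b == 1) 2L else 1L
      blk <- list(
        conv1 = he_init(c(9L * cin, cout), 9L * cin),
        conv2 = he_init(c(9L * cout, cout), 9L * cout),
        stride = stride
      )
      if (stride != 1L || cin != cout) {
        blk$down <- he_init(c(cin, cout), cin)
      }
      blocks[[length(blocks) + 1L]] <- blk
      cin <- cout
    }
  }
  w <- list(stem = he_init(c(7L * 7L * 3L, 64L), 147L), blocks = blocks)
  if (feature_dim != 512L) w$proj <- he_init(c(512L, feature_dim), 512L)
  w
}

# Strided, padded im2col convolution: batch B x H x W x Cin, weight
# (k*k*Cin) x Cout.
conv2d <- function(batch, w, k, stride = 1L, pad = 0L) {
  d <- dim(batch)
  if (pad > 0L) {
    padded <- array(0, c(d[1], d[2] + 2L * pad, d[3] + 2L * pad, d[4]))
    padded[, pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- batch
    batch <- padded
    d <- dim(batch)
  }
  oh <- (d[2] - k) %/% stride + 1L
  ow <- (d[3] - k) %/% stride + 1L
  ys <- seq(0L, by = stride, length.out = oh)
  xs <- seq(0L, by = stride, length.out = ow)
  cols <- matrix(0, d[1] * oh * ow, k * k * d[4])
  col <- 1L
  for (c in seq_len(d[4])) {
    for (dx in seq_len(k)) {
      for (dy in seq_len(k)) {
        cols[, col] <- as.vector(batch[, ys + dy, xs + dx, c, drop = FALSE])
        col <- col + 1L
      }
    }
  }
  array(cols %*% w, c(d[1], oh, ow, ncol(w)))
}

# Per-channel standardization over batch and spatial positions.
channel_norm <- function(batch, eps = 1e-5) {
  d <- dim(batch)
  m <- matrix(batch, d[1] * d[2] * d[3], d[4])
  mu <- colMeans(m)
  sdv <- sqrt(colMeans(sweep(m, 2, mu)^2) + eps)
  array(sweep(sweep(m, 2, mu), 2, sdv, "/"), d)
}

maxpool_3x3_s2 <- function(batch) {
  d <- dim(batch)
  pad <- 1L
  padded <- array(-Inf, c(d[1], d[2] + 2L, d[3] + 2L, d[4]))
  padded[, 1L + seq_len(d[2]), 1L + seq_len(d[3]), ] <- batch
  oh <- (d[2] + 2L - 3L) %/% 2L + 1L
  ow <- (d[3] + 2L - 3L) %/% 2L + 1L
  ys <- seq(0L, by = 2L, length.out = oh)
  xs <- seq(0L, by = 2L, length.out = ow)
  out <- array(-Inf, c(d[1], oh, ow, d[4]))
  for (dy in seq_len(3L)) {
    for (dx in seq_len(3L)) {
      out <- pmax(out, padded[, ys + dy, xs + dx, , drop = FALSE])
    }
  }
  out
}

basic_block <- function(x, blk) {
  y <- pmax(channel_norm(conv2d(x, blk$conv1, 3L, stride = blk$stride, pad = 1L)), 0)
  y <- channel_norm(conv2d(y, blk$conv2, 3L, stride = 1L, pad = 1L))
  skip <- if (!is.null(blk$down)) {
    channel_norm(conv2d(x, blk$down, 1L, stride = blk$stride, pad = 0L))
  } else x
  pmax(y + skip, 0)
}

resnet34_forward <- function(batch, w) {
  x <- pmax(channel_norm(conv2d(batch, w$stem, 7L, stride = 2L, pad = 3L)), 0)
  x <- maxpool_3x3_s2(x)
  for (blk in w$blocks) x <- basic_block(x, blk)
  d <- dim(x)
  feats <- apply(array(x, c(d[1], d[2] * d[3], d[4])), c(1, 3), mean)
  feats <- matrix(feats, d[1], d[4])
  if (!is.null(w$proj)) feats <- feats %*% w$proj
  feats
}
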