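#' Frozen feature backbone
#'
#' The backbone is a pluggable, frozen feature extractor turning a patch tile
#' into a fixed-length feature vector; it receives no gradient updates during
#' MIL training. Two presets ship:
#'
#' * `"resnet34"` — a 34-layer residual network (7x7 stem, four stages of basic
#'   blocks \[3, 4, 6, 3\] with 64/128/256/512 channels, global average
#'   pooling) producing 512 features from 224x224 tiles.
#' * `"tiny"` — a small two-layer convolutional net on 32x32 tiles (input
#'   tiles are block-mean downscaled) producing 64 features; meant for
#'   desk-scale experiments and tests.
#'
#' Weights are either freshly initialized from a seeded He-normal draw
#' (`weights_source = "random"`) or loaded from an RDS file
#' (`weights_source = "file"`). Self-supervised pretraining of the backbone is
#' outside this package; any externally trained weights can be supplied
#' through the file route.
#'
#' @param architecture `"tiny"` or `"resnet34"`.
#' @param feature_dim Length of the produced feature vector; defaults to 64
#'   (tiny) or 512 (resnet34).
#' @param weights_source `"random"` or `"file"`.
#' @param weights_file Path to an RDS with a weight list when
#'   `weights_source = "file"`.
#' @param seed Seed for random initialization.
#' @return An object of class `pathmil_backbone` with elements
#'   `architecture`, `feature_dim`, `input_size`, `frozen` (always `TRUE`)
#'   and `weights`.
#' @export
backbone_spec <- function(architecture = c("tiny", "resnet34"), feature_dim = NULL,
                          weights_source = c("random", "file"),
                          weights_file = NULL, seed = 1L) {
  architecture <- match.arg(architecture)
  weights_source <- match.arg(weights_source)
  if (is.null(feature_dim)) {
    feature_dim <- if (architecture == "resnet34") 512L else 64L
  }
  input_size <- if (architecture == "resnet34") 224L else 32L
  weights <- if (weights_source == "file") {
    if (is.null(weights_file)) {
      abort("weights_file is required when weights_source = 'file'",
            class = "pathmil_validation_error")
    }
    readRDS(weights_file)
  } else if (architecture == "tiny") {
    with_local_seed(seed, init_tiny_weights(feature_dim))
  } else {
    with_local_seed(seed, init_resnet34_weights(feature_dim))
  }
  structure(list(architecture = architecture, feature_dim = as.integer(feature_dim),
                 input_size = input_size, frozen = TRUE,
                 weights_source = weights_source, weights = weights),
            class = "pathmil_backbone")
}

#' @export
print.pathmil_backbone <- function(x, ...) {
  cat(sprintf("<pathmil_backbone '%s'> %d features from %dx%d tiles (frozen, %s weights)\n",
              x$architecture, x$feature_dim, x$input_size, x$input_size,
              x$weights_source))
  invisible(x)
}

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

init_tiny_weights <- function(feature_dim) {
  if (feature_dim <= 6) {
    abort("tiny backbone needs feature_dim > 6", class = "pathmil_validation_error")
  }
  list(
    conv1 = he_init(c(27, 8), 27),    # 3x3x3 -> 8
    b1 = numeric(8),
    conv2 = he_init(c(72, 16), 72),   # 3x3x8 -> 16
    b2 = numeric(16),
    # 6 slots are reserved for per-channel colour statistics of the raw tile
    proj = he_init(c(576, feature_dim - 6L), 576)  # 6x6x16 flattened
  )
}

#' Extract backbone features for a list of tiles
#'
#' Tiles are block-mean downscaled (or bilinearly resized) to the backbone's
#' input size, then passed through the frozen network. Deterministic given the
#' backbone.
#'
#' @param tiles List of H x W x 3 arrays, or a precomputed p x feature_dim
#'   matrix (returned unchanged after a dimension check).
#' @param backbone A `pathmil_backbone`.
#' @return p x feature_dim numeric matrix, one row per tile.
#' @export
backbone_features <- function(tiles, backbone) {
  if (is.matrix(tiles)) {
    if (ncol(tiles) != backbone$feature_dim) {
      abort(sprintf("feature matrix has %d columns, backbone expects %d",
                    ncol(tiles), backbone$feature_dim),
            class = "pathmil_shape_error")
    }
    return(tiles)
  }
  batch <- tiles_to_batch(tiles, backbone$input_size)
  if (backbone$architecture == "tiny") {
    tiny_forward(batch, backbone$weights)
  } else {
    resnet34_forward(batch, backbone$weights)
  }
}

# Stack tiles into a B x S x S x 3 array at the backbone input size.
tiles_to_batch <- function(tiles, size) {
  mats <- lapply(tiles, function(tl) {
    d <- dim(tl)
    if (d[1] == size && d[2] == size) return(tl)
    if (d[1] %% size == 0 && d[1] == d[2]) return(block_mean(tl, d[1] %/% size))
    resize_raster(tl, size, size)
  })
  b <- length(mats)
  out <- array(0, c(b, size, size, 3))
  for (i in seq_len(b)) out[i, , , ] <- mats[[i]]
  out
}

# Valid (unpadded) im2col convolution over a B x H x W x Cin batch with a
# (kh*kw*Cin) x Cout weight matrix; returns B x OH x OW x Cout.
conv2d_valid <- function(batch, w, k = 3L) {
  d <- dim(batch)
  oh <- d[2] - k + 1L; ow <- d[3] - k + 1L
  cin <- d[4]
  cols <- matrix(0, d[1] * oh * ow, k * k * cin)
  col <- 1L
  for (c in seq_len(cin)) {
    for (dx in seq_len(k)) {
      for (dy in seq_len(k)) {
        cols[, col] <- as.vector(batch[, dy:(dy + oh - 1L), dx:(dx + ow - 1L), c])
        col <- col + 1L
      }
    }
  }
  array(cols %*% w, c(d[1], oh, ow, ncol(w)))
}

# 2x2 max pooling (floor semantics on odd dims).
maxpool2 <- function(batch) {
  d <- dim(batch)
  oh <- d[2] %/% 2L; ow <- d[3] %/% 2L
  i1 <- seq(1L, 2L * oh, by = 2L); i2 <- i1 + 1L
  j1 <- seq(1L, 2L * ow, by = 2L); j2 <- j1 + 1L
  pmax(batch[, i1, j1, , drop = FALSE], batch[, i2, j1, , drop = FALSE],
       batch[, i1, j2, , drop = FALSE], batch[, i2, j2, , drop = FALSE])
}

add_bias <- function(batch, b) {
  sweep(batch, 4, b, "+")
}

# Random-weight conv texture features plus raw per-channel colour statistics
# (mean and sd of R, G, B over the tile) — the colour statistics carry the
# stain signal that pretrained backbones would encode, the conv maps carry
# texture frequency.
tiny_forward <- function(batch, w) {
  b <- dim(batch)[1]
  x <- pmax(add_bias(conv2d_valid(batch, w$conv1), w$b1), 0)  # B x 30 x 30 x 8
  x <- maxpool2(x)                                            # B x 15 x 15 x 8
  x <- pmax(add_bias(conv2d_valid(x, w$conv2), w$b2), 0)      # B x 13 x 13 x 16
  x <- maxpool2(x)                                            # B x 6 x 6 x 16
  flat <- matrix(x, b, 576)
  px <- array(batch, c(b, prod(dim(batch)[2:3]), 3))
  ch_mean <- apply(px, c(1, 3), mean)
  ch_sd <- sqrt(pmax(apply(px^2, c(1, 3), mean) - ch_mean^2, 0))
  cbind(flat %*% w$proj, matrix(ch_mean, b, 3) * 2, matrix(ch_sd, b, 3) * 2)
}
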