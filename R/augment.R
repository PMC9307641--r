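#' WSI-level data augmentation
#'
#' Samples one transformation pipeline per slide and applies the identical
#' transform to every patch of the bag, mirroring augmentation at WSI level.
#' Three operations are each included independently with probability 0.5:
#' rotation (angle drawn from 90/180/270 degrees), flipping (horizontal or
#' vertical), and colour jitter in HSV space with bounded shifts (hue +-20,
#' saturation +-30, value +-20 on the 8-bit scale). Fully determined by
#' `seed`.
#'
#' @param tiles Non-empty list of H x W x 3 arrays (square tiles for
#'   rotation).
#' @param seed Integer seed.
#' @return List with `tiles` (transformed, same order) and `transform` (the
#'   sampled descriptor: `rotate`, `flip`, `colour`).
#' @export
wsi_augment <- function(tiles, seed) {
  if (length(tiles) == 0) {
    abort("tiles must be non-empty", class = "pathmil_validation_error")
  }
  tr <- with_local_seed(seed, sample_wsi_transform())
  list(tiles = lapply(tiles, apply_tile_transform, tr = tr), transform = tr)
}

sample_wsi_transform <- function() {
  rotate <- if (runif(1) < 0.5) sample(c(90, 180, 270), 1) else 0
  flip <- if (runif(1) < 0.5) sample(c("horizontal", "vertical"), 1) else "none"
  colour <- if (runif(1) < 0.5) {
    list(dh = runif(1, -20, 20) / 255, ds = runif(1, -30, 30) / 255,
         dv = runif(1, -20, 20) / 255)
  } else NULL
  list(rotate = rotate, flip = flip, colour = colour)
}

apply_tile_transform <- function(tile, tr) {
  out <- tile
  if (tr$rotate > 0) {
    for (k in seq_len(tr$rotate / 90)) out <- rot90cw(out)
  }
  if (tr$flip == "horizontal") out <- out[, rev(seq_len(dim(out)[2])), , drop = FALSE]
  if (tr$flip == "vertical") out <- out[rev(seq_len(dim(out)[1])), , , drop = FALSE]
  if (!is.null(tr$colour)) out <- hsv_jitter(out, tr$colour)
  out
}

# 90-degree clockwise rotation of an H x W x C array.
rot90cw <- function(a) {
  b <- aperm(a, c(2, 1, 3))
  b[, rev(seq_len(dim(b)[2])), , drop = FALSE]
}

# Bounded HSV shift of a colour tile; hue wraps, saturation and value clamp.
hsv_jitter <- function(tile, colour) {
  d <- dim(tile)
  rgb <- rbind(as.vector(tile[, , 1]), as.vector(tile[, , 2]), as.vector(tile[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  h <- (hsv[1, ] + colour$dh) %% 1
  s <- pmin(1, pmax(0, hsv[2, ] + colour$ds))
  v <- pmin(1, pmax(0, hsv[3, ] + colour$dv))
  array(hsv_to_rgb(h, s, v), d)
}

# Vectorized numeric HSV -> RGB (grDevices::hsv yields hex strings, too slow
# on the per-epoch augmentation path). Returns c(r, g, b) stacked columnwise.
hsv_to_rgb <- function(h, s, v) {
  i <- floor(h * 6) %% 6
  f <- h * 6 - floor(h * 6)
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  c(r, g, b)
}

# Evaluate expr under a temporary RNG state so library calls stay pure.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a child seed from a parent seed and a stream index; keeps every
# random behaviour traceable to one master seed while staying in 32-bit range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 9973) %% 2147483647)
}
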