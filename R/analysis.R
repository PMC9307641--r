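#' Render an attention heatmap over a slide
#'
#' Paints each patch's attention weight for one class into its footprint,
#' min-max normalized to \[0, 1\] per slide (ranking-preserving), and
#' optionally alpha-blends the result as a red overlay onto a slide
#' thumbnail. Pixels without a retained patch (background) are untouched.
#'
#' @param dims Slide dimensions `c(h, w)` at the extraction magnification.
#' @param patches Patch tibble from [extract_patches()] (`x`, `y` 0-based).
#' @param attention 5 x p attention matrix (rows in canonical class order),
#'   columns aligned with `patches` rows.
#' @param class Class whose attention row is rendered.
#' @param thumbnail Optional H x W x 3 raster matching `dims` to blend over.
#' @param patch_size Patch edge, default 224.
#' @param alpha Blend strength in (0, 1\], default 0.6.
#' @return An object of class `pathmil_heatmap`: `heat` (H x W matrix, `NA`
#'   outside patch footprints), `overlay` (blended raster or `NULL`),
#'   `weights` (per-patch tibble).
#' @export
render_heatmap <- function(dims, patches, attention, class, thumbnail = NULL,
                           patch_size = 224L, alpha = 0.6) {
  assert_known_classes(class)
  if (ncol(attention) != nrow(patches)) {
    abort(sprintf("attention has %d columns but %d patch records",
                  ncol(attention), nrow(patches)),
          class = "pathmil_validation_error")
  }
  w <- attention[which(class_names() == class), ]
  rng <- range(w)
  wn <- if (diff(rng) < 1e-12) rep(0.5, length(w)) else (w - rng[1]) / diff(rng)
  heat <- matrix(NA_real_, dims[1], dims[2])
  for (i in seq_len(nrow(patches))) {
    ys <- (patches$y[i] + 1):(patches$y[i] + patch_size)
    xs <- (patches$x[i] + 1):(patches$x[i] + patch_size)
    heat[ys, xs] <- wn[i]
  }
  overlay <- NULL
  if (!is.null(thumbnail)) {
    overlay <- thumbnail
    mask <- !is.na(heat)
    hv <- heat[mask]
    r <- overlay[, , 1][mask]; g <- overlay[, , 2][mask]; b <- overlay[, , 3][mask]
    overlay[, , 1][mask] <- (1 - alpha * hv) * r + alpha * hv * 1
    overlay[, , 2][mask] <- (1 - alpha * hv) * g
    overlay[, , 3][mask] <- (1 - alpha * hv) * b
  }
  structure(list(heat = heat, overlay = overlay, class = class,
                 weights = bind_cols(patches, tibble(weight = w, normalized = wn))),
            class = "pathmil_heatmap")
}

#' Export the latent space for 2-D projection
#'
#' Retains patches whose maximum class probability exceeds the threshold,
#' tags each with its predicted class, and computes seeded 2-D coordinates
#' with t-SNE on the embedding rows.
#'
#' @param embeddings p x embed_dim matrix (the embedding-layer output).
#' @param probabilities p x 5 patch probability matrix.
#' @param threshold Retention threshold on the max class probability,
#'   default 0.5.
#' @param seed Seed for the projection.
#' @param perplexity t-SNE perplexity; default 10 (clamped for tiny inputs).
#' @return Tibble with `dim1`, `dim2`, `class`, `max_prob`, `row` (index into
#'   the input). Empty when nothing clears the threshold.
#' @export
export_latent <- function(embeddings, probabilities, threshold = 0.5,
                          seed = 1L, perplexity = 10) {
  max_prob <- apply(probabilities, 1, max)
  keep <- which(max_prob > threshold)
  if (length(keep) == 0) {
    return(tibble(dim1 = numeric(), dim2 = numeric(), class = character(),
                  max_prob = numeric(), row = integer()))
  }
  cls <- class_names()[max.col(probabilities, ties.method = "first")][keep]
  x <- embeddings[keep, , drop = FALSE]
  coords <- if (length(keep) < 4) {
    cbind(seq_along(keep), 0)
  } else {
    tsne_embed(x, seed = seed,
               perplexity = min(perplexity, (length(keep) - 1) / 3))
  }
  tibble(dim1 = coords[, 1], dim2 = coords[, 2], class = cls,
         max_prob = max_prob[keep], row = keep)
}
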