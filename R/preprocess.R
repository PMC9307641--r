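#' Construct a slide raster
#'
#' In-memory representation of a (possibly pyramidal) slide: a level-0 colour
#' raster stored as an H x W x 3 array in \[0, 1\], the nominal objective power
#' it was scanned at, and optional extra pyramid levels. Slides without
#' magnification metadata should be constructed with an assumed base (the
#' package assumes 20x in the readers, loudly).
#'
#' @param pixels H x W x 3 numeric array in \[0, 1\].
#' @param base_magnification Objective power of level 0 (e.g. 40, 20, 10).
#' @param slide_id Identifier string.
#' @param levels Numeric vector of pyramid downsample factors, strictly
#'   increasing from 1.
#' @param pyramid Optional list of rasters matching `levels` (level 0 may be
#'   `NULL` to mean `pixels`).
#' @return An object of class `pathmil_slide`.
#' @export
slide_raster <- function(pixels, base_magnification, slide_id = "slide",
                         levels = 1, pyramid = NULL) {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  if (base_magnification <= 0) {
    abort("base_magnification must be > 0", class = "pathmil_validation_error")
  }
  if (levels[1] != 1 || is.unsorted(levels, strictly = TRUE)) {
    abort("pyramid downsample factors must strictly increase from 1",
          class = "pathmil_validation_error")
  }
  structure(list(pixels = pixels, base_magnification = base_magnification,
                 slide_id = slide_id, levels = levels, pyramid = pyramid),
            class = "pathmil_slide")
}

#' @export
print.pathmil_slide <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<pathmil_slide '%s'> %dx%d at %gx, %d level(s)\n",
              x$slide_id, d[1], d[2], x$base_magnification, length(x$levels)))
  invisible(x)
}

#' Read a slide raster from PNG or TIFF
#'
#' @param path File path (.png, .tif/.tiff).
#' @param base_magnification Objective power; defaults to 20 with a prominent
#'   message when no value is supplied.
#' @param slide_id Defaults to the file name without extension.
#' @return A `pathmil_slide`.
#' @export
read_slide <- function(path, base_magnification = NULL, slide_id = NULL) {
  if (is.null(slide_id)) slide_id <- sub("\\.[^.]+$", "", basename(path))
  if (is.null(base_magnification)) {
    inform(paste0("No magnification metadata for ", basename(path),
                  "; assuming base 20x"))
    base_magnification <- 20
  }
  ext <- tolower(sub(".*\\.", "", path))
  a <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      abort("package 'tiff' is needed to read TIFF rasters")
    }
    tiff::readTIFF(path)
  } else {
    abort(paste0("Unsupported raster format: ", ext))
  }
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  slide_raster(a, base_magnification, slide_id)
}

#' Preprocessing configuration
#'
#' @param patch_size Patch edge length in pixels at the extraction
#'   magnification; default 224 (the input size of the residual-network backbone preset).
#' @param target_magnification Extraction power; default 10.
#' @param tissue_threshold Minimal tissue fraction for a patch to be kept;
#'   default 0.5.
#' @param stride Grid stride in pixels; defaults to `patch_size`
#'   (non-overlapping tiling).
#' @return A list of class `pathmil_preprocess_config`.
#' @export
preprocess_config <- function(patch_size = 224L, target_magnification = 10,
                              tissue_threshold = 0.5, stride = patch_size) {
  if (patch_size < 1 || stride < 1) {
    abort("patch_size and stride must be >= 1", class = "pathmil_validation_error")
  }
  if (tissue_threshold <= 0 || tissue_threshold > 1) {
    abort("tissue_threshold must be in (0, 1]", class = "pathmil_validation_error")
  }
  structure(list(patch_size = as.integer(patch_size),
                 target_magnification = target_magnification,
                 tissue_threshold = tissue_threshold,
                 stride = as.integer(stride)),
            class = "pathmil_preprocess_config")
}

#' Compute a tissue mask from a colour raster
#'
#' Thresholds the saturation channel of the HSV transform with Otsu's method,
#' then applies morphological opening and closing (disk radius 2) and hole
#' filling. White background has near-zero saturation while stained tissue is
#' saturated, so this separates tissue from glass deterministically. A
#' degenerate single-colour raster yields an empty or full mask rather than an
#' error.
#'
#' @param slide A `pathmil_slide` or an H x W x 3 array.
#' @param downsample Integer factor at which to compute the mask (block-mean
#'   downscale first); default 1.
#' @return List with `mask` (logical H' x W' matrix) and `downsample`.
#' @export
compute_tissue_mask <- function(slide, downsample = 1L) {
  pixels <- if (inherits(slide, "pathmil_slide")) slide$pixels else slide
  if (downsample > 1) pixels <- block_mean(pixels, downsample)
  d <- dim(pixels)
  rgb <- t(matrix(pixels, d[1] * d[2], 3))
  sat <- matrix(grDevices::rgb2hsv(rgb, maxColorValue = 1)[2, ], d[1], d[2])
  if (max(sat) - min(sat) < 1e-6) {
    return(list(mask = matrix(max(sat) > 0.1, d[1], d[2]), downsample = downsample))
  }
  thr <- EBImage::otsu(EBImage::Image(sat), range = c(0, 1))
  mask <- EBImage::Image(sat > thr)
  brush <- EBImage::makeBrush(5, shape = "disc")
  mask <- EBImage::opening(mask, brush)
  mask <- EBImage::closing(mask, brush)
  mask <- EBImage::fillHull(mask)
  list(mask = EBImage::imageData(mask) > 0, downsample = downsample)
}

#' Select the pyramid level for a target magnification
#'
#' Picks the level with the smallest magnification that is still at least the
#' target, together with the exact downscale factor needed to land on the
#' target. Single-level rasters rescale directly from base.
#'
#' @param slide A `pathmil_slide`.
#' @param target_magnification Requested power.
#' @param allow_upscale Permit upscaling when no level reaches the target;
#'   default `FALSE` (an error instead).
#' @return List with `level` (1-based index), `magnification` of that level,
#'   and `rescale` (factor to apply; 1 means use as-is).
#' @export
resolve_level <- function(slide, target_magnification, allow_upscale = FALSE) {
  mags <- slide$base_magnification / slide$levels
  ok <- which(mags >= target_magnification - 1e-9)
  if (length(ok) == 0) {
    if (!allow_upscale) {
      abort(sprintf("No pyramid level reaches %gx (best is %gx) and upscaling is disabled",
                    target_magnification, max(mags)),
            class = "pathmil_resolution_error")
    }
    lev <- which.max(mags)
  } else {
    lev <- ok[which.min(mags[ok])]
  }
  list(level = lev, magnification = mags[lev],
       rescale = target_magnification / mags[lev])
}

slide_level_pixels <- function(slide, level) {
  if (level == 1 || is.null(slide$pyramid) || is.null(slide$pyramid[[level]])) {
    if (level == 1) return(slide$pixels)
    return(block_mean(slide$pixels, slide$levels[level]))
  }
  slide$pyramid[[level]]
}

#' Extract tissue patches from a slide
#'
#' Tiles the slide at the target magnification on a regular grid (row-major;
#' partial border cells are dropped, never padded) and keeps a patch iff the
#' fraction of tissue pixels under it is at least the configured threshold.
#'
#' @param slide A `pathmil_slide`.
#' @param mask Tissue mask from [compute_tissue_mask()]; computed on the fly
#'   when `NULL`.
#' @param config [preprocess_config()].
#' @param allow_upscale Passed to [resolve_level()].
#' @return List with `patches` (tibble `slide_id`, `x`, `y` 0-based top-left
#'   at the extraction magnification, `magnification`, `tissue_fraction`),
#'   `tiles` (list of patch arrays, same order) and `warnings`.
#' @export
extract_patches <- function(slide, mask = NULL, config = preprocess_config(),
                            allow_upscale = FALSE) {
  res <- resolve_level(slide, config$target_magnification, allow_upscale)
  pixels <- slide_level_pixels(slide, res$level)
  if (abs(res$rescale - 1) > 1e-9) {
    pixels <- resize_raster(pixels, round(dim(pixels)[1] * res$rescale),
                            round(dim(pixels)[2] * res$rescale))
  }
  if (is.null(mask)) mask <- compute_tissue_mask(slide)
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  ps <- config$patch_size
  empty <- list(patches = tibble(slide_id = character(), x = integer(),
                                 y = integer(), magnification = numeric(),
                                 tissue_fraction = numeric()),
                tiles = list(), warnings = character())
  if (h < ps || w < ps) {
    empty$warnings <- sprintf("slide %s (%dx%d) is smaller than one %d-pixel patch",
                              slide$slide_id, h, w, ps)
    return(empty)
  }
  # bring the mask onto the extraction raster grid once
  mres <- resize_mask(mask$mask, h, w)
  xs <- seq(0L, w - ps, by = config$stride)
  ys <- seq(0L, h - ps, by = config$stride)
  rows <- list(); tiles <- list()
  for (y in ys) {
    for (x in xs) {
      frac <- mean(mres[(y + 1):(y + ps), (x + 1):(x + ps)])
      if (frac >= config$tissue_threshold) {
        rows[[length(rows) + 1L]] <- tibble(
          slide_id = slide$slide_id, x = x, y = y,
          magnification = config$target_magnification, tissue_fraction = frac)
        tiles[[length(tiles) + 1L]] <- pixels[(y + 1):(y + ps), (x + 1):(x + ps), , drop = FALSE]
      }
    }
  }
  if (length(rows) == 0) return(empty)
  list(patches = bind_rows(rows), tiles = tiles, warnings = character())
}

# Block-mean downscale of a matrix or H x W x C array by an integer factor.
block_mean <- function(a, f) {
  f <- as.integer(round(f))
  if (f <= 1) return(a)
  if (length(dim(a)) == 2) {
    h <- (dim(a)[1] %/% f) * f; w <- (dim(a)[2] %/% f) * f
    a <- a[seq_len(h), seq_len(w), drop = FALSE]
    s <- colMeans(array(a, c(f, h %/% f, f, w %/% f)))     # (h/f, f, w/f)
    return(colMeans(aperm(s, c(2, 1, 3))))                 # (h/f, w/f)
  }
  out <- lapply(seq_len(dim(a)[3]), function(c) block_mean(a[, , c], f))
  array(unlist(out), c(dim(out[[1]]), length(out)))
}

# Bilinear resize of an H x W x 3 array (EBImage does the interpolation).
resize_raster <- function(a, new_h, new_w) {
  img <- EBImage::Image(aperm(a, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(img, w = new_w, h = new_h)
  aperm(EBImage::imageData(out), c(2, 1, 3))
}

# Nearest-neighbour resize of a logical mask to given dims.
resize_mask <- function(mask, new_h, new_w) {
  ri <- pmin(nrow(mask), pmax(1L, round((seq_len(new_h) - 0.5) * nrow(mask) / new_h + 0.5)))
  ci <- pmin(ncol(mask), pmax(1L, round((seq_len(new_w) - 0.5) * ncol(mask) / new_w + 0.5)))
  mask[ri, ci, drop = FALSE]
}

#' Write a patch manifest CSV
#'
#' @param patches Patch tibble from [extract_patches()].
#' @param path Output file.
#' @export
write_patch_manifest <- function(patches, path) {
  readr::write_csv(patches, path)
  invisible(path)
}
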