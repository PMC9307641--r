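#' Per-class procedural texture parameters
#'
#' Each annotation class renders as a gland-like periodic texture on a white
#' background. The deformation amplitude and fill solidity are strictly
#' ordered across classes (normal < hyperplastic < low-grade < high-grade <
#' cancer), echoing the morphology gradient from well-shaped to poorly
#' defined glands, and the base colours are spaced far enough apart in hue to
#' survive the bounded HSV augmentation. Rendering is deterministic given a
#' seed.
#'
#' @return Tibble with one row per class: `class`, `ring_spacing`, `deform`,
#'   `solidity`, `base_r/g/b`, `gland_r/g/b`.
#' @export
texture_spec <- function() {
  tibble(
    class = class_names(),
    ring_spacing = c(22, 26, 30, 34, 38),
    deform = c(14, 10, 6, 3, 0),  # cancer most deformed, normal regular
    solidity = c(0.85, 0.65, 0.45, 0.30, 0.15),
    base_r = c(0.75, 0.62, 0.80, 0.90, 0.92),
    base_g = c(0.45, 0.50, 0.84, 0.74, 0.70),
    base_b = c(0.55, 0.80, 0.52, 0.52, 0.78),
    gland_r = c(0.55, 0.42, 0.58, 0.70, 0.75),
    gland_g = c(0.20, 0.30, 0.64, 0.50, 0.45),
    gland_b = c(0.32, 0.62, 0.30, 0.30, 0.58)
  )
}

#' Render a synthetic slide with known ground truth
#'
#' Paints one elliptical tissue region per set class (non-overlapping
#' vertical strips) with that class's procedural texture on a white
#' background, and derives per-pixel and per-patch ground truth. The per-cell
#' ground truth is the class covering at least half of the cell's tissue,
#' `NA` otherwise.
#'
#' @param labels Finalized label vector.
#' @param size Square slide edge in pixels; default 1120 (a 5x5 grid of
#'   224-pixel patches).
#' @param seed Integer seed.
#' @param patch_size Grid cell used for `patch_gt`; default 224.
#' @return List with `slide` (`pathmil_slide` at 10x), `region_mask` (H x W
#'   integer matrix, 0 = background, else canonical class index), `patch_gt`
#'   (gy x gx character matrix, `NA` for no class) and `gt_label`.
#' @export
synth_slide <- function(labels, size = 1120L, seed = 1L, patch_size = 224L) {
  labels <- as_label(labels)
  classes <- label_classes(labels)
  k <- length(classes)
  if (k < 1) abort("labels must be finalized", class = "pathmil_validation_error")
  if (size < patch_size) {
    abort("slide smaller than one patch", class = "pathmil_generation_error")
  }
  if (size %/% k < patch_size) {
    abort(sprintf("%d classes do not fit a %d-pixel slide (each needs a %d-wide strip)",
                  k, size, patch_size),
          class = "pathmil_generation_error")
  }
  spec <- texture_spec()
  with_local_seed(seed, {
    h <- w <- as.integer(size)
    px <- array(1, c(h, w, 3))
    region <- matrix(0L, h, w)
    strip_w <- w %/% k
    # textures are evaluated on a half-resolution lattice and pixel-replicated;
    # the ring spacings (>= 22 px) are far coarser than the 2-px lattice
    f <- if (h %% 2L == 0L && strip_w %% 2L == 0L) 2L else 1L
    for (i in seq_len(k)) {
      cls <- classes[i]
      sp <- spec[spec$class == cls, ]
      x0 <- (i - 1L) * strip_w
      cols <- (x0 + 1L):(x0 + strip_w)
      h2 <- h %/% f; sw2 <- strip_w %/% f
      ys <- matrix(rep(seq_len(h2) * f - (f - 1L) / 2, sw2), h2, sw2)
      xs <- matrix(rep(x0 + seq_len(sw2) * f - (f - 1L) / 2, each = h2), h2, sw2)
      cx <- x0 + strip_w / 2 + runif(1, -0.05, 0.05) * strip_w
      cy <- h / 2 + runif(1, -0.05, 0.05) * h
      rx <- strip_w * runif(1, 0.40, 0.46)
      ry <- h * runif(1, 0.38, 0.46)
      inside <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
      phx <- runif(1, 0, 2 * pi); phy <- runif(1, 0, 2 * pi)
      xd <- xs + sp$deform * sin(ys / 17 + phx)
      yd <- ys + sp$deform * sin(xs / 23 + phy)
      tex <- sin(2 * pi * xd / sp$ring_spacing) * sin(2 * pi * yd / sp$ring_spacing)
      mix <- 0.15 + 0.7 * ((tex + 1) / 2 > sp$solidity) +
        matrix(rnorm(h2 * sw2, sd = 0.04), h2, sw2)
      mix[mix < 0] <- 0; mix[mix > 1] <- 1
      up_r <- rep(seq_len(h2), each = f)
      up_c <- rep(seq_len(sw2), each = f)
      inside_full <- inside[up_r, up_c, drop = FALSE]
      idx <- which(inside_full)
      for (ch in 1:3) {
        base <- sp[[paste0("base_", c("r", "g", "b")[ch])]]
        gl <- sp[[paste0("gland_", c("r", "g", "b")[ch])]]
        plane <- px[, cols, ch]
        mix_full <- mix[up_r, up_c, drop = FALSE]
        plane[idx] <- base + (gl - base) * mix_full[idx]
        px[, cols, ch] <- plane
      }
      reg <- region[, cols]
      reg[idx] <- which(class_names() == cls)
      region[, cols] <- reg
    }
    px[px < 0] <- 0; px[px > 1] <- 1
    gy <- h %/% patch_size; gx <- w %/% patch_size
    patch_gt <- matrix(NA_character_, gy, gx)
    for (r in seq_len(gy)) {
      for (c in seq_len(gx)) {
        cell <- region[((r - 1) * patch_size + 1):(r * patch_size),
                       ((c - 1) * patch_size + 1):(c * patch_size)]
        tissue <- cell[cell > 0]
        if (length(tissue) == 0) next
        tab <- tabulate(tissue, n_classes())
        j <- which.max(tab)
        if (tab[j] >= length(tissue) / 2) patch_gt[r, c] <- class_names()[j]
      }
    }
    list(slide = slide_raster(px, base_magnification = 10,
                              slide_id = paste0("synth_", seed)),
         region_mask = region, patch_gt = patch_gt, gt_label = labels)
  })
}

report_templates <- function() {
  list(
    cancer = c("infiltrating adenocarcinoma is identified.",
               "fragments with invasive adenocarcinoma."),
    high_grade_dysplasia = c("adenoma with high-grade dysplasia.",
                             "severe dysplasia is noted."),
    low_grade_dysplasia = c("tubular adenoma with low-grade dysplasia.",
                            "mild dysplasia of the glandular epithelium."),
    hyperplastic_polyp = c("hyperplastic polyp of the sigmoid colon.",
                           "fragments of a hyperplastic polyp."),
    normal = c("normal colonic mucosa.", "regular mucosa without alterations.")
  )
}

negated_phrases <- function() {
  c(cancer = "no adenocarcinoma.",
    high_grade_dysplasia = "no high-grade dysplasia.",
    low_grade_dysplasia = "no low-grade dysplasia.",
    hyperplastic_polyp = "no hyperplastic polyp.")
}

distractor_phrase <- function() {
  "margin of resection on hyperplasia-adenomatous mucosa."
}

#' Generate a synthetic pathology report for a label set
#'
#' Emits one affirmative template phrase per set class. Pure-normal cases
#' omit findings entirely with probability 0.5 (exercising the labeler's
#' `normal` fallback) and otherwise state the normal mucosa explicitly. With
#' probability `negation_rate` a negated phrase for an unset class is
#' appended (e.g. "no high-grade dysplasia"), and with probability
#' `distractor_rate` the hyperplasia-margin trap clause is appended when the
#' hyperplastic class is unset.
#'
#' @param labels Finalized label vector.
#' @param report_id Identifier.
#' @param negation_rate,distractor_rate Noise probabilities in \[0, 1\].
#' @param seed Integer seed.
#' @return List with `report` (one-row tibble `report_id`, `text`),
#'   `negated_class` (`NA` or the unset class negated) and `distractor`
#'   (logical).
#' @export
synth_report <- function(labels, report_id = "r1", negation_rate = 0,
                         distractor_rate = 0, seed = 1L) {
  labels <- as_label(labels)
  classes <- label_classes(labels)
  if (length(classes) == 0) abort("labels must be finalized",
                                  class = "pathmil_validation_error")
  with_local_seed(seed, {
    tpl <- report_templates()
    parts <- c(sample(c("colon biopsy.", "polypectomy specimen of the sigmoid colon."), 1))
    for (cls in classes) {
      if (cls == "normal" && length(classes) == 1 && runif(1) < 0.5) {
        parts <- c(parts, "three tissue fragments examined.")
      } else {
        parts <- c(parts, sample(tpl[[cls]], 1))
      }
    }
    negated_class <- NA_character_
    if (runif(1) < negation_rate) {
      unset <- setdiff(names(negated_phrases()), classes)
      if (length(unset) > 0) {
        negated_class <- if (length(unset) == 1) unset else sample(unset, 1)
        parts <- c(parts, negated_phrases()[[negated_class]])
      }
    }
    distractor <- FALSE
    if (runif(1) < distractor_rate && !"hyperplastic_polyp" %in% classes) {
      parts <- c(parts, distractor_phrase())
      distractor <- TRUE
    }
    list(report = tibble(report_id = report_id, text = paste(parts, collapse = " ")),
         negated_class = negated_class, distractor = distractor)
  })
}

#' Corpus generation configuration
#'
#' `class_prevalence` is a distribution over label sets (names are
#' '+'-joined class names) mirroring a screening corpus where normal and
#' low-grade dysplasia dominate; `mislabel_rate` injects weak-label noise by
#' flipping exactly one class indicator in a fixed fraction of cases,
#' emulating the 15-25% error rate of automatic report labeling.
#'
#' @param n_cases Number of cases.
#' @param class_prevalence Named numeric vector over label sets, summing to 1.
#' @param slide_size Slide edge in pixels, default 1120.
#' @param patch_size Grid cell, default 224.
#' @param mislabel_rate,negation_rate,distractor_rate Rates in \[0, 1\].
#' @param bags_per_patient Slides assigned per synthetic patient, default 2.
#' @param seed Master seed.
#' @return A list of class `pathmil_corpus_config`.
#' @export
corpus_config <- function(n_cases = 100L,
                          class_prevalence = c(
                            "normal" = 0.30,
                            "low_grade_dysplasia" = 0.22,
                            "hyperplastic_polyp" = 0.12,
                            "cancer" = 0.12,
                            "high_grade_dysplasia" = 0.06,
                            "high_grade_dysplasia+low_grade_dysplasia" = 0.08,
                            "cancer+high_grade_dysplasia" = 0.06,
                            "low_grade_dysplasia+hyperplastic_polyp" = 0.04),
                          slide_size = 1120L, patch_size = 224L,
                          mislabel_rate = 0, negation_rate = 0,
                          distractor_rate = 0, bags_per_patient = 2L,
                          seed = 1L) {
  rates <- c(mislabel_rate, negation_rate, distractor_rate)
  if (any(rates < 0 | rates > 1)) {
    abort("rates must be in [0, 1]", class = "pathmil_validation_error")
  }
  if (abs(sum(class_prevalence) - 1) > 1e-8) {
    abort("class_prevalence must sum to 1", class = "pathmil_validation_error")
  }
  structure(list(n_cases = as.integer(n_cases),
                 class_prevalence = class_prevalence,
                 slide_size = as.integer(slide_size),
                 patch_size = as.integer(patch_size),
                 mislabel_rate = mislabel_rate, negation_rate = negation_rate,
                 distractor_rate = distractor_rate,
                 bags_per_patient = as.integer(bags_per_patient),
                 seed = as.integer(seed)),
            class = "pathmil_corpus_config")
}

flip_one_class <- function(label, seed) {
  with_local_seed(seed, {
    repeat {
      j <- sample.int(n_classes(), 1)
      flipped <- label
      flipped[j] <- 1L - flipped[j]
      if (sum(flipped) >= 1) return(flipped)
    }
  })
}

#' Generate a paired synthetic corpus
#'
#' Draws label sets from the configured prevalence, renders one report (and
#' optionally one slide) per case, assigns patients round-robin with
#' `bags_per_patient` slides each, and corrupts exactly
#' `floor(mislabel_rate * n)` randomly chosen cases by flipping one class
#' indicator. The manifest records every corruption and every injected noise
#' clause, so noise recovery can be checked exactly.
#'
#' @param config A [corpus_config()].
#' @param render_slides Render slide rasters (memory-heavy for large
#'   corpora); default `TRUE`.
#' @param transform Optional function applied to each case right after
#'   generation; its result replaces the heavy `slide`/`region_mask` fields
#'   (use [case_to_bag()] to turn cases into MIL bags on the fly).
#' @return List with `cases`, `manifest` (tibble), `reports`, `labels_gt`,
#'   `labels_noisy`.
#' @export
synth_corpus <- function(config = corpus_config(), render_slides = TRUE,
                         transform = NULL) {
  n <- config$n_cases
  sets <- names(config$class_prevalence)
  draw <- with_local_seed(config$seed,
                          sample(sets, n, replace = TRUE,
                                 prob = config$class_prevalence))
  n_bad <- floor(config$mislabel_rate * n)
  bad_idx <- with_local_seed(derive_seed(config$seed, 1L),
                             if (n_bad > 0) sample.int(n, n_bad) else integer())
  cases <- vector("list", n)
  manifest <- vector("list", n)
  for (i in seq_len(n)) {
    case_id <- sprintf("case_%04d", i)
    patient_id <- sprintf("P%04d", (i - 1L) %/% config$bags_per_patient + 1L)
    gt <- make_label(strsplit(draw[i], "+", fixed = TRUE)[[1]])
    rep_seed <- derive_seed(config$seed, 1000L + i)
    rep <- synth_report(gt, report_id = case_id,
                        negation_rate = config$negation_rate,
                        distractor_rate = config$distractor_rate,
                        seed = rep_seed)
    corrupted <- i %in% bad_idx
    noisy <- if (corrupted) {
      flip_one_class(gt, derive_seed(config$seed, 2000L + i))
    } else gt
    case <- list(case_id = case_id, patient_id = patient_id,
                 report = rep$report, gt_label = gt,
                 noisy_label = noisy, corrupted = corrupted)
    if (render_slides) {
      sl <- synth_slide(gt, size = config$slide_size,
                        seed = derive_seed(config$seed, 3000L + i),
                        patch_size = config$patch_size)
      sl$slide$slide_id <- case_id
      case$slide <- sl$slide
      case$region_mask <- sl$region_mask
      case$patch_gt <- sl$patch_gt
    }
    if (!is.null(transform)) case <- transform(case)
    cases[[i]] <- case
    flipped <- if (corrupted) {
      class_names()[which(noisy != gt)]
    } else NA_character_
    manifest[[i]] <- tibble(case_id = case_id, patient_id = patient_id,
                            label_set = paste(label_classes(gt), collapse = "+"),
                            corrupted = corrupted, flipped_class = flipped,
                            negated_class = rep$negated_class,
                            distractor = rep$distractor)
  }
  manifest <- bind_rows(manifest)
  labels_gt <- labels_to_tibble(manifest$case_id,
                                do.call(rbind, map(cases, "gt_label")))
  labels_noisy <- labels_to_tibble(manifest$case_id,
                                   do.call(rbind, map(cases, "noisy_label")))
  reports <- bind_rows(map(cases, "report"))
  list(cases = cases, manifest = manifest, reports = reports,
       labels_gt = labels_gt, labels_noisy = labels_noisy)
}

#' Turn a synthetic case into a MIL bag
#'
#' Extracts tissue patches from the case's slide, aligns them with the
#' per-cell ground truth, optionally downscales tiles to a working size
#' (block mean) so large corpora fit in memory, and attaches the requested
#' label source as the bag label.
#'
#' @param case One element of `synth_corpus()$cases` (with a slide).
#' @param config A [preprocess_config()].
#' @param tile_size Optional edge length to downscale tiles to (e.g. the tiny
#'   backbone's 32).
#' @param label_source `"gt"` or `"noisy"`.
#' @param mask_downsample Downsample factor for the tissue mask (coarser is
#'   faster; 4 is plenty for patch-level tissue fractions).
#' @return A `pathmil_bag` carrying `patch_gt`.
#' @export
case_to_bag <- function(case, config = preprocess_config(), tile_size = NULL,
                        label_source = c("gt", "noisy"), mask_downsample = 4L) {
  label_source <- match.arg(label_source)
  mask <- compute_tissue_mask(case$slide, downsample = mask_downsample)
  ex <- extract_patches(case$slide, mask = mask, config = config)
  if (nrow(ex$patches) == 0) {
    abort(paste0("no tissue patches in case ", case$case_id),
          class = "pathmil_generation_error")
  }
  ps <- config$patch_size
  gt_vec <- map_chr(seq_len(nrow(ex$patches)), function(i) {
    r <- ex$patches$y[i] %/% ps + 1L
    c <- ex$patches$x[i] %/% ps + 1L
    if (r <= nrow(case$patch_gt) && c <= ncol(case$patch_gt))
      case$patch_gt[r, c] else NA_character_
  })
  tiles <- ex$tiles
  if (!is.null(tile_size)) {
    tiles <- lapply(tiles, function(tl) block_mean(tl, dim(tl)[1] %/% tile_size))
  }
  label <- if (label_source == "noisy") case$noisy_label else case$gt_label
  make_bag(tiles, label, slide_id = case$case_id, patient_id = case$patient_id,
           coords = ex$patches, patch_gt = gt_vec)
}
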