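#' Construct a patch bag
#'
#' A bag is the MIL unit: one slide's ordered patch collection, its weak
#' multilabel WSI label, and the patient the slide belongs to (so folds can be
#' split at patient level).
#'
#' @param patches List of patch tiles (H x W x 3 arrays) or a precomputed
#'   p x feature_dim matrix.
#' @param label Finalized label vector (at least one class set).
#' @param slide_id,patient_id Identifiers.
#' @param coords Optional patch tibble (from [extract_patches()]) aligned with
#'   `patches`.
#' @param patch_gt Optional character vector of per-patch ground-truth classes
#'   (`NA` for none), used only for evaluation.
#' @return An object of class `pathmil_bag`.
#' @export
make_bag <- function(patches, label, slide_id, patient_id = slide_id,
                     coords = NULL, patch_gt = NULL) {
  p <- if (is.matrix(patches)) nrow(patches) else length(patches)
  if (p < 1) abort("a bag needs at least one patch", class = "pathmil_validation_error")
  label <- as_label(label)
  if (sum(label) < 1) {
    abort("bag label must be finalized (at least one class set)",
          class = "pathmil_validation_error")
  }
  structure(list(patches = patches, label = label, slide_id = slide_id,
                 patient_id = patient_id, coords = coords, patch_gt = patch_gt,
                 n_patches = p),
            class = "pathmil_bag")
}

#' @export
print.pathmil_bag <- function(x, ...) {
  cat(sprintf("<pathmil_bag '%s'> %d patches, label {%s}, patient %s\n",
              x$slide_id, x$n_patches,
              paste(label_classes(x$label), collapse = ", "), x$patient_id))
  invisible(x)
}

#' Initialize a MIL head
#'
#' The trainable part of the classifier: an embedding layer mapping backbone
#' features to a lower-dimensional embedding (ReLU activated), a per-patch
#' 5-class classifier, and an attention network scoring each patch per class.
#' Defaults follow the reference architecture: 512-d features in, 128-d
#' embedding.
#'
#' @param feature_dim Backbone feature length (default 512).
#' @param embed_dim Embedding width (default 128).
#' @param shared_attention Use one attention score per patch shared by all
#'   classes instead of per-class scores; default `FALSE`.
#' @param seed Seed for weight initialization.
#' @return An object of class `pathmil_mil_head`.
#' @export
mil_head <- function(feature_dim = 512L, embed_dim = 128L,
                     shared_attention = FALSE, seed = 1L) {
  att_cols <- if (shared_attention) 1L else n_classes()
  w <- with_local_seed(seed, list(
    W1 = he_init(c(feature_dim, embed_dim), feature_dim),
    b1 = numeric(embed_dim),
    Wc = he_init(c(embed_dim, n_classes()), embed_dim),
    bc = numeric(n_classes()),
    Wa = he_init(c(embed_dim, att_cols), embed_dim),
    ba = numeric(att_cols)
  ))
  structure(list(feature_dim = as.integer(feature_dim),
                 embed_dim = as.integer(embed_dim),
                 shared_attention = isTRUE(shared_attention),
                 classes = class_names(), weights = w),
            class = "pathmil_mil_head")
}

#' @export
print.pathmil_mil_head <- function(x, ...) {
  cat(sprintf("<pathmil_mil_head> %d -> %d embedding, 5-class classifier, %s attention\n",
              x$feature_dim, x$embed_dim,
              if (x$shared_attention) "shared" else "per-class"))
  invisible(x)
}

#' Embed a bag's patches
#'
#' Runs the frozen backbone over the bag's tiles (or accepts precomputed
#' features) and applies the embedding layer with ReLU. Patch order is
#' preserved; the backbone receives no updates.
#'
#' @param bag A `pathmil_bag` (or a feature matrix / list of tiles).
#' @param backbone A `pathmil_backbone`.
#' @param head A `pathmil_mil_head`.
#' @return p x embed_dim embedding matrix.
#' @export
embed_bag <- function(bag, backbone, head) {
  patches <- if (inherits(bag, "pathmil_bag")) bag$patches else bag
  feats <- backbone_features(patches, backbone)
  if (ncol(feats) != head$feature_dim) {
    abort(sprintf("backbone produced %d features but head expects %d",
                  ncol(feats), head$feature_dim),
          class = "pathmil_shape_error")
  }
  pmax(feats %*% head$weights$W1 +
         matrix(head$weights$b1, nrow(feats), head$embed_dim, byrow = TRUE), 0)
}

row_softmax <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

col_softmax <- function(m) {
  e <- exp(sweep(m, 2, apply(m, 2, max)))
  sweep(e, 2, colSums(e), "/")
}

#' Per-patch multiclass prediction
#'
#' Softmax over the five class logits of every patch; the hard label is the
#' argmax with ties broken by the lowest class index.
#'
#' @param embeddings p x embed_dim matrix from [embed_bag()].
#' @param head A `pathmil_mil_head`.
#' @return List with `logits` (p x 5), `probabilities` (p x 5, rows sum to 1)
#'   and `classes` (character vector of hard labels).
#' @export
patch_predict <- function(embeddings, head) {
  z <- embeddings %*% head$weights$Wc +
    matrix(head$weights$bc, nrow(embeddings), n_classes(), byrow = TRUE)
  pr <- row_softmax(z)
  colnames(z) <- colnames(pr) <- class_names()
  list(logits = z, probabilities = pr,
       classes = class_names()[max.col(pr, ties.method = "first")])
}

# Attention scores for a bag: p x 5 (shared scores replicated across classes).
attention_scores <- function(embeddings, head) {
  s <- embeddings %*% head$weights$Wa +
    matrix(head$weights$ba, nrow(embeddings), ncol(head$weights$Wa), byrow = TRUE)
  if (head$shared_attention) s <- s[, rep(1L, n_classes()), drop = FALSE]
  s
}

#' Attention pooling of patch predictions
#'
#' For each class, the attention weights over the bag's patches are the
#' softmax of that class's attention scores, so every class row sums to 1.
#' The WSI logit of a class is the attention-weighted sum of that class's
#' patch logits, and the WSI probability is its logistic transform — a
#' multilabel slide prediction aggregated from instance-level predictions.
#'
#' @param embeddings p x embed_dim matrix.
#' @param patch_logits p x 5 logit matrix from [patch_predict()].
#' @param head A `pathmil_mil_head`.
#' @return List with `attention` (5 x p matrix, rows named by class, each row
#'   a probability vector), `wsi_logits` and `wsi_prob` (named length-5
#'   vectors).
#' @export
attention_pool <- function(embeddings, patch_logits, head) {
  s <- attention_scores(embeddings, head)
  a <- col_softmax(s)                      # p x 5, columns sum to 1
  wsi_logits <- colSums(a * patch_logits)
  wsi_prob <- 1 / (1 + exp(-wsi_logits))
  att <- t(a)
  rownames(att) <- class_names()
  names(wsi_logits) <- names(wsi_prob) <- class_names()
  list(attention = att, wsi_logits = wsi_logits, wsi_prob = wsi_prob)
}

#' Predict the multilabel diagnosis of one slide
#'
#' Full forward pass for a bag: embed, per-patch prediction, attention
#' pooling, and thresholding of the WSI probabilities. A class is set iff its
#' probability exceeds `threshold`; when no class clears it, the argmax class
#' is set so a diagnosis is always emitted.
#'
#' @param bag A `pathmil_bag`.
#' @param backbone A `pathmil_backbone`.
#' @param head A `pathmil_mil_head`.
#' @param threshold Decision threshold, default 0.5.
#' @return List with `label`, `probabilities`, `attention`, and `patch` (the
#'   [patch_predict()] result).
#' @export
predict_wsi <- function(bag, backbone, head, threshold = 0.5) {
  if (inherits(bag, "pathmil_bag") && bag$n_patches < 1) {
    abort("empty bag", class = "pathmil_validation_error")
  }
  emb <- embed_bag(bag, backbone, head)
  pp <- patch_predict(emb, head)
  pool <- attention_pool(emb, pp$logits, head)
  pred <- threshold_predictions(matrix(pool$wsi_prob, 1), threshold)[1, ]
  list(label = setNames(as.integer(pred), class_names()),
       probabilities = pool$wsi_prob, attention = pool$attention, patch = pp)
}
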