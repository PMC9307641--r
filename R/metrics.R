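#' Build a multilabel prediction table
#'
#' The shared evaluation currency: one row per case with ground-truth
#' indicators (`gt_*`), class probabilities (`prob_*`) and thresholded
#' predictions (`pred_*`). A class is predicted iff its probability exceeds
#' `threshold`; when no class clears the threshold the argmax class is set, so
#' a prediction is never empty (every slide receives a diagnosis).
#'
#' @param case_id Character vector of case ids (unique).
#' @param prob Numeric n x 5 matrix of class probabilities in canonical order.
#' @param gt Label tibble (`case_id` + indicator columns) or n x 5 0/1 matrix.
#' @param threshold Decision threshold, default 0.5.
#' @return A tibble with 16 columns: `case_id`, `gt_*`, `prob_*`, `pred_*`.
#' @export
prediction_table <- function(case_id, prob, gt, threshold = 0.5) {
  if (anyDuplicated(case_id) > 0) {
    abort("case_id values must be unique", class = "pathmil_validation_error")
  }
  if (is.data.frame(gt)) {
    gt <- label_matrix(gt[match(case_id, gt$case_id), ])
  }
  pred <- threshold_predictions(prob, threshold)
  out <- tibble(case_id = case_id)
  for (j in seq_len(n_classes())) {
    cls <- class_names()[j]
    out[[paste0("gt_", cls)]] <- as.integer(gt[, j])
    out[[paste0("prob_", cls)]] <- as.numeric(prob[, j])
    out[[paste0("pred_", cls)]] <- pred[, j]
  }
  out
}

# Threshold rule shared by prediction_table() and predict_wsi(): classes above
# threshold; argmax fallback (first index on ties) when none clears it.
threshold_predictions <- function(prob, threshold = 0.5) {
  prob <- rbind(prob)
  pred <- matrix(as.integer(prob > threshold), nrow = nrow(prob))
  none <- rowSums(pred) == 0
  if (any(none)) {
    for (i in which(none)) pred[i, which.max(prob[i, ])] <- 1L
  }
  colnames(pred) <- class_names()
  pred
}

gt_matrix <- function(table) {
  as.matrix(table[, paste0("gt_", class_names())])
}
pred_matrix <- function(table) {
  as.matrix(table[, paste0("pred_", class_names())])
}

#' Multilabel micro-accuracy
#'
#' Accuracy pooled over every (sample, class) indicator cell:
#' (TP + TN) / (TP + TN + FP + FN). This is the headline WSI-level metric of
#' the evaluation protocol; the per-sample exact-match rate is available via
#' [exact_match_accuracy()] but is never the headline.
#'
#' @param table Prediction table (needs `gt_*` and `pred_*` columns).
#' @return A single number in \[0, 1\].
#' @export
micro_accuracy <- function(table) {
  if (nrow(table) == 0) {
    abort("prediction table must be non-empty", class = "pathmil_validation_error")
  }
  gt <- gt_matrix(table)
  pred <- pred_matrix(table)
  mean(gt == pred)
}

#' @rdname micro_accuracy
#' @export
exact_match_accuracy <- function(table) {
  if (nrow(table) == 0) {
    abort("prediction table must be non-empty", class = "pathmil_validation_error")
  }
  mean(rowSums(gt_matrix(table) == pred_matrix(table)) == n_classes())
}

#' Per-class precision, recall and F1
#'
#' One-vs-rest counts per class on the multilabel indicator columns. The F1
#' zero-division convention is 0: a class that is present but never predicted
#' (or predicted but never present) scores F1 = 0.
#'
#' @param table Prediction table.
#' @return Tibble with `class`, `tp`, `fp`, `fn`, `precision`, `recall`, `f1`,
#'   `support`.
#' @export
per_class_metrics <- function(table) {
  gt <- gt_matrix(table)
  pred <- pred_matrix(table)
  rows <- map(seq_len(n_classes()), function(j) {
    tp <- sum(gt[, j] == 1 & pred[, j] == 1)
    fp <- sum(gt[, j] == 0 & pred[, j] == 1)
    fn <- sum(gt[, j] == 1 & pred[, j] == 0)
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
    tibble(class = class_names()[j], tp = tp, fp = fp, fn = fn,
           precision = precision, recall = recall, f1 = f1, support = tp + fn)
  })
  bind_rows(rows)
}

#' Support-weighted macro F1
#'
#' Per-class F1 averaged with weights proportional to class support (number of
#' true positives cases of the class). Zero-support classes carry zero weight
#' and are excluded.
#'
#' @param table Prediction table.
#' @return List with `weighted_f1` and the `per_class` tibble.
#' @export
weighted_f1 <- function(table) {
  pc <- per_class_metrics(table)
  if (sum(pc$support) == 0) {
    abort("weighted F1 is undefined: all class supports are zero",
          class = "pathmil_metric_error")
  }
  keep <- pc$support > 0
  list(weighted_f1 = sum(pc$f1[keep] * pc$support[keep]) / sum(pc$support[keep]),
       per_class = pc)
}

#' Cohen's kappa for patch-level multiclass agreement
#'
#' Chance-corrected agreement between predicted and ground-truth patch
#' classes: kappa = (p_o - p_e) / (1 - p_e), with observed agreement p_o and
#' chance agreement p_e from the product of marginals. Returns 1 when both
#' p_o and p_e equal 1 (degenerate single-category case).
#'
#' @param table Tibble with columns `gt_class` and `pred_class` (values from
#'   `class_names()`), or two equal-length vectors via `gt`/`pred`.
#' @param gt,pred Optional vectors used instead of `table`.
#' @return Kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(table = NULL, gt = NULL, pred = NULL) {
  if (!is.null(table)) {
    gt <- table$gt_class
    pred <- table$pred_class
  }
  if (length(gt) == 0) {
    abort("need at least one row", class = "pathmil_validation_error")
  }
  lev <- sort(unique(c(gt, pred)))
  gt <- factor(gt, levels = lev)
  pred <- factor(pred, levels = lev)
  n <- length(gt)
  tab <- table(gt, pred)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < .Machine$double.eps) {
    return(if (po == 1) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

#' One-vs-rest ROC curve and AUC
#'
#' Threshold sweep over the unique scores of one class with trapezoidal area.
#' A class without both a positive and a negative case is degenerate: the AUC
#' is flagged undefined (`NA` with attribute `degenerate`), never reported as
#' 0.
#'
#' @param table Prediction table (needs `gt_<class>` and `prob_<class>`).
#' @param class One of `class_names()`.
#' @return List with `curve` (tibble `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(table, class) {
  assert_known_classes(class)
  y <- table[[paste0("gt_", class)]]
  s <- table[[paste0("prob_", class)]]
  if (sum(y == 1) == 0 || sum(y == 0) == 0) {
    auc <- NA_real_
    attr(auc, "degenerate") <- TRUE
    return(structure(list(curve = tibble(threshold = numeric(), fpr = numeric(),
                                         tpr = numeric()), auc = auc,
                          class_name = class),
                     class = "pathmil_roc"))
  }
  thr <- c(Inf, sort(unique(s), decreasing = TRUE))
  tpr <- map_dbl(thr, function(t) mean(s[y == 1] >= t))
  fpr <- map_dbl(thr, function(t) mean(s[y == 0] >= t))
  o <- order(fpr, tpr)
  auc <- sum(diff(fpr[o]) * (head(tpr[o], -1) + tail(tpr[o], -1)) / 2)
  structure(list(curve = tibble(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc, class_name = class),
            class = "pathmil_roc")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Used to compare performance distributions between label sources (e.g.
#' models trained with automatic vs. manual weak labels). The null
#' distribution is enumerated exactly when the combined sample size is at most
#' 12; larger samples use the normal approximation with tie and continuity
#' corrections.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return Tibble with `statistic` (rank-sum of sample a), `p_value`, `method`.
#' @export
rank_sum_test <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    abort("both samples must be non-empty", class = "pathmil_validation_error")
  }
  na <- length(sample_a)
  nb <- length(sample_b)
  pooled <- c(sample_a, sample_b)
  r <- rank(pooled)
  w <- sum(r[seq_len(na)])
  if (na + nb <= 12) {
    idx <- combn(na + nb, na)
    sums <- colSums(matrix(r[idx], nrow = na))
    eps <- 1e-9
    mu <- na * (na + nb + 1) / 2
    p <- mean(abs(sums - mu) >= abs(w - mu) - eps)
    return(tibble(statistic = w, p_value = p, method = "exact"))
  }
  mu <- na * (na + nb + 1) / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / ((na + nb) * (na + nb - 1))
  sigma2 <- na * nb / 12 * ((na + nb + 1) - tie_term)
  z <- max(abs(w - mu) - 0.5, 0) / sqrt(sigma2)
  tibble(statistic = w, p_value = min(1, 2 * pnorm(-z)), method = "normal")
}

#' Find cases mislabeled by the automatic labeler
#'
#' A case is mislabeled iff at least one of its five indicators differs
#' between the automatic label table and the ground truth — the definition
#' used to restrict evaluation to the weak-label error subset.
#'
#' @param auto_labels,gt_labels Label tibbles over the same `case_id` set.
#' @return List with `case_ids` (mislabeled cases), `fraction`, and
#'   `per_class` disagreement counts.
#' @export
find_mislabeled <- function(auto_labels, gt_labels) {
  if (!setequal(auto_labels$case_id, gt_labels$case_id)) {
    abort("auto and ground-truth tables must cover the same case_ids",
          class = "pathmil_validation_error")
  }
  gt_labels <- gt_labels[match(auto_labels$case_id, gt_labels$case_id), ]
  a <- label_matrix(auto_labels)
  g <- label_matrix(gt_labels)
  diff <- a != g
  list(
    case_ids = auto_labels$case_id[rowSums(diff) > 0],
    fraction = mean(rowSums(diff) > 0),
    per_class = tibble(class = class_names(), disagreements = colSums(diff))
  )
}

#' Aggregate a prediction table onto an external scheme
#'
#' Maps both ground truth and predictions of a multilabel prediction table
#' onto an external dataset's label scheme and computes micro-accuracy over
#' the scheme's external classes. A case whose mapped prediction is empty
#' scores wrong against any positive ground truth.
#'
#' @param table Prediction table.
#' @param scheme Scheme name or scheme tibble (see [map_to_scheme()]).
#' @param schemes Scheme table.
#' @return List with `table` (external indicator columns `gt_*`/`pred_*`) and
#'   `micro_accuracy`.
#' @export
evaluate_on_scheme <- function(table, scheme, schemes = read_schemes()) {
  if (is.character(scheme)) {
    scheme_tab <- schemes %>% filter(.data$scheme_name == scheme)
  } else {
    scheme_tab <- scheme
  }
  ext <- sort(unique(scheme_tab$external_class))
  gt <- gt_matrix(table)
  pred <- pred_matrix(table)
  map_one <- function(mat_row) {
    hits <- map_to_scheme(setNames(mat_row, class_names()), scheme_tab)
    as.integer(ext %in% hits)
  }
  gt_ext <- t(apply(gt, 1, map_one))
  pred_ext <- t(apply(pred, 1, map_one))
  out <- tibble(case_id = table$case_id)
  for (j in seq_along(ext)) {
    out[[paste0("gt_", ext[j])]] <- gt_ext[, j]
    out[[paste0("pred_", ext[j])]] <- pred_ext[, j]
  }
  list(table = out, micro_accuracy = mean(gt_ext == pred_ext))
}
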