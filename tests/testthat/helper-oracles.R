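# Independent brute-force oracles used to check the package implementations.
# They are deliberately written from first principles (loops, enumeration,
# direct formulas) and share no code with the package internals.

oracle_micro_accuracy <- function(gt, pred) {
  correct <- 0; total <- 0
  for (i in seq_len(nrow(gt))) {
    for (j in seq_len(ncol(gt))) {
      total <- total + 1
      if (gt[i, j] == pred[i, j]) correct <- correct + 1
    }
  }
  correct / total
}

oracle_class_prf <- function(gt, pred, j) {
  tp <- fp <- fn <- 0
  for (i in seq_len(nrow(gt))) {
    if (gt[i, j] == 1 && pred[i, j] == 1) tp <- tp + 1
    if (gt[i, j] == 0 && pred[i, j] == 1) fp <- fp + 1
    if (gt[i, j] == 1 && pred[i, j] == 0) fn <- fn + 1
  }
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(precision = p, recall = r, f1 = f1, support = tp + fn)
}

oracle_weighted_f1 <- function(gt, pred) {
  num <- 0; den <- 0
  for (j in seq_len(ncol(gt))) {
    prf <- oracle_class_prf(gt, pred, j)
    if (prf$support > 0) {
      num <- num + prf$f1 * prf$support
      den <- den + prf$support
    }
  }
  num / den
}

oracle_kappa <- function(gt, pred) {
  lev <- sort(unique(c(gt, pred)))
  n <- length(gt)
  po <- sum(gt == pred) / n
  pe <- 0
  for (l in lev) {
    pe <- pe + (sum(gt == l) / n) * (sum(pred == l) / n)
  }
  if (abs(1 - pe) < 1e-15) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

# AUC as the probability a random positive outranks a random negative,
# counting ties as 1/2 (concordance form).
oracle_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  conc <- 0
  for (a in pos) {
    for (b in neg) {
      conc <- conc + (a > b) + 0.5 * (a == b)
    }
  }
  conc / (length(pos) * length(neg))
}

# Dynamic-programming Levenshtein distance.
oracle_edit_distance <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  d <- matrix(0, n + 1, m + 1)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- if (x[i] == y[j]) 0 else 1
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1, d[i + 1, j] + 1, d[i, j] + cost)
    }
  }
  d[n + 1, m + 1]
}

# All occurrences of gazetteer terms in a token stream; used to brute-force
# the greedy longest-match recognizer on small inputs.
oracle_greedy_match <- function(tokens, term_token_list) {
  hits <- list()
  i <- 1
  while (i <= length(tokens)) {
    best_len <- 0
    for (tt in term_token_list) {
      len <- length(tt)
      if (len > best_len && i + len - 1 <= length(tokens) &&
          identical(tokens[i:(i + len - 1)], tt)) {
        best_len <- len
      }
    }
    if (best_len > 0) {
      hits[[length(hits) + 1]] <- c(i, i + best_len - 1)
      i <- i + best_len
    } else {
      i <- i + 1
    }
  }
  hits
}

# Random multilabel prediction table (gt and pred indicator matrices plus
# probabilities) in the package's column layout.
random_prediction_table <- function(n, seed) {
  set.seed(seed)
  gt <- matrix(rbinom(n * 5, 1, 0.4), n, 5)
  prob <- matrix(runif(n * 5), n, 5)
  pred <- matrix(rbinom(n * 5, 1, 0.5), n, 5)
  tab <- tibble::tibble(case_id = paste0("c", seq_len(n)))
  cls <- pathmil::class_names()
  for (j in 1:5) {
    tab[[paste0("gt_", cls[j])]] <- gt[, j]
    tab[[paste0("prob_", cls[j])]] <- prob[, j]
    tab[[paste0("pred_", cls[j])]] <- pred[, j]
  }
  list(table = tab, gt = gt, pred = pred, prob = prob)
}

# A miniature gazetteer built in code for fast labeler tests.
toy_gazetteer <- function() {
  tibble::tibble(
    concept_id = c("c:adeno", "c:hgd", "c:lgd", "c:dys", "c:hyp", "c:norm",
                   "c:ta", "c:margin"),
    preferred_term = c("adenocarcinoma", "high-grade dysplasia",
                       "low-grade dysplasia", "dysplasia",
                       "hyperplastic polyp", "normal mucosa",
                       "tubular adenoma", "margin of resection"),
    synonyms = list(character(), "severe dysplasia", "mild dysplasia",
                    character(), "hyperplasia", "normal colonic mucosa",
                    character(), "resection margin"),
    mapped_class = c("cancer", "high_grade_dysplasia", "low_grade_dysplasia",
                     NA, "hyperplastic_polyp", "normal", NA, NA),
    grade_sensitive = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  )
}

# Tiny single-texture slide case -> bag, shared by MIL tests.
make_synth_bag <- function(label_set, seed, size = 672, tile_size = 32,
                           label_source = "gt") {
  sl <- synth_slide(make_label(label_set), size = size, seed = seed,
                    patch_size = 224)
  case <- list(case_id = paste0("case", seed), patient_id = paste0("pat", seed),
               slide = sl$slide, patch_gt = sl$patch_gt,
               gt_label = sl$gt_label, noisy_label = sl$gt_label)
  case_to_bag(case, tile_size = tile_size, label_source = label_source)
}
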