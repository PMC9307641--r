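test_that("micro-accuracy pools indicator cells and rejects empty tables", {
  tab <- random_prediction_table(3, seed = 1)$table
  # perfect and fully-flipped tables hit the boundaries
  perfect <- tab
  for (cls in class_names()) perfect[[paste0("pred_", cls)]] <- perfect[[paste0("gt_", cls)]]
  expect_equal(micro_accuracy(perfect), 1.0)
  flipped <- tab
  for (cls in class_names()) flipped[[paste0("pred_", cls)]] <- 1L - flipped[[paste0("gt_", cls)]]
  expect_equal(micro_accuracy(flipped), 0.0)
  # 3-sample table with exactly 2 wrong cells of 15
  two_off <- perfect
  two_off$pred_cancer[1] <- 1L - two_off$pred_cancer[1]
  two_off$pred_normal[3] <- 1L - two_off$pred_normal[3]
  expect_equal(micro_accuracy(two_off), 13 / 15)
  expect_error(micro_accuracy(perfect[0, ]), class = "pathmil_validation_error")
})

test_that("multilabel metrics match brute-force oracles on many random tables", {
  for (s in 1:200) {
    rt <- random_prediction_table(20, seed = s)
    expect_equal(micro_accuracy(rt$table), oracle_micro_accuracy(rt$gt, rt$pred),
                 tolerance = 1e-9)
    if (sum(rt$gt) > 0) {
      expect_equal(weighted_f1(rt$table)$weighted_f1,
                   oracle_weighted_f1(rt$gt, rt$pred), tolerance = 1e-9)
    }
    pc <- per_class_metrics(rt$table)
    j <- (s %% 5) + 1
    prf <- oracle_class_prf(rt$gt, rt$pred, j)
    expect_equal(pc$precision[j], prf$precision, tolerance = 1e-9)
    expect_equal(pc$recall[j], prf$recall, tolerance = 1e-9)
  }
  # supports sum to the total number of positive labels
  rt <- random_prediction_table(50, seed = 999)
  expect_identical(sum(per_class_metrics(rt$table)$support), sum(rt$gt))
})

test_that("weighted F1 applies the zero-division and zero-support conventions", {
  # single class present, half its positives found, no false positives
  tab <- tibble::tibble(case_id = paste0("c", 1:4))
  for (cls in class_names()) {
    tab[[paste0("gt_", cls)]] <- 0L
    tab[[paste0("prob_", cls)]] <- 0
    tab[[paste0("pred_", cls)]] <- 0L
  }
  tab$gt_cancer <- c(1L, 1L, 0L, 0L)
  tab$pred_cancer <- c(1L, 0L, 0L, 0L)
  res <- weighted_f1(tab)
  expect_equal(res$per_class$f1[1], 2 / 3)
  expect_equal(res$weighted_f1, 2 / 3)  # only cancer carries weight
  # all-zero supports are an error, not a number
  tab$gt_cancer <- 0L
  expect_error(weighted_f1(tab), class = "pathmil_metric_error")
})

test_that("Cohen's kappa matches the direct p_o/p_e formula and its invariances", {
  x <- sample(class_names(), 50, replace = TRUE)
  expect_equal(cohen_kappa(gt = x, pred = x), 1.0)
  for (s in 1:100) {
    set.seed(s)
    gt <- sample(class_names(), 40, replace = TRUE)
    pred <- sample(class_names(), 40, replace = TRUE)
    expect_equal(cohen_kappa(gt = gt, pred = pred), oracle_kappa(gt, pred),
                 tolerance = 1e-12)
    # invariance under simultaneous relabeling of both columns
    perm <- setNames(sample(class_names()), class_names())
    expect_equal(cohen_kappa(gt = unname(perm[gt]), pred = unname(perm[pred])),
                 cohen_kappa(gt = gt, pred = pred), tolerance = 1e-12)
  }
  # independent draws with matching marginals sit near zero
  set.seed(1)
  gt <- sample(class_names(), 5000, replace = TRUE)
  pred <- sample(class_names(), 5000, replace = TRUE)
  expect_lt(abs(cohen_kappa(gt = gt, pred = pred)), 0.05)
})

test_that("ROC/AUC matches a concordance oracle and handles degeneracy", {
  # perfectly separated scores
  tab <- random_prediction_table(10, seed = 5)$table
  tab$gt_cancer <- rep(c(1L, 0L), each = 5)
  tab$prob_cancer <- c(runif(5, 0.8, 1), runif(5, 0, 0.2))
  expect_equal(roc_auc(tab, "cancer")$auc, 1.0)
  # constant scores give chance area
  tab$prob_cancer <- rep(0.4, 10)
  expect_equal(roc_auc(tab, "cancer")$auc, 0.5)
  # random scores agree with the pairwise concordance count (tie-corrected)
  for (s in 1:50) {
    rt <- random_prediction_table(30, seed = 1000 + s)
    y <- rt$table$gt_low_grade_dysplasia
    if (sum(y) == 0 || sum(y) == 30) next
    r <- roc_auc(rt$table, "low_grade_dysplasia")
    expect_equal(r$auc, oracle_auc(y, rt$table$prob_low_grade_dysplasia),
                 tolerance = 1e-9)
    # AUC invariant under strictly monotone score transforms
    rt2 <- rt$table
    rt2$prob_low_grade_dysplasia <- exp(3 * rt2$prob_low_grade_dysplasia) - 0.5
    expect_equal(roc_auc(rt2, "low_grade_dysplasia")$auc, r$auc, tolerance = 1e-9)
  }
  # degenerate class flagged undefined, not zero
  tab0 <- random_prediction_table(6, seed = 2)$table
  tab0$gt_normal <- 1L
  a <- roc_auc(tab0, "normal")$auc
  expect_true(is.na(a))
  expect_true(isTRUE(attr(a, "degenerate")))
})

test_that("the rank-sum test enumerates exactly for small samples", {
  same <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$method, "exact")
  expect_equal(same$p_value, 1.0)
  # maximal separation: p equals the exact enumeration value 2/C(6,3)
  sep <- rank_sum_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$p_value, 2 / choose(6, 3))
  # exact and approximate branches agree near the switch point
  set.seed(4)
  a <- rnorm(6)
  b <- rnorm(6, 0.5)
  exact <- rank_sum_test(a, b)            # n = 12 -> exact
  approx <- rank_sum_test(c(a, rnorm(1, 100)), b)  # n = 13 -> normal branch
  expect_identical(exact$method, "exact")
  expect_identical(approx$method, "normal")
  # the normal branch tracks the reference implementation
  big_a <- c(a, a + 0.01)
  big_b <- c(b, b + 0.01)
  ours <- rank_sum_test(big_a, big_b)
  ref <- stats::wilcox.test(big_a, big_b, exact = FALSE, correct = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  expect_error(rank_sum_test(numeric(), 1), class = "pathmil_validation_error")
})

test_that("exact and approximate rank-sum branches agree at borderline sizes", {
  set.seed(9)
  for (i in 1:20) {
    a <- rnorm(6)
    b <- rnorm(6, runif(1, 0, 1))
    exact_p <- rank_sum_test(a, b)$p_value
    pooled <- c(a, b)
    r <- rank(pooled)
    w <- sum(r[1:6])
    mu <- 6 * 13 / 2
    sigma2 <- 6 * 6 / 12 * 13
    approx_p <- min(1, 2 * pnorm(-max(abs(w - mu) - 0.5, 0) / sqrt(sigma2)))
    expect_lt(abs(exact_p - approx_p), 0.02)
  }
})

test_that("mislabeled cases are exactly the rows with a differing indicator", {
  labs <- pathmil:::labels_to_tibble(paste0("c", 1:4), rbind(
    make_label("cancer"), make_label("normal"),
    make_label(c("cancer", "high_grade_dysplasia")), make_label("low_grade_dysplasia")))
  expect_length(find_mislabeled(labs, labs)$case_ids, 0)
  bad <- labs
  bad$normal[2] <- 0L
  bad$cancer[2] <- 1L
  res <- find_mislabeled(bad, labs)
  expect_identical(res$case_ids, "c2")
  expect_identical(as.integer(sum(res$per_class$disagreements)), 2L)
  expect_error(find_mislabeled(bad[1:3, ], labs), class = "pathmil_validation_error")
})

test_that("heatmaps paint normalized weights into patch footprints only", {
  patches <- tibble::tibble(slide_id = "s", x = c(0L, 224L), y = c(0L, 0L),
                            magnification = 10, tissue_fraction = 1)
  att <- matrix(0.5, 5, 2)
  att[1, ] <- c(0.9, 0.1)
  hm <- render_heatmap(c(224, 672), patches, att, "cancer")
  # untouched background stays NA
  expect_true(all(is.na(hm$heat[, 449:672])))
  # single dominant patch holds the unique maximum
  expect_equal(max(hm$heat, na.rm = TRUE), 1)
  expect_equal(unique(as.vector(hm$heat[, 1:224])), 1)
  expect_equal(unique(as.vector(hm$heat[, 225:448])), 0)
  # uniform attention renders at constant intensity
  hm_u <- render_heatmap(c(224, 672), patches, matrix(0.5, 5, 2), "cancer")
  expect_equal(unique(as.vector(hm_u$heat[, 1:448])), 0.5)
  # ranking of weights survives normalization
  att3 <- matrix(runif(10), 5, 2)
  hm3 <- render_heatmap(c(224, 672), patches, att3, "normal")
  expect_identical(order(hm3$weights$weight), order(hm3$weights$normalized))
  expect_error(render_heatmap(c(224, 672), patches, att[, 1, drop = FALSE], "cancer"),
               class = "pathmil_validation_error")
})

test_that("latent export filters by confidence and is seeded", {
  set.seed(3)
  emb <- matrix(rnorm(30 * 8), 30, 8)
  prob <- matrix(runif(30 * 5, 0, 0.49), 30, 5)
  # nothing above 0.5 -> empty
  expect_identical(nrow(export_latent(emb, prob)), 0L)
  # retained rows equal a brute-force filter count
  prob2 <- matrix(runif(30 * 5), 30, 5)
  lat <- export_latent(emb, prob2, seed = 11)
  expect_identical(nrow(lat), sum(apply(prob2, 1, max) > 0.5))
  lat2 <- export_latent(emb, prob2, seed = 11)
  expect_equal(lat, lat2)
})

test_that("scheme evaluation aggregates predictions before scoring", {
  tab <- prediction_table(
    c("a", "b"),
    rbind(c(0.9, 0.8, 0.1, 0.1, 0.1), c(0.1, 0.1, 0.1, 0.2, 0.9)),
    pathmil:::labels_to_tibble(c("a", "b"), rbind(
      make_label(c("cancer", "high_grade_dysplasia")), make_label("normal"))))
  res <- evaluate_on_scheme(tab, "imp_crc")
  expect_identical(res$table$`gt_High-risk`, c(1L, 0L))
  expect_identical(res$table$`pred_High-risk`, c(1L, 0L))
  expect_identical(res$table$`gt_Non-neoplastic`, c(0L, 1L))
  expect_equal(res$micro_accuracy, 1.0)
})
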