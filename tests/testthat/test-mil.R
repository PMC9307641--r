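test_that("the full-size residual architecture produces 512 features and a 128-d embedding", {
  bb <- backbone_spec("resnet34", seed = 1)
  expect_identical(bb$feature_dim, 512L)
  expect_identical(bb$input_size, 224L)
  expect_true(bb$frozen)
  head <- mil_head(bb$feature_dim)
  expect_identical(head$embed_dim, 128L)
  expect_identical(dim(head$weights$W1), c(512L, 128L))
  tile <- array(runif(224 * 224 * 3), c(224, 224, 3))
  feats <- backbone_features(list(tile), bb)
  expect_identical(dim(feats), c(1L, 512L))
  emb <- embed_bag(list(tile), bb, head)
  expect_identical(dim(emb), c(1L, 128L))
})

test_that("bag embedding preserves order, determinism and shape contracts", {
  bb <- backbone_spec("tiny", seed = 3)
  head <- mil_head(bb$feature_dim, 32, seed = 4)
  tile <- array(runif(32 * 32 * 3), c(32, 32, 3))
  emb <- embed_bag(list(tile, tile, tile), bb, head)
  expect_identical(dim(emb), c(3L, 32L))
  # identical patches -> identical rows
  expect_equal(emb[1, ], emb[2, ])
  expect_equal(emb[1, ], emb[3, ])
  # zero embedding map -> all-zero embeddings
  zero_head <- head
  zero_head$weights$W1[] <- 0
  zero_head$weights$b1[] <- 0
  expect_true(all(embed_bag(list(tile), bb, zero_head) == 0))
  # mismatched feature length -> shape error
  expect_error(embed_bag(matrix(0, 2, 7), bb, head), class = "pathmil_shape_error")
})

test_that("patch prediction is a softmax with lowest-index tie-breaking", {
  head <- mil_head(8, 4, seed = 1)
  # uniform logits -> uniform probabilities
  flat_head <- head
  flat_head$weights$Wc[] <- 0
  flat_head$weights$bc[] <- 0
  emb <- matrix(runif(3 * 4), 3, 4)
  pp <- patch_predict(emb, flat_head)
  expect_equal(unname(pp$probabilities), matrix(0.2, 3, 5), tolerance = 1e-12)
  expect_identical(pp$classes, rep("cancer", 3))
  # random logits match the direct exp/sum formula
  set.seed(7)
  emb2 <- matrix(rnorm(6 * 4), 6, 4)
  pp2 <- patch_predict(emb2, head)
  z <- emb2 %*% head$weights$Wc + matrix(head$weights$bc, 6, 5, byrow = TRUE)
  brute <- t(apply(z, 1, function(r) exp(r) / sum(exp(r))))
  expect_equal(unname(pp2$probabilities), brute, tolerance = 1e-9)
  expect_true(all(abs(rowSums(pp2$probabilities) - 1) < 1e-6))
})

test_that("attention rows are probability vectors with the stated edge cases", {
  head <- mil_head(16, 8, seed = 2)
  # p = 1: every class puts weight 1 on the only patch
  emb1 <- matrix(rnorm(16), 1, 16)
  pool1 <- attention_pool(pmax(emb1 %*% head$weights$W1, 0),
                          matrix(rnorm(5), 1, 5), head)
  expect_equal(unname(pool1$attention[, 1]), rep(1, 5))
  # identical embeddings -> uniform 1/p weights for every class
  embp <- matrix(rep(rnorm(8), each = 6), 6, 8)
  pool <- attention_pool(embp, matrix(rnorm(30), 6, 5), head = mil_head(16, 8, seed = 3))
  expect_equal(unname(pool$attention), matrix(1 / 6, 5, 6), tolerance = 1e-12)
})

test_that("WSI aggregation matches a hand-rolled weighted-sum oracle", {
  head <- mil_head(8, 4, seed = 9)
  set.seed(11)
  emb <- matrix(rnorm(3 * 4), 3, 4)
  logits <- matrix(rnorm(15), 3, 5)
  pool <- attention_pool(emb, logits, head)
  # oracle: per class, softmax attention scores over patches, weighted sum
  s <- emb %*% head$weights$Wa + matrix(head$weights$ba, 3, 5, byrow = TRUE)
  for (c in 1:5) {
    a <- exp(s[, c] - max(s[, c]))
    a <- a / sum(a)
    expect_equal(unname(pool$attention[c, ]), a, tolerance = 1e-9)
    wsi <- sum(a * logits[, c])
    expect_equal(unname(pool$wsi_logits[c]), wsi, tolerance = 1e-9)
    expect_equal(unname(pool$wsi_prob[c]), 1 / (1 + exp(-wsi)), tolerance = 1e-9)
  }
})

test_that("permuting patches permutes attention and leaves WSI probabilities unchanged", {
  bb <- backbone_spec("tiny", seed = 3)
  head <- mil_head(bb$feature_dim, 32, seed = 5)
  set.seed(13)
  tiles <- lapply(1:7, function(i) array(runif(32 * 32 * 3), c(32, 32, 3)))
  bag1 <- make_bag(tiles, make_label("cancer"), "s1")
  perm <- c(4, 1, 7, 3, 6, 2, 5)
  bag2 <- make_bag(tiles[perm], make_label("cancer"), "s1")
  p1 <- predict_wsi(bag1, bb, head)
  p2 <- predict_wsi(bag2, bb, head)
  expect_equal(p1$probabilities, p2$probabilities, tolerance = 1e-12)
  expect_equal(p1$attention[, perm], p2$attention, tolerance = 1e-12)
})

test_that("WSI thresholding is multilabel with an argmax fallback", {
  pred <- pathmil:::threshold_predictions(matrix(c(0.9, 0.1, 0.1, 0.1, 0.1), 1), 0.5)
  expect_identical(unname(pred[1, ]), c(1L, 0L, 0L, 0L, 0L))
  pred2 <- pathmil:::threshold_predictions(matrix(c(0.6, 0.7, 0.1, 0.1, 0.1), 1), 0.5)
  expect_identical(unname(pred2[1, ]), c(1L, 1L, 0L, 0L, 0L))
  # all below threshold: argmax (normal) set, never an empty prediction
  pred3 <- pathmil:::threshold_predictions(matrix(c(0.2, 0.1, 0.3, 0.2, 0.45), 1), 0.5)
  expect_identical(unname(pred3[1, ]), c(0L, 0L, 0L, 0L, 1L))
  # argmax ties resolve to the lowest class index
  pred4 <- pathmil:::threshold_predictions(matrix(c(0.4, 0.4, 0.2, 0.2, 0.2), 1), 0.5)
  expect_identical(unname(pred4[1, ]), c(1L, 0L, 0L, 0L, 0L))
})

test_that("patient folds partition patients with sizes differing by at most one", {
  folds <- make_folds(paste0("P", 1:20), k = 10, seed = 3)
  expect_identical(sort(unique(folds$fold)), 1:10)
  expect_identical(as.integer(table(folds$fold)), rep(2L, 10))
  expect_setequal(folds$patient_id, paste0("P", 1:20))
  expect_identical(anyDuplicated(folds$patient_id), 0L)
  expect_error(make_folds(paste0("P", 1:5), k = 10), class = "pathmil_validation_error")
})

test_that("training reduces the loss, is seeded, and never touches the backbone", {
  bb <- backbone_spec("tiny", seed = 21)
  set.seed(31)
  train_bags <- lapply(1:20, function(i) {
    cls <- class_names()[(i - 1) %% 5 + 1]
    make_synth_bag(cls, seed = 100 + i)
  })
  val_bags <- lapply(1:5, function(i) {
    make_synth_bag(class_names()[i], seed = 200 + i)
  })
  # patients differ by construction (seed-derived ids)
  cfg <- train_config(epochs = 5, seed = 17)
  before <- bb$weights
  fit <- train_fold(train_bags, val_bags, bb, cfg)
  expect_identical(bb$weights, before)  # frozen backbone untouched
  # training loss decreases over the first epochs on a separable problem
  expect_lt(fit$history$train_loss[3], fit$history$train_loss[1])
  # same seed twice -> bit-identical history
  fit2 <- train_fold(train_bags, val_bags, bb, cfg)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$head$weights, fit2$head$weights)
  # patient overlap between train and val is rejected
  expect_error(train_fold(train_bags, train_bags[1], bb, cfg),
               class = "pathmil_validation_error")
})

test_that("validation bags never contribute gradients", {
  bb <- backbone_spec("tiny", seed = 21)
  train_bags <- lapply(1:6, function(i) {
    make_synth_bag(class_names()[(i - 1) %% 5 + 1], seed = 300 + i)
  })
  val_a <- lapply(1:2, function(i) make_synth_bag("cancer", seed = 400 + i))
  val_b <- lapply(1:2, function(i) make_synth_bag("normal", seed = 500 + i))
  # a single epoch pins the early-stop epoch, so the returned head must be
  # a function of the training bags only
  cfg <- train_config(epochs = 1, seed = 23)
  fit_a <- train_fold(train_bags, val_a, bb, cfg)
  fit_b <- train_fold(train_bags, val_b, bb, cfg)
  expect_identical(fit_a$best_epoch, fit_b$best_epoch)
  expect_identical(fit_a$head$weights, fit_b$head$weights)
})

test_that("grid search is exhaustive, dominated configs lose, order does not matter", {
  bb <- backbone_spec("tiny", seed = 21)
  bags <- lapply(1:8, function(i) {
    make_synth_bag(class_names()[(i - 1) %% 5 + 1], seed = 600 + i)
  })
  folds <- make_folds(sapply(bags, function(b) b$patient_id), k = 2, seed = 1)
  base <- train_config(epochs = 2, seed = 29)
  # singleton space returns that configuration
  single <- grid_search(bags, bb, folds, base,
                        grid = list(learning_rate = 1e-3, weight_decay = 1e-3,
                                    embed_dim = 16L))
  expect_equal(single$best_config$learning_rate, 1e-3)
  expect_identical(nrow(single$trials), 1L)
  # a divergent learning rate is strictly dominated
  two <- grid_search(bags, bb, folds, base,
                     grid = list(learning_rate = c(1e-3, 50),
                                 weight_decay = 1e-3, embed_dim = 16L))
  expect_equal(two$best_config$learning_rate, 1e-3)
  # enumeration order does not change the winner
  rev_two <- grid_search(bags, bb, folds, base,
                         grid = list(learning_rate = c(50, 1e-3),
                                     weight_decay = 1e-3, embed_dim = 16L))
  expect_equal(rev_two$best_config$learning_rate, two$best_config$learning_rate)
})

test_that("cross-validation aggregates fold metrics as mean and sd", {
  bb <- backbone_spec("tiny", seed = 21)
  bags <- lapply(1:8, function(i) {
    make_synth_bag(class_names()[(i - 1) %% 5 + 1], seed = 700 + i)
  })
  cv <- cross_validate(bags, bb, train_config(epochs = 2, seed = 37), k = 2)
  expect_length(cv$fits, 2)
  expect_identical(nrow(cv$fold_metrics), 2L)
  agg <- cv$summary
  expect_equal(agg$mean[agg$metric == "micro_accuracy"],
               mean(cv$fold_metrics$micro_accuracy))
  expect_equal(agg$sd[agg$metric == "micro_accuracy"],
               sd(cv$fold_metrics$micro_accuracy))
  g <- glance(cv)
  expect_identical(g$k, 2L)
  expect_identical(tidy(cv), cv$fold_metrics)
})
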