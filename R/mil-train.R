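#' Training configuration for the MIL classifier
#'
#' Defaults follow the reference training recipe: 15 epochs of Adam at
#' learning rate 1e-3 with decay 1e-3, one bag per gradient step, a 128-d
#' embedding and a 0.5 decision threshold. The default `grid` is the
#' hyperparameter search space (learning rate and decay over 1e-2..1e-5,
#' embedding width over 32/64/128/256).
#'
#' @param epochs Training epochs (>= 1), default 15.
#' @param learning_rate Adam step size, default 1e-3.
#' @param weight_decay L2 penalty coefficient on weight matrices, default 1e-3.
#' @param embed_dim Embedding width, default 128.
#' @param decision_threshold WSI decision threshold, default 0.5.
#' @param augment Apply WSI-level augmentation to training bags each epoch;
#'   default `TRUE` (only possible when bags carry tiles, not features).
#' @param shared_attention Passed to [mil_head()].
#' @param seed Master seed; per-fold and per-epoch streams derive from it.
#' @param grid Named list of vectors defining the search space for
#'   [grid_search()].
#' @return A list of class `pathmil_train_config`.
#' @export
train_config <- function(epochs = 15L, learning_rate = 1e-3, weight_decay = 1e-3,
                         embed_dim = 128L, decision_threshold = 0.5,
                         augment = TRUE, shared_attention = FALSE, seed = 1L,
                         grid = list(learning_rate = 10^-(2:5),
                                     weight_decay = 10^-(2:5),
                                     embed_dim = c(32L, 64L, 128L, 256L))) {
  if (epochs < 1) abort("epochs must be >= 1", class = "pathmil_validation_error")
  if (learning_rate <= 0 || weight_decay < 0) {
    abort("learning_rate must be > 0 and weight_decay >= 0",
          class = "pathmil_validation_error")
  }
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 weight_decay = weight_decay, embed_dim = as.integer(embed_dim),
                 decision_threshold = decision_threshold,
                 augment = isTRUE(augment),
                 shared_attention = isTRUE(shared_attention),
                 seed = as.integer(seed), grid = grid),
            class = "pathmil_train_config")
}

# Forward pass on a feature matrix, keeping intermediates for backprop.
mil_forward <- function(feats, head) {
  w <- head$weights
  pre <- feats %*% w$W1 + matrix(w$b1, nrow(feats), head$embed_dim, byrow = TRUE)
  h <- pmax(pre, 0)
  z <- h %*% w$Wc + matrix(w$bc, nrow(h), n_classes(), byrow = TRUE)
  s_raw <- h %*% w$Wa + matrix(w$ba, nrow(h), ncol(w$Wa), byrow = TRUE)
  s <- if (head$shared_attention) s_raw[, rep(1L, n_classes()), drop = FALSE] else s_raw
  a <- col_softmax(s)
  wsi_logits <- colSums(a * z)
  wsi_prob <- 1 / (1 + exp(-wsi_logits))
  list(pre = pre, h = h, z = z, a = a, wsi_logits = wsi_logits, wsi_prob = wsi_prob)
}

bce_loss <- function(prob, y, eps = 1e-12) {
  p <- pmin(pmax(prob, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Gradients of the mean per-class binary cross-entropy w.r.t. head weights.
mil_backward <- function(feats, fwd, y, head) {
  g <- (fwd$wsi_prob - y) / n_classes()            # dL/d wsi_logit, length 5
  dz <- sweep(fwd$a, 2, g, "*")                    # p x 5
  da <- sweep(fwd$z, 2, g, "*")                    # p x 5
  inner <- colSums(fwd$a * da)
  ds <- fwd$a * sweep(da, 2, inner)                # softmax-over-patches back
  if (head$shared_attention) ds <- matrix(rowSums(ds), ncol = 1L)
  w <- head$weights
  dh <- dz %*% t(w$Wc) + ds %*% t(w$Wa)
  dpre <- dh * (fwd$pre > 0)
  list(W1 = t(feats) %*% dpre, b1 = colSums(dpre),
       Wc = t(fwd$h) %*% dz, bc = colSums(dz),
       Wa = t(fwd$h) %*% ds, ba = colSums(ds))
}

adam_init <- function(weights) {
  list(m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0), t = 0L)
}

adam_step <- function(weights, grads, state, lr, decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(weights)) {
    g <- grads[[nm]]
    if (!nm %in% c("b1", "bc", "ba")) g <- g + decay * weights[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    weights[[nm]] <- weights[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(weights = weights, state = state)
}

# Precompute per-bag tile lists at the backbone input size (so per-epoch
# augmentation works on small tiles) or feature matrices when bags already
# carry features.
prepare_bags <- function(bags, backbone) {
  lapply(bags, function(bag) {
    if (is.matrix(bag$patches)) {
      list(features = bag$patches, tiles = NULL, label = as_label(bag$label))
    } else {
      small <- lapply(bag$patches, function(tl) {
        d <- dim(tl)
        if (d[1] == backbone$input_size && d[2] == backbone$input_size) tl
        else if (d[1] == d[2] && d[1] %% backbone$input_size == 0)
          block_mean(tl, d[1] %/% backbone$input_size)
        else resize_raster(tl, backbone$input_size, backbone$input_size)
      })
      list(features = NULL, tiles = small, label = as_label(bag$label))
    }
  })
}

bag_features <- function(prep, backbone, augment_seed = NULL) {
  if (!is.null(prep$features)) return(prep$features)
  tiles <- prep$tiles
  if (!is.null(augment_seed)) tiles <- wsi_augment(tiles, augment_seed)$tiles
  backbone_features(tiles, backbone)
}

#' Train the MIL head on one fold
#'
#' Minimizes the mean per-class binary cross-entropy between the attention-
#' pooled WSI probabilities and the weak bag labels, one bag per Adam step,
#' with WSI-level augmentation applied to training bags each epoch. The
#' backbone stays frozen throughout. Returns the epoch checkpoint with the
#' lowest validation loss. Fully seeded: the same seed reproduces the history
#' bit for bit.
#'
#' @param train_bags,val_bags Lists of `pathmil_bag` with disjoint patients.
#' @param backbone A `pathmil_backbone`.
#' @param config A [train_config()].
#' @param seed Overrides `config$seed` when given.
#' @return An object of class `pathmil_fit`: `head` (best checkpoint),
#'   `history` (tibble epoch/train_loss/val_loss), `best_epoch`, `config`.
#' @export
train_fold <- function(train_bags, val_bags, backbone, config = train_config(),
                       seed = NULL) {
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  tp <- unique(map_chr(train_bags, "patient_id"))
  vp <- unique(map_chr(val_bags, "patient_id"))
  if (length(intersect(tp, vp)) > 0) {
    abort("train and validation bags share patients",
          class = "pathmil_validation_error")
  }
  head <- mil_head(backbone$feature_dim, config$embed_dim,
                   shared_attention = config$shared_attention,
                   seed = derive_seed(seed, 0L))
  prep_train <- prepare_bags(train_bags, backbone)
  prep_val <- prepare_bags(val_bags, backbone)
  val_feats <- lapply(prep_val, bag_features, backbone = backbone)
  state <- adam_init(head$weights)
  best <- list(loss = Inf, weights = head$weights, epoch = 0L)
  history <- vector("list", config$epochs)
  n_train <- length(prep_train)
  for (epoch in seq_len(config$epochs)) {
    eseed <- derive_seed(seed, epoch)
    order_idx <- with_local_seed(eseed, sample.int(n_train))
    losses <- numeric(n_train)
    for (ii in seq_along(order_idx)) {
      i <- order_idx[ii]
      aug_seed <- if (config$augment && is.null(prep_train[[i]]$features)) {
        derive_seed(eseed, i)
      } else NULL
      feats <- bag_features(prep_train[[i]], backbone, aug_seed)
      fwd <- mil_forward(feats, head)
      losses[ii] <- bce_loss(fwd$wsi_prob, prep_train[[i]]$label)
      grads <- mil_backward(feats, fwd, prep_train[[i]]$label, head)
      upd <- adam_step(head$weights, grads, state,
                       config$learning_rate, config$weight_decay)
      head$weights <- upd$weights
      state <- upd$state
    }
    val_losses <- map_dbl(seq_along(prep_val), function(i) {
      bce_loss(mil_forward(val_feats[[i]], head)$wsi_prob, prep_val[[i]]$label)
    })
    val_loss <- if (length(val_losses)) mean(val_losses) else NA_real_
    history[[epoch]] <- tibble(epoch = epoch, train_loss = mean(losses),
                               val_loss = val_loss)
    if (!is.na(val_loss) && val_loss < best$loss) {
      best <- list(loss = val_loss, weights = head$weights, epoch = epoch)
    }
  }
  if (is.infinite(best$loss)) best <- list(loss = NA_real_, weights = head$weights,
                                           epoch = config$epochs)
  head$weights <- best$weights
  structure(list(head = head, history = bind_rows(history),
                 best_epoch = best$epoch, config = config, seed = seed),
            class = "pathmil_fit")
}

#' @export
print.pathmil_fit <- function(x, ...) {
  cat(sprintf("<pathmil_fit> %d epochs, best epoch %d (val loss %.4f)\n",
              nrow(x$history), x$best_epoch,
              x$history$val_loss[x$best_epoch]))
  invisible(x)
}

#' Patient-level fold assignment
#'
#' Random partition of patients into k folds whose sizes differ by at most
#' one; all bags of a patient land in one fold, so images never leak between
#' training and validation partitions.
#'
#' @param patient_ids Character vector (repeats allowed; folds are assigned to
#'   unique patients).
#' @param k Number of folds, default 10.
#' @param seed Integer seed.
#' @return Tibble with `patient_id` and `fold` (1..k).
#' @export
make_folds <- function(patient_ids, k = 10L, seed = 1L) {
  patients <- unique(patient_ids)
  if (k > length(patients)) {
    abort(sprintf("k = %d exceeds the number of patients (%d)", k, length(patients)),
          class = "pathmil_validation_error")
  }
  shuffled <- with_local_seed(seed, sample(patients))
  tibble(patient_id = shuffled, fold = rep(seq_len(k), length.out = length(shuffled))) %>%
    arrange(.data$patient_id)
}

#' Exhaustive hyperparameter grid search
#'
#' Trains one model per (configuration, fold) pair and selects the
#' configuration with the lowest mean validation loss (each fold contributing
#' its best-epoch loss). Ties break toward the smaller embedding, then the
#' smaller learning rate, so the result does not depend on enumeration order.
#'
#' @param bags List of `pathmil_bag`.
#' @param backbone A `pathmil_backbone`.
#' @param folds Fold tibble from [make_folds()].
#' @param config Base [train_config()]; its `grid` defines the space unless
#'   `grid` is supplied.
#' @param grid Named list with any of `learning_rate`, `weight_decay`,
#'   `embed_dim`.
#' @param seed Master seed.
#' @return List with `best_config` (a `pathmil_train_config`) and `trials`
#'   (tibble of every configuration's mean validation loss).
#' @export
grid_search <- function(bags, backbone, folds, config = train_config(),
                        grid = config$grid, seed = config$seed) {
  space <- expand.grid(
    learning_rate = grid$learning_rate %||% config$learning_rate,
    weight_decay = grid$weight_decay %||% config$weight_decay,
    embed_dim = grid$embed_dim %||% config$embed_dim,
    KEEP.OUT.ATTRS = FALSE
  )
  if (nrow(space) == 0) abort("empty search space", class = "pathmil_validation_error")
  patients <- map_chr(bags, "patient_id")
  ks <- sort(unique(folds$fold))
  trials <- map(seq_len(nrow(space)), function(i) {
    cfg <- config
    cfg$learning_rate <- space$learning_rate[i]
    cfg$weight_decay <- space$weight_decay[i]
    cfg$embed_dim <- as.integer(space$embed_dim[i])
    losses <- map_dbl(ks, function(f) {
      val_pat <- folds$patient_id[folds$fold == f]
      fit <- train_fold(bags[!patients %in% val_pat], bags[patients %in% val_pat],
                        backbone, cfg, seed = derive_seed(seed, f))
      min(fit$history$val_loss)
    })
    tibble(learning_rate = cfg$learning_rate, weight_decay = cfg$weight_decay,
           embed_dim = cfg$embed_dim, mean_val_loss = mean(losses))
  }) %>% bind_rows()
  ranked <- trials %>%
    arrange(.data$mean_val_loss, .data$embed_dim, .data$learning_rate)
  best <- config
  best$learning_rate <- ranked$learning_rate[1]
  best$weight_decay <- ranked$weight_decay[1]
  best$embed_dim <- as.integer(ranked$embed_dim[1])
  list(best_config = best, trials = trials)
}

#' k-fold cross-validation of the MIL classifier
#'
#' One model per fold, trained on the other k-1 folds and validated on the
#' held-out fold; WSI-level metrics are reported per fold and aggregated as
#' mean and sample standard deviation across the k models.
#'
#' @param bags List of `pathmil_bag`.
#' @param backbone A `pathmil_backbone`.
#' @param config A [train_config()].
#' @param k Number of folds, default 10.
#' @param seed Master seed.
#' @return An object of class `pathmil_cv`: `fits` (k `pathmil_fit`),
#'   `fold_metrics`, `summary` (mean/sd per metric), `folds`.
#' @export
cross_validate <- function(bags, backbone, config = train_config(), k = 10L,
                           seed = config$seed) {
  patients <- map_chr(bags, "patient_id")
  folds <- make_folds(patients, k, seed = derive_seed(seed, 0L))
  fits <- list()
  fold_metrics <- list()
  for (f in seq_len(k)) {
    val_pat <- folds$patient_id[folds$fold == f]
    fit <- train_fold(bags[!patients %in% val_pat], bags[patients %in% val_pat],
                      backbone, config, seed = derive_seed(seed, f))
    fits[[f]] <- fit
    tab <- predict_bags(bags[patients %in% val_pat], backbone, fit$head,
                        config$decision_threshold)
    fold_metrics[[f]] <- tibble(
      fold = f,
      micro_accuracy = micro_accuracy(tab),
      weighted_f1 = weighted_f1(tab)$weighted_f1,
      val_loss = fit$history$val_loss[fit$best_epoch]
    )
  }
  fold_metrics <- bind_rows(fold_metrics)
  summary <- fold_metrics %>%
    tidyr::pivot_longer(-"fold", names_to = "metric", values_to = "value") %>%
    group_by(.data$metric) %>%
    summarise(mean = mean(.data$value), sd = sd(.data$value), .groups = "drop")
  structure(list(fits = fits, fold_metrics = fold_metrics, summary = summary,
                 folds = folds, config = config),
            class = "pathmil_cv")
}

#' Predict a set of bags into a prediction table
#'
#' @param bags List of `pathmil_bag` (with finalized labels used as ground
#'   truth columns).
#' @param backbone,head Model components.
#' @param threshold Decision threshold.
#' @return A [prediction_table()].
#' @export
predict_bags <- function(bags, backbone, head, threshold = 0.5) {
  prob <- do.call(rbind, map(bags, function(bag) {
    predict_wsi(bag, backbone, head, threshold)$probabilities
  }))
  gt <- do.call(rbind, map(bags, "label"))
  prediction_table(map_chr(bags, "slide_id"), prob, gt, threshold)
}

#' Patch-level evaluation table
#'
#' Pairs each patch's ground-truth class (from bags carrying `patch_gt`) with
#' the model's hard patch prediction; patches without ground truth are
#' skipped. Feed the result to [cohen_kappa()].
#'
#' @param bags List of `pathmil_bag` with `patch_gt`.
#' @param backbone,head Model components.
#' @return Tibble with `slide_id`, `patch`, `gt_class`, `pred_class`.
#' @export
patch_eval_table <- function(bags, backbone, head) {
  bind_rows(map(bags, function(bag) {
    if (is.null(bag$patch_gt)) return(NULL)
    pred <- predict_wsi(bag, backbone, head)$patch$classes
    keep <- !is.na(bag$patch_gt)
    if (!any(keep)) return(NULL)
    tibble(slide_id = bag$slide_id, patch = which(keep),
           gt_class = bag$patch_gt[keep], pred_class = pred[keep])
  }))
}
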