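#' Tidy a cross-validation result
#'
#' @param x A `pathmil_cv`.
#' @param ... Unused.
#' @return The per-fold metric tibble (`fold`, `micro_accuracy`,
#'   `weighted_f1`, `val_loss`).
#' @export
tidy.pathmil_cv <- function(x, ...) {
  x$fold_metrics
}

#' @rdname tidy.pathmil_cv
#' @return `glance()`: one row with `<metric>_mean` / `<metric>_sd` columns
#'   plus `k`.
#' @export
glance.pathmil_cv <- function(x, ...) {
  wide <- x$summary %>%
    tidyr::pivot_wider(names_from = "metric", values_from = c("mean", "sd"),
                       names_glue = "{metric}_{.value}")
  bind_cols(wide, tibble(k = length(x$fits)))
}

#' Tidy a single-fold fit
#'
#' @param x A `pathmil_fit`.
#' @param ... Unused.
#' @return The epoch history tibble.
#' @export
tidy.pathmil_fit <- function(x, ...) {
  x$history
}

#' @rdname tidy.pathmil_fit
#' @export
glance.pathmil_fit <- function(x, ...) {
  tibble(epochs = nrow(x$history), best_epoch = x$best_epoch,
         best_val_loss = x$history$val_loss[x$best_epoch],
         final_train_loss = x$history$train_loss[nrow(x$history)],
         embed_dim = x$head$embed_dim,
         learning_rate = x$config$learning_rate,
         weight_decay = x$config$weight_decay)
}
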