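#' Plot a one-vs-rest ROC curve
#'
#' @param object A `pathmil_roc` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pathmil_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(colour = "#B2182B", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = paste0("ROC - ", object$class_name),
      subtitle = sprintf("AUC = %.3f", object$auc),
      x = "False positive rate", y = "True positive rate") +
    ggplot2::theme_minimal()
}

#' Plot an attention heatmap
#'
#' @param object A `pathmil_heatmap` from [render_heatmap()].
#' @param ... Unused.
#' @return A ggplot of the (downsampled) heat raster.
#' @export
autoplot.pathmil_heatmap <- function(object, ...) {
  heat <- object$heat
  f <- max(1L, floor(nrow(heat) / 280))
  if (f > 1L) {
    nah <- is.na(heat)
    heat[nah] <- 0
    heat <- block_mean(heat, f)
    cover <- block_mean(1 - nah, f)
    heat[cover < 0.5] <- NA
  }
  df <- tidyr::expand_grid(y = seq_len(nrow(heat)), x = seq_len(ncol(heat)))
  df$weight <- as.vector(t(heat))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "white", limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0("Attention - ", object$class),
                  fill = "weight", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the training history of a fold
#'
#' @param object A `pathmil_fit`.
#' @param ... Unused.
#' @return A ggplot of train/validation loss per epoch.
#' @export
autoplot.pathmil_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, -"epoch",
                            names_to = "partition", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$partition)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dotted") +
    ggplot2::labs(title = "MIL training", y = "mean BCE loss") +
    ggplot2::theme_minimal()
}

#' Plot cross-validation fold metrics
#'
#' @param object A `pathmil_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pathmil_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(object$fold_metrics, -"fold",
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold), y = .data$value)) +
    ggplot2::geom_col(fill = "#2166AC") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "fold", y = NULL, title = "Cross-validation metrics") +
    ggplot2::theme_minimal()
}

#' Plot a 2-D latent-space export
#'
#' @param latent Tibble from [export_latent()].
#' @return A ggplot coloured by predicted class.
#' @export
plot_latent <- function(latent) {
  ggplot2::ggplot(latent, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                       colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(
      cancer = "#D7191C", high_grade_dysplasia = "#1A9641",
      low_grade_dysplasia = "#FDAE61", hyperplastic_polyp = "#2B83BA",
      normal = "grey20"), drop = FALSE) +
    ggplot2::labs(title = "Patch embedding space", colour = "predicted class") +
    ggplot2::theme_minimal()
}
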