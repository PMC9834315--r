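#' @importFrom ggplot2 autoplot ggplot aes
#' @export
ggplot2::autoplot

#' Plot the model vs control performance distributions
#'
#' The classic two-histogram view: chance performances from the
#' shuffled-label control pool in purple, real selection-model
#' performances in red, as fractions of models per performance bin.
#'
#' @param object A `ensemble_result`.
#' @param binwidth Histogram bin width (default 0.02).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ensemble_result
#' @export
autoplot.ensemble_result <- function(object, binwidth = 0.02, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(performance = object$runs$performance, pool = "selection models"),
    tibble::tibble(performance = object$controls$performance, pool = "control models")
  )
  ggplot(df, aes(x = .data$performance,
                 y = ggplot2::after_stat(density) * binwidth,
                 fill = .data$pool)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "identity", alpha = 0.65) +
    ggplot2::scale_fill_manual(values = c("selection models" = "#c0392b",
                                          "control models" = "#6c3483")) +
    ggplot2::geom_vline(xintercept = 1 / object$n_classes, linetype = 2) +
    ggplot2::labs(x = "fraction correct", y = "fraction of models", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Map significant features in Fourier space
#'
#' Tiles the spatial-frequency x orientation plane (SF band radially
#' ordered on the y axis, orientation bin on the x axis) and fills
#' significant wedges with their weight (percent correct). For 2-image
#' (awareness) relevance tables the left and right image features are
#' shown as facets.
#'
#' @param result A scored `ensemble_result`.
#' @param grid The `feature_grid` the features came from.
#' @return A ggplot.
#' @export
plot_relevance_map <- function(result, grid) {
  rel <- if (is.data.frame(result)) result else tidy(result)
  two_sided <- all(grepl("_[LR]$", rel$feature_id))
  if (two_sided) {
    rel$side <- ifelse(grepl("_L$", rel$feature_id), "left image", "right image")
    rel$wedge <- sub("_[LR]$", "", rel$feature_id)
  } else {
    rel$side <- "image"
    rel$wedge <- rel$feature_id
  }
  parts <- do.call(rbind, strsplit(sub("^f", "", rel$wedge), "_"))
  rel$sf_band <- as.integer(parts[, 1])
  rel$ori_bin <- as.integer(parts[, 2])
  rel$ori_deg <- (rel$ori_bin - 1) * 180 / grid$n_ori
  rel$weight_pct <- ifelse(rel$significant, 100 * rel$weight, NA_real_)
  p <- ggplot(rel, aes(x = .data$ori_deg, y = .data$sf_band, fill = .data$weight_pct)) +
    ggplot2::geom_tile(color = "grey85", linewidth = 0.1) +
    ggplot2::scale_fill_viridis_c(option = "inferno", na.value = "grey97",
                                  name = "% correct") +
    ggplot2::scale_x_continuous(breaks = c(0, 45, 90, 135)) +
    ggplot2::labs(x = "propagation direction (deg; 0 = horizontal Fourier axis)",
                  y = "spatial-frequency band (low to high)") +
    ggplot2::theme_minimal()
  if (two_sided) p <- p + ggplot2::facet_wrap(~side)
  p
}

#' Plot per-class first-percept fractions
#'
#' @param fractions Output of [first_percept_fractions()].
#' @return A ggplot (one point per subject, class means as columns).
#' @export
plot_first_percept <- function(fractions) {
  ggplot(fractions, aes(x = .data$class, y = .data$fraction)) +
    ggplot2::stat_summary(fun = mean, geom = "col", fill = "grey80", width = 0.6) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "image class", y = "fraction perceived first") +
    ggplot2::theme_minimal()
}

#' Plot the bias-prediction permutation test
#'
#' @param object A `bias_prediction`.
#' @param ... Unused.
#' @return A ggplot of per-fold accuracies with the overall accuracy and
#'   permutation p in the title.
#' @method autoplot bias_prediction
#' @export
autoplot.bias_prediction <- function(object, ...) {
  ggplot(tidy(object), aes(x = factor(.data$fold), y = .data$accuracy)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_hline(yintercept = object$overall_accuracy, color = "#c0392b") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "fold", y = "accuracy",
                  title = sprintf("bias-based prediction: %.1f%% (perm p = %.3f)",
                                  100 * object$overall_accuracy, object$perm_p)) +
    ggplot2::theme_minimal()
}
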