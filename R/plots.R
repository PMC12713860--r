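# Plotting: hypnograms, normalized confusion matrices, SHAP rankings.

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_step geom_col
#'   geom_text scale_fill_gradient labs theme_minimal coord_flip
NULL

#' Plot a hypnogram
#'
#' Classic staircase display with wake on top and deep sleep at the
#' bottom.
#'
#' @param object An `eda_hypnogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eda_hypnogram <- function(object, ...) {
  depth <- c(W = 5, REM = 4, N1 = 3, N2 = 2, N3 = 1)
  df <- tibble::tibble(
    hours = object$epoch * EPOCH_LEN_S / 3600,
    depth = depth[as.character(object$stage)]
  )
  ggplot(df, aes(x = .data$hours, y = .data$depth)) +
    geom_step() +
    ggplot2::scale_y_continuous(
      breaks = unname(depth), labels = names(depth),
      limits = c(0.5, 5.5)
    ) +
    labs(x = "time (h)", y = NULL, title = "Hypnogram") +
    theme_minimal()
}

#' Plot the row-normalized confusion matrix of an evaluation
#'
#' @param object An `eda_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eda_eval <- function(object, ...) {
  cm <- normalized_confusion(object$folds$truth, object$folds$pred, object$classes)
  df <- tidyr::expand_grid(
    truth = factor(rownames(cm), levels = rev(object$classes)),
    pred = factor(colnames(cm), levels = object$classes)
  )
  df$value <- mapply(
    function(a, b) cm[a, b],
    as.character(df$truth), as.character(df$pred)
  )
  ggplot(df, aes(x = .data$pred, y = .data$truth, fill = .data$value)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f", .data$value)), size = 3) +
    scale_fill_gradient(low = "white", high = "steelblue", limits = c(0, 1)) +
    labs(
      x = "predicted", y = "true", fill = "row fraction",
      title = sprintf("%s (%s)", object$task, object$mode)
    ) +
    theme_minimal()
}

#' Plot a SHAP importance ranking
#'
#' @param object An `eda_shap` from [shap_report()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eda_shap <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot(df, aes(x = .data$feature, y = .data$mean_abs_shap)) +
    geom_col(fill = "steelblue") +
    coord_flip() +
    labs(x = NULL, y = "mean |SHAP|", title = "Feature importance") +
    theme_minimal()
}
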