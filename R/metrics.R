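# Evaluation metrics and SHAP-based interpretation.

#' Macro F1, macro recall, and accuracy
#'
#' Per-class recall, precision, and F1 with the 0/0 -> 0 convention,
#' macro-averaged over the full class vocabulary (classes absent from
#' the predictions, or from the truth, still contribute — with zero
#' support they contribute 0, which deliberately depresses scores when a
#' fold lacks a class).
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param classes Class vocabulary; defaults to the union of observed
#'   labels.
#' @return Named numeric vector
#'   `(macro_f1, macro_recall, accuracy)`, plus per-class scores in the
#'   `"per_class"` attribute.
#' @export
macro_scores <- function(y_true, y_pred, classes = NULL) {
  if (length(y_true) == 0 || length(y_true) != length(y_pred)) {
    abort("`y_true` and `y_pred` must be non-empty and of equal length")
  }
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  if (!all(c(y_true, y_pred) %in% classes)) {
    abort("labels outside the supplied class vocabulary")
  }
  per <- purrr::map_dfr(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    fp <- sum(y_true != cl & y_pred == cl)
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    tibble::tibble(class = cl, recall = recall, precision = precision, f1 = f1)
  })
  out <- c(
    macro_f1 = mean(per$f1),
    macro_recall = mean(per$recall),
    accuracy = mean(y_true == y_pred)
  )
  attr(out, "per_class") <- per
  out
}

#' Adjusted accuracy for the three-class OSA task
#'
#' Collapses mild and moderate-severe into one OSA class and returns the
#' resulting binary accuracy; confusing the two OSA severities no longer
#' counts as an error, only missing (or inventing) OSA does.
#'
#' @param y_true,y_pred Label vectors over the three-class OSA
#'   vocabulary.
#' @return Binary accuracy in `[0, 1]`.
#' @export
adjusted_accuracy <- function(y_true, y_pred) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (!all(c(y_true, y_pred) %in% OSA3)) {
    abort("adjusted accuracy is defined for the three-class OSA labels only")
  }
  collapse <- function(y) ifelse(y == "non-OSA", "non-OSA", "OSA")
  mean(collapse(y_true) == collapse(y_pred))
}

#' Row-normalized confusion matrix
#'
#' @param y_true,y_pred Label vectors.
#' @param classes Class vocabulary (default: union of observed labels).
#' @return A K x K matrix whose rows sum to 1; rows without support are
#'   all zero and listed in the `"zero_rows"` attribute.
#' @export
normalized_confusion <- function(y_true, y_pred, classes = NULL) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  cm <- table(
    factor(y_true, levels = classes),
    factor(y_pred, levels = classes)
  )
  cm <- unclass(cm)
  rs <- rowSums(cm)
  out <- cm / ifelse(rs > 0, rs, 1)
  attr(out, "zero_rows") <- classes[rs == 0]
  out
}

#' SHAP feature-importance report
#'
#' Exact tree-SHAP contributions for every sample; the importance of a
#' feature is the mean absolute SHAP value across samples, summed over
#' the class outputs for multiclass models. Additivity (contributions
#' plus bias equal the model's margin output) is verified internally.
#'
#' @param model An `eda_model`.
#' @param newdata Feature tibble matching the model's schema.
#' @param top_k Number of features to report (default 20).
#' @return A tibble of class `eda_shap` with `feature` and `mean_abs_shap`,
#'   sorted descending, at most `top_k` rows; the full ranking is kept in
#'   the `"full"` attribute.
#' @export
shap_report <- function(model, newdata, top_k = 20) {
  if (!inherits(model, "eda_model")) abort("`model` must be a fitted eda_model")
  x <- design_matrix(newdata, model$feature_cols)
  dm <- xgboost::xgb.DMatrix(x)
  contrib <- predict(model$booster, dm, predcontrib = TRUE)
  marg <- predict(model$booster, dm, outputmargin = TRUE)
  if (length(dim(contrib)) == 3) { # [n, class, feature + bias]
    add_err <- max(abs(apply(contrib, c(1, 2), sum) - marg))
    per_feat <- apply(abs(contrib), 3, mean) # mean |phi| per feature, summed
    per_feat <- per_feat * dim(contrib)[2] # over classes (mean -> sum)
    names(per_feat) <- dimnames(contrib)[[3]]
  } else {
    add_err <- max(abs(rowSums(contrib) - marg))
    per_feat <- colMeans(abs(contrib))
  }
  if (!is.finite(add_err) || add_err > 1e-3) {
    abort(sprintf("SHAP additivity violated (max error %.2e)", add_err))
  }
  per_feat <- per_feat[names(per_feat) != "BIAS" & names(per_feat) != "(Intercept)"]
  full <- tibble::tibble(
    feature = names(per_feat),
    mean_abs_shap = unname(per_feat)
  ) |>
    dplyr::arrange(dplyr::desc(.data$mean_abs_shap))
  out <- head(full, top_k)
  attr(out, "full") <- full
  attr(out, "additivity_error") <- add_err
  class(out) <- c("eda_shap", class(out))
  out
}

#' Per-fold metrics of an evaluation
#'
#' One row per validation fold (subject) with macro F1, macro recall,
#' accuracy, and — for the three-class OSA tasks — adjusted accuracy.
#'
#' @param x An `eda_eval`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy eda_eval
#' @export
tidy.eda_eval <- function(x, ...) {
  purrr::map_dfr(split(x$folds, x$folds$subject_id), function(f) {
    ms <- macro_scores(f$truth, f$pred, x$classes)
    row <- tibble::tibble(
      subject_id = f$subject_id[1],
      n_epochs = nrow(f),
      macro_f1 = ms[["macro_f1"]],
      macro_recall = ms[["macro_recall"]],
      accuracy = ms[["accuracy"]]
    )
    if (startsWith(x$task, "osa3")) {
      row$adjusted_accuracy <- adjusted_accuracy(f$truth, f$pred)
    }
    row
  })
}

#' Aggregate metrics of an evaluation
#'
#' Fold-averaged macro F1, macro recall, accuracy (and adjusted accuracy
#' for three-class OSA tasks) in one row; `aggregate = "pooled"` scores
#' all epochs jointly instead of averaging per-subject scores.
#'
#' @param x An `eda_eval`.
#' @param aggregate `"fold"` (default) or `"pooled"`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance eda_eval
#' @export
glance.eda_eval <- function(x, aggregate = c("fold", "pooled"), ...) {
  aggregate <- match.arg(aggregate)
  if (aggregate == "fold") {
    per <- tidy.eda_eval(x)
    out <- tibble::tibble(
      task = x$task, mode = x$mode, n_subjects = nrow(per),
      n_epochs = sum(per$n_epochs),
      macro_f1 = mean(per$macro_f1),
      macro_recall = mean(per$macro_recall),
      accuracy = mean(per$accuracy)
    )
    if ("adjusted_accuracy" %in% names(per)) {
      out$adjusted_accuracy <- mean(per$adjusted_accuracy)
    }
  } else {
    ms <- macro_scores(x$folds$truth, x$folds$pred, x$classes)
    out <- tibble::tibble(
      task = x$task, mode = x$mode,
      n_subjects = length(unique(x$folds$subject_id)),
      n_epochs = nrow(x$folds),
      macro_f1 = ms[["macro_f1"]],
      macro_recall = ms[["macro_recall"]],
      accuracy = ms[["accuracy"]]
    )
    if (startsWith(x$task, "osa3")) {
      out$adjusted_accuracy <- adjusted_accuracy(x$folds$truth, x$folds$pred)
    }
  }
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
print.eda_eval <- function(x, ...) {
  g <- glance.eda_eval(x)
  cat(sprintf(
    "<eda_eval> task %s, %s validation: %d subjects, %d epochs\n",
    x$task, x$mode, g$n_subjects, g$n_epochs
  ))
  cat(sprintf(
    "  macro F1 %.3f | macro recall %.3f | accuracy %.3f%s\n",
    g$macro_f1, g$macro_recall, g$accuracy,
    if ("adjusted_accuracy" %in% names(g)) {
      sprintf(" | adjusted accuracy %.3f", g$adjusted_accuracy)
    } else {
      ""
    }
  ))
  invisible(x)
}
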