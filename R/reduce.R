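# Greedy correlation-based feature elimination.
#
# Redundant variables are discarded by scanning the Pearson correlation
# matrix: anchors are visited in ascending column order, skipping columns
# already eliminated, and every later column correlated with the anchor
# beyond the threshold is dropped. With r_th = 0.8 this collapses the
# three large clusters the feature set exhibits (time-domain statistics,
# wavelet statistics, non-linear features) to single representatives.

#' Pairwise Pearson correlation of feature columns
#'
#' @param m An `eda_features` tibble (or any data frame); only the
#'   numeric feature columns enter. Zero-variance columns get
#'   correlation 0 with a warning.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
feature_cor_matrix <- function(m) {
  cols <- numeric_feature_columns(m)
  if (length(cols) == 0) cols <- names(m)[vapply(m, is.numeric, logical(1))]
  x <- as.matrix(m[cols])
  if (nrow(x) < 3) abort("need at least 3 epochs to estimate correlations")
  sds <- apply(x, 2, sd)
  flat <- !is.finite(sds) | sds == 0
  if (any(flat)) {
    warn(paste0(
      "zero-variance column(s); their correlations are set to 0: ",
      paste(cols[flat], collapse = ", ")
    ))
  }
  cc <- suppressWarnings(cor(x))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 1
  cc
}

#' Greedy threshold-based feature reduction
#'
#' Scans anchors `i` in ascending index order, skipping anchors that
#' were already eliminated; for each surviving anchor, eliminates every
#' not-yet-eliminated column `j > i` whose correlation with the anchor
#' exceeds `r_th`. By default the absolute correlation is thresholded
#' (anticorrelated duplicates are equally redundant); set
#' `absolute = FALSE` for the literal signed rule.
#'
#' @param corr Square symmetric correlation matrix (e.g. from
#'   [feature_cor_matrix()]).
#' @param r_th Threshold in (0, 1); default 0.8.
#' @param absolute Threshold `|r|` (default) or signed `r`.
#' @param keep Column names or indices never eliminated (e.g. a
#'   categorical column such as sex is exempt by construction since it
#'   never enters the correlation matrix).
#' @return A list of class `eda_reduction`: `retained` (ordered indices),
#'   `retained_names`, `eliminated` (tibble of dropped index, anchor,
#'   r value), `r_th`.
#' @export
greedy_reduce <- function(corr, r_th = 0.8, absolute = TRUE, keep = NULL) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr)) {
    abort("`corr` must be a square matrix")
  }
  if (!is.numeric(r_th) || length(r_th) != 1 || r_th <= 0 || r_th >= 1) {
    abort("`r_th` must lie strictly between 0 and 1")
  }
  p <- ncol(corr)
  keep_idx <- if (is.character(keep)) match(keep, colnames(corr)) else keep
  keep_idx <- keep_idx[!is.na(keep_idx)]
  alive <- rep(TRUE, p)
  drop_i <- integer()
  drop_anchor <- integer()
  drop_r <- numeric()
  for (i in seq_len(p)) {
    if (!alive[i]) next
    if (i == p) break
    js <- which(alive & seq_len(p) > i)
    js <- setdiff(js, keep_idx)
    r <- corr[i, js]
    hit <- if (absolute) abs(r) > r_th else r > r_th
    if (any(hit)) {
      victims <- js[hit]
      alive[victims] <- FALSE
      drop_i <- c(drop_i, victims)
      drop_anchor <- c(drop_anchor, rep(i, length(victims)))
      drop_r <- c(drop_r, corr[i, victims])
    }
  }
  structure(
    list(
      retained = which(alive),
      retained_names = colnames(corr)[alive],
      eliminated = tibble::tibble(
        dropped = drop_i, anchor = drop_anchor, r_value = drop_r
      ),
      r_th = r_th, absolute = absolute
    ),
    class = "eda_reduction"
  )
}

#' Reduce a feature matrix
#'
#' Fits the correlation matrix on `m` (typically the training fold) and
#' returns the reduction result; apply it to any matrix with
#' `m[, c(meta, result$retained_names, "sex")]`.
#'
#' @inheritParams feature_cor_matrix
#' @inheritParams greedy_reduce
#' @return An `eda_reduction`.
#' @export
reduce_features <- function(m, r_th = 0.8, absolute = TRUE) {
  greedy_reduce(feature_cor_matrix(m), r_th = r_th, absolute = absolute)
}

#' @export
print.eda_reduction <- function(x, ...) {
  cat(sprintf(
    "<eda_reduction> r_th = %.2f (%s): %d retained, %d eliminated\n",
    x$r_th, if (x$absolute) "|r|" else "signed r",
    length(x$retained), nrow(x$eliminated)
  ))
  invisible(x)
}
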