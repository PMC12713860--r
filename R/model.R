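# Label construction, SMOTE balancing, gradient-boosted classification,
# and the two validation protocols (leave-one-subject-out and
# personalized).

#' Merge the five scored stages into four
#'
#' N1 and N2 become light sleep, N3 becomes deep sleep; W and REM keep
#' their names.
#'
#' @param labels Factor or character vector over W, N1, N2, N3, REM.
#' @return Factor with levels W, light, deep, REM.
#' @export
merge_stages <- function(labels) {
  lab <- as.character(labels)
  bad <- setdiff(unique(lab), STAGES5)
  if (length(bad) > 0) {
    abort(paste0(
      "unknown stage code(s): ", paste(bad, collapse = ", "),
      " (expected the five-stage vocabulary W, N1, N2, N3, REM)"
    ))
  }
  map <- c(W = "W", N1 = "light", N2 = "light", N3 = "deep", REM = "REM")
  factor(unname(map[lab]), levels = STAGES4)
}

#' Assign the three-class OSA severity from AHI or ODI
#'
#' Severity classes: below 5 events/hour non-OSA, 5 up to (excluding) 15
#' mild, 15 and above moderate-severe. The same boundaries apply to both
#' indices.
#'
#' @param index_value Numeric AHI or ODI values (events/hour, >= 0).
#' @return Factor with levels non-OSA, mild, moderate-severe.
#' @export
assign_osa_class <- function(index_value) {
  if (any(index_value < 0 | !is.finite(index_value))) {
    abort("AHI/ODI values must be finite and non-negative")
  }
  cut(index_value,
    breaks = c(-Inf, 5, 15, Inf), right = FALSE,
    labels = OSA3
  )
}

#' Task specification
#'
#' @param task One of `"stage5"`, `"stage4"`, `"osa3_ahi"`, `"osa3_odi"`,
#'   `"osa2_ahi"`, `"osa2_odi"`.
#' @return A list of class `eda_task` with the class vocabulary and a
#'   labelling function `eda_features -> factor`.
#' @export
label_spec <- function(task = c(
                         "stage5", "stage4", "osa3_ahi", "osa3_odi",
                         "osa2_ahi", "osa2_odi"
                       )) {
  task <- match.arg(task)
  fun <- switch(task,
    stage5 = function(m) factor(as.character(m$stage), levels = STAGES5),
    stage4 = function(m) merge_stages(m$stage),
    osa3_ahi = function(m) assign_osa_class(m$ahi),
    osa3_odi = function(m) assign_osa_class(m$odi),
    osa2_ahi = function(m) {
      factor(ifelse(m$ahi < 5, "non-OSA", "OSA"), levels = OSA2)
    },
    osa2_odi = function(m) {
      factor(ifelse(m$odi < 5, "non-OSA", "OSA"), levels = OSA2)
    }
  )
  classes <- switch(task,
    stage5 = STAGES5, stage4 = STAGES4,
    osa3_ahi = OSA3, osa3_odi = OSA3, osa2_ahi = OSA2, osa2_odi = OSA2
  )
  structure(list(task = task, classes = classes, label_fun = fun),
    class = "eda_task"
  )
}

#' SMOTE balancing of a labelled training table
#'
#' Oversamples every minority class up to the majority count by
#' interpolating between a class member and one of its `k` nearest
#' same-class neighbours (Euclidean distance over the numeric feature
#' columns). The categorical `sex` column and the metadata columns are
#' copied from the seed sample (the nominal-feature variant); synthetic
#' rows are flagged in `.synthetic`. Classes smaller than `k + 1` use a
#' reduced neighbour count with a warning. Applied to training data only,
#' after any train/test split.
#'
#' @param m A labelled `eda_features` tibble.
#' @param label_col Name of the class column.
#' @param k Number of candidate neighbours (default 5).
#' @param seed Integer seed.
#' @return The balanced tibble (original rows first).
#' @export
smote_balance <- function(m, label_col = "label", k = 5, seed = 1) {
  y <- m[[label_col]]
  if (is.null(y)) abort(sprintf("no `%s` column", label_col))
  cols <- numeric_feature_columns(m)
  counts <- table(droplevels(factor(y)))
  target <- max(counts)
  m$.synthetic <- FALSE
  if (all(counts == target)) return(m)
  x <- as.matrix(m[cols])
  new_rows <- list()
  with_seed(seed, {
    for (cl in names(counts)[counts < target]) {
      idx <- which(y == cl)
      need <- target - length(idx)
      k_use <- min(k, length(idx) - 1)
      if (k_use < 1) {
        warn(sprintf("class `%s` has a single member; duplicated instead of interpolated", cl))
        pick <- rep(idx, length.out = need)
        block <- m[pick, ]
        block$.synthetic <- TRUE
        new_rows[[cl]] <- block
        next
      }
      if (k_use < k) {
        warn(sprintf("class `%s`: only %d neighbours available (k reduced)", cl, k_use))
      }
      xc <- x[idx, , drop = FALSE]
      dm <- as.matrix(dist(xc))
      diag(dm) <- Inf
      nn <- apply(dm, 1, function(r) order(r)[seq_len(k_use)])
      nn <- matrix(nn, ncol = length(idx)) # k_use x n_class
      seed_pick <- sample(seq_along(idx), need, replace = TRUE)
      nb_pick <- vapply(
        seed_pick,
        function(s) nn[sample.int(k_use, 1), s],
        integer(1)
      )
      gap <- runif(need)
      synth <- xc[seed_pick, , drop = FALSE] +
        gap * (xc[nb_pick, , drop = FALSE] - xc[seed_pick, , drop = FALSE])
      block <- m[idx[seed_pick], ]
      block[cols] <- as.data.frame(synth)
      block$.synthetic <- TRUE
      new_rows[[cl]] <- block
    }
  })
  dplyr::bind_rows(m, dplyr::bind_rows(new_rows))
}

#' Gradient-boosting hyperparameters
#'
#' @param nrounds Number of boosting rounds (default 300).
#' @param max_depth Tree depth (default 6).
#' @param eta Learning rate (default 0.1).
#' @param subsample,colsample_bytree Row/column subsampling (default 1).
#' @return A list of class `eda_boost_params`.
#' @export
boost_params <- function(nrounds = 300, max_depth = 6, eta = 0.1,
                         subsample = 1, colsample_bytree = 1) {
  structure(
    list(
      nrounds = nrounds, max_depth = max_depth, eta = eta,
      subsample = subsample, colsample_bytree = colsample_bytree
    ),
    class = "eda_boost_params"
  )
}

# Numeric design matrix for the booster: retained numeric columns plus
# sex as 0/1.
design_matrix <- function(m, feature_cols) {
  num <- setdiff(feature_cols, "sex")
  x <- as.matrix(m[num])
  if ("sex" %in% feature_cols) {
    x <- cbind(x, sex = as.numeric(m$sex == "M"))
  }
  x
}

#' Train the gradient-boosted stage/OSA classifier
#'
#' Fits an XGBoost decision-tree ensemble (softprob objective for more
#' than two classes, logistic for two) on the supplied design columns.
#' Single-threaded and seeded, so identical data and seed give identical
#' predictions.
#'
#' @param m Labelled training tibble (column `label`).
#' @param feature_cols Feature columns to use (include `"sex"` for the
#'   categorical covariate).
#' @param classes Class vocabulary (ordered).
#' @param params A [boost_params()].
#' @param seed Integer seed.
#' @return An object of class `eda_model`.
#' @export
fit_classifier <- function(m, feature_cols, classes,
                           params = boost_params(), seed = 1) {
  y <- factor(m$label, levels = classes)
  present <- levels(droplevels(y))
  if (length(present) < 2) abort("training data holds a single class")
  x <- design_matrix(m, feature_cols)
  n_class <- length(classes)
  obj <- if (n_class > 2) "multi:softprob" else "binary:logistic"
  plist <- list(
    objective = obj,
    max_depth = params$max_depth,
    eta = params$eta,
    subsample = params$subsample,
    colsample_bytree = params$colsample_bytree,
    nthread = 1,
    seed = seed
  )
  if (n_class > 2) plist$num_class <- n_class
  dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
  booster <- xgboost::xgb.train(params = plist, data = dtrain,
    nrounds = params$nrounds, verbose = 0)
  structure(
    list(
      booster = booster, feature_cols = feature_cols, classes = classes,
      params = params, seed = seed
    ),
    class = "eda_model"
  )
}

#' @export
predict.eda_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- design_matrix(newdata, object$feature_cols)
  p <- predict(object$booster, xgboost::xgb.DMatrix(x))
  k <- length(object$classes)
  pm <- if (is.matrix(p)) p else if (k > 2) {
    matrix(p, ncol = k, byrow = TRUE)
  } else {
    cbind(1 - p, p)
  }
  colnames(pm) <- object$classes
  if (type == "prob") return(pm)
  factor(object$classes[max.col(pm, ties.method = "first")],
    levels = object$classes
  )
}

# Shared per-fold pipeline: normalize on train, reduce on train, SMOTE
# train, fit, predict test.
run_fold <- function(train, test, spec, r_th, reduction, smote, k_smote,
                     params, seed, keep_model = FALSE) {
  norm <- fit_feature_normalizer(train)
  train_n <- predict(norm, train)
  test_n <- predict(norm, test)
  red <- if (is.null(reduction)) reduce_features(train_n, r_th = r_th) else reduction
  feat_cols <- c(red$retained_names, "sex")
  train_n$label <- spec$label_fun(train_n)
  if (smote) {
    train_n <- suppressWarnings(
      smote_balance(train_n, "label", k = k_smote, seed = derive_seed(seed, "smote"))
    )
  }
  model <- fit_classifier(train_n, feat_cols, spec$classes,
    params = params, seed = derive_seed(seed, "model")
  )
  pred <- predict(model, test_n)
  out <- tibble::tibble(
    subject_id = test$subject_id,
    epoch = test$epoch,
    truth = spec$label_fun(test),
    pred = pred
  )
  list(folds = out, model = if (keep_model) model else NULL, reduction = red)
}

#' Leave-one-subject-out evaluation
#'
#' One fold per subject: the subject's epochs form the test set and all
#' remaining subjects the training set. Normalization, feature
#' reduction, SMOTE, and model fitting are all fitted inside the fold's
#' training portion, so nothing from the test subject leaks into
#' training (`reduce_scope = "global"` reproduces the laxer whole-cohort
#' reduction protocol).
#'
#' @param cohort_features `eda_features` tibble covering >= 2 subjects.
#' @param task Task name or [label_spec()].
#' @param r_th Correlation-reduction threshold (default 0.8).
#' @param reduce_scope `"fold"` (default) or `"global"`.
#' @param smote Balance the training classes with SMOTE (default TRUE).
#' @param k_smote SMOTE neighbour count (default 5).
#' @param params A [boost_params()].
#' @param seed Master seed.
#' @param keep_models Keep each fold's fitted model (default FALSE).
#' @return An object of class `eda_eval`.
#' @export
loso_evaluate <- function(cohort_features, task = "stage4", r_th = 0.8,
                          reduce_scope = c("fold", "global"), smote = TRUE,
                          k_smote = 5, params = boost_params(), seed = 1,
                          keep_models = FALSE) {
  reduce_scope <- match.arg(reduce_scope)
  spec <- if (inherits(task, "eda_task")) task else label_spec(task)
  subjects <- unique(cohort_features$subject_id)
  if (length(subjects) < 2) abort("leave-one-subject-out needs at least 2 subjects")
  global_red <- if (reduce_scope == "global") {
    reduce_features(normalize_features(cohort_features), r_th = r_th)
  } else {
    NULL
  }
  folds <- purrr::map(subjects, function(sid) {
    test <- dplyr::filter(cohort_features, .data$subject_id == sid)
    train <- dplyr::filter(cohort_features, .data$subject_id != sid)
    if (nrow(test) == 0) {
      warn(sprintf("subject %s has no epochs; skipped", sid))
      return(NULL)
    }
    run_fold(train, test, spec,
      r_th = r_th, reduction = global_red,
      smote = smote, k_smote = k_smote, params = params,
      seed = derive_seed(seed, paste0("fold_", sid)),
      keep_model = keep_models
    )
  })
  folds <- purrr::compact(folds)
  structure(
    list(
      folds = dplyr::bind_rows(purrr::map(folds, "folds")),
      models = if (keep_models) purrr::map(folds, "model") else NULL,
      reductions = purrr::map(folds, "reduction"),
      task = spec$task, classes = spec$classes, mode = "loso", seed = seed
    ),
    class = "eda_eval"
  )
}

#' Personalized evaluation
#'
#' Like [loso_evaluate()], but a seeded random 25% of the left-out
#' subject's epochs joins the training set before SMOTE; the remaining
#' 75% is tested. The selection seed derives deterministically from the
#' master seed, so the same master seed always picks the same epochs.
#' Only the sleep-staging tasks use this protocol; OSA labels are
#' subject-level constants, so personalization would hand the classifier
#' the answer.
#'
#' @inheritParams loso_evaluate
#' @param frac Fraction of the left-out subject's epochs moved to
#'   training (default 0.25, exclusive of 0 and 1).
#' @return An `eda_eval` with `mode = "personalized"`.
#' @export
personalized_evaluate <- function(cohort_features, task = "stage4",
                                  frac = 0.25, r_th = 0.8,
                                  smote = TRUE, k_smote = 5,
                                  params = boost_params(), seed = 1,
                                  keep_models = FALSE) {
  if (!is.numeric(frac) || frac <= 0 || frac >= 1) {
    abort("`frac` must lie strictly between 0 and 1")
  }
  spec <- if (inherits(task, "eda_task")) task else label_spec(task)
  if (startsWith(spec$task, "osa")) {
    abort("OSA tasks are evaluated with leave-one-subject-out only")
  }
  subjects <- unique(cohort_features$subject_id)
  if (length(subjects) < 2) abort("need at least 2 subjects")
  folds <- purrr::map(subjects, function(sid) {
    mine <- dplyr::filter(cohort_features, .data$subject_id == sid)
    others <- dplyr::filter(cohort_features, .data$subject_id != sid)
    if (nrow(mine) < 8) {
      warn(sprintf("subject %s has fewer than 8 epochs; skipped", sid))
      return(NULL)
    }
    n_pers <- round(frac * nrow(mine))
    pick <- with_seed(
      derive_seed(seed, paste0("pers_", sid)),
      sample(nrow(mine), n_pers)
    )
    train <- dplyr::bind_rows(others, mine[pick, ])
    test <- mine[-pick, ]
    run_fold(train, test, spec,
      r_th = r_th, reduction = NULL,
      smote = smote, k_smote = k_smote, params = params,
      seed = derive_seed(seed, paste0("fold_", sid)),
      keep_model = keep_models
    )
  })
  folds <- purrr::compact(folds)
  structure(
    list(
      folds = dplyr::bind_rows(purrr::map(folds, "folds")),
      models = if (keep_models) purrr::map(folds, "model") else NULL,
      reductions = purrr::map(folds, "reduction"),
      task = spec$task, classes = spec$classes, mode = "personalized",
      seed = seed, frac = frac
    ),
    class = "eda_eval"
  )
}

#' Extract features for every subject of a cohort
#'
#' Runs preprocessing, event/storm detection, and feature extraction on
#' each recording of a [generate_cohort()] result (or any list of
#' `recording`/`truth` pairs) and stacks the per-subject tables.
#'
#' @param cohort List of per-subject lists with a `recording` element.
#' @param cfg A [preprocess_config()].
#' @param amp_threshold Event-detector amplitude threshold.
#' @return One `eda_features` tibble for the whole cohort.
#' @export
cohort_features <- function(cohort, cfg = preprocess_config(),
                            amp_threshold = 0.05) {
  purrr::map_dfr(cohort, function(subj) {
    rec <- subj$recording
    derived <- preprocess_recording(rec, cfg)
    ev <- detect_events(derived$eda, amp_threshold = amp_threshold, fs = cfg$fs_out)
    st <- detect_storms(ev, total_s = length(derived$eda) / cfg$fs_out)
    extract_features(rec, derived, ev, st)
  })
}
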