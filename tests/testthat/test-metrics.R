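# Metrics and SHAP.

test_that("macro scores follow the hand confusion-matrix arithmetic", {
  p <- macro_scores(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
  expect_equal(p[["macro_recall"]], 0.75)
  expect_equal(p[["macro_f1"]], mean(c(2 / 3, 0.8)))
  expect_equal(p[["accuracy"]], 0.75)
  per <- attr(p, "per_class")
  expect_equal(per$recall, c(0.5, 1.0))

  perf <- macro_scores(c("x", "y"), c("x", "y"))
  expect_equal(unname(perf), c(1, 1, 1), ignore_attr = TRUE)

  const <- macro_scores(rep(c("a", "b", "c", "d"), 25), rep("a", 100))
  expect_equal(const[["accuracy"]], 0.25)
  expect_equal(const[["macro_recall"]], 0.25)
  expect_error(macro_scores(character(), character()), "non-empty")
})

test_that("metrics agree with an independent reference on random vectors", {
  for (s in 1:100) {
    set.seed(s)
    k <- sample(2:5, 1)
    classes <- LETTERS[1:k]
    n <- sample(20:60, 1)
    yt <- factor(sample(classes, n, TRUE), levels = classes)
    yp <- factor(sample(classes, n, TRUE), levels = classes)
    ours <- macro_scores(yt, yp, classes)
    ref <- caret::confusionMatrix(yp, yt, mode = "everything")
    byc <- as.matrix(ref$byClass)
    if (k == 2) byc <- rbind(byc[1, ], NA) # caret reports one row for 2 classes
    rec <- if (k == 2) {
      e <- caret::confusionMatrix(yp, yt)$table
      c(e[1, 1] / sum(e[, 1]), e[2, 2] / sum(e[, 2]))
    } else {
      unname(as.matrix(ref$byClass)[, "Sensitivity"])
    }
    rec[is.na(rec)] <- 0
    expect_equal(ours[["macro_recall"]], mean(rec), tolerance = 1e-12)
    expect_equal(ours[["accuracy"]], unname(ref$overall["Accuracy"]), tolerance = 1e-12)
    if (k > 2) {
      f1 <- unname(as.matrix(ref$byClass)[, "F1"])
      f1[is.na(f1)] <- 0
      expect_equal(ours[["macro_f1"]], mean(f1), tolerance = 1e-12)
    }
  }
})

test_that("metrics are invariant to joint permutation of the pairs", {
  set.seed(4)
  yt <- sample(c("a", "b", "c"), 60, TRUE)
  yp <- sample(c("a", "b", "c"), 60, TRUE)
  perm <- sample(60)
  expect_equal(
    unname(macro_scores(yt, yp)),
    unname(macro_scores(yt[perm], yp[perm]))
  )
})

test_that("adjusted accuracy collapses the OSA severities", {
  expect_equal(adjusted_accuracy("mild", "moderate-severe"), 1)
  expect_equal(adjusted_accuracy(rep("mild", 4), rep("non-OSA", 4)), 0)
  for (s in 1:50) {
    set.seed(s)
    yt <- sample(c("non-OSA", "mild", "moderate-severe"), 30, TRUE)
    yp <- sample(c("non-OSA", "mild", "moderate-severe"), 30, TRUE)
    expect_gte(
      adjusted_accuracy(yt, yp),
      macro_scores(yt, yp)[["accuracy"]]
    )
  }
  expect_error(adjusted_accuracy("W", "N1"), "three-class OSA")
})

test_that("normalized confusion rows sum to one", {
  cm <- normalized_confusion(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
  expect_equal(unname(cm["A", ]), c(0.5, 0.5))
  expect_equal(unname(cm["B", ]), c(0, 1))
  expect_equal(unname(rowSums(cm)), c(1, 1), tolerance = 1e-12)
  id <- normalized_confusion(c("x", "y"), c("x", "y"))
  expect_equal(unname(id), diag(2), ignore_attr = TRUE)
  z <- normalized_confusion(c("a", "a"), c("a", "a"), classes = c("a", "b"))
  expect_equal(attr(z, "zero_rows"), "b")
  expect_equal(unname(rowSums(z)), c(1, 0))
})

test_that("SHAP ranks a single informative feature first and is additive", {
  # Only the storm-coverage feature carries the class signal.
  fm <- fake_features(4, 50, seed = 21)
  fm$label <- factor(ifelse(fm$ahi < 5, "non-OSA", "OSA"), levels = c("non-OSA", "OSA"))
  fm$storm_frac <- as.numeric(fm$label == "OSA") + rnorm(nrow(fm), sd = 0.2)
  cols <- c(setdiff(intersect(eda_feature_names(), names(fm)), "sex"), "sex")
  model <- fit_classifier(fm, cols, c("non-OSA", "OSA"),
    boost_params(nrounds = 60), seed = 3
  )
  rep <- shap_report(model, fm, top_k = 20)
  expect_equal(rep$feature[1], "storm_frac")
  expect_lt(attr(rep, "additivity_error"), 1e-3)

  # a feature the model never splits on carries zero SHAP mass
  full <- attr(rep, "full")
  lowest <- dplyr::filter(full, feature == "dl4_median")
  expect_lt(lowest$mean_abs_shap, rep$mean_abs_shap[1] / 10)

  # multiclass path: ranking still led by the informative feature
  fm3 <- fm
  fm3$label <- assign_osa_class(fm3$ahi)
  fm3$storm_frac <- as.numeric(fm3$label) + rnorm(nrow(fm3), sd = 0.2)
  m3 <- fit_classifier(fm3, cols, levels(fm3$label), boost_params(nrounds = 60), seed = 4)
  rep3 <- shap_report(m3, fm3, top_k = 5)
  expect_equal(rep3$feature[1], "storm_frac")
})

test_that("tidy and glance summarize an evaluation", {
  fm <- fake_features(3, 30, seed = 23)
  ev <- suppressWarnings(
    loso_evaluate(fm, "stage4", params = boost_params(nrounds = 20), seed = 2)
  )
  td <- tidy(ev)
  expect_equal(nrow(td), 3)
  expect_true(all(td$macro_f1 >= 0 & td$macro_f1 <= 1))
  g <- glance(ev)
  expect_equal(g$macro_f1, mean(td$macro_f1))
  gp <- glance(ev, aggregate = "pooled")
  expect_equal(gp$n_epochs, 90)
})
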