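# Labels, SMOTE, classifier, and validation protocols.

test_that("stage merging follows the clinical map and rejects foreign codes", {
  expect_equal(
    as.character(merge_stages(c("W", "N1", "N2", "N3", "REM"))),
    c("W", "light", "light", "deep", "REM")
  )
  expect_true(all(merge_stages(rep("N1", 5)) == "light"))
  expect_error(merge_stages(c("W", "light")), "unknown stage")
})

test_that("OSA severity boundaries land in the higher class", {
  expect_equal(as.character(assign_osa_class(2.8)), "non-OSA")
  expect_equal(as.character(assign_osa_class(24.9)), "moderate-severe")
  expect_equal(as.character(assign_osa_class(5)), "mild")
  expect_equal(as.character(assign_osa_class(15)), "moderate-severe")
  expect_equal(
    as.character(assign_osa_class(c(0, 4.99, 14.99))),
    c("non-OSA", "non-OSA", "mild")
  )
  expect_error(assign_osa_class(-1), "non-negative")
})

test_that("SMOTE balances to the majority and interpolates within class", {
  fm <- fake_features(2, 60, seed = 7)
  fm$label <- factor(rep(c("A", "B"), c(100, 20)))
  out <- smote_balance(fm, "label", k = 5, seed = 3)
  expect_equal(as.integer(table(out$label)), c(100L, 100L))
  expect_equal(sum(!out$.synthetic), nrow(fm))

  # balanced input returned unchanged
  fm2 <- fake_features(2, 30, seed = 8)
  fm2$label <- factor(rep(c("A", "B"), each = 30))
  expect_equal(nrow(smote_balance(fm2, "label")), nrow(fm2))

  # k = 1: every synthetic row lies on the segment between its seed and
  # the unique nearest neighbour
  small <- fake_features(1, 12, seed = 9)
  small$label <- factor(rep(c("A", "B"), c(8, 4)))
  aug <- smote_balance(small, "label", k = 1, seed = 5)
  syn <- dplyr::filter(aug, .synthetic)
  real <- dplyr::filter(aug, !.synthetic, label == "B")
  cols <- setdiff(intersect(eda_feature_names(), names(aug)), "sex")
  xr <- as.matrix(real[cols])
  on_segment <- vapply(seq_len(nrow(syn)), function(i) {
    v <- as.numeric(syn[i, cols])
    any(vapply(seq_len(nrow(xr)), function(a) {
      any(vapply(seq_len(nrow(xr)), function(b) {
        if (a == b) return(FALSE)
        d <- xr[b, ] - xr[a, ]
        tt <- sum((v - xr[a, ]) * d) / sum(d * d)
        tt >= -1e-8 && tt <= 1 + 1e-8 &&
          sqrt(sum((xr[a, ] + tt * d - v)^2)) < 1e-8
      }, logical(1)))
    }, logical(1)))
  }, logical(1))
  expect_true(all(on_segment))
})

test_that("the classifier is reproducible and learns separable data", {
  fm <- fake_features(4, 40, seed = 11, signal_cols = c("eda_mode", "eda_median"), effect = 4)
  fm$label <- merge_stages(fm$stage)
  cols <- c(setdiff(intersect(eda_feature_names(), names(fm)), "sex"), "sex")
  m1 <- fit_classifier(fm, cols, levels(fm$label), boost_params(nrounds = 60), seed = 2)
  m2 <- fit_classifier(fm, cols, levels(fm$label), boost_params(nrounds = 60), seed = 2)
  expect_identical(predict(m1, fm), predict(m2, fm))
  expect_gt(mean(predict(m1, fm) == fm$label), 0.99)
  one <- fm
  one$label <- factor("W", levels = levels(fm$label))
  expect_error(fit_classifier(one, cols, levels(fm$label)), "single class")
})

test_that("LOSO folds never leak the test subject", {
  fm <- fake_features(3, 24, seed = 13)
  ev <- suppressWarnings(
    loso_evaluate(fm, "stage4", params = boost_params(nrounds = 20), seed = 5)
  )
  expect_equal(sort(unique(ev$folds$subject_id)), sprintf("S%02d", 1:3))
  expect_equal(nrow(ev$folds), nrow(fm))
  per_subj <- table(ev$folds$subject_id)
  expect_true(all(per_subj == 24))
})

test_that("personalized validation uses a seeded 25% split", {
  fm <- fake_features(3, 100, seed = 14)
  p1 <- suppressWarnings(
    personalized_evaluate(fm, "stage4", params = boost_params(nrounds = 20), seed = 9)
  )
  p2 <- suppressWarnings(
    personalized_evaluate(fm, "stage4", params = boost_params(nrounds = 20), seed = 9)
  )
  expect_identical(p1$folds, p2$folds)
  tested <- dplyr::filter(p1$folds, subject_id == "S01")
  expect_equal(nrow(tested), 75)
  expect_error(personalized_evaluate(fm, "stage4", frac = 1.5), "between 0 and 1")
  expect_error(personalized_evaluate(fm, "osa3_ahi"), "leave-one-subject-out")
})

test_that("pure-noise features give chance-level LOSO scores", {
  # 4 balanced classes of noise: macro F1 should hover around 0.25.
  f1s <- vapply(1:5, function(s) {
    fm <- fake_features(4, 40, seed = 100 + s)
    ev <- suppressWarnings(
      loso_evaluate(fm, "stage4", params = boost_params(nrounds = 40), seed = s)
    )
    glance(ev, aggregate = "pooled")$macro_f1
  }, numeric(1))
  expect_lt(abs(mean(f1s) - 0.25), 0.1)
})
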