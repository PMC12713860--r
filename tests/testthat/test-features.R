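# The 77-variable feature set.

test_that("epoch slicing truncates trailing partial windows", {
  expect_equal(nrow(epoch_slices(300 * 35, 35)), 10)
  expect_equal(nrow(epoch_slices(299 * 35, 35)), 9)
  sl <- epoch_slices(300 * 35, 35)
  expect_equal(sl$start_s, 30 * (0:9))
  expect_equal(sl$start_idx[2], 35 * 30 + 1)
  expect_error(epoch_slices(100, 35), "shorter")
})

test_that("time features follow their closed forms on simple inputs", {
  f <- time_features(rep(3, 1050))
  expect_equal(unname(f["median"]), 3)
  expect_equal(unname(f["absmax"]), 3)
  expect_equal(unname(f["line_length"]), 0)
  expect_equal(unname(f["q10"]), 3)
  expect_equal(unname(f["q75"]), 3)
  expect_equal(unname(f["shannon_entropy"]), 0)
  expect_equal(unname(f["svd_entropy"]), 0)
  expect_equal(unname(time_features(c(0, 1, 0, 1, 0))["line_length"]), 4)
})

test_that("SVD entropy of a sine is below that of matched noise", {
  t35 <- (0:1049) / 35
  s <- sin(2 * pi * t35)
  cmp <- vapply(1:20, function(i) {
    set.seed(i)
    edasleep:::svd_entropy(s) < edasleep:::svd_entropy(rnorm(1050, sd = sd(s)))
  }, logical(1))
  expect_true(all(cmp))
})

test_that("derivative features use the documented conventions", {
  expect_equal(unname(derivative_features(c(-1, -2))["n_pos"]), 0)
  f <- derivative_features(c(-1, 1))
  expect_equal(unname(f["mean"]), 0)
  expect_equal(unname(f["var"]), 2) # unbiased sample variance
  expect_equal(unname(f["median"]), 0)
  expect_equal(unname(f["n_pos"]), 1)
  x <- rnorm(100)
  expect_equal(
    unname(derivative_features(x)["var"]),
    unname(derivative_features(-x)["var"])
  )
  expect_error(derivative_features(numeric(0)), "empty")
})

test_that("spectral features recover a pure tone and reject noise periodicity", {
  t35 <- (0:1049) / 35
  f <- freq_features(sin(2 * pi * 1.0 * t35), 35)
  expect_lt(abs(f[["psd_fmax"]] - 1.0), 35 / 1050 + 1e-9)
  expect_gt(f[["fishers_g"]], 0.9)
  gs <- vapply(1:20, function(i) {
    set.seed(i)
    freq_features(rnorm(1050), 35)[["fishers_g"]]
  }, numeric(1))
  expect_lt(max(gs), 0.2)
  expect_equal(unname(freq_features(numeric(1050), 35)), c(0, 0, 0))
  expect_error(freq_features(rnorm(32), 35), "64")
})

test_that("wavelet features follow hand-computed values", {
  z <- wavelet_features(numeric(64))
  expect_true(all(z == 0))
  expect_equal(unname(wavelet_features(c(3, 4))["norm"]), 5)
  f <- wavelet_features(c(-1, 2, 0, 5))
  expect_gte(f[["npos_frac"]], 0)
  expect_lte(f[["npos_frac"]], 1)
  expect_equal(f[["npos_frac"]], 0.5)
  expect_error(wavelet_features(numeric(0)), "empty")
})

test_that("Lyapunov estimate separates regular from chaotic dynamics", {
  t35 <- (0:1049) / 35
  s <- 2.5 * sin(2 * pi * t35)
  nf <- nonlinear_features(s, 35)
  expect_lte(nf[["lyapunov"]], 0.05)
  expect_lt(abs(nf[["env_max"]] - 2.5) / 2.5, 0.02)
  expect_lt(abs(nf[["env_min"]] + 2.5) / 2.5, 0.02)

  lg <- numeric(1050)
  lg[1] <- 0.4
  for (i in 2:1050) lg[i] <- 4 * lg[i - 1] * (1 - lg[i - 1])
  expect_gt(edasleep:::lyapunov_estimate(lg), 0)
  expect_equal(edasleep:::lyapunov_estimate(rep(1, 1050)), 0)
})

test_that("diffEDA features satisfy their algebraic identities", {
  expect_equal(unname(diff_features(numeric(0))), c(0, 0))
  d <- c(0.3, -1, 2, 0.5)
  f <- diff_features(d)
  expect_equal(f[["xcorr_sum"]], sum(d)^2)
  expect_equal(unname(diff_features(c(1, 1))["conv_max"]), 2)
})

test_that("extraction yields exactly 77 deterministic, finite columns", {
  r <- clean_event_recording(6, n_epochs = 8)
  d <- preprocess_recording(r$recording)
  ev <- detect_events(d$eda)
  st <- detect_storms(ev, total_s = length(d$eda) / 35)
  fm1 <- extract_features(r$recording, d, ev, st)
  fm2 <- extract_features(r$recording, d, ev, st)
  expect_identical(fm1, fm2)
  feats <- eda_feature_names()
  expect_length(feats, 77)
  expect_identical(intersect(names(fm1), feats), feats) # order frozen
  num <- fm1[setdiff(feats, "sex")]
  expect_true(all(vapply(num, function(cl) all(is.finite(cl)), logical(1))))
  # features 73-76 equal the events module's own output for a spot epoch
  k <- 3
  sl <- epoch_slices(length(d$eda), 35)
  es <- event_storm_features(
    ev, st, c(sl$start_s[k], sl$end_s[k]),
    d$eda[sl$start_idx[k]:sl$end_idx[k]], 35
  )
  expect_equal(
    unname(unlist(fm1[k, c("event_frac", "event_energy", "storm_frac", "storm_energy")])),
    unname(es)
  )
})

test_that("row order permutations only permute rows", {
  fm <- fake_features(2, 20, seed = 3)
  perm <- sample(nrow(fm))
  expect_equal(fm[perm, ], fm[perm, ]) # trivially stable
  expect_identical(fm[perm, ][order(perm), ], fm)
})

test_that("normalization is fitted on training subjects only", {
  fm <- fake_features(4, 30, seed = 5)
  train <- dplyr::filter(fm, subject_id != "S04")
  test <- dplyr::filter(fm, subject_id == "S04")
  norm <- fit_feature_normalizer(train)
  train_n <- predict(norm, train)
  test_n <- predict(norm, test)
  cols <- setdiff(intersect(eda_feature_names(), names(fm)), "sex")
  mtr <- vapply(train_n[cols], mean, numeric(1))
  vtr <- vapply(train_n[cols], var, numeric(1))
  expect_lt(max(abs(mtr)), 1e-10)
  expect_lt(max(abs(vtr - 1)), 1e-10)
  expect_gt(max(abs(vapply(test_n[cols], mean, numeric(1)))), 1e-6)

  fm$eda_mode <- 7 # constant column
  expect_warning(fit_feature_normalizer(fm), "constant")
  n2 <- suppressWarnings(fit_feature_normalizer(fm))
  expect_equal(predict(n2, fm)$eda_mode, rep(7, nrow(fm)))
})
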