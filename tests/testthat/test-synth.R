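# Synthetic generator: hypnograms, recordings, cohorts.

test_that("degenerate stage mix gives an all-wake hypnogram", {
  h <- generate_hypnogram(50, stage_mix = c(1, 0, 0, 0, 0), seed = 3)
  expect_equal(nrow(h), 50)
  expect_true(all(h$stage == "W"))
})

test_that("hypnogram proportions calibrate to the requested mix", {
  mix <- c(0.122, 0.165, 0.325, 0.182, 0.206)
  h <- generate_hypnogram(100000, stage_mix = mix, seed = 11)
  emp <- as.numeric(table(h$stage) / nrow(h))
  expect_lt(max(abs(emp - mix)), 0.02)
})

test_that("hypnogram generation is deterministic and validates inputs", {
  expect_identical(
    generate_hypnogram(200, seed = 5)$stage,
    generate_hypnogram(200, seed = 5)$stage
  )
  expect_error(
    generate_hypnogram(10, stage_mix = c(0.5, 0.2, 0.1, 0.1, 0.2)),
    "sum to 1"
  )
  expect_error(generate_hypnogram(0), "n_epochs")
})

test_that("silent profile yields a constant trace and empty ground truth", {
  h <- generate_hypnogram(4, seed = 1)
  prof <- subject_profile(
    tonic_level = 2, drift_coeffs = c(0.5, 0, 0),
    stage_event_rate = c(W = 0, N1 = 0, N2 = 0, N3 = 0, REM = 0),
    storm_base_per_h = 0, storm_slope_per_ahi = 0,
    artifact_rate = 0, noise_sd = 0, rw_sd = 0
  )
  r <- generate_recording(h, prof, seed = 2)
  expect_equal(max(abs(r$recording$signal - 2.5)), 0)
  expect_equal(nrow(r$truth$events), 0)
  expect_equal(nrow(r$truth$storms), 0)
  expect_error(generate_recording(h[0, ], prof), "non-empty")
})

test_that("stage-dependent event rates show up in planted events", {
  h <- generate_hypnogram(120,
    stage_mix = c(0.5, 0, 0, 0.5, 0),
    cycle_len_epochs = 40, seed = 9
  )
  prof <- subject_profile(
    stage_event_rate = c(W = 0.2, N1 = 0, N2 = 0, N3 = 6, REM = 0),
    storm_base_per_h = 0, storm_slope_per_ahi = 0, artifact_rate = 0
  )
  r <- generate_recording(h, prof, seed = 4)
  ev_epoch <- floor(r$truth$events$onset_s / 30)
  stage_of <- as.character(h$stage)[ev_epoch + 1]
  n_w <- sum(h$stage == "W")
  n_n3 <- sum(h$stage == "N3")
  expect_gt(sum(stage_of == "N3") / n_n3, sum(stage_of == "W") / n_w)
})

test_that("ground truth is consistent with the recording", {
  r <- clean_event_recording(2)
  total_s <- length(r$recording$signal) / r$recording$fs
  ev <- r$truth$events
  expect_true(all(ev$onset_s < ev$offset_s))
  expect_true(all(ev$onset_s >= 0 & ev$offset_s <= total_s))
  expect_false(is.unsorted(ev$onset_s))
  # storms: every interval spans >= 60 s and holds >= 2 events
  h <- generate_hypnogram(120, seed = 5)
  rs <- generate_recording(h, subject_profile(ahi = 30), seed = 6)
  st <- rs$truth$storms
  if (nrow(st) > 0) {
    expect_true(all(st$offset_s - st$onset_s >= 60))
    n_in <- vapply(
      seq_len(nrow(st)),
      function(i) {
        sum(rs$truth$events$onset_s >= st$onset_s[i] &
          rs$truth$events$onset_s <= st$offset_s[i])
      },
      numeric(1)
    )
    expect_true(all(n_in >= 2))
  }
})

test_that("storm load grows with AHI (Monte-Carlo over seeds)", {
  frac_for <- function(ahi, seed) {
    h <- generate_hypnogram(40, seed = seed)
    prof <- subject_profile(
      ahi = ahi,
      stage_event_rate = c(W = 0.3, N1 = 0.3, N2 = 0.3, N3 = 0.3, REM = 0.3)
    )
    r <- generate_recording(h, prof, seed = seed + 1000)
    total_s <- 40 * 30
    sum(pmin(r$truth$storms$offset_s, total_s) - r$truth$storms$onset_s) / total_s
  }
  lo <- vapply(1:20, function(s) frac_for(2, s), numeric(1))
  hi <- vapply(1:20, function(s) frac_for(25, s), numeric(1))
  expect_gt(mean(hi), mean(lo))
})

test_that("cohorts are deterministic, stratified, and need >= 2 subjects", {
  sc <- cohort_scenario("osa", n_epochs = 4)
  c1 <- generate_cohort(3, sc, seed = 21)
  c2 <- generate_cohort(3, sc, seed = 21)
  expect_identical(
    purrr::map(c1, ~ .x$recording$signal),
    purrr::map(c2, ~ .x$recording$signal)
  )
  cls <- vapply(
    c1,
    function(s) as.character(assign_osa_class(s$recording$profile$ahi)),
    character(1)
  )
  expect_setequal(cls, c("non-OSA", "mild", "moderate-severe"))
  expect_error(generate_cohort(1, sc), ">= 2")
})
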