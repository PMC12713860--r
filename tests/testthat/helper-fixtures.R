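# Shared fixtures, all built in code at test time.

# Match planted to detected events by onset with a tolerance; returns the
# detection F1 (this greedy matcher is independent of the detector).
event_match_f1 <- function(truth_onsets, detected_onsets, tol_s = 1) {
  used <- logical(length(detected_onsets))
  tp <- 0
  for (g in truth_onsets) {
    j <- which(!used & abs(detected_onsets - g) <= tol_s)
    if (length(j) > 0) {
      used[j[1]] <- TRUE
      tp <- tp + 1
    }
  }
  if (length(detected_onsets) == 0 || length(truth_onsets) == 0) return(0)
  prec <- tp / length(detected_onsets)
  rec <- tp / length(truth_onsets)
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

# A recording with well-separated high-SNR planted events and no storms,
# for detector recovery tests.
clean_event_recording <- function(seed, n_epochs = 60) {
  h <- generate_hypnogram(n_epochs, seed = seed)
  prof <- subject_profile(
    stage_event_rate = c(W = 2, N1 = 2, N2 = 2, N3 = 2, REM = 2),
    storm_base_per_h = 0, storm_slope_per_ahi = 0, artifact_rate = 0,
    noise_sd = 0.005, rw_sd = 0.001, event_amp = c(0.2, 0.5)
  )
  generate_recording(h, prof, seed = seed * 7 + 1)
}

# Synthetic feature table with the full 77-column schema, bypassing signal
# processing: for model-mechanics tests (leakage, SMOTE, determinism).
# `signal_col` columns get a class-dependent mean shift of `effect`.
fake_features <- function(n_subjects = 4, epochs = 40, seed = 1,
                          signal_cols = character(), effect = 2) {
  cols <- setdiff(eda_feature_names(), "sex")
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_subjects), function(i) {
      stage <- factor(
        sample(c("W", "N1", "N2", "N3", "REM"), epochs, replace = TRUE),
        levels = c("W", "N1", "N2", "N3", "REM")
      )
      m <- tibble::as_tibble(
        matrix(rnorm(epochs * length(cols)),
          nrow = epochs,
          dimnames = list(NULL, cols)
        )
      )
      for (sc in signal_cols) {
        m[[sc]] <- m[[sc]] + effect * as.integer(stage)
      }
      dplyr::bind_cols(
        tibble::tibble(
          subject_id = sprintf("S%02d", i),
          epoch = seq_len(epochs) - 1L,
          stage = stage,
          ahi = c(2, 8, 20, 30)[(i - 1) %% 4 + 1],
          odi = c(2, 8, 20, 30)[(i - 1) %% 4 + 1]
        ),
        m,
        tibble::tibble(sex = factor(ifelse(i %% 2 == 0, "M", "F"), levels = c("F", "M")))
      )
    })
  })
}

# Heavier end-to-end cohorts shared between the model tests and the
# acceptance suite; computed once per test run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

strong_acceptance_features <- function() {
  cached("strong_fm", {
    coh <- generate_cohort(10, cohort_scenario("strong", n_epochs = 80), seed = 102)
    cohort_features(coh)
  })
}

null_acceptance_features <- function() {
  cached("null_fm", {
    coh <- generate_cohort(10, cohort_scenario("null", n_epochs = 80), seed = 101)
    cohort_features(coh)
  })
}

# Independent oracle for the greedy correlation reduction: a
# differently-coded elimination scan.
brute_force_scan <- function(cc, r_th, absolute = TRUE) {
  p <- ncol(cc)
  eliminated <- rep(FALSE, p)
  i <- 1
  while (i <= p) {
    if (!eliminated[i]) {
      j <- i + 1
      while (j <= p) {
        if (!eliminated[j]) {
          v <- if (absolute) abs(cc[i, j]) else cc[i, j]
          if (v > r_th) eliminated[j] <- TRUE
        }
        j <- j + 1
      }
    }
    i <- i + 1
  }
  which(!eliminated)
}

# Random correlation structures with strong common factors, so the scan
# actually has something to eliminate.
random_corr <- function(p, seed) {
  set.seed(seed)
  x <- matrix(rnorm(3 * p), ncol = p) %*% diag(runif(p, 0.5, 2))
  x <- x + matrix(rnorm(3), nrow = 3) %*% t(runif(p, -1, 1)) * 2
  cc <- suppressWarnings(cor(x))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 1
  cc
}
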