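# Synthetic full-night EDA cohorts with ground truth.
#
# The generator is the test bed for every downstream stage: it plants
# band-limited (0.25-3 Hz) oscillatory events on top of a slow tonic
# baseline, clusters a share of them into storms whose nightly density
# grows with the subject's apnoea severity, and records exactly what it
# planted so detectors and classifiers can be scored against ground truth.

#' Generate a synthetic hypnogram
#'
#' Draws a per-epoch sleep-stage sequence (30 s epochs) from a first-order
#' Markov chain whose target occupancy is `stage_mix` and whose innovation
#' distribution is modulated along a sleep cycle of `cycle_len_epochs`
#' epochs (deep sleep favoured early in each cycle, REM late), imitating
#' the cyclic architecture of human sleep. The phase-dependent innovation
#' distributions are rescaled by a fixed-point correction so that the
#' long-run stage proportions converge to `stage_mix` exactly in
#' expectation.
#'
#' @param n_epochs Number of 30 s epochs (>= 1).
#' @param stage_mix Numeric vector of 5 proportions for stages
#'   W, N1, N2, N3, REM; must sum to 1. The default is the stage
#'   distribution typical of adult clinical cohorts.
#' @param cycle_len_epochs Sleep-cycle period in epochs (default 180,
#'   i.e. 90 min).
#' @param seed Integer seed; the same seed reproduces the same hypnogram.
#' @param persistence Probability of repeating the previous epoch's stage
#'   before consulting the innovation distribution; controls bout length.
#' @return A tibble of class `eda_hypnogram` with columns `epoch`
#'   (0-based index) and `stage` (factor with levels W, N1, N2, N3, REM).
#' @examples
#' h <- generate_hypnogram(960, seed = 1)
#' table(h$stage) / nrow(h)
#' @export
generate_hypnogram <- function(n_epochs,
                               stage_mix = c(0.122, 0.165, 0.325, 0.182, 0.206),
                               cycle_len_epochs = 180,
                               seed = 1,
                               persistence = 0.88) {
  assert_scalar_number(n_epochs, "n_epochs", min = 1)
  if (length(stage_mix) != 5 || any(stage_mix < 0)) {
    abort("`stage_mix` must be 5 non-negative proportions (W, N1, N2, N3, REM)")
  }
  if (abs(sum(stage_mix) - 1) > 1e-9) {
    abort(sprintf(
      "`stage_mix` must sum to 1 (got %.12f); normalize it first",
      sum(stage_mix)
    ))
  }
  if (persistence < 0 || persistence >= 1) abort("`persistence` must be in [0, 1)")

  phase <- (seq_len(cycle_len_epochs) - 1) / cycle_len_epochs
  mod <- matrix(1, nrow = cycle_len_epochs, ncol = 5)
  mod[, 4] <- 1 + 0.7 * cos(2 * pi * phase) # N3 early in cycle
  mod[, 5] <- 1 - 0.7 * cos(2 * pi * phase) # REM late in cycle

  # Fixed-point correction: scale the base mix so that the cycle-average of
  # the normalized phase distributions equals stage_mix.
  base <- stage_mix
  for (iter in 1:200) {
    pt <- sweep(mod, 2, base, `*`)
    pt <- pt / rowSums(pt)
    avg <- colMeans(pt)
    ratio <- ifelse(avg > 0, stage_mix / avg, 1)
    base <- base * ratio
    if (sum(base) > 0) base <- base / sum(base)
    if (max(abs(avg - stage_mix)) < 1e-12) break
  }
  pt <- sweep(mod, 2, base, `*`)
  pt <- pt / pmax(rowSums(pt), .Machine$double.xmin)

  stages <- integer(n_epochs)
  with_seed(seed, {
    stages[1] <- sample.int(5, 1, prob = pt[1, ])
    if (n_epochs > 1) {
      u_stay <- runif(n_epochs)
      for (i in 2:n_epochs) {
        ph <- ((i - 1) %% cycle_len_epochs) + 1
        if (u_stay[i] < persistence && pt[ph, stages[i - 1]] > 0) {
          stages[i] <- stages[i - 1]
        } else {
          stages[i] <- sample.int(5, 1, prob = pt[ph, ])
        }
      }
    }
  })
  out <- tibble::tibble(
    epoch = seq_len(n_epochs) - 1L,
    stage = factor(STAGES5[stages], levels = STAGES5)
  )
  class(out) <- c("eda_hypnogram", class(out))
  out
}

#' Subject profile for the EDA generator
#'
#' Bundles the physiological "dials" of one synthetic subject: tonic
#' baseline and drift, per-stage phasic event rates, storm behaviour and
#' its coupling to apnoea severity, movement artifacts, and sensor noise.
#'
#' @param subject_id Subject identifier.
#' @param sex `"F"` or `"M"`.
#' @param ahi Apnoea-hypopnoea index, events/hour (>= 0).
#' @param odi Oxygen-desaturation index, events/hour (>= 0); defaults to
#'   `ahi`.
#' @param tonic_level Baseline skin-potential level (signal units).
#' @param drift_coeffs Three coefficients `c(a0, a1, a2)` of the slow
#'   second-order polynomial drift `a0 + a1*u + a2*u^2` over normalized
#'   night time `u` in `[0, 1]`.
#' @param stage_event_rate Named vector of background EDA-event rates per
#'   minute for stages W, N1, N2, N3, REM. The default places most phasic
#'   activity in deep sleep, where EDA storms are classically observed.
#' @param storm_burst_rate Event rate (events/min) inside a storm.
#' @param storm_base_per_h,storm_slope_per_ahi Storm density: storms/hour
#'   equals `storm_base_per_h + storm_slope_per_ahi * min(ahi, 30)`, the
#'   monotone coupling between apnoea severity and nocturnal storm load.
#' @param artifact_rate Movement-artifact spikes per hour.
#' @param noise_sd White measurement-noise standard deviation.
#' @param rw_sd Innovation SD of the slow tonic random walk (per sample at
#'   200 Hz, smoothed); 0 disables it.
#' @param event_amp Length-2 range of planted event peak amplitudes;
#'   amplitudes are drawn log-uniformly inside it.
#' @param stage_amp_scale Named multiplier of event amplitude per stage
#'   (default all 1): deep-sleep storms carry larger waves than the
#'   small, frequent arousal responses of wake.
#' @return A list of class `eda_profile`.
#' @export
subject_profile <- function(subject_id = "S01",
                            sex = c("F", "M"),
                            ahi = 2,
                            odi = ahi,
                            tonic_level = 1,
                            drift_coeffs = c(0, 0.3, -0.2),
                            stage_event_rate = c(
                              W = 0.25, N1 = 0.5, N2 = 1.2,
                              N3 = 3.0, REM = 0.7
                            ),
                            storm_burst_rate = 6,
                            storm_base_per_h = 0.4,
                            storm_slope_per_ahi = 0.12,
                            artifact_rate = 2,
                            noise_sd = 0.01,
                            rw_sd = 0.002,
                            event_amp = c(0.15, 0.5),
                            stage_amp_scale = c(
                              W = 1, N1 = 1, N2 = 1, N3 = 1, REM = 1
                            )) {
  sex <- match.arg(sex)
  assert_scalar_number(ahi, "ahi", min = 0)
  assert_scalar_number(odi, "odi", min = 0)
  assert_scalar_number(storm_burst_rate, "storm_burst_rate", min = 0)
  assert_scalar_number(artifact_rate, "artifact_rate", min = 0)
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  assert_scalar_number(rw_sd, "rw_sd", min = 0)
  if (length(drift_coeffs) != 3) abort("`drift_coeffs` must have exactly 3 entries")
  if (!all(STAGES5 %in% names(stage_event_rate))) {
    abort("`stage_event_rate` must name all of W, N1, N2, N3, REM")
  }
  if (any(stage_event_rate < 0)) abort("event rates must be non-negative")
  structure(
    list(
      subject_id = subject_id, sex = sex, ahi = ahi, odi = odi,
      tonic_level = tonic_level, drift_coeffs = drift_coeffs,
      stage_event_rate = stage_event_rate[STAGES5],
      storm_burst_rate = storm_burst_rate,
      storm_base_per_h = storm_base_per_h,
      storm_slope_per_ahi = storm_slope_per_ahi,
      artifact_rate = artifact_rate, noise_sd = noise_sd, rw_sd = rw_sd,
      event_amp = event_amp,
      stage_amp_scale = stage_amp_scale[STAGES5]
    ),
    class = "eda_profile"
  )
}

# One planted event waveform added in place. Lobe counts: mono = 1 half
# period, bi = 2, tri = 3; a short Tukey taper avoids edge discontinuities
# without eating the outer lobes.
event_waveform <- function(kind, freq, amp, fs) {
  lobes <- switch(kind, "mono+" = 1, "mono-" = 1, "bi" = 2, "tri" = 3)
  dur <- lobes / (2 * freq)
  n <- max(4L, round(dur * fs))
  t <- seq_len(n) / fs
  w <- sin(pi * t / dur * lobes)
  edge <- pmin(1, pmin(t, dur - t) / (0.08 * dur))
  w <- w * pmax(edge, 0)
  if (kind == "mono-") w <- -w
  amp * w / max(abs(w))
}

#' Generate one synthetic full-night EDA recording
#'
#' Synthesizes a raw EDA trace at `fs` Hz aligned with a hypnogram:
#' second-order polynomial drift plus a slow tonic random walk, planted
#' damped-oscillation events (carrier frequency drawn from 0.25-3 Hz) at
#' the current stage's event rate, storm bursts whose nightly count grows
#' linearly with `min(ahi, 30)`, sparse rectangular movement artifacts,
#' and white noise. Everything planted is returned as ground truth.
#'
#' @param hypnogram An [generate_hypnogram()] result (non-empty).
#' @param profile A [subject_profile()].
#' @param fs Sampling rate in Hz (>= 70 so downstream 35 Hz downsampling
#'   is meaningful); the study hardware used 200 Hz.
#' @param seed Integer seed.
#' @return A list with `recording` (class `eda_recording`: `signal`, `fs`,
#'   `hypnogram`, `profile`) and `truth` (class `eda_truth`: tibbles
#'   `events` (onset_s, offset_s, kind) and `storms` (onset_s, offset_s)).
#' @examples
#' h <- generate_hypnogram(20, seed = 1)
#' r <- generate_recording(h, subject_profile(), seed = 1)
#' length(r$recording$signal) / r$recording$fs # seconds
#' @export
generate_recording <- function(hypnogram, profile, fs = 200, seed = 1) {
  if (!inherits(hypnogram, "eda_hypnogram") || nrow(hypnogram) < 1) {
    abort("`hypnogram` must be a non-empty eda_hypnogram")
  }
  if (!inherits(profile, "eda_profile")) abort("`profile` must be a subject_profile()")
  assert_scalar_number(fs, "fs", min = 70)

  n_epochs <- nrow(hypnogram)
  total_s <- n_epochs * EPOCH_LEN_S
  n <- as.integer(round(total_s * fs))
  u <- (seq_len(n) - 1) / (n - 1)
  dc <- profile$drift_coeffs
  x <- profile$tonic_level + dc[1] + dc[2] * u + dc[3] * u^2

  ev_on <- numeric(); ev_off <- numeric(); ev_kind <- character()
  st_on <- numeric(); st_off <- numeric()

  with_seed(seed, {
    if (profile$rw_sd > 0) {
      # Slow tonic wander: heavily smoothed random walk.
      steps <- rnorm(n, sd = profile$rw_sd)
      rw <- cumsum(steps)
      k <- max(1L, as.integer(fs)) # ~1 s moving average
      rw <- as.numeric(stats::filter(rw, rep(1 / k, k), sides = 2))
      ok <- which(!is.na(rw))
      rw[seq_len(ok[1] - 1)] <- rw[ok[1]]
      rw[seq.int(ok[length(ok)] + 1, length.out = length(rw) - ok[length(ok)])] <-
        rw[ok[length(ok)]]
      x <- x + rw
    }

    kinds <- c("mono+", "mono-", "bi", "tri")
    kind_p <- c(0.4, 0.2, 0.25, 0.15)
    stage_chr <- as.character(hypnogram$stage)
    draw_amp <- function(onset_s) {
      ep <- min(n_epochs, floor(onset_s / EPOCH_LEN_S) + 1)
      amp <- exp(runif(1, log(profile$event_amp[1]), log(profile$event_amp[2])))
      amp * profile$stage_amp_scale[[stage_chr[ep]]]
    }

    # Storm windows: density linear in min(AHI, 30).
    hours <- total_s / 3600
    lam <- (profile$storm_base_per_h +
      profile$storm_slope_per_ahi * min(profile$ahi, 30)) * hours
    n_storms <- rpois(1, lam)
    if (n_storms > 0 && total_s > 180) {
      s_dur <- runif(n_storms, 60, 150)
      s_start <- sort(runif(n_storms, 0, total_s - max(s_dur)))
      keep <- c(TRUE, diff(s_start) > 200) # storms well separated
      s_start <- s_start[keep]; s_dur <- s_dur[keep]
      st_on <- s_start
      st_off <- s_start + s_dur
    }

    # Events inside storms: a burst of at least 2.
    for (i in seq_along(st_on)) {
      m <- max(2L, rpois(1, profile$storm_burst_rate * (st_off[i] - st_on[i]) / 60))
      on <- sort(runif(m, st_on[i], st_off[i] - 4))
      on <- on[c(TRUE, diff(on) > 3)]
      while (length(on) < 2) on <- sort(c(on, runif(1, st_on[i], st_off[i] - 4)))
      for (o in on) {
        kd <- sample(kinds, 1, prob = kind_p)
        lob <- switch(kd, "mono+" = 1, "mono-" = 1, "bi" = 2, "tri" = 3)
        fr <- runif(1, if (lob == 1) 1.2 else 0.7, 3)
        ev_on <- c(ev_on, o); ev_kind <- c(ev_kind, kd)
        ev_off <- c(ev_off, o + lob / (2 * fr))
        wf <- event_waveform(kd, fr, draw_amp(o), fs)
        i0 <- as.integer(round(o * fs)) + 1L
        idx <- i0:min(n, i0 + length(wf) - 1L)
        x[idx] <- x[idx] + wf[seq_along(idx)]
      }
    }

    # Background events at the stage-dependent rate, kept clear of storms
    # and of each other (>= 8 s gaps) so detector tests stay sharp.
    rates <- profile$stage_event_rate[as.character(hypnogram$stage)]
    counts <- rpois(n_epochs, rates * (EPOCH_LEN_S / 60))
    bg_on <- numeric()
    for (e in which(counts > 0)) {
      t0 <- (e - 1) * EPOCH_LEN_S
      bg_on <- c(bg_on, runif(counts[e], t0, t0 + EPOCH_LEN_S - 4))
    }
    bg_on <- sort(bg_on)
    if (length(bg_on) > 1) bg_on <- bg_on[c(TRUE, diff(bg_on) > 6)]
    if (length(st_on) > 0 && length(bg_on) > 0) {
      in_storm <- vapply(
        bg_on,
        function(o) any(o >= st_on - 8 & o <= st_off + 8),
        logical(1)
      )
      bg_on <- bg_on[!in_storm]
    }
    for (o in bg_on) {
      kd <- sample(kinds, 1, prob = kind_p)
      lob <- switch(kd, "mono+" = 1, "mono-" = 1, "bi" = 2, "tri" = 3)
      # Carrier range per kind: an n-lobe waveform of carrier f spans
      # n/(2f) seconds; below these floors a single excursion is not
      # representable inside the 0.25-3 Hz event band.
      fr <- runif(1, if (lob == 1) 1.2 else 0.7, 3)
      ev_on <- c(ev_on, o); ev_kind <- c(ev_kind, kd)
      ev_off <- c(ev_off, o + lob / (2 * fr))
      wf <- event_waveform(kd, fr, draw_amp(o), fs)
      i0 <- as.integer(round(o * fs)) + 1L
      idx <- i0:min(n, i0 + length(wf) - 1L)
      x[idx] <- x[idx] + wf[seq_along(idx)]
    }

    # Movement artifacts: rectangular spikes, 0.5-2 s, >= 5x tonic level.
    n_art <- rpois(1, profile$artifact_rate * hours)
    if (n_art > 0) {
      a_on <- runif(n_art, 0, total_s - 2)
      a_dur <- runif(n_art, 0.5, 2)
      a_amp <- abs(profile$tonic_level) * runif(n_art, 5, 8)
      for (i in seq_len(n_art)) {
        idx <- (as.integer(a_on[i] * fs) + 1L):min(n, as.integer((a_on[i] + a_dur[i]) * fs))
        x[idx] <- x[idx] + a_amp[i]
      }
    }

    if (profile$noise_sd > 0) x <- x + rnorm(n, sd = profile$noise_sd)
  })

  o <- order(ev_on)
  truth <- structure(
    list(
      events = tibble::tibble(
        onset_s = ev_on[o], offset_s = ev_off[o],
        kind = factor(ev_kind[o], levels = c("mono+", "mono-", "bi", "tri"))
      ),
      storms = tibble::tibble(onset_s = st_on, offset_s = st_off)
    ),
    class = "eda_truth"
  )
  rec <- structure(
    list(signal = x, fs = fs, hypnogram = hypnogram, profile = profile),
    class = "eda_recording"
  )
  list(recording = rec, truth = truth)
}

#' Cohort scenario presets
#'
#' A scenario fixes the study conditions of a synthetic cohort: night
#' length, stage-dependent event rates (the sleep-stage "signal"), noise
#' level, and the three apnoea-severity strata subjects are drawn from.
#'
#' @param name `"strong"` (clear stage-dependent EDA activity),
#'   `"null"` (identical event rates in every stage, i.e. no stage signal),
#'   or `"osa"` (stage rates as in `"strong"`, subjects spread over the
#'   full AHI range so severity effects dominate).
#' @param n_epochs Epochs per subject night (default 120, i.e. 1 h; the
#'   statistical structure, not the clock length, is what downstream
#'   stages consume).
#' @return A list of class `eda_scenario`.
#' @export
cohort_scenario <- function(name = c("strong", "null", "osa"), n_epochs = 120) {
  name <- match.arg(name)
  rates <- switch(name,
    strong = c(W = 3.0, N1 = 0.2, N2 = 0.5, N3 = 7.0, REM = 1.3),
    null = c(W = 1.2, N1 = 1.2, N2 = 1.2, N3 = 1.2, REM = 1.2),
    osa = c(W = 0.2, N1 = 0.6, N2 = 1.5, N3 = 4.5, REM = 0.9)
  )
  amp_scale <- if (name == "strong") {
    c(W = 0.5, N1 = 1, N2 = 1, N3 = 1.8, REM = 1)
  } else {
    c(W = 1, N1 = 1, N2 = 1, N3 = 1, REM = 1)
  }
  structure(
    list(
      name = name,
      n_epochs = n_epochs,
      # Compressed nights keep ~3 sleep cycles regardless of length, so
      # every subject's night samples all stages.
      cycle_len_epochs = max(10, round(n_epochs / 3)),
      stage_event_rate = rates,
      stage_amp_scale = amp_scale,
      noise_sd = 0.01,
      # The staging scenarios isolate the stage signal: no movement
      # artifacts and a non-OSA cohort (storms are stage-independent, so
      # an OSA spread would only dilute the stage contrast). The "osa"
      # scenario keeps the full severity spread and artifact load.
      artifact_rate = if (name == "osa") 1 else 0,
      ahi_strata = if (name == "osa") {
        list(c(0, 5), c(5, 15), c(15, 40))
      } else {
        list(c(0, 5), c(0, 5), c(0, 5))
      }
    ),
    class = "eda_scenario"
  )
}

#' Generate a synthetic cohort
#'
#' Draws `n_subjects` subjects with deterministic per-subject seeds from
#' one master seed. Subjects cycle through the scenario's three AHI
#' severity strata; AHI is drawn uniformly inside the stratum, ODI within
#' 20% of the AHI, and sex alternates.
#'
#' @param n_subjects Number of subjects (>= 2; leave-one-subject-out
#'   validation is undefined for fewer).
#' @param scenario A [cohort_scenario()].
#' @param seed Master integer seed.
#' @return A list of per-subject lists, each with `recording` and `truth`.
#' @export
generate_cohort <- function(n_subjects, scenario = cohort_scenario(), seed = 1) {
  if (!is.numeric(n_subjects) || n_subjects < 2) {
    abort("`n_subjects` must be >= 2 (leave-one-subject-out needs at least two)")
  }
  if (!inherits(scenario, "eda_scenario")) abort("`scenario` must be a cohort_scenario()")
  n_subjects <- as.integer(n_subjects)
  purrr::map(seq_len(n_subjects), function(i) {
    s_i <- derive_seed(seed, "cohort", i)
    stratum <- scenario$ahi_strata[[((i - 1) %% 3) + 1]]
    prof <- with_seed(s_i, {
      ahi <- runif(1, stratum[1], stratum[2])
      subject_profile(
        subject_id = sprintf("S%02d", i),
        sex = if (i %% 2 == 0) "M" else "F",
        ahi = ahi,
        odi = max(0, ahi * runif(1, 0.8, 1.2)),
        tonic_level = runif(1, 0.6, 1.6),
        drift_coeffs = c(0, runif(1, -0.4, 0.4), runif(1, -0.3, 0.3)),
        stage_event_rate = scenario$stage_event_rate,
        stage_amp_scale = scenario$stage_amp_scale,
        artifact_rate = scenario$artifact_rate,
        noise_sd = scenario$noise_sd
      )
    })
    hyp <- generate_hypnogram(scenario$n_epochs,
      cycle_len_epochs = scenario$cycle_len_epochs,
      seed = derive_seed(seed, "hypno", i)
    )
    generate_recording(hyp, prof, seed = derive_seed(seed, "signal", i))
  })
}
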