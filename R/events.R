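# EDA event and storm detection.
#
# Events are band-limited (0.25-3 Hz) oscillations of the skin potential,
# classified by the number of alternating-sign lobes: positive or
# negative monophasic, biphasic, triphasic. A storm is a timespan of at
# least one minute holding at least two events.

#' Detect EDA events in a 35 Hz trace
#'
#' The trace is band-pass filtered to the 0.25-3 Hz event band with a
#' zero-phase Butterworth filter (so onsets are not shifted), then
#' segmented into zero-crossing-delimited lobes. An event is a maximal
#' run of consecutive lobes around a lobe whose peak absolute amplitude
#' reaches `amp_threshold`; neighbouring lobes are absorbed while their
#' peaks stay above 25% of the event's maximum (`lobe_frac`). The number
#' of retained lobes classifies the event: one lobe is monophasic (sign
#' of its peak), two biphasic, three or more triphasic. Event duration is
#' capped at `max_dur_s`.
#'
#' @param x Numeric trace at `fs` Hz, at least 60 s long.
#' @param amp_threshold Peak-amplitude threshold in signal units (> 0).
#' @param fs Sampling rate (default 35).
#' @param band Event frequency band in Hz (default `c(0.25, 3)`).
#' @param lobe_frac Fraction of the event's peak a lobe must reach to
#'   count as a phase (default 0.25).
#' @param max_dur_s Maximum event duration in seconds (default 12, a few
#'   periods of the slowest in-band oscillation).
#' @param refractory_s Dead zone around a claimed event (default 3 s):
#'   weaker candidate lobes this close to an accepted event are treated
#'   as its filter ringing rather than as separate events.
#' @return A tibble with columns `onset_s`, `offset_s`, `kind` (factor
#'   mono+/mono-/bi/tri), `peak_amplitude`, sorted by onset,
#'   non-overlapping.
#' @export
detect_events <- function(x, amp_threshold = 0.05, fs = 35,
                          band = c(0.25, 3), lobe_frac = 0.25,
                          max_dur_s = 12, refractory_s = 3) {
  if (amp_threshold <= 0) abort("`amp_threshold` must be positive")
  if (length(x) < 60 * fs) abort("trace must be at least 60 s long")
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  # Odd-reflection padding before zero-phase filtering: continues the
  # local trend across the boundary, so neither the filter transient nor
  # a slope kink masquerades as an event at the recording edges.
  npad <- min(length(x) - 1, 30 * fs)
  left <- 2 * x[1] - rev(x[seq_len(npad) + 1])
  right <- 2 * x[length(x)] - rev(x)[seq_len(npad) + 1]
  xp <- c(left, x, right)
  xb <- as.numeric(signal::filtfilt(bf, xp))[npad + seq_along(x)]

  # Zero-crossing-delimited lobes of the band-passed trace.
  sgn <- sign(xb)
  sgn[sgn == 0] <- 1
  run <- rle(sgn)
  ends <- cumsum(run$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  peak <- vapply(
    seq_along(starts),
    function(i) {
      seg <- xb[starts[i]:ends[i]]
      seg[which.max(abs(seg))]
    },
    numeric(1)
  )
  n_lobe <- length(starts)

  empty <- tibble::tibble(
    onset_s = numeric(), offset_s = numeric(),
    kind = factor(character(), levels = c("mono+", "mono-", "bi", "tri")),
    peak_amplitude = numeric()
  )
  cand <- which(abs(peak) >= amp_threshold)
  if (length(cand) == 0) return(empty)

  used <- logical(n_lobe)
  out_on <- numeric(); out_off <- numeric(); out_kind <- character(); out_amp <- numeric()
  ev_spans <- NULL
  for (i in order(-abs(peak[cand]))) {
    c0 <- cand[i]
    if (used[c0]) next
    # Inside the refractory zone of an already-claimed (stronger) event?
    lobe_mid <- (starts[c0] + ends[c0]) / 2 / fs
    if (!is.null(ev_spans) &&
      any(lobe_mid >= ev_spans[, 1] - refractory_s &
        lobe_mid <= ev_spans[, 2] + refractory_s)) {
      used[c0] <- TRUE
      next
    }
    pk <- abs(peak[c0])
    lo <- c0
    hi <- c0
    while (lo > 1 && !used[lo - 1] && abs(peak[lo - 1]) >= lobe_frac * pk) lo <- lo - 1
    while (hi < n_lobe && !used[hi + 1] && abs(peak[hi + 1]) >= lobe_frac * pk) hi <- hi + 1
    # Enforce the duration cap by trimming the weakest outer lobes.
    repeat {
      dur <- (ends[hi] - starts[lo] + 1) / fs
      if (dur <= max_dur_s || lo == hi) break
      if (abs(peak[lo]) < abs(peak[hi])) lo <- lo + 1 else hi <- hi - 1
    }
    used[lo:hi] <- TRUE
    ev_spans <- rbind(ev_spans, c((starts[lo] - 1) / fs, ends[hi] / fs))
    k <- hi - lo + 1
    kind <- if (k == 1) {
      if (peak[c0] > 0) "mono+" else "mono-"
    } else if (k == 2) "bi" else "tri"
    out_on <- c(out_on, (starts[lo] - 1) / fs)
    out_off <- c(out_off, ends[hi] / fs)
    out_kind <- c(out_kind, kind)
    out_amp <- c(out_amp, pk)
  }
  o <- order(out_on)
  tibble::tibble(
    onset_s = out_on[o], offset_s = out_off[o],
    kind = factor(out_kind[o], levels = c("mono+", "mono-", "bi", "tri")),
    peak_amplitude = out_amp[o]
  )
}

#' Detect EDA storms from a sorted event list
#'
#' Every 60 s sliding window containing at least two event onsets
#' qualifies; overlapping qualifying windows merge into one storm. For
#' each consecutive event pair with onsets at most `window_s` apart, the
#' union of qualifying window positions spans from `window_s` before the
#' later onset to `window_s` after the earlier one; merged unions are the
#' storms. Spans are clipped to `[0, total_s]` when the recording length
#' is supplied, and always cover at least `window_s`.
#'
#' @param events A tibble from [detect_events()] (sorted by onset).
#' @param window_s Storm window in seconds (default 60).
#' @param total_s Optional recording length for clipping.
#' @return A tibble with `onset_s`, `offset_s`, `n_events`.
#' @export
detect_storms <- function(events, window_s = 60, total_s = NULL) {
  if (!all(c("onset_s", "offset_s") %in% names(events))) {
    abort("`events` must have onset_s and offset_s columns")
  }
  if (is.unsorted(events$onset_s)) abort("`events` must be sorted by onset")
  empty <- tibble::tibble(onset_s = numeric(), offset_s = numeric(), n_events = integer())
  if (nrow(events) < 2) return(empty)
  on <- events$onset_s
  gap_ok <- which(diff(on) <= window_s)
  if (length(gap_ok) == 0) return(empty)
  span_on <- on[gap_ok + 1] - window_s
  span_off <- on[gap_ok] + window_s
  merged <- merge_intervals(span_on, span_off)
  if (!is.null(total_s)) {
    merged$onset_s <- pmax(merged$onset_s, 0)
    merged$offset_s <- pmin(merged$offset_s, total_s)
  } else {
    merged$onset_s <- pmax(merged$onset_s, 0)
  }
  short <- merged$offset_s - merged$onset_s < window_s
  merged$offset_s[short] <- merged$onset_s[short] + window_s
  merged$n_events <- vapply(
    seq_len(nrow(merged)),
    function(i) sum(on >= merged$onset_s[i] & on <= merged$offset_s[i]),
    integer(1)
  )
  merged
}

#' Per-epoch event and storm features
#'
#' For one 30 s epoch: the fraction of epoch samples lying inside any
#' detected event, the Euclidean norm of the (raw) trace restricted to
#' those samples, and the same pair for storms.
#'
#' @param events,storms Tibbles with `onset_s`/`offset_s` columns.
#' @param epoch_window Numeric `c(start_s, end_s)`, an exact 30 s span.
#' @param x_epoch The trace samples of that epoch (at `fs` Hz).
#' @param fs Sampling rate (default 35).
#' @return Named numeric vector
#'   `(event_frac, event_energy, storm_frac, storm_energy)`.
#' @export
event_storm_features <- function(events, storms, epoch_window, x_epoch, fs = 35) {
  if (length(epoch_window) != 2 ||
    abs(diff(epoch_window) - EPOCH_LEN_S) > 1e-9) {
    abort("`epoch_window` must span exactly 30 s")
  }
  n <- length(x_epoch)
  t0 <- epoch_window[1]
  mark <- function(tab) {
    if (nrow(tab) == 0) return(logical(n))
    samples_in_intervals(n, fs, tab$onset_s - t0, tab$offset_s - t0)
  }
  in_ev <- mark(events)
  in_st <- mark(storms)
  c(
    event_frac = mean(in_ev),
    event_energy = sqrt(sum(x_epoch[in_ev]^2)),
    storm_frac = mean(in_st),
    storm_energy = sqrt(sum(x_epoch[in_st]^2))
  )
}
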