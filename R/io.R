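# File interchange: EDF signals, CSV sidecars, YAML run configuration.
#
# EDF (European Data Format) is the export format of the study hardware;
# the reader/writer here implements the standard 16-bit EDF layout
# directly (fixed-width ASCII header blocks followed by little-endian
# two-byte samples).

edf_pad <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

#' Write a one-channel EDA recording to EDF
#'
#' Standard EDF, one signal labelled `EDA`, one-second data records.
#' Samples are scaled to the 16-bit digital range; the trailing partial
#' second (if any) is dropped.
#'
#' @param recording An `eda_recording` or numeric trace.
#' @param path Output file path.
#' @param fs Sampling rate (taken from the recording when available).
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, fs = 200) {
  x <- if (inherits(recording, "eda_recording")) recording$signal else recording
  if (inherits(recording, "eda_recording")) fs <- recording$fs
  n_rec <- floor(length(x) / fs)
  if (n_rec < 1) abort("recording shorter than one EDF data record (1 s)")
  x <- x[seq_len(n_rec * fs)]
  pmin <- min(x)
  pmax <- max(x)
  if (pmax - pmin < 1e-9) pmax <- pmin + 1 # degenerate flat trace
  dmin <- -32768L
  dmax <- 32767L
  dig <- as.integer(round((x - pmin) / (pmax - pmin) * (dmax - dmin) + dmin))

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("synthetic subject", 80),
    edf_pad("edasleep synthetic EDA", 80),
    edf_pad("01.01.26", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + 256, 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad(1, 8),
    edf_pad(1, 4),
    # one signal block
    edf_pad("EDA", 16),
    edf_pad("skin electrodes", 80),
    edf_pad("mV", 8),
    edf_pad(sprintf("%.6g", pmin), 8),
    edf_pad(sprintf("%.6g", pmax), 8),
    edf_pad(dmin, 8),
    edf_pad(dmax, 8),
    edf_pad("none", 80),
    edf_pad(fs, 8),
    edf_pad("", 32)
  )
  writeChar(hdr, con, eos = NULL)
  writeBin(dig, con, size = 2, endian = "little")
  invisible(path)
}

read_edf_header <- function(con) {
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  list(
    version = rd(8), patient = rd(80), recording = rd(80),
    startdate = rd(8), starttime = rd(8),
    header_bytes = as.integer(rd(8)), reserved = rd(44),
    n_records = as.integer(rd(8)), record_duration = as.numeric(rd(8)),
    n_signals = as.integer(rd(4))
  )
}

#' Read a one-channel EDA recording from EDF
#'
#' Parses the EDF header, locates the single channel whose label
#' mentions EDA, and returns the physically calibrated trace at the
#' sampling rate the header declares (no silent resampling).
#'
#' @param path EDF file path.
#' @return An `eda_recording` (without hypnogram/profile; attach those
#'   from their CSV sidecars).
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- read_edf_header(con)
  if (is.na(hdr$n_signals) || hdr$n_signals < 1 ||
    is.na(hdr$header_bytes) || hdr$header_bytes != 256 + 256 * hdr$n_signals) {
    abort("corrupt EDF header")
  }
  ns <- hdr$n_signals
  rd_block <- function(w) {
    vapply(seq_len(ns), function(i) trimws(readChar(con, w, useBytes = TRUE)), character(1))
  }
  label <- rd_block(16)
  rd_block(80) # transducer
  rd_block(8) # physical dimension
  phys_min <- as.numeric(rd_block(8))
  phys_max <- as.numeric(rd_block(8))
  dig_min <- as.numeric(rd_block(8))
  dig_max <- as.numeric(rd_block(8))
  rd_block(80) # prefiltering
  spr <- as.integer(rd_block(8))
  rd_block(32)

  is_eda <- grepl("EDA", label, ignore.case = TRUE)
  if (sum(is_eda) == 0) abort("no EDA-labelled channel in this EDF")
  if (sum(is_eda) > 1) abort("ambiguous EDF: more than one EDA-labelled channel")
  ch <- which(is_eda)

  out <- vector("list", ns)
  for (i in seq_len(ns)) out[[i]] <- numeric(0)
  raw <- readBin(con, "integer",
    n = hdr$n_records * sum(spr), size = 2,
    endian = "little", signed = TRUE
  )
  if (length(raw) < hdr$n_records * sum(spr)) abort("truncated EDF data section")
  per_rec <- sum(spr)
  offs <- cumsum(c(0, spr))[ch]
  idx <- as.vector(outer(offs + seq_len(spr[ch]), (seq_len(hdr$n_records) - 1) * per_rec, `+`))
  dig <- raw[idx]
  gain <- (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
  x <- phys_min[ch] + (dig - dig_min[ch]) * gain
  structure(
    list(
      signal = x,
      fs = spr[ch] / hdr$record_duration,
      hypnogram = NULL,
      profile = NULL
    ),
    class = "eda_recording"
  )
}

#' Write a synthetic cohort to disk
#'
#' One EDF per subject plus CSV sidecars: a hypnogram
#' (`epoch_index, stage`), a subject table
#' (`subject_id, sex, ahi, odi`), and the ground-truth event and storm
#' intervals (`subject_id, onset_s, offset_s, kind`).
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subjects <- purrr::map_dfr(cohort, function(s) {
    p <- s$recording$profile
    tibble::tibble(
      subject_id = p$subject_id, sex = p$sex, ahi = p$ahi, odi = p$odi
    )
  })
  utils::write.csv(subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  truth <- purrr::map_dfr(cohort, function(s) {
    ev <- s$truth$events
    st <- s$truth$storms
    dplyr::bind_rows(
      tibble::tibble(
        subject_id = s$recording$profile$subject_id,
        onset_s = ev$onset_s, offset_s = ev$offset_s,
        kind = as.character(ev$kind)
      ),
      tibble::tibble(
        subject_id = s$recording$profile$subject_id,
        onset_s = st$onset_s, offset_s = st$offset_s, kind = "storm"
      )
    )
  })
  utils::write.csv(truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  for (s in cohort) {
    sid <- s$recording$profile$subject_id
    write_edf(s$recording, file.path(dir, paste0(sid, ".edf")))
    utils::write.csv(
      data.frame(
        epoch_index = s$recording$hypnogram$epoch,
        stage = as.character(s$recording$hypnogram$stage)
      ),
      file.path(dir, paste0(sid, "_hypnogram.csv")),
      row.names = FALSE
    )
  }
  invisible(dir)
}

#' Read or write a run configuration
#'
#' The configuration gathers every tunable of the pipeline (generator
#' scenario, preprocessing, detector thresholds, reduction threshold,
#' boosting hyperparameters, task, validation mode) around one mandatory
#' master seed, and round-trips losslessly through YAML.
#'
#' @param path YAML file path.
#' @param config Named list to write; must contain `seed`.
#' @return `read_run_config()` returns the named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such config: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) abort("config is missing the mandatory `seed` key")
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  if (is.null(config$seed)) abort("config is missing the mandatory `seed` key")
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Export events or storms as CSV
#'
#' @param intervals Tibble with `onset_s`/`offset_s` (plus `kind` or
#'   `n_events`).
#' @param path Output path.
#' @export
write_intervals <- function(intervals, path) {
  utils::write.csv(as.data.frame(intervals), path, row.names = FALSE)
  invisible(path)
}
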