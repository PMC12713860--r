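# Per-epoch feature engineering: 77 variables per 30 s epoch.
#
# Feature groups and column order (fixed; guarded by a schema test):
#   1-18   time-domain statistics of EDA and detEDA (9 each)
#   19-34  derivative statistics of d1EDA, d2EDA, d1detEDA, d2detEDA (4 each)
#   35-40  periodogram features of EDA and detEDA (3 each)
#   41-64  wavelet detail-coefficient statistics, levels 1-4 (6 each)
#   65-70  non-linear features of EDA and detEDA (3 each)
#   71-72  diffEDA cross-correlation/convolution summaries
#   73-76  event/storm coverage and energy
#   77     sex

#' Canonical feature-column names
#'
#' @return Character vector of the 77 feature column names in their
#'   fixed order.
#' @export
eda_feature_names <- function() {
  time9 <- c(
    "mode", "median", "absmax", "line_length", "q10", "q75",
    "svd_entropy", "nl_energy", "shannon_entropy"
  )
  deriv4 <- c("mean", "var", "median", "n_pos")
  freq3 <- c("psd_max", "psd_fmax", "fishers_g")
  wav6 <- c("max", "mean", "sd", "median", "norm", "npos_frac")
  nl3 <- c("lyapunov", "env_max", "env_min")
  c(
    paste0("eda_", time9), paste0("det_", time9),
    paste0("d1eda_", deriv4), paste0("d2eda_", deriv4),
    paste0("d1det_", deriv4), paste0("d2det_", deriv4),
    paste0("eda_", freq3), paste0("det_", freq3),
    paste0("dl1_", wav6), paste0("dl2_", wav6),
    paste0("dl3_", wav6), paste0("dl4_", wav6),
    paste0("eda_", nl3), paste0("det_", nl3),
    "diff_xcorr_sum", "diff_conv_max",
    "event_frac", "event_energy", "storm_frac", "storm_energy",
    "sex"
  )
}

#' Epoch slicing
#'
#' Cuts a recording into consecutive non-overlapping 30 s windows
#' aligned to the hypnogram; a trailing partial window is dropped.
#'
#' @param n_samples Trace length in samples (or an `eda_recording`, in
#'   which case `fs` is taken from it).
#' @param fs Sampling rate in Hz.
#' @return A tibble with `epoch` (0-based), `start_s`, `end_s`,
#'   `start_idx`, `end_idx` (1-based sample indices).
#' @export
epoch_slices <- function(n_samples, fs = 35) {
  if (inherits(n_samples, "eda_recording")) {
    fs <- n_samples$fs
    n_samples <- length(n_samples$signal)
  }
  spe <- EPOCH_LEN_S * fs
  n_ep <- floor(n_samples / spe)
  if (n_ep < 1) abort("recording shorter than one 30 s epoch")
  k <- seq_len(n_ep) - 1L
  tibble::tibble(
    epoch = k,
    start_s = k * EPOCH_LEN_S,
    end_s = (k + 1) * EPOCH_LEN_S,
    start_idx = as.integer(k * spe + 1),
    end_idx = as.integer((k + 1) * spe)
  )
}

# Freedman-Diaconis histogram shared by the mode and Shannon entropy; a
# degenerate (single-bin) distribution has mode = median and entropy 0.
fd_hist <- function(x) {
  iqr <- stats::IQR(x)
  if (!is.finite(iqr) || iqr <= 0 || diff(range(x)) == 0) {
    return(list(mids = median(x), p = 1))
  }
  bw <- 2 * iqr / length(x)^(1 / 3)
  brks <- seq(min(x), max(x) + bw, by = bw)
  h <- graphics::hist(x, breaks = brks, plot = FALSE)
  list(mids = h$mids, p = h$counts / sum(h$counts))
}

hist_mode <- function(x) {
  h <- fd_hist(x)
  h$mids[which.max(h$p)]
}

shannon_entropy <- function(x) {
  p <- fd_hist(x)$p
  p <- p[p > 0]
  -sum(p * log(p))
}

# SVD entropy: Shannon entropy of the normalized singular values of the
# delay-embedding matrix (delay 1, dimension 10).
svd_entropy <- function(x, dim = 10) {
  if (length(x) <= dim) return(0)
  emb <- stats::embed(x, dim)
  ev <- eigen(crossprod(emb), symmetric = TRUE, only.values = TRUE)$values
  s <- sqrt(pmax(ev, 0))
  s[s < max(s) * 1e-8] <- 0 # rank-deficient: drop numerical dust
  tot <- sum(s)
  if (tot <= 0) return(0)
  p <- s / tot
  p <- p[p > 0]
  -sum(p * log(p))
}

# Teager-Kaiser operator averaged over the epoch.
nl_energy <- function(x) {
  n <- length(x)
  if (n < 3) return(0)
  mean(x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n])
}

#' Time-domain epoch features
#'
#' Mode (Freedman-Diaconis histogram mode), median, maximum absolute
#' value, line length (sum of absolute successive differences), 10th and
#' 75th quantiles, SVD entropy, non-linear (Teager-Kaiser) energy, and
#' Shannon entropy. Constant input is valid: the entropies are 0 by
#' convention.
#'
#' @param x Numeric epoch trace.
#' @return Named numeric vector of 9 values.
#' @export
time_features <- function(x) {
  c(
    mode = hist_mode(x),
    median = median(x),
    absmax = max(abs(x)),
    line_length = sum(abs(diff(x))),
    q10 = unname(quantile(x, 0.10)),
    q75 = unname(quantile(x, 0.75)),
    svd_entropy = svd_entropy(x),
    nl_energy = nl_energy(x),
    shannon_entropy = shannon_entropy(x)
  )
}

#' Derivative epoch features
#'
#' Mean, variance (unbiased, `stats::var`), median, and the count of
#' strictly positive samples.
#'
#' @param d Numeric derivative epoch trace (non-empty).
#' @return Named numeric vector of 4 values.
#' @export
derivative_features <- function(d) {
  if (length(d) == 0) abort("empty derivative trace")
  c(
    mean = mean(d),
    var = if (length(d) > 1) var(d) else 0,
    median = median(d),
    n_pos = sum(d > 0)
  )
}

#' Frequency-domain epoch features
#'
#' Periodogram-based: maximum power spectral density ordinate, its
#' frequency, and Fisher's g (the maximum ordinate over the ordinate
#' sum), with the zero-frequency term excluded. An epoch with no
#' oscillatory energy returns zeros.
#'
#' @param x Numeric epoch trace (>= 64 samples).
#' @param fs Sampling rate in Hz.
#' @return Named numeric vector `(psd_max, psd_fmax, fishers_g)`.
#' @export
freq_features <- function(x, fs = 35) {
  n <- length(x)
  if (n < 64) abort("epoch too short for spectral features (need >= 64 samples)")
  p <- Mod(fft(x - mean(x)))^2 / n
  k <- seq_len(floor(n / 2)) # exclude DC
  p <- p[k + 1]
  tot <- sum(p)
  if (tot <= .Machine$double.eps * n) {
    return(c(psd_max = 0, psd_fmax = 0, fishers_g = 0))
  }
  i <- which.max(p)
  c(psd_max = p[i], psd_fmax = k[i] * fs / n, fishers_g = p[i] / tot)
}

#' Wavelet detail-coefficient epoch features
#'
#' Six statistics of one decomposition level's (thresholded) detail
#' coefficients restricted to the epoch: maximum, mean, standard
#' deviation, median, Euclidean norm, and the count of strictly positive
#' coefficients normalized by the span length.
#'
#' @param dl Numeric detail coefficients of the epoch's span (non-empty).
#' @return Named numeric vector of 6 values.
#' @export
wavelet_features <- function(dl) {
  if (length(dl) == 0) abort("empty detail-coefficient span")
  c(
    max = max(dl),
    mean = mean(dl),
    sd = if (length(dl) > 1) sd(dl) else 0,
    median = median(dl),
    norm = sqrt(sum(dl^2)),
    npos_frac = mean(dl > 0)
  )
}

# Largest-Lyapunov-exponent estimate in the style of Rosenstein et al.:
# delay embedding, nearest neighbour outside a Theiler window, average
# log divergence over k steps, least-squares slope of the initial linear
# region. The epoch is thinned (stride 3) before embedding; the slope is
# per time step of the thinned series divided by the step length, i.e.
# units of 1/s. Degenerate epochs return 0.
lyapunov_estimate <- function(x, fs = 35, stride = 3L, m = 6L, tau = 1L,
                              theiler = 12L, k_max = 8L) {
  x <- x[seq(1, length(x), by = stride)]
  if (sd(x) == 0) return(0)
  x <- (x - mean(x)) / sd(x)
  n <- length(x)
  span <- (m - 1) * tau
  n_pts <- n - span - k_max
  if (n_pts < 2 * theiler + 4) return(0)
  emb <- stats::embed(x[seq_len(n - k_max)], m)[, m:1, drop = FALSE]
  dm <- as.matrix(dist(emb))
  idx <- seq_len(nrow(emb))
  off <- abs(outer(idx, idx, `-`))
  dm[off <= theiler] <- Inf
  nn <- apply(dm, 1, which.min)
  d0 <- dm[cbind(idx, nn)]
  valid <- is.finite(d0) & d0 > 0
  if (sum(valid) < 4) return(0)
  mean_log <- numeric(k_max + 1)
  for (k in 0:k_max) {
    a <- emb_rows(x, idx[valid] + k, m, tau)
    b <- emb_rows(x, nn[valid] + k, m, tau)
    dk <- sqrt(rowSums((a - b)^2))
    mean_log[k + 1] <- mean(log(pmax(dk, 1e-12)))
  }
  kk <- 0:k_max
  unname(coef(lm(mean_log ~ kk))[2]) * fs / stride
}

# Row-wise delay embedding starting at positions `at` (1-based).
emb_rows <- function(x, at, m, tau) {
  sapply(0:(m - 1), function(j) x[at + j * tau])
}

# Upper/lower signal envelopes by linear interpolation through local
# extrema (endpoints included).
envelope_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(upper = x, lower = x))
  dx <- diff(x)
  up_i <- which(dx[-length(dx)] > 0 & dx[-1] <= 0) + 1L
  lo_i <- which(dx[-length(dx)] < 0 & dx[-1] >= 0) + 1L
  interp <- function(i) {
    pts <- unique(c(1L, i, n))
    stats::approx(pts, x[pts], xout = seq_len(n))$y
  }
  list(upper = interp(up_i), lower = interp(lo_i))
}

#' Non-linear epoch features
#'
#' Largest-Lyapunov-exponent estimate (Rosenstein-style; 0 for a
#' constant epoch), the maximum of the upper envelope, and the minimum
#' of the lower envelope (envelopes interpolate local extrema).
#'
#' @param x Numeric epoch trace.
#' @param fs Sampling rate in Hz.
#' @return Named numeric vector `(lyapunov, env_max, env_min)`.
#' @export
nonlinear_features <- function(x, fs = 35) {
  env <- envelope_extrema(x)
  c(
    lyapunov = lyapunov_estimate(x, fs = fs),
    env_max = max(env$upper),
    env_min = min(env$lower)
  )
}

#' diffEDA epoch features
#'
#' The sum over all lags of the autocorrelation sequence of the epoch's
#' diffEDA trace (algebraically `sum(d)^2`) and the maximum of its
#' self-convolution. The trace is paired with itself: the feature-set
#' definition names a single signal.
#'
#' @param d Numeric diffEDA epoch trace.
#' @return Named numeric vector `(xcorr_sum, conv_max)`.
#' @export
diff_features <- function(d) {
  if (length(d) == 0) return(c(xcorr_sum = 0, conv_max = 0))
  # Full correlation and convolution sequences.
  xc <- conv_open(d, rev(d)) # correlation sequence at all lags
  cv <- conv_open(d, d) # self-convolution
  c(xcorr_sum = sum(xc), conv_max = max(cv))
}

# Map a base-trace (35 Hz) sample span to a derivative trace, aligning
# by the samples discarded at the start (offset) minus the group delay.
slice_derivative <- function(d, start_idx, end_idx) {
  shift <- attr(d, "offset") - attr(d, "delay")
  i0 <- max(1L, as.integer(start_idx - shift))
  i1 <- min(length(d), as.integer(end_idx - shift))
  if (i1 < i0) abort("derivative span empty for this epoch")
  d[i0:i1]
}

#' Extract the full 77-variable feature matrix of a recording
#'
#' Computes every per-epoch feature from the preprocessed traces, the
#' detected events/storms, and the subject's sex, and attaches the
#' epoch's stage label and the subject's identifiers.
#'
#' @param recording An `eda_recording`.
#' @param derived Its [preprocess_recording()] output.
#' @param events,storms Detection results ([detect_events()],
#'   [detect_storms()]).
#' @return A tibble of class `eda_features`: columns `subject_id`,
#'   `epoch`, `stage`, `ahi`, `odi`, then the 77 feature columns of
#'   [eda_feature_names()] (`sex` is a factor, the rest numeric).
#' @examples
#' h <- generate_hypnogram(4, seed = 1)
#' r <- generate_recording(h, subject_profile(), seed = 1)
#' d <- preprocess_recording(r$recording)
#' ev <- detect_events(d$eda)
#' fm <- extract_features(r$recording, d, ev, detect_storms(ev))
#' dim(fm)
#' @export
extract_features <- function(recording, derived, events, storms) {
  if (!inherits(derived, "eda_derived")) abort("`derived` must come from preprocess_recording()")
  fs <- derived$fs
  sl <- epoch_slices(length(derived$eda), fs)
  n_ep_hyp <- nrow(recording$hypnogram)
  if (nrow(sl) > n_ep_hyp) sl <- sl[seq_len(n_ep_hyp), ]
  prof <- recording$profile

  rows <- purrr::map(seq_len(nrow(sl)), function(i) {
    a <- sl$start_idx[i]
    b <- sl$end_idx[i]
    x_eda <- derived$eda[a:b]
    x_det <- derived$det_eda[a:b]
    x_diff <- derived$diff_eda[a:b]
    wav <- purrr::map(1:4, function(lv) {
      stridev <- derived$level_stride[lv]
      j0 <- max(1L, ceiling(a / stridev))
      j1 <- min(length(derived$dwt_detail[[lv]]), floor(b / stridev))
      wavelet_features(derived$dwt_detail[[lv]][j0:j1])
    })
    es <- event_storm_features(
      events, storms, c(sl$start_s[i], sl$end_s[i]), x_eda,
      fs = fs
    )
    v <- c(
      time_features(x_eda), time_features(x_det),
      derivative_features(slice_derivative(derived$d1_eda, a, b)),
      derivative_features(slice_derivative(derived$d2_eda, a, b)),
      derivative_features(slice_derivative(derived$d1_det, a, b)),
      derivative_features(slice_derivative(derived$d2_det, a, b)),
      freq_features(x_eda, fs), freq_features(x_det, fs),
      unlist(wav),
      nonlinear_features(x_eda, fs), nonlinear_features(x_det, fs),
      diff_features(x_diff),
      es
    )
    unname(v)
  })
  num <- do.call(rbind, rows)
  colnames(num) <- head(eda_feature_names(), -1)
  out <- tibble::as_tibble(num)
  out$sex <- factor(prof$sex, levels = c("F", "M"))
  out <- dplyr::bind_cols(
    tibble::tibble(
      subject_id = prof$subject_id,
      epoch = sl$epoch,
      stage = recording$hypnogram$stage[seq_len(nrow(sl))],
      ahi = prof$ahi,
      odi = prof$odi
    ),
    out
  )
  class(out) <- c("eda_features", class(out))
  out
}

meta_columns <- c("subject_id", "epoch", "stage", "ahi", "odi")

numeric_feature_columns <- function(m) {
  setdiff(intersect(eda_feature_names(), names(m)), "sex")
}

#' Fit a cross-individual feature normalizer
#'
#' Learns per-column means and standard deviations from the pooled
#' epochs of the supplied (training) subjects. Zero-variance columns are
#' left unscaled with a warning. The categorical `sex` column is exempt.
#'
#' @param m An `eda_features` tibble (the training rows only, to avoid
#'   information leaking from test subjects).
#' @return An object of class `eda_normalizer`.
#' @export
fit_feature_normalizer <- function(m) {
  cols <- numeric_feature_columns(m)
  center <- vapply(m[cols], mean, numeric(1))
  scale <- vapply(m[cols], sd, numeric(1))
  flat <- !is.finite(scale) | scale <= 0
  if (any(flat)) {
    warn(paste0(
      "constant feature column(s) left unscaled: ",
      paste(cols[flat], collapse = ", ")
    ))
    scale[flat] <- 1
    center[flat] <- 0
  }
  structure(
    list(columns = cols, center = center, scale = scale, constant = cols[flat]),
    class = "eda_normalizer"
  )
}

#' @export
predict.eda_normalizer <- function(object, newdata, ...) {
  for (j in seq_along(object$columns)) {
    cl <- object$columns[j]
    newdata[[cl]] <- (newdata[[cl]] - object$center[j]) / object$scale[j]
  }
  newdata
}

#' Normalize features across individuals
#'
#' Convenience wrapper: fits the normalizer on `m` itself and applies
#' it. Within cross-validation use [fit_feature_normalizer()] on the
#' training fold and `predict()` on the test fold instead.
#'
#' @inheritParams fit_feature_normalizer
#' @return The normalized tibble.
#' @export
normalize_features <- function(m) {
  predict(fit_feature_normalizer(m), m)
}
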