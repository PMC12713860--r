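# Signal conditioning for endosomatic EDA.
#
# The chain: rational downsampling 200 -> 35 Hz, whole-night second-order
# polynomial detrending, seventh-order Savitzky-Golay smoothing, wavelet
# soft-threshold denoising, their difference (diffEDA), and FIR
# differentiation of the raw and detrended traces. Everything after the
# downsampler operates at 35 Hz.

#' Preprocessing configuration
#'
#' @param fs_in Input sampling rate, Hz (default 200).
#' @param fs_out Working rate after downsampling, Hz (default 35).
#' @param sg_order Savitzky-Golay polynomial order (default 7).
#' @param sg_window Savitzky-Golay window length in samples; must be odd
#'   and greater than `sg_order`. Default 127 (~3.6 s at 35 Hz): long
#'   enough to suppress content above the 3 Hz event band, short enough
#'   not to flatten events.
#' @param wavelet Wavelet family for denoising (default `"db4"`).
#' @param dwt_levels Wavelet decomposition depth (default 4; levels 1-4
#'   feed the time-frequency features).
#' @param fir_order Differentiator FIR order (default 50).
#' @param fir_passband,fir_stopband Differentiator band edges in Hz
#'   (defaults 10 and 12.5; the stopband must stay below `fs_out/2`).
#' @param transient_discard Samples dropped after each differentiator
#'   pass to remove the filter transient (default 50).
#' @return A list of class `eda_preprocess_config`.
#' @export
preprocess_config <- function(fs_in = 200, fs_out = 35,
                              sg_order = 7, sg_window = 127,
                              wavelet = "db4", dwt_levels = 4L,
                              fir_order = 50, fir_passband = 10,
                              fir_stopband = 12.5, transient_discard = 50L) {
  if (sg_window %% 2 != 1 || sg_window <= sg_order) {
    abort("`sg_window` must be odd and greater than `sg_order`")
  }
  if (!(fir_passband < fir_stopband && fir_stopband < fs_out / 2)) {
    abort("need fir_passband < fir_stopband < fs_out/2")
  }
  structure(
    list(
      fs_in = fs_in, fs_out = fs_out, sg_order = sg_order,
      sg_window = sg_window, wavelet = wavelet, dwt_levels = dwt_levels,
      fir_order = fir_order, fir_passband = fir_passband,
      fir_stopband = fir_stopband, transient_discard = as.integer(transient_discard)
    ),
    class = "eda_preprocess_config"
  )
}

# Polyphase rational resampler. The interpolation kernel is a Kaiser-
# windowed sinc with cutoff at the smaller of the two Nyquist rates; each
# polyphase branch is normalized to unit sum so constant signals pass
# through exactly and edge samples (computed on edge-replicated padding)
# show no transient. Branch convolutions run through FFTs.
resample_rational <- function(x, p, q, lobes = 10, beta = 10) {
  n <- length(x)
  if (n < 1) abort("empty input")
  g <- gcd_int(p, q)
  p <- p / g
  q <- q / g
  if (p == q) return(x)
  K <- lobes * max(p, q) # kernel half-width in upsampled samples
  k <- (-K):K
  fc <- 1 / (2 * max(p, q)) # cycles per upsampled sample
  kern <- 2 * fc * sinc(2 * fc * k) *
    besselI(beta * sqrt(pmax(0, 1 - (k / K)^2)), 0) / besselI(beta, 0)
  J <- K %/% p + 1L
  n_out <- ceiling(n * p / q)
  m <- seq_len(n_out) - 1L
  mq <- m * q
  qm <- mq %/% p # 0-based input index anchoring output m
  r <- mq %% p # polyphase branch
  # Odd-reflection padding continues the local trend past both ends, so
  # neither a flat shelf nor a slope kink leaks into the output edges.
  pad <- J + 1L
  if (n > pad) {
    left <- 2 * x[1] - x[1 + seq_len(pad)]
    right <- 2 * x[n] - x[n - seq_len(pad)]
  } else {
    left <- rep(x[1], pad)
    right <- rep(x[n], pad)
  }
  xp <- c(rev(left), x, right)
  y <- numeric(n_out)
  for (phase in unique(r)) {
    j <- (-J):J
    pos <- j * p + phase
    gv <- numeric(length(j))
    ok <- abs(pos) <= K
    gv[ok] <- kern[pos[ok] + K + 1]
    gv <- gv / sum(gv)
    cv <- conv_open(xp, gv)
    sel <- r == phase
    y[sel] <- cv[qm[sel] + 1L + pad + J]
  }
  y
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)
sinc <- function(t) ifelse(t == 0, 1, sin(pi * t) / (pi * t))

#' Downsample a 200 Hz EDA trace to 35 Hz
#'
#' Anti-aliased rational resampling by 7/40 (in general `fs_out/fs_in`
#' reduced to lowest terms). The output length is `ceiling(n * 7/40)`.
#'
#' @param x Numeric trace at `cfg$fs_in` Hz (>= 40 samples).
#' @param cfg A [preprocess_config()].
#' @return Numeric trace at `cfg$fs_out` Hz.
#' @export
downsample_eda <- function(x, cfg = preprocess_config()) {
  if (length(x) < 40) abort("input too short to downsample (need >= 40 samples)")
  resample_rational(x, cfg$fs_out, cfg$fs_in)
}

#' Remove the whole-night second-order polynomial trend
#'
#' Fits a single degree-2 polynomial to the entire trace by least squares
#' and subtracts it, removing the subject-specific tonic drift so that
#' signals are comparable across individuals.
#'
#' @param x Numeric trace (length >= 3).
#' @return Detrended trace of the same length.
#' @export
detrend_poly2 <- function(x) {
  n <- length(x)
  if (n < 3) abort("need at least 3 samples to fit a quadratic")
  t <- seq(-1, 1, length.out = n)
  basis <- cbind(1, t, t^2)
  fit <- qr.fitted(qr(basis), x)
  x - fit
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing (order `cfg$sg_order`, window
#' `cfg$sg_window`); polynomials up to the filter order pass through
#' unchanged in the window interior, while higher-frequency content is
#' attenuated.
#'
#' @inheritParams downsample_eda
#' @return Smoothed trace, same length.
#' @export
sg_smooth <- function(x, cfg = preprocess_config()) {
  if (length(x) < cfg$sg_window) abort("input shorter than the Savitzky-Golay window")
  as.numeric(signal::sgolayfilt(x, p = cfg$sg_order, n = cfg$sg_window))
}

#' diffEDA: wavelet-denoised minus Savitzky-Golay trace
#'
#' @param dwt_eda,sg_eda Equal-length traces.
#' @return Their pointwise difference.
#' @export
make_diff_eda <- function(dwt_eda, sg_eda) {
  if (length(dwt_eda) != length(sg_eda)) abort("trace lengths differ")
  dwt_eda - sg_eda
}

# Least-squares design of the odd-length antisymmetric (type III)
# differentiator: amplitude response ~ omega in the passband, ~ 0 in the
# stopband, transition band unconstrained.
design_differentiator <- function(order, passband, stopband, fs) {
  stopifnot(order %% 2 == 0)
  half <- order / 2
  wp <- 2 * pi * passband / fs
  ws <- 2 * pi * stopband / fs
  w <- c(seq(0, wp, length.out = 1024), seq(ws, pi, length.out = 512))
  target <- c(seq(0, wp, length.out = 1024), rep(0, 512))
  A <- sapply(seq_len(half), function(k) sin(k * w))
  b <- qr.solve(qr(A), target)
  h <- numeric(order + 1)
  h[half + 1] <- 0
  for (k in seq_len(half)) {
    h[half + 1 - k] <- b[k] / 2
    h[half + 1 + k] <- -b[k] / 2
  }
  h
}

#' FIR differentiation
#'
#' First or second time derivative via a least-squares linear-phase FIR
#' differentiator (order `cfg$fir_order`, passband `cfg$fir_passband` Hz,
#' stopband `cfg$fir_stopband` Hz). The second derivative is two passes
#' of the same filter. After each pass the first `cfg$transient_discard`
#' samples are dropped; the total number of samples removed from the
#' start is recorded in the `offset` attribute (the filter's group delay,
#' `cfg$fir_order/2` samples per pass, is included in `delay`).
#'
#' @param x Numeric trace at `cfg$fs_out` Hz.
#' @param order Derivative order, 1 or 2.
#' @param cfg A [preprocess_config()].
#' @return Derivative trace in signal units per second, with attributes
#'   `offset` (samples dropped from the start) and `delay` (group delay
#'   in samples).
#' @export
fir_derivative <- function(x, order = 1, cfg = preprocess_config()) {
  if (!order %in% c(1, 2)) abort("`order` must be 1 or 2")
  need <- order * (cfg$fir_order + cfg$transient_discard)
  if (length(x) <= need) abort("input too short for the requested derivative")
  h <- design_differentiator(
    cfg$fir_order, cfg$fir_passband, cfg$fir_stopband, cfg$fs_out
  )
  y <- x
  for (pass in seq_len(order)) {
    y <- stats::filter(y, h, method = "convolution", sides = 1)
    y <- as.numeric(y[-seq_len(cfg$transient_discard)])
    y <- y * cfg$fs_out
  }
  structure(y,
    offset = order * cfg$transient_discard,
    delay = order * cfg$fir_order / 2
  )
}

#' Run the full preprocessing chain on a recording
#'
#' Downsamples to 35 Hz, then derives every conditioned trace the feature
#' set consumes: detrended EDA, Savitzky-Golay smoothed EDA, wavelet
#' denoised EDA (with per-level detail coefficients), diffEDA, and the
#' first and second FIR derivatives of the raw and detrended traces.
#'
#' @param recording An `eda_recording` (from [generate_recording()] or
#'   [read_edf()]), or a bare numeric trace at `cfg$fs_in` Hz.
#' @param cfg A [preprocess_config()].
#' @return A list of class `eda_derived` with elements `eda`, `det_eda`,
#'   `sg_eda`, `dwt_eda`, `diff_eda` (equal lengths, 35 Hz), derivative
#'   traces `d1_eda`, `d2_eda`, `d1_det`, `d2_det` (shorter, with
#'   `offset`/`delay` attributes), `dwt_detail` (4 coefficient vectors),
#'   `level_stride`, and `fs`.
#' @examples
#' h <- generate_hypnogram(10, seed = 1)
#' r <- generate_recording(h, subject_profile(), seed = 1)
#' d <- preprocess_recording(r$recording)
#' lengths(d[c("eda", "det_eda", "diff_eda")])
#' @export
preprocess_recording <- function(recording, cfg = preprocess_config()) {
  x <- if (inherits(recording, "eda_recording")) recording$signal else recording
  if (!is.numeric(x)) abort("`recording` must be an eda_recording or numeric trace")
  eda <- downsample_eda(x, cfg)
  det <- detrend_poly2(eda)
  sg <- sg_smooth(eda, cfg)
  dn <- dwt_denoise(eda, wavelet = cfg$wavelet, levels = cfg$dwt_levels)
  structure(
    list(
      eda = eda,
      det_eda = det,
      sg_eda = sg,
      dwt_eda = dn$x,
      diff_eda = make_diff_eda(dn$x, sg),
      d1_eda = fir_derivative(eda, 1, cfg),
      d2_eda = fir_derivative(eda, 2, cfg),
      d1_det = fir_derivative(det, 1, cfg),
      d2_det = fir_derivative(det, 2, cfg),
      dwt_detail = dn$details,
      level_stride = dn$level_stride,
      fs = cfg$fs_out
    ),
    class = "eda_derived"
  )
}
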