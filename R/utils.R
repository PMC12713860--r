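# Internal helpers shared across modules.

# Deterministic child seeds: every stochastic routine draws its own seed
# from a master seed plus a named substream, so one master seed fixes the
# whole simulate -> evaluate chain without coupling the substreams.
derive_seed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 48271 + h * 69621 + index * 1013904223) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min) {
    abort(sprintf("`%s` must be a single finite number >= %s", name, min))
  }
  invisible(x)
}

# Linear ("open") convolution via FFTs zero-padded to a 2-3-5-smooth
# length. stats::convolve transforms at length n1+n2-1, which R's
# mixed-radix FFT handles in quadratic time when that length has a large
# prime factor; padding to a smooth length keeps it n log n.
conv_open <- function(a, b) {
  m <- length(a) + length(b) - 1L
  n <- stats::nextn(m, c(2, 3, 5))
  fa <- fft(c(a, numeric(n - length(a))))
  fb <- fft(c(b, numeric(n - length(b))))
  Re(fft(fa * fb, inverse = TRUE))[seq_len(m)] / n
}

# Interval utilities (seconds); intervals are two-column data frames with
# onset_s < offset_s, kept sorted by onset.
merge_intervals <- function(onset, offset) {
  if (length(onset) == 0) {
    return(tibble::tibble(onset_s = numeric(), offset_s = numeric()))
  }
  o <- order(onset)
  onset <- onset[o]
  offset <- offset[o]
  res_on <- onset[1]
  res_off <- offset[1]
  out_on <- numeric()
  out_off <- numeric()
  for (i in seq_along(onset)[-1]) {
    if (onset[i] <= res_off) {
      res_off <- max(res_off, offset[i])
    } else {
      out_on <- c(out_on, res_on)
      out_off <- c(out_off, res_off)
      res_on <- onset[i]
      res_off <- offset[i]
    }
  }
  tibble::tibble(onset_s = c(out_on, res_on), offset_s = c(out_off, res_off))
}

# Mark samples of a trace (at rate fs, starting at t = 0) that fall inside
# any [onset, offset) interval.
samples_in_intervals <- function(n, fs, onset, offset) {
  inside <- logical(n)
  t <- (seq_len(n) - 1) / fs
  for (i in seq_along(onset)) {
    inside <- inside | (t >= onset[i] & t < offset[i])
  }
  inside
}
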