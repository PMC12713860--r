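# Preprocessing chain: downsampling, detrending, smoothing, wavelet
# denoising, diffEDA, FIR differentiation.

cfg <- preprocess_config()

test_that("downsampling is exact on constants and accurate on in-band sines", {
  y <- downsample_eda(rep(2.5, 400), cfg)
  expect_length(y, 70)
  expect_lt(max(abs(y - 2.5)), 1e-9)

  t <- seq(0, 60 - 1 / 200, by = 1 / 200)
  ys <- downsample_eda(sin(2 * pi * t), cfg)
  expect_length(ys, ceiling(length(t) * 7 / 40))
  t35 <- (seq_along(ys) - 1) / 35
  mid <- 200:(length(ys) - 200)
  expect_lt(max(abs(ys[mid] - sin(2 * pi * t35[mid]))), 1e-3)
})

test_that("downsampling attenuates content above the new Nyquist", {
  t <- seq(0, 60 - 1 / 200, by = 1 / 200)
  y30 <- downsample_eda(sin(2 * pi * 30 * t), cfg)
  expect_lt(sqrt(mean(y30^2)), 0.05)
  expect_error(downsample_eda(numeric(0)), "short")
})

test_that("quadratic detrending annihilates quadratics and is idempotent", {
  tt <- seq_len(1000)
  x <- 3 + 0.1 * tt - 0.002 * tt^2
  expect_lt(max(abs(detrend_poly2(x))) / max(abs(x)), 1e-8)

  set.seed(1)
  z <- rnorm(500)
  expect_lt(max(abs(detrend_poly2(detrend_poly2(z)) - detrend_poly2(z))), 1e-9)
  expect_error(detrend_poly2(c(1, 2)), "3 samples")
})

test_that("detrending matches a direct normal-equations solve", {
  n <- 400
  tt <- seq_len(n)
  x <- 1 + 0.01 * tt - 1e-5 * tt^2 + sin(2 * pi * 0.5 * tt / 35)
  # independent oracle: explicit normal equations on the raw basis
  basis <- cbind(1, tt, tt^2)
  beta <- solve(t(basis) %*% basis, t(basis) %*% x)
  expect_lt(max(abs(detrend_poly2(x) - (x - basis %*% beta))), 1e-6)
})

test_that("Savitzky-Golay passes low-order polynomials and smooths noise", {
  tt <- seq(0, 1, length.out = 1000)
  x <- tt^3
  y <- sg_smooth(x, cfg)
  expect_lt(max(abs(y[200:800] - x[200:800])), 1e-8)
  expect_equal(sg_smooth(rep(4, 500), cfg), rep(4, 500), tolerance = 1e-10)

  smoother <- vapply(1:20, function(s) {
    set.seed(s)
    z <- rnorm(2000)
    var(sg_smooth(z, cfg)) < var(z)
  }, logical(1))
  expect_true(all(smoother))
  expect_error(
    preprocess_config(sg_window = 128),
    "odd"
  )
})

test_that("wavelet transform reconstructs perfectly at zero threshold", {
  set.seed(2)
  x <- rnorm(1000)
  d <- dwt_denoise(x, threshold = 0)
  expect_lt(max(abs(d$x - x)), 1e-10)
  z <- dwt_denoise(numeric(128))
  expect_equal(max(abs(z$x)), 0)
  expect_true(all(vapply(z$details, function(v) all(v == 0), logical(1))))
  expect_error(dwt_denoise(numeric(8), levels = 4), "shorter")
})

test_that("wavelet soft thresholding denoises a noisy sine (Monte-Carlo)", {
  t <- seq(0, 30, length.out = 2100)
  clean <- sin(2 * pi * 0.3 * t)
  wins <- vapply(1:20, function(s) {
    set.seed(s)
    noisy <- clean + rnorm(length(t), sd = sd(clean) / sqrt(10)) # SNR 10 dB
    mean((dwt_denoise(noisy)$x - clean)^2) < mean((noisy - clean)^2)
  }, logical(1))
  expect_true(all(wins))
})

test_that("diffEDA is a pointwise antisymmetric difference", {
  a <- rnorm(100)
  b <- rnorm(100)
  expect_equal(make_diff_eda(a, a), rep(0, 100))
  expect_equal(make_diff_eda(a, rep(0, 100)), a)
  expect_equal(make_diff_eda(a, b), -make_diff_eda(b, a))
  expect_error(make_diff_eda(a, b[-1]), "lengths")
})

test_that("FIR differentiator matches analytic sine derivatives", {
  t35 <- (0:(35 * 30 - 1)) / 35
  xs <- sin(2 * pi * t35)
  d1 <- fir_derivative(xs, 1, cfg)
  mid <- 100:(length(d1) - 100)
  amp1 <- max(abs(d1[mid]))
  expect_lt(abs(amp1 - 2 * pi) / (2 * pi), 0.02)

  d2 <- fir_derivative(xs, 2, cfg)
  mid2 <- 100:(length(d2) - 100)
  amp2 <- max(abs(d2[mid2]))
  expect_lt(abs(amp2 - (2 * pi)^2) / (2 * pi)^2, 0.04)

  dc <- fir_derivative(rep(3, 2000), 1, cfg)
  expect_lt(max(abs(dc)), 1e-6 * 3)
  expect_equal(attr(d1, "offset"), 50)
  expect_equal(attr(d2, "offset"), 100)
  expect_error(fir_derivative(rnorm(90), 1, cfg), "short")
})

test_that("all linear stages are linear on random inputs", {
  set.seed(3)
  a <- rnorm(2000)
  b <- rnorm(2000)
  for (f in list(
    function(z) downsample_eda(z, cfg),
    detrend_poly2,
    function(z) sg_smooth(z, cfg),
    function(z) as.numeric(fir_derivative(z, 1, cfg))
  )) {
    lhs <- f(2 * a - 3 * b)
    rhs <- 2 * f(a) - 3 * f(b)
    expect_lt(max(abs(lhs - rhs)), 1e-8 * max(1, max(abs(lhs))))
  }
})

test_that("the full chain on a constant recording yields null derived traces", {
  h <- generate_hypnogram(3, seed = 1)
  prof <- subject_profile(
    tonic_level = 1.5, drift_coeffs = c(0, 0, 0),
    stage_event_rate = c(W = 0, N1 = 0, N2 = 0, N3 = 0, REM = 0),
    storm_base_per_h = 0, storm_slope_per_ahi = 0,
    artifact_rate = 0, noise_sd = 0, rw_sd = 0
  )
  r <- generate_recording(h, prof, seed = 1)
  d <- preprocess_recording(r$recording, cfg)
  expect_lt(max(abs(d$det_eda)), 1e-8)
  expect_lt(max(abs(d$diff_eda)), 1e-8)
  expect_lt(max(abs(d$d1_eda)), 1e-6)
  expect_lt(max(abs(d$d2_det)), 1e-6)
  expect_equal(length(d$eda), length(d$dwt_eda))
  expect_equal(length(d$eda), length(d$sg_eda))
})
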