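test_that("noise sigma follows the median-based estimator", {
  expect_equal(estimate_noise_sigma(rep(c(0.6745, -0.6745), 50)), 1.0)
  expect_equal(estimate_noise_sigma(rep(0, 100)), 0)
  set.seed(1)
  expect_equal(estimate_noise_sigma(rnorm(1e6)), 1.0, tolerance = 0.01)
  expect_error(estimate_noise_sigma(numeric(0)), "empty")
})

test_that("threshold is multiplier times sigma", {
  expect_equal(compute_threshold(1), 4)
  expect_equal(compute_threshold(0), 0)
  expect_equal(compute_threshold(0.25, 4), 1.0)
  expect_error(compute_threshold(-1), ">= 0")
})

test_that("band-pass filter removes DC and preserves in-band tones", {
  fs <- 10000
  dc <- raw_recording(rep(2, 4000), fs = fs)
  out <- bandpass_filter(dc, c(300, 4000))
  expect_lt(max(abs(out$samples)), 1e-6 * 2)

  t <- seq(0, 0.5, by = 1 / fs)
  tone <- raw_recording(sin(2 * pi * 1000 * t), fs = fs)
  filt <- bandpass_filter(tone, c(300, 4000))
  mid <- seq(1000, length(t) - 1000)  # ignore filter edge transients
  # frequency-domain oracle: squared magnitude response of the same design
  # (forward-backward pass) at 1 kHz
  bf <- signal::butter(2, c(300, 4000) / (fs / 2), type = "pass")
  z <- exp(-1i * 2 * pi * 1000 / fs * (seq_along(bf$b) - 1))
  gain_expected <- Mod(sum(bf$b * z) / sum(bf$a * z))^2
  # measure the tone amplitude by least squares: with only ten samples per
  # cycle the sample grid misses the true peak of the zero-phase output
  basis <- cbind(sin(2 * pi * 1000 * t[mid]), cos(2 * pi * 1000 * t[mid]))
  amp <- sqrt(sum(qr.solve(basis, filt$samples[mid])^2))
  expect_equal(amp, gain_expected, tolerance = 0.001)
  expect_equal(amp, 1, tolerance = 0.05)  # within 5% at 1 kHz

  expect_error(bandpass_filter(tone, c(300, 6000)), "Nyquist")
})

test_that("quadratic peak fitting recovers the analytic vertex", {
  fs <- 10000
  x <- numeric(200)
  # parabola bump with vertex height 5 at a deliberately off-grid position
  t0 <- 100.37
  idx <- 95:106
  x[idx] <- 5 - 0.8 * (idx - t0)^2
  x <- pmax(x, 0)
  ev <- detect_peaks(x, fs = fs, threshold = 4)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$time_s * fs + 1 - t0), 0.05)  # |dt| < 0.05 sample
  expect_equal(ev$amplitude, 5, tolerance = 1e-6)

  # same bump scaled below threshold is ignored
  ev0 <- detect_peaks(x * 3 / 5, fs = fs, threshold = 4)
  expect_equal(nrow(ev0), 0)
})

test_that("refractory rejection keeps the first of two close peaks", {
  fs <- 10000
  x <- numeric(300)
  for (p in c(100, 105)) x[(p - 2):(p + 2)] <- c(2, 4.5, 5, 4.5, 2)
  ev <- detect_peaks(x, fs = fs, threshold = 4, dead_time_ms = 1)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$time_s - 99 / fs), 2 / fs)
  # with a short dead time both survive
  ev2 <- detect_peaks(x, fs = fs, threshold = 4, dead_time_ms = 0.2)
  expect_equal(nrow(ev2), 2)
})

test_that("event count is non-increasing in the threshold", {
  set.seed(3)
  x <- stats::filter(rnorm(20000), rep(1 / 3, 3), circular = TRUE)
  x <- as.numeric(x)
  counts <- vapply(seq(0.5, 3, by = 0.25),
                   function(thr) nrow(detect_peaks(x, fs = 10000, threshold = thr)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("extraction window structure matches the pipeline constants", {
  fs <- 10000
  cfg <- sim_config(fs = fs, duration = 1, noise_level = 0, seed = 5)
  te <- make_templates(cfg)
  x <- numeric(2000)
  pk <- te$peak_idx[1]
  x[500:(500 + nrow(te$W) - 1)] <- te$W[, 1]
  events <- detect_peaks(x, fs = fs, threshold = 0.5)
  wm <- extract_waveforms(x, events, fs = fs)
  expect_equal(wm$raw_window_ms, 1.8)       # 18 raw samples at 10 kHz
  expect_equal(wm$n_interp, 36L)            # spline upsampling by two
  expect_equal(ncol(wm$A), 24L)             # 6 trimmed from each end
  expect_equal(ncol(wm$A) * wm$dt * 1000, 1.2)
  expect_equal(wm$peak_col, 10L)
})

test_that("a noiseless spike is extracted as its spline-resampled template", {
  fs <- 10000
  cfg <- sim_config(fs = fs, duration = 1, noise_level = 0, seed = 5)
  te <- make_templates(cfg)
  x <- numeric(2000)
  p0 <- 500
  x[p0:(p0 + nrow(te$W) - 1)] <- te$W[, 2]
  peak_sample <- p0 + te$peak_idx[2] - 1L
  ev <- tibble::tibble(time_s = (peak_sample - 1) / fs)
  wm <- extract_waveforms(x, ev, fs = fs)
  # oracle: natural-spline resample of the raw 18-sample window, centered on
  # the closed-form quadratic vertex of the three samples around the peak
  w <- x[(peak_sample - 8):(peak_sample + 9)]
  a <- (w[8] + w[10] - 2 * w[9]) / 2
  b <- (w[10] - w[8]) / 2
  delta <- -b / (2 * a)
  f <- stats::splinefun(0:17, w, method = "natural")
  expected <- f(8 + delta + 0.5 * ((6:29) - 16))
  expect_lt(max(abs(wm$A[1, ] - expected)), 1e-6)
  expect_equal(which.max(abs(wm$A[1, ])), 11L)  # peak at 0-based column 10
})

test_that("events whose window crosses a trace edge are dropped and counted", {
  fs <- 10000
  x <- numeric(100)
  x[3] <- 1
  ev <- tibble::tibble(time_s = c(2 / fs, 50 / fs))
  wm <- extract_waveforms(x, ev, fs = fs)
  expect_equal(nrow(wm$A), 1)
  expect_equal(wm$n_dropped, 1)
})

test_that("zero-noise synthetic spikes are recovered to within one sample", {
  cfg <- sim_config(duration = 3, noise_level = 0, firing_rate = c(10, 10, 10),
                    seed = 11)
  g <- generate_recording(cfg)
  ev <- detect_peaks(g$recording, threshold = 0.3)
  wm <- extract_waveforms(g$recording, ev)
  ok <- g$truth$time_s > 0.002 & g$truth$time_s < cfg$duration - 0.002
  iso <- !g$truth$is_overlapping & ok
  miss <- vapply(g$truth$time_s[iso],
                 function(t0) min(abs(ev$time_s - t0)), numeric(1))
  expect_lt(max(miss), 1 / cfg$fs)
  # alignment: per-row argmax jitter is suppressed
  am <- apply(abs(wm$A), 1, which.max)
  expect_lte(stats::sd(am), 0.5)
})
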