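test_that("template sets satisfy their normalization and similarity contracts", {
  cfg <- sim_config(duration = 1, seed = 2)
  easy <- make_templates(cfg, "easy")
  expect_equal(ncol(easy$W), 3)
  expect_equal(apply(abs(easy$W), 2, max), rep(1, 3), tolerance = 1e-9)
  hard <- make_templates(cfg, "hard")
  # hard sets are deliberately more similar than easy sets
  expect_lt(max(hard$pairwise_nrms), min(easy$pairwise_nrms))
  expect_gt(min(easy$pairwise_nrms), 0.5)
  expect_lt(max(hard$pairwise_nrms), 0.3)

  # near-duplicate parameter sets are rejected
  p <- list(list(tau1 = 0.3, p1 = 4, r = 0.5, tau2 = 0.7, p2 = 5),
            list(tau1 = 0.3, p1 = 4, r = 0.5, tau2 = 0.7, p2 = 5),
            list(tau1 = 0.301, p1 = 4, r = 0.5, tau2 = 0.7, p2 = 5))
  expect_error(make_templates(cfg, params = p), "duplicate")

  expect_error(make_templates(sim_config(fs = 1000, duration = 1)), "too low")
})

test_that("background noise hits the target standard deviation exactly", {
  cfg <- sim_config(duration = 10, noise_level = 0.2, seed = 4)
  te <- make_templates(cfg)
  noise <- generate_background_noise(te, cfg)
  expect_equal(stats::sd(noise), 0.2, tolerance = 1e-12)
  cfg2 <- sim_config(duration = 10, noise_level = 0.05, seed = 4)
  expect_equal(stats::sd(generate_background_noise(te, cfg2)), 0.05,
               tolerance = 1e-12)
  # seeded determinism is bit-exact
  expect_identical(generate_background_noise(te, cfg),
                   generate_background_noise(te, cfg))
  expect_error(generate_background_noise(te, cfg, n_samples = 0), "zero")
})

test_that("seeded recordings are fully reproducible", {
  cfg <- sim_config(duration = 5, noise_level = 0.15, seed = 123)
  a <- generate_recording(cfg)
  b <- generate_recording(cfg)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$truth, b$truth)
})

test_that("zero-noise spikes appear verbatim in the trace at truth times", {
  cfg <- sim_config(duration = 2, noise_level = 0, firing_rate = c(3, 3, 3),
                    seed = 31)
  g <- generate_recording(cfg)
  te <- g$templates
  iso <- which(!g$truth$is_overlapping)
  ev <- g$truth[iso[2], ]
  u <- ev$unit_id
  s <- round(ev$time_s * cfg$fs) + 1
  lo <- s - te$peak_idx[u] + 1
  seg <- g$recording$samples[lo:(lo + nrow(te$W) - 1)]
  expect_equal(seg, te$W[, u], tolerance = 1e-9)
})

test_that("ground truth obeys the overlap rule and the minimum ISI", {
  cfg <- sim_config(duration = 20, noise_level = 0.1, seed = 17)
  g <- generate_recording(cfg)
  tt <- g$truth$time_s
  expect_false(is.unsorted(tt))
  # brute-force re-derivation of the 0.7 ms overlap flag
  flags <- vapply(seq_along(tt), function(i) {
    others <- tt[-i]
    min(abs(others - tt[i])) < 0.0007
  }, logical(1))
  expect_equal(g$truth$is_overlapping, flags)
  for (u in unique(g$truth$unit_id)) {
    isis <- diff(tt[g$truth$unit_id == u])
    expect_gte(min(isis), cfg$min_isi - 1e-9)
  }
})

test_that("sparse firing produces no overlap flags", {
  cfg <- sim_config(duration = 10, noise_level = 0.05,
                    firing_rate = c(1, 1, 1), seed = 8)
  g <- generate_recording(cfg)
  # rates this low rarely collide; if they do the flag must mark both sides
  expect_lt(mean(g$truth$is_overlapping), 0.05)
})

test_that("a forced overlap target raises the overlap fraction", {
  cfg0 <- sim_config(duration = 10, noise_level = 0.1, seed = 21)
  cfg1 <- sim_config(duration = 10, noise_level = 0.1, seed = 21,
                     overlap_fraction = 0.2)
  f0 <- mean(generate_recording(cfg0)$truth$is_overlapping)
  f1 <- mean(generate_recording(cfg1)$truth$is_overlapping)
  expect_gt(f1, f0)
  expect_gte(f1, 0.18)
})

test_that("constructed twin spikes 0.5 ms apart are both flagged overlapping", {
  flags <- spikefuzz:::overlap_flags(c(0.1, 0.1005, 0.2))
  expect_equal(flags, c(TRUE, TRUE, FALSE))
})

test_that("incompatible firing rate and minimum ISI raise an error", {
  cfg <- sim_config(duration = 1, firing_rate = 500, min_isi = 0.0025)
  expect_error(generate_recording(cfg), "incompatible")
})
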