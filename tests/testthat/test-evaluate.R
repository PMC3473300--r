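test_that("event matching is greedy, one-to-one and tolerance-bounded", {
  t0 <- tibble::tibble(time_s = c(0.1, 0.2, 0.3))
  m <- match_events(t0, t0, tol_ms = 0.5)
  expect_equal(nrow(m$pairs), 3)
  expect_length(m$miss_idx, 0)
  expect_length(m$fp_idx, 0)

  shifted <- tibble::tibble(time_s = t0$time_s + 0.0003)
  m2 <- match_events(shifted, t0, tol_ms = 0.5)
  expect_equal(nrow(m2$pairs), 3)

  far <- tibble::tibble(time_s = t0$time_s + 0.0008)
  m3 <- match_events(far, t0, tol_ms = 0.5)
  expect_equal(nrow(m3$pairs), 0)
  expect_length(m3$miss_idx, 3)
  expect_length(m3$fp_idx, 3)

  expect_error(match_events(t0, t0, tol_ms = -1), ">= 0")
})

test_that("misses shrink and matches grow with the tolerance", {
  set.seed(9)
  truth <- tibble::tibble(time_s = sort(runif(200, 0, 10)))
  det <- tibble::tibble(time_s = sort(truth$time_s + rnorm(200, 0, 3e-4)))
  tols <- c(0.1, 0.25, 0.5, 1)
  misses <- vapply(tols, function(tl) length(match_events(det, truth, tl)$miss_idx), numeric(1))
  expect_true(all(diff(misses) <= 0))
})

test_that("sorting scores are assignment-invariant and count errors correctly", {
  set.seed(13)
  n <- 300
  truth <- tibble::tibble(
    time_s = sort(runif(n, 0, 30)),
    unit_id = sample(1:3, n, replace = TRUE),
    is_overlapping = FALSE
  )
  det <- tibble::tibble(time_s = truth$time_s)
  m <- match_events(det, truth)
  perfect <- score_sorting(truth$unit_id, m, truth)
  expect_equal(perfect$errors_nonoverlap, 0)
  expect_equal(perfect$misclassification_pct, 0)
  expect_equal(perfect$misses, 0)

  # renaming clusters changes nothing
  renamed <- score_sorting(c(2L, 3L, 1L)[truth$unit_id], m, truth)
  expect_equal(renamed$errors_nonoverlap, 0)

  # random labels across 3 equal units leave ~2/3 errors after remapping
  set.seed(14)
  rand <- score_sorting(sample(1:3, n, replace = TRUE), m, truth)
  expect_gt(rand$misclassification_pct, 50)
  expect_lt(rand$misclassification_pct, 75)
})

test_that("overlapping-spike errors never contaminate the non-overlap count", {
  truth <- tibble::tibble(
    time_s = seq(0.1, 1, by = 0.1),
    unit_id = rep(1:2, 5),
    is_overlapping = c(TRUE, TRUE, rep(FALSE, 8))
  )
  det <- tibble::tibble(time_s = truth$time_s)
  m <- match_events(det, truth)
  labels <- truth$unit_id
  labels[truth$is_overlapping] <- 3 - labels[truth$is_overlapping]  # wreck overlaps only
  sc <- score_sorting(labels, m, truth)
  expect_equal(sc$errors_nonoverlap, 0)
  expect_equal(sc$misclassification_pct, 0)
  expect_equal(sc$overlap_false_matches, 2)
})

test_that("balanced class reduction keeps the TPR at its initial value", {
  b <- make_blobs(n_per = 60, sd = 0.15, seed = 19)
  curve <- robustness_curve(b$scores, b$labels, class_id = NULL,
                            saturations = c(1, 0.5, 0.2, 0.05, 1 / 60))
  expect_true(all(curve$tpr == 1))
  # down to a single spike per class
  expect_equal(min(curve$n_kept), 1)
})

test_that("unbalanced reduction reports per-class rates at full saturation", {
  b <- make_blobs(n_per = 40, sd = 0.15, seed = 20)
  curve <- robustness_curve(b$scores, b$labels, class_id = 2,
                            saturations = c(1, 0.5))
  full <- dplyr::filter(curve, .data$saturation == 1, .data$class == 2)
  expect_equal(full$tpr, 1)
  expect_error(robustness_curve(b$scores, b$labels, saturations = c(0, 1)),
               "0, 1")
})

test_that("ISI histogram counts intervals and refractory violations", {
  reg <- seq(0, 1, by = 0.1)  # regular 10 Hz train
  h <- isi_histogram(reg, bin_ms = 1, max_ms = 200)
  expect_equal(sum(h$counts$count), 10)
  expect_equal(h$counts$count[h$counts$isi_ms == 100], 10)
  expect_equal(h$n_violations, 0)

  h1 <- isi_histogram(0.5)
  expect_equal(sum(h1$counts$count), 0)

  burst <- c(0, 0.0005, 0.1)
  expect_equal(isi_histogram(burst)$n_violations, 1)
  expect_error(isi_histogram(c(2, 1)), "sorted")
})

test_that("PSTH pools latencies relative to each stimulus", {
  stim <- c(1, 2, 3)
  spikes <- stim + 0.010
  h <- psth(spikes, stim, window_ms = c(-50, 50), bin_ms = 10)
  expect_equal(sum(h$count), 3)
  expect_equal(h$count[h$latency_ms == 10], 3)
  expect_error(psth(spikes, numeric(0)), "no stimuli")
})

test_that("burst and pause indices follow their ISI definitions", {
  reg <- seq(0, 2, by = 0.05)
  expect_equal(burst_index(reg), 1)
  mixed <- cumsum(c(0, rep(0.010, 9), 0.100)) # 9 short + 1 long ISI
  expect_equal(pause_index(mixed), 1 / 9)
  expect_error(burst_index(c(0, 1)), "at least 3")
})
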