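test_that("l1 norm sums absolute components", {
  expect_equal(l1_norm(c(1, -2, 3)), 6)
  expect_equal(l1_norm(rep(0, 5)), 0)
  expect_error(l1_norm(numeric(0)), "empty")
  set.seed(1)
  for (i in 1:20) {  # triangle inequality
    a <- rnorm(6); b <- rnorm(6)
    expect_lte(l1_norm(a + b), l1_norm(a) + l1_norm(b) + 1e-12)
  }
  m <- rbind(c(1, -2, 3), c(0, 0, 0))
  expect_equal(l1_norm(m), c(6, 0))
})

test_that("optimal bin width follows the 3.49 sigma N^(-1/3) rule", {
  expect_equal(optimal_bin_width(1, 1), 3.49)
  expect_equal(optimal_bin_width(1, 1000), 0.349)
  expect_equal(optimal_bin_width(2, 8), 3.49)
  expect_error(optimal_bin_width(0, 10), "> 0")
  expect_error(optimal_bin_width(1, 0), ">= 1")
})

test_that("cluster count is recovered from well-separated norm mixtures", {
  set.seed(99)
  three <- c(rnorm(300, 0, 0.5), rnorm(300, 10, 0.5), rnorm(300, 20, 0.5))
  expect_equal(estimate_cluster_count(three)$c_hat, 3L)
  one <- rnorm(900, 5, 1)
  expect_equal(estimate_cluster_count(one)$c_hat, 1L)
  expect_equal(estimate_cluster_count(rep(2, 50))$c_hat, 1L)  # degenerate
})

test_that("modes below the valley threshold are not counted", {
  set.seed(7)
  # a dominant mode plus a small shoulder bump weaker than the post-mode
  # valley count: the bump must not be counted as a cluster
  norms <- c(rnorm(1000, 0, 1), rnorm(25, 2.5, 0.2))
  h <- estimate_cluster_count(norms, trim = 0)
  expect_equal(h$c_hat, 1L)
  expect_gt(h$valley_threshold, 0)
})

test_that("cluster-count recovery is stable across seeded norm mixtures", {
  hits <- vapply(1:20, function(seed) {
    set.seed(seed)
    norms <- c(rnorm(250, 0, 0.6), rnorm(350, 8, 0.7), rnorm(500, 16, 0.8))
    estimate_cluster_count(norms)$c_hat == 3L
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("FCM solves trivial and separable problems exactly", {
  x <- rbind(c(0, 0), c(10, 10))
  res <- fcm(x, c = 2, m = 1.5)
  expect_gte(res$memberships[1, res$labels[1]], 1 - 1e-6)
  expect_gte(res$memberships[2, res$labels[2]], 1 - 1e-6)
  expect_equal(res$centroids[order(res$centroids[, 1]), ], x,
               tolerance = 1e-6, ignore_attr = TRUE)

  b <- make_blobs(sd = 0.1)
  res3 <- fcm(b$scores, c = 3, m = 1.1)
  oracle <- nearest_center_labels(b$scores, b$centers)
  expect_equal(perm_agreement(res3$labels, oracle), 1.0)
})

test_that("FCM memberships approach 1/c in the high-fuzziness limit", {
  b <- make_blobs(sd = 0.5)
  # as m -> Inf the centroids coalesce at the grand mean; start them there
  # and the converged memberships must all equal 1/c
  mu <- colMeans(b$scores)
  init <- rbind(mu, mu + 1e-6, mu - 1e-6)
  res <- fcm(b$scores, c = 3, m = 100, max_iter = 500, init = init)
  expect_lt(max(abs(res$memberships - 1 / 3)), 0.01)
})

test_that("FCM hardens to the nearest-centroid solution as m -> 1", {
  b <- make_blobs(sd = 0.2, seed = 8)
  res <- fcm(b$scores, c = 3, m = 1.01)
  oracle <- nearest_center_labels(b$scores, b$centers)
  expect_equal(perm_agreement(res$labels, oracle), 1.0)
  expect_gte(min(apply(res$memberships, 1, max)), 1 - 1e-4)
})

test_that("FCM objective is non-increasing and rows always sum to 1", {
  set.seed(21)
  x <- matrix(rnorm(400), 200, 2)
  res <- fcm(x, c = 4, m = 1.3)
  expect_true(all(diff(res$objective_trace) <= 1e-9 * res$objective_trace[1]))
  expect_lt(max(abs(rowSums(res$memberships) - 1)), 1e-9)
  expect_true(all(res$memberships >= 0 & res$memberships <= 1))
})

test_that("FCM agrees with an independent implementation on separable data", {
  skip_if_not_installed("e1071")
  b <- make_blobs(sd = 0.15, seed = 31)
  ours <- fcm(b$scores, c = 3, m = 1.3)
  ref <- e1071::cmeans(b$scores, centers = ours$centroids, m = 1.3)
  expect_equal(perm_agreement(ours$labels, as.integer(ref$cluster)), 1.0)
  expect_equal(ours$centroids[order(ours$centroids[, 1]), ],
               unname(ref$centers[order(ref$centers[, 1]), ]),
               tolerance = 1e-3)
})

test_that("permuting input rows permutes FCM output identically", {
  b <- make_blobs(sd = 0.2, seed = 12)
  res <- fcm(b$scores, c = 3, m = 1.1)
  set.seed(5)
  perm <- sample(nrow(b$scores))
  res_p <- fcm(b$scores[perm, ], c = 3, m = 1.1)
  expect_equal(perm_agreement(res_p$labels, res$labels[perm]), 1.0)
})

test_that("FCM validates its inputs", {
  expect_error(fcm(matrix(1:4, 2), c = 3), "exceed")
  expect_error(fcm(matrix(1:4, 2), c = 2, m = 1), "> 1")
  expect_error(fcm(matrix(c(1, NA, 3, 4), 2), c = 1), "finite")
})

test_that("Mahalanobis outlier marking flags only genuinely distant spikes", {
  set.seed(77)
  x <- matrix(rnorm(400), 200, 2)
  x <- rbind(x, c(10, 0))  # 10 sd along the first axis
  res <- fcm(x, c = 1, m = 1.1)
  res <- mark_outliers(x, res, quantile = 0.999)
  expect_true(res$outlier_flags[201])
  centroid_idx <- which.min(rowSums(sweep(x, 2, res$centroids[1, ])^2))
  expect_false(res$outlier_flags[centroid_idx])

  # coincident points: regularized covariance, nothing flagged, no error
  xc <- matrix(1, 30, 2)
  resc <- fcm(xc, c = 1, m = 1.1)
  resc <- mark_outliers(xc, resc)
  expect_false(any(resc$outlier_flags))
})
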