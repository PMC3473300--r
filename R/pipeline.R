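#' Unsupervised spike sorting of a recording
#'
#' The full offline pipeline: detect spikes (median-based automatic
#' threshold, quadratic sub-sample peak fit, refractory rejection), extract
#' spline-aligned 24-sample waveforms, row-center and factorize them by SVD,
#' retain the scree-test (optimal coordinates) number of components, estimate
#' the number of clusters from the l1-norm histogram, run fuzzy C-means
#' (m = 1.1 by default) seeded from the histogram peaks, mark Mahalanobis
#' outliers, and score the partition.
#'
#' @param rec A [raw_recording()].
#' @param cfg A [detection_config()].
#' @param clusters Manual override of the cluster count (default `NULL`:
#'   automatic histogram estimate).
#' @param m Fuzziness exponent (default 1.1).
#' @param tol,max_iter FCM convergence controls.
#' @param outlier_quantile Chi-square probability for noise marking
#'   (default 0.999).
#' @param l_ratio_threshold Drift-alarm level (default 5).
#' @param min_spikes Minimum number of detected spikes required (default 50).
#' @return An object of class `spike_sorting`: list with `events` (tibble
#'   `time_s`, `amplitude`, `label`, `is_outlier`, `max_membership`),
#'   `waveforms`, `svd`, `scores`, `histogram`, `fcm`, `quality`, `sigma`,
#'   `threshold`, `config`.
#' @export
sort_spikes <- function(rec, cfg = detection_config(), clusters = NULL,
                        m = 1.1, tol = 1e-5, max_iter = 300L,
                        outlier_quantile = 0.999, l_ratio_threshold = 5,
                        min_spikes = 50L) {
  det <- detect_spikes(rec, cfg)
  n <- nrow(det$waveforms$A)
  if (n < min_spikes) {
    abort(sprintf("too few spikes: %d detected, %d required", n, min_spikes))
  }
  cen <- center_rows(det$waveforms)
  sv <- fit_svd(cen$X)
  scores <- sv$U[, seq_len(sv$k), drop = FALSE]
  # the cluster-count histogram pools the components that carry class
  # structure; beyond the first few, each whitened component adds mostly
  # folded noise that blurs the modes, so the pool is capped at three
  # while FCM itself still runs on all k retained components
  norms <- l1_norm(scores[, seq_len(min(sv$k, 3L)), drop = FALSE])
  hist <- estimate_cluster_count(norms)
  c_use <- clusters %||% hist$c_hat
  init <- histogram_peak_init(scores, norms, hist, c_use)
  res <- fcm(scores, c = c_use, m = m, tol = tol, max_iter = max_iter,
             init = init)
  res <- mark_outliers(scores, res, quantile = outlier_quantile)
  qual <- quality_report(scores, res, l_ratio_threshold = l_ratio_threshold)
  events <- det$events
  events$label <- res$labels
  events$is_outlier <- res$outlier_flags
  events$max_membership <- apply(res$memberships, 1L, max)
  structure(
    list(events = events, waveforms = det$waveforms, svd = sv,
         scores = scores, histogram = hist, fcm = res, quality = qual,
         sigma = det$sigma, threshold = det$threshold, config = cfg,
         m = m, outlier_quantile = outlier_quantile,
         l_ratio_threshold = l_ratio_threshold),
    class = "spike_sorting"
  )
}

# deterministic FCM initialization: one spike per detected histogram peak
# (the spike whose l1-norm is nearest the peak-bin center); falls back to
# farthest-point seeding when the peak count does not match c
histogram_peak_init <- function(scores, norms, hist, c) {
  if (is.null(hist$breaks) || length(hist$peak_bins) != c) {
    return(farthest_point_init(scores, c))
  }
  centers <- hist$breaks[hist$peak_bins] + hist$bin_width / 2
  idx <- vapply(centers, function(ct) which.min(abs(norms - ct)), integer(1))
  if (anyDuplicated(idx)) return(farthest_point_init(scores, c))
  scores[idx, , drop = FALSE]
}

#' @export
print.spike_sorting <- function(x, ...) {
  cat(sprintf(
    "<spike_sorting> %d spikes, k = %d components, c = %d clusters (m = %g)\n",
    nrow(x$events), x$svd$k, x$fcm$c, x$fcm$m
  ))
  cat(sprintf("  sigma = %.4g, threshold = %.4g, %d outlier(s)\n",
              x$sigma, x$threshold, sum(x$fcm$outlier_flags)))
  print(x$quality)
  invisible(x)
}

#' @export
tidy.spike_sorting <- function(x, ...) x$events

#' @export
glance.spike_sorting <- function(x, ...) {
  tibble(
    n_spikes = nrow(x$events), k = x$svd$k, c = x$fcm$c, m = x$fcm$m,
    variance_fraction = x$svd$variance_fraction,
    sigma = x$sigma, threshold = x$threshold,
    n_steps = x$fcm$n_steps, objective = x$fcm$objective,
    pc = x$quality$pc, pe = x$quality$pe,
    max_l_ratio = max(x$quality$clusters$l_ratio)
  )
}

#' @export
augment.fcm_result <- function(x, ...) {
  u <- x$memberships
  colnames(u) <- paste0("u", seq_len(ncol(u)))
  out <- as_tibble(u)
  out$label <- x$labels
  out$is_outlier <- x$outlier_flags
  out
}

#' @export
tidy.fcm_result <- function(x, ...) {
  v <- x$centroids
  colnames(v) <- paste0("dim", seq_len(ncol(v)))
  out <- as_tibble(v)
  out <- dplyr::bind_cols(tibble(cluster = seq_len(x$c)), out)
  out$size <- as.integer(tabulate(x$labels, nbins = x$c))
  out
}

#' @export
glance.fcm_result <- function(x, ...) {
  tibble(c = x$c, m = x$m, n_steps = x$n_steps, objective = x$objective,
         converged = x$converged, n_outliers = sum(x$outlier_flags))
}

#' Export sorted features as a tibble
#'
#' One row per spike: time, k score columns, crisp label and outlier flag.
#'
#' @param x A `spike_sorting` object.
#' @return A tibble.
#' @export
feature_table <- function(x) {
  stopifnot(inherits(x, "spike_sorting"))
  sc <- x$scores
  colnames(sc) <- paste0("pc", seq_len(ncol(sc)))
  dplyr::bind_cols(tibble(time_s = x$events$time_s), as_tibble(sc),
                   tibble(label = x$events$label,
                          is_outlier = x$events$is_outlier))
}
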