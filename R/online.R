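#' Train a sorter prototype on a test-acquisition recording
#'
#' Runs the full unsupervised pipeline ([sort_spikes()]) and packs the
#' projection operators, centroids, per-cluster covariances and frozen
#' detection parameters into a [sorter_model()] for streaming use.
#'
#' @inheritParams sort_spikes
#' @return A list with `model` (a [sorter_model()]) and `sorting` (the
#'   underlying `spike_sorting` result).
#' @export
train_prototype <- function(rec, cfg = detection_config(), clusters = NULL,
                            m = 1.1, min_spikes = 50L,
                            outlier_quantile = 0.999,
                            l_ratio_threshold = 5) {
  srt <- sort_spikes(rec, cfg = cfg, clusters = clusters, m = m,
                     min_spikes = min_spikes,
                     outlier_quantile = outlier_quantile,
                     l_ratio_threshold = l_ratio_threshold)
  k <- srt$svd$k
  covs <- lapply(seq_len(srt$fcm$c), function(j) {
    idx <- srt$fcm$labels == j
    if (sum(idx) > k) {
      regularized_cov(srt$scores[idx, , drop = FALSE])
    } else {
      diag(1, k)
    }
  })
  model <- sorter_model(
    V_k = srt$svd$V[, seq_len(k), drop = FALSE],
    S_k = srt$svd$S[seq_len(k)],
    centroids = srt$fcm$centroids,
    m = m,
    sigma_noise = srt$sigma,
    threshold = srt$threshold,
    covariances = covs,
    fs = rec$fs,
    dead_time_ms = cfg$dead_time_ms,
    polarity = cfg$polarity,
    outlier_quantile = outlier_quantile,
    l_ratio_threshold = l_ratio_threshold
  )
  list(model = model, sorting = srt)
}

classify_scores <- function(scores, model) {
  d2 <- pairwise_sqdist(scores, model$centroids)
  u <- memberships_from_d2(d2, 2 / (model$m - 1))
  labels <- max.col(u, ties.method = "first")
  cut <- stats::qchisq(model$outlier_quantile, df = model$k)
  is_noise <- vapply(seq_len(nrow(scores)), function(i) {
    j <- labels[i]
    dm <- stats::mahalanobis(scores[i, , drop = FALSE],
                             center = model$centroids[j, ],
                             cov = model$covariances[[j]])
    dm > cut
  }, logical(1))
  list(labels = labels, memberships = u, is_noise = is_noise)
}

#' Classify a single aligned waveform against a prototype
#'
#' Row-centers the 24-sample waveform, projects it through the stored
#' truncated basis (`x V_k S_k^{-1}`), computes its FCM memberships against
#' the frozen centroids, and labels it by maximum membership — or `NA`
#' (noise) when the Mahalanobis distance to the winning cluster exceeds the
#' outlier gate.
#'
#' @param waveform Numeric vector, one aligned waveform (24 samples).
#' @param model A [sorter_model()].
#' @return A list with `label` (integer or `NA` for noise), `membership`
#'   (length-c vector) and `mahalanobis_ok`.
#' @export
classify_spike <- function(waveform, model) {
  stopifnot(inherits(model, "sorter_model"))
  if (length(waveform) != nrow(model$V_k)) {
    abort(sprintf("waveform must have %d samples", nrow(model$V_k)))
  }
  x <- matrix(waveform - mean(waveform), nrow = 1L)
  sc <- project_psvd(x, model)
  cl <- classify_scores(sc, model)
  list(label = if (cl$is_noise[1]) NA_integer_ else cl$labels[1],
       membership = as.numeric(cl$memberships[1, ]),
       mahalanobis_ok = !cl$is_noise[1])
}

#' Streaming classification with L-ratio monitoring
#'
#' Detects and extracts spikes with the model's frozen threshold and
#' detection settings, classifies every spike against the prototype, and
#' recomputes a sliding-window L-ratio per cluster (buffer of the most
#' recent `window` classified spikes, refreshed every `every` spikes) using
#' buffer-estimated covariances. Whenever a cluster's L-ratio exceeds the
#' model's alarm threshold an alert record is logged — alerts are data,
#' never errors.
#'
#' @param rec A [raw_recording()] with the model's sampling rate.
#' @param model A [sorter_model()].
#' @param window Monitoring buffer size in spikes (default 1000).
#' @param every Recompute interval in spikes (default 100).
#' @return A list of class `stream_result`: `events` (tibble `time_s`,
#'   `amplitude`, `label`, `is_noise`, `max_membership`), `monitor` (tibble
#'   `spike_index`, `time_s`, `cluster`, `l_ratio`, `alarm`), `alerts`
#'   (alarm rows only).
#' @export
stream_classify <- function(rec, model, window = 1000L, every = 100L) {
  stopifnot(inherits(rec, "raw_recording"), inherits(model, "sorter_model"))
  if (abs(rec$fs - model$fs) > 1e-9) {
    abort(sprintf("sampling rate mismatch: recording %g Hz, model %g Hz",
                  rec$fs, model$fs))
  }
  cfg <- detection_config(dead_time_ms = model$dead_time_ms,
                          polarity = model$polarity, bandpass = FALSE)
  det <- detect_spikes(rec, cfg, threshold = model$threshold)
  n <- nrow(det$waveforms$A)
  empty_monitor <- tibble(spike_index = integer(0), time_s = numeric(0),
                          cluster = integer(0), l_ratio = numeric(0),
                          alarm = logical(0))
  if (n == 0L) {
    return(structure(list(
      events = tibble(time_s = numeric(0), amplitude = numeric(0),
                      label = integer(0), is_noise = logical(0),
                      max_membership = numeric(0)),
      monitor = empty_monitor, alerts = empty_monitor
    ), class = "stream_result"))
  }
  X <- center_rows(det$waveforms)$X
  scores <- project_psvd(X, model)
  cl <- classify_scores(scores, model)
  events <- tibble(
    time_s = det$events$time_s,
    amplitude = det$events$amplitude,
    label = ifelse(cl$is_noise, NA_integer_, cl$labels),
    is_noise = cl$is_noise,
    max_membership = apply(cl$memberships, 1L, max)
  )

  monitor <- list()
  checkpoints <- seq(every, n, by = every)
  for (cp in checkpoints) {
    lo <- max(1L, cp - window + 1L)
    buf <- lo:cp
    if (length(buf) < 10L) next
    # cluster membership in the buffer is what the classifier accepted
    # (gate-passing spikes); everything else in the buffer — including
    # noise-gated spikes — counts as potential contamination. Spikes the
    # gate rejects are exactly the ones that signal a deteriorating
    # classification, so they must not vanish from the monitor.
    sc <- scores[buf, , drop = FALSE]
    lb_eff <- ifelse(cl$is_noise[buf], 0L, cl$labels[buf])
    for (j in sort(unique(lb_eff[lb_eff > 0L]))) {
      if (sum(lb_eff == j) <= model$k) next
      lr <- l_ratio(sc, lb_eff, j, df = model$k)
      monitor[[length(monitor) + 1L]] <- tibble(
        spike_index = cp, time_s = events$time_s[cp],
        cluster = as.integer(j), l_ratio = lr,
        alarm = lr > model$l_ratio_threshold
      )
    }
  }
  monitor <- if (length(monitor)) dplyr::bind_rows(monitor) else empty_monitor
  structure(
    list(events = events, monitor = monitor,
         alerts = monitor[monitor$alarm, , drop = FALSE]),
    class = "stream_result"
  )
}

#' @export
print.stream_result <- function(x, ...) {
  cat(sprintf(
    "<stream_result> %d spikes classified (%d noise), %d monitor checkpoints, %d alert(s)\n",
    nrow(x$events), sum(x$events$is_noise), nrow(x$monitor), nrow(x$alerts)
  ))
  invisible(x)
}

#' @export
tidy.stream_result <- function(x, ...) x$events

#' @export
glance.stream_result <- function(x, ...) {
  tibble(n_spikes = nrow(x$events), n_noise = sum(x$events$is_noise),
         n_alerts = nrow(x$alerts),
         max_l_ratio = if (nrow(x$monitor)) max(x$monitor$l_ratio) else NA_real_)
}
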