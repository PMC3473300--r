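#' Match detected events to ground truth
#'
#' Greedy nearest-in-time one-to-one matching within a tolerance: candidate
#' (detected, truth) pairs are ranked by |time difference| and accepted when
#' both sides are still free. Unmatched truth events are misses; unmatched
#' detections are false positives.
#'
#' @param detected Tibble with a `time_s` column (sorted).
#' @param truth Tibble with a `time_s` column (sorted).
#' @param tol_ms Matching tolerance in ms (default 0.5).
#' @return A list of class `event_matching`: `pairs` (tibble `det_idx`,
#'   `truth_idx`, `dt_s`), `miss_idx`, `fp_idx`, `tol_ms`.
#' @export
match_events <- function(detected, truth, tol_ms = 0.5) {
  if (tol_ms < 0) abort("`tol_ms` must be >= 0")
  td <- detected$time_s
  tt <- truth$time_s
  if (is.unsorted(td) || is.unsorted(tt)) abort("event lists must be sorted")
  tol <- tol_ms / 1000
  cand <- list()
  if (length(td) && length(tt)) {
    # for each detection consider the truth neighbours around it
    pos <- findInterval(td, tt)
    for (i in seq_along(td)) {
      for (j in unique(pmin(pmax(c(pos[i], pos[i] + 1L), 1L), length(tt)))) {
        dt <- td[i] - tt[j]
        if (abs(dt) <= tol) {
          cand[[length(cand) + 1L]] <- c(i, j, dt)
        }
      }
    }
  }
  if (length(cand)) {
    cm <- do.call(rbind, cand)
    cm <- cm[order(abs(cm[, 3])), , drop = FALSE]
    used_d <- logical(length(td))
    used_t <- logical(length(tt))
    keep <- logical(nrow(cm))
    for (r in seq_len(nrow(cm))) {
      i <- cm[r, 1]; j <- cm[r, 2]
      if (!used_d[i] && !used_t[j]) {
        used_d[i] <- TRUE
        used_t[j] <- TRUE
        keep[r] <- TRUE
      }
    }
    cm <- cm[keep, , drop = FALSE]
    pairs <- tibble(det_idx = as.integer(cm[, 1]),
                    truth_idx = as.integer(cm[, 2]), dt_s = cm[, 3])
  } else {
    pairs <- tibble(det_idx = integer(0), truth_idx = integer(0),
                    dt_s = numeric(0))
  }
  structure(
    list(pairs = pairs,
         miss_idx = setdiff(seq_along(tt), pairs$truth_idx),
         fp_idx = setdiff(seq_along(td), pairs$det_idx),
         tol_ms = tol_ms),
    class = "event_matching"
  )
}

#' @export
print.event_matching <- function(x, ...) {
  cat(sprintf(
    "<event_matching> %d matched, %d missed, %d false positive(s) (tol %.2f ms)\n",
    nrow(x$pairs), length(x$miss_idx), length(x$fp_idx), x$tol_ms
  ))
  invisible(x)
}

# best injective assignment of clusters to units, maximizing matched
# agreement; exhaustive over permutations (c and u are both small)
best_assignment <- function(conf) {
  cl <- rownames(conf) %||% as.character(seq_len(nrow(conf)))
  un <- colnames(conf) %||% as.character(seq_len(ncol(conf)))
  nc <- nrow(conf); nu <- ncol(conf)
  if (nc == 0L || nu == 0L) return(integer(0))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- NULL; best_score <- -Inf
  if (nc <= nu) {
    # choose nc units and order them over clusters
    for (sel in utils::combn(nu, nc, simplify = FALSE)) {
      for (p in perms(sel)) {
        sc <- sum(conf[cbind(seq_len(nc), p)])
        if (sc > best_score) { best_score <- sc; best <- p }
      }
    }
    assign <- best
  } else {
    # more clusters than units: each unit gets its best-permuted cluster,
    # remaining clusters map to NA
    best <- NULL
    for (sel in utils::combn(nc, nu, simplify = FALSE)) {
      for (p in perms(sel)) {
        sc <- sum(conf[cbind(p, seq_len(nu))])
        if (sc > best_score) { best_score <- sc; best <- p }
      }
    }
    assign <- rep(NA_integer_, nc)
    assign[best] <- seq_len(nu)
  }
  as.integer(assign)
}

#' Score a sorting against ground truth
#'
#' Maps clusters to true units by the injective assignment maximizing
#' matched agreement, then counts classification errors separately for
#' non-overlapping and overlapping matched spikes (an overlapping spike
#' never contaminates the non-overlapping error count), plus misses and
#' false positives.
#'
#' @param labels Integer cluster labels of the detected events (NA = noise).
#' @param matching An [match_events()] result for the same detections.
#' @param truth Ground-truth tibble (`time_s`, `unit_id`, `is_overlapping`).
#' @return An object of class `eval_report`: list with counts (`n_truth`,
#'   `n_detected`, `misses`, `false_positives`, `matched`,
#'   `matched_nonoverlap`, `errors_nonoverlap`, `overlap_false_matches`,
#'   `classification_errors`), `misclassification_pct` (errors among matched
#'   non-overlapping spikes, %), `assignment` (cluster -> unit) and
#'   `confusion` (matrix clusters x units over matched spikes).
#' @export
score_sorting <- function(labels, matching, truth) {
  pairs <- matching$pairs
  n_det <- length(labels)
  if (nrow(pairs) && max(pairs$det_idx) > n_det) {
    abort("labels/matching size mismatch")
  }
  lab_m <- labels[pairs$det_idx]
  unit_m <- truth$unit_id[pairs$truth_idx]
  ov_m <- truth$is_overlapping[pairs$truth_idx]

  clusters <- sort(unique(lab_m[!is.na(lab_m)]))
  units <- sort(unique(truth$unit_id))
  conf <- matrix(0L, length(clusters), length(units),
                 dimnames = list(clusters, units))
  for (r in seq_along(lab_m)) {
    if (is.na(lab_m[r])) next
    conf[as.character(lab_m[r]), as.character(unit_m[r])] <-
      conf[as.character(lab_m[r]), as.character(unit_m[r])] + 1L
  }
  assign <- best_assignment(conf)
  unit_of_cluster <- stats::setNames(units[assign], clusters)

  pred_unit <- rep(NA_integer_, length(lab_m))
  has_lab <- !is.na(lab_m)
  pred_unit[has_lab] <- unit_of_cluster[as.character(lab_m[has_lab])]

  wrong <- !is.na(pred_unit) & pred_unit != unit_m
  noise_matched <- is.na(pred_unit)  # matched truth spike classified as noise
  err_non <- sum((wrong | noise_matched) & !ov_m)
  err_ov <- sum((wrong | noise_matched) & ov_m)
  fp_assigned <- sum(!is.na(labels[matching$fp_idx]))
  matched_non <- sum(!ov_m)

  structure(
    list(
      n_truth = nrow(truth), n_detected = n_det,
      misses = length(matching$miss_idx),
      false_positives = length(matching$fp_idx),
      matched = nrow(pairs),
      matched_nonoverlap = matched_non,
      errors_nonoverlap = err_non,
      overlap_false_matches = err_ov,
      classification_errors = err_non + fp_assigned,
      misclassification_pct = if (matched_non > 0) 100 * err_non / matched_non else NA_real_,
      assignment = unit_of_cluster,
      confusion = conf
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    paste0("<eval_report> %d truth / %d detected: %d matched ",
           "(%d non-overlapping), %d missed, %d FP\n"),
    x$n_truth, x$n_detected, x$matched, x$matched_nonoverlap, x$misses,
    x$false_positives
  ))
  cat(sprintf(
    "  errors: %d non-overlapping (%.2f%%), %d overlapping, %d total classification errors\n",
    x$errors_nonoverlap, x$misclassification_pct, x$overlap_false_matches,
    x$classification_errors
  ))
  invisible(x)
}

#' @export
glance.eval_report <- function(x, ...) {
  tibble(n_truth = x$n_truth, n_detected = x$n_detected,
         matched = x$matched, misses = x$misses,
         false_positives = x$false_positives,
         matched_nonoverlap = x$matched_nonoverlap,
         errors_nonoverlap = x$errors_nonoverlap,
         overlap_false_matches = x$overlap_false_matches,
         classification_errors = x$classification_errors,
         misclassification_pct = x$misclassification_pct)
}

#' Cluster-size robustness curve
#'
#' Emulates the class-saturation experiment: progressively subsample one
#' class (or all classes together in the balanced "uniform" mode), re-run
#' FCM with the same number of clusters, optimally remap the clusters to the
#' original labels, and report the true-positive rate of each class at each
#' saturation.
#'
#' @param scores n x k feature matrix.
#' @param labels Original crisp labels (taken as reference truth).
#' @param class_id Class to subsample, or `NULL` for the balanced mode in
#'   which all classes are reduced together.
#' @param saturations Fractions in (0, 1] (kept class size is
#'   `max(1, ceiling(n_class * f))`).
#' @param m,tol,max_iter FCM controls.
#' @param seed Seed for the subsampling draws.
#' @return A tibble with columns `saturation`, `class`, `n_kept`, `tpr`.
#' @export
robustness_curve <- function(scores, labels, class_id = NULL,
                             saturations = seq(1, 0.1, by = -0.1),
                             m = 1.1, tol = 1e-5, max_iter = 300L,
                             seed = 1L) {
  if (!is.matrix(scores)) scores <- as.matrix(scores)
  if (any(saturations <= 0 | saturations > 1)) {
    abort("`saturations` must lie in (0, 1]")
  }
  classes <- sort(unique(labels))
  c_use <- length(classes)
  out <- list()
  for (s_i in seq_along(saturations)) {
    f <- saturations[s_i]
    set.seed(seed + s_i)
    keep <- unlist(lapply(classes, function(cl) {
      idx <- which(labels == cl)
      if (is.null(class_id) || cl == class_id) {
        n_keep <- max(1L, ceiling(length(idx) * f))
        sort(sample(idx, n_keep))
      } else {
        idx
      }
    }))
    keep <- sort(keep)
    sub <- scores[keep, , drop = FALSE]
    sub_lab <- labels[keep]
    res <- fcm(sub, c = c_use, m = m, tol = tol, max_iter = max_iter)
    conf <- table(factor(res$labels, levels = seq_len(c_use)),
                  factor(sub_lab, levels = classes))
    conf <- matrix(as.integer(conf), nrow = c_use,
                   dimnames = list(seq_len(c_use), classes))
    assign <- best_assignment(conf)
    mapped <- classes[assign][res$labels]
    for (cl in classes) {
      idx <- sub_lab == cl
      out[[length(out) + 1L]] <- tibble(
        saturation = f, class = cl, n_kept = sum(idx),
        tpr = if (any(idx)) mean(mapped[idx] == cl) else NA_real_
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Inter-spike interval histogram
#'
#' Histogram of successive spike-time differences, with a count of
#' refractory-period violations (intervals shorter than `refractory_ms`).
#'
#' @param times Sorted spike times (s).
#' @param bin_ms Bin width in ms (default 1).
#' @param max_ms Histogram upper limit in ms (default 100).
#' @param refractory_ms Violation threshold in ms (default 1).
#' @return A list of class `isi_histogram`: `counts` tibble (`isi_ms`,
#'   `count`; `isi_ms` is the left bin edge), `n_violations`, `isis_ms`.
#' @export
isi_histogram <- function(times, bin_ms = 1, max_ms = 100,
                          refractory_ms = 1) {
  if (is.unsorted(times)) abort("`times` must be sorted")
  isis <- round(diff(times) * 1000, 6)  # ns resolution; stabilizes bin edges
  breaks <- seq(0, max_ms, by = bin_ms)
  cnt <- tabulate(findInterval(isis[isis < max_ms], breaks),
                  nbins = length(breaks) - 1L)
  structure(
    list(counts = tibble(isi_ms = breaks[-length(breaks)], count = cnt),
         n_violations = sum(isis < refractory_ms),
         isis_ms = isis),
    class = "isi_histogram"
  )
}

#' Peri-stimulus time histogram
#'
#' Pools spike latencies relative to each stimulus within a window and bins
#' them.
#'
#' @param times Sorted spike times (s).
#' @param stimulus_times Sorted stimulus/event times (s); must be non-empty.
#' @param window_ms Length-2 window around each stimulus in ms
#'   (default c(-100, 400)).
#' @param bin_ms Bin width in ms (default 10).
#' @return A tibble with `latency_ms` (left bin edge) and `count`.
#' @export
psth <- function(times, stimulus_times, window_ms = c(-100, 400),
                 bin_ms = 10) {
  if (length(stimulus_times) == 0L) abort("no stimuli")
  lat <- unlist(lapply(stimulus_times, function(s) {
    d <- round((times - s) * 1000, 6)  # ns resolution at the bin edges
    d[d >= window_ms[1] & d < window_ms[2]]
  }))
  breaks <- seq(window_ms[1], window_ms[2], by = bin_ms)
  cnt <- tabulate(findInterval(lat, breaks), nbins = length(breaks) - 1L)
  tibble(latency_ms = breaks[-length(breaks)], count = cnt)
}

#' Burst and pause indices
#'
#' Clinical spike-train regularity indices derived from the ISI
#' distribution (definitions follow the standard movement-disorder
#' convention): the burst index is the mean ISI divided by the modal ISI
#' (mode of the ISI histogram at `bin_ms` resolution), and the pause index
#' is the ratio of counts of ISIs longer vs shorter than `split_ms`.
#'
#' @param times Sorted spike times (s), at least 3 spikes.
#' @param bin_ms Bin width used to locate the modal ISI (default 1 ms).
#' @param split_ms Long/short ISI split for the pause index (default 50 ms).
#' @return A single numeric value.
#' @export
burst_index <- function(times, bin_ms = 1) {
  if (length(times) < 3L) abort("need at least 3 spikes")
  if (is.unsorted(times)) abort("`times` must be sorted")
  isis <- round(diff(times) * 1000, 6)
  edges <- seq(0, max(isis) + bin_ms, by = bin_ms)
  bins <- findInterval(isis, edges)
  cnt <- tabulate(bins, nbins = length(edges) - 1L)
  # modal ISI = mean of the ISIs in the modal bin (exact for regular trains)
  modal <- mean(isis[bins == which.max(cnt)])
  mean(isis) / modal
}

#' @rdname burst_index
#' @export
pause_index <- function(times, split_ms = 50) {
  if (length(times) < 3L) abort("need at least 3 spikes")
  if (is.unsorted(times)) abort("`times` must be sorted")
  isis <- diff(times) * 1000
  n_short <- sum(isis < split_ms)
  if (n_short == 0L) return(Inf)
  sum(isis > split_ms) / n_short
}
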