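#' l1-norm of score vectors
#'
#' The generalized length `sum(|x_i|)` of each spike's feature vector; the
#' distribution of these norms over all spikes drives the automatic
#' cluster-count estimate.
#'
#' @param v Numeric vector, or a matrix whose rows are scored spikes.
#' @return A scalar for a vector input, or one value per row for a matrix.
#' @export
l1_norm <- function(v) {
  if (is.matrix(v)) {
    if (ncol(v) < 1L) abort("empty vectors")
    return(rowSums(abs(v)))
  }
  if (length(v) < 1L) abort("empty vector")
  sum(abs(v))
}

#' Optimal histogram bin width
#'
#' Scott's rule `W = 3.49 sigma N^(-1/3)` for an unbiased density estimate.
#'
#' @param sigma Standard deviation of the distribution (> 0).
#' @param N Number of samples (>= 1).
#' @return Bin width W.
#' @export
optimal_bin_width <- function(sigma, N) {
  if (!is.finite(sigma) || sigma <= 0) abort("`sigma` must be > 0")
  if (N < 1) abort("`N` must be >= 1")
  3.49 * sigma * N^(-1 / 3)
}

#' Estimate the number of clusters from the l1-norm histogram
#'
#' Builds a histogram of per-spike l1-norms with the Scott-rule bin width,
#' smooths it with a centered moving average, and thresholds it at the
#' count of the first valley after the mode to suppress noise peaks. The
#' number of local maxima above that threshold is the cluster-count
#' estimate.
#'
#' @param norms Numeric vector of l1-norm values (n >= 10 for a meaningful
#'   estimate; smaller inputs return c = 1).
#' @param smooth Width of the moving-average smoother in bins (odd; 1
#'   disables smoothing; `TRUE`/`FALSE` are accepted as 3-bin/off). The
#'   default `"auto"` scales the window with the histogram length (roughly
#'   one seventh of the bins, capped at 7), so bin-level count noise is
#'   suppressed on long histograms without smearing short ones.
#' @param trim Fraction of extreme norms dropped from each tail before the
#'   histogram is built (default 0.005). Overlap-spike outliers otherwise
#'   inflate the bin-width sigma and create isolated far-tail bins that
#'   would count as peaks.
#' @return A list of class `l1_histogram`: `c_hat` (estimated cluster count,
#'   >= 1), `norms`, `bin_width`, `breaks`, `counts` (smoothed counts used for
#'   peak finding), `raw_counts`, `mode_bin`, `valley_threshold`, `peak_bins`,
#'   `peak_count`.
#' @export
estimate_cluster_count <- function(norms, smooth = "auto", trim = 0.005) {
  if (isTRUE(smooth)) smooth <- 3L
  if (isFALSE(smooth)) smooth <- 1L
  norms <- as.numeric(norms)
  if (trim > 0 && length(norms) >= 10L) {
    lim <- stats::quantile(norms, c(trim, 1 - trim), names = FALSE)
    norms <- norms[norms >= lim[1] & norms <= lim[2]]
  }
  n <- length(norms)
  sigma <- stats::sd(norms)
  if (n < 2L || !is.finite(sigma) || sigma == 0) {
    return(structure(list(c_hat = 1L, norms = norms, bin_width = NA_real_,
                          breaks = NULL, counts = NULL, raw_counts = NULL,
                          mode_bin = 1L, valley_threshold = 0,
                          peak_bins = integer(0), peak_count = 1L),
                     class = "l1_histogram"))
  }
  W <- optimal_bin_width(sigma, n)
  breaks <- seq(min(norms), max(norms) + W, by = W)
  raw <- tabulate(findInterval(norms, breaks, rightmost.closed = TRUE),
                  nbins = length(breaks) - 1L)
  nb <- length(raw)
  if (identical(smooth, "auto")) {
    smooth <- 2L * min(3L, nb %/% 7L) + 1L
  }
  hw <- (max(1L, as.integer(smooth)) - 1L) %/% 2L
  counts <- if (hw > 0L && nb >= 3L) {
    vapply(seq_len(nb),
           function(i) mean(raw[max(1L, i - hw):min(nb, i + hw)]),
           numeric(1))
  } else {
    as.numeric(raw)
  }

  mode_bin <- which.max(counts)
  # first local minimum after the mode; the trace end counts as a valley
  valley <- NA_integer_
  if (mode_bin < nb) {
    for (j in (mode_bin + 1L):nb) {
      nxt <- if (j < nb) counts[j + 1L] else Inf
      if (counts[j] <= counts[j - 1L] && counts[j] <= nxt) {
        valley <- j
        break
      }
    }
  }
  valley_threshold <- if (is.na(valley)) 0 else counts[valley]

  peak_bins <- find_peaks(counts)
  sig_peaks <- peak_bins[counts[peak_bins] > valley_threshold]
  c_hat <- max(length(sig_peaks), 1L)
  structure(
    list(c_hat = as.integer(c_hat), norms = norms, bin_width = W,
         breaks = breaks, counts = counts, raw_counts = raw,
         mode_bin = mode_bin, valley_threshold = valley_threshold,
         peak_bins = sig_peaks, peak_count = length(sig_peaks)),
    class = "l1_histogram"
  )
}

# local maxima strictly greater than both neighbours; plateaus take the
# leftmost bin; boundary bins qualify against their single neighbour
find_peaks <- function(counts) {
  nb <- length(counts)
  if (nb == 1L) return(1L)
  r <- rle(counts)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(0)
  for (s in seq_along(r$values)) {
    left <- if (s > 1L) r$values[s - 1L] else -Inf
    right <- if (s < length(r$values)) r$values[s + 1L] else -Inf
    if (r$values[s] > left && r$values[s] > right) out <- c(out, starts[s])
  }
  out
}

#' @export
print.l1_histogram <- function(x, ...) {
  cat(sprintf(
    "<l1_histogram> n = %d, bin width %.4g, %d peak(s) above valley threshold %.3g -> c = %d\n",
    length(x$norms), x$bin_width, x$peak_count, x$valley_threshold, x$c_hat
  ))
  invisible(x)
}

#' Fuzzy C-means clustering
#'
#' Alternating-optimization FCM in the k-dimensional score space: memberships
#' `u_ij = 1 / sum_l (d_ij/d_il)^(2/(m-1))` and centroids
#' `v_j = sum_i u_ij^m x_i / sum_i u_ij^m`, iterated until the maximum
#' membership change falls below `tol`. The fuzziness exponent defaults to
#' m = 1.1; as m -> 1 labels harden to classical ISODATA clustering and as
#' m -> Inf all memberships tend to 1/c. A point coinciding with a centroid
#' receives membership 1 there. The objective `J_m` is recorded at every
#' iteration and is non-increasing.
#'
#' @param scores n x k feature matrix (or an object with a `scores` matrix).
#' @param c Number of clusters (>= 1, <= n).
#' @param m Fuzziness exponent (> 1, default 1.1).
#' @param tol Convergence tolerance on the max membership change
#'   (default 1e-5).
#' @param max_iter Iteration cap (default 300).
#' @param init Optional c x k matrix of initial centroids. When omitted, a
#'   deterministic farthest-point scheme seeds the centroids.
#' @return An object of class `fcm_result`: `memberships` (n x c),
#'   `centroids` (c x k), `labels` (crisp argmax), `m`, `c`, `n_steps`,
#'   `objective` (final J_m), `objective_trace`, `converged`,
#'   `outlier_flags` (filled by [mark_outliers()], initially all FALSE).
#' @export
fcm <- function(scores, c, m = 1.1, tol = 1e-5, max_iter = 300L,
                init = NULL) {
  if (!is.matrix(scores)) scores <- as.matrix(scores)
  if (!all(is.finite(scores))) abort("non-finite scores")
  n <- nrow(scores)
  if (c < 1L) abort("`c` must be >= 1")
  if (c > n) abort("`c` cannot exceed the number of points")
  if (m <= 1) abort("`m` must be > 1")

  centroids <- init %||% farthest_point_init(scores, c)
  if (nrow(centroids) != c || ncol(centroids) != ncol(scores)) {
    abort("`init` must be a c x k matrix")
  }

  u_old <- NULL
  trace <- numeric(0)
  n_steps <- 0L
  converged <- FALSE
  expo <- 2 / (m - 1)
  repeat {
    d2 <- pairwise_sqdist(scores, centroids)
    u <- memberships_from_d2(d2, expo)
    trace <- c(trace, sum((u^m) * d2))
    n_steps <- n_steps + 1L
    if (!is.null(u_old) && max(abs(u - u_old)) < tol) {
      converged <- TRUE
      break
    }
    if (n_steps >= max_iter) break
    um <- u^m
    centroids <- crossprod(um, scores) / colSums(um)
    u_old <- u
  }

  labels <- max.col(u, ties.method = "first")
  structure(
    list(memberships = u, centroids = centroids, labels = labels,
         m = m, c = as.integer(c), n_steps = n_steps,
         objective = trace[length(trace)], objective_trace = trace,
         converged = converged,
         outlier_flags = rep(FALSE, n)),
    class = "fcm_result"
  )
}

pairwise_sqdist <- function(x, v) {
  # n x c matrix of squared Euclidean distances
  xx <- rowSums(x^2)
  vv <- rowSums(v^2)
  d2 <- outer(xx, vv, "+") - 2 * tcrossprod(x, v)
  pmax(d2, 0)
}

memberships_from_d2 <- function(d2, expo) {
  n <- nrow(d2); c <- ncol(d2)
  u <- matrix(0, n, c)
  zero <- d2 < .Machine$double.eps
  any_zero <- rowSums(zero) > 0
  if (any(any_zero)) {
    for (i in which(any_zero)) {
      u[i, which(zero[i, ])[1L]] <- 1
    }
  }
  idx <- which(!any_zero)
  if (length(idx)) {
    dd <- d2[idx, , drop = FALSE]
    # normalize by the row minimum before exponentiating so w <= 1 and the
    # large exponents of small m cannot overflow
    dd <- dd / apply(dd, 1L, min)
    w <- dd^(-expo / 2)  # (d_ij/d_imin)^{-2/(m-1)}
    u[idx, ] <- w / rowSums(w)
  }
  u
}

# deterministic farthest-point initialization: start from the point farthest
# from the data mean, then repeatedly add the point farthest from the chosen
# set
farthest_point_init <- function(scores, c) {
  n <- nrow(scores)
  mu <- colMeans(scores)
  d0 <- rowSums(sweep(scores, 2, mu)^2)
  chosen <- which.max(d0)
  while (length(chosen) < c) {
    d2 <- pairwise_sqdist(scores, scores[chosen, , drop = FALSE])
    mind <- apply(d2, 1L, min)
    mind[chosen] <- -Inf
    chosen <- c(chosen, which.max(mind))
  }
  scores[chosen, , drop = FALSE]
}

#' @export
print.fcm_result <- function(x, ...) {
  cat(sprintf(
    "<fcm_result> n = %d, c = %d, m = %g, %d steps (J = %.4g, %s), %d outlier(s)\n",
    nrow(x$memberships), x$c, x$m, x$n_steps, x$objective,
    if (x$converged) "converged" else "max_iter", sum(x$outlier_flags)
  ))
  invisible(x)
}

#' Mark noise spikes by Mahalanobis distance
#'
#' Flags spikes lying far from their assigned cluster centre: a spike is an
#' outlier when its squared Mahalanobis distance to the assigned centroid
#' (under the cluster's own covariance) exceeds the chi-square quantile with
#' k degrees of freedom. Near-singular covariances are ridge-regularized
#' (1e-9 * trace/k added to the diagonal), never an error.
#'
#' @param scores n x k feature matrix.
#' @param result An `fcm_result` for these scores.
#' @param quantile Chi-square probability for the cut (default 0.999).
#' @return The `fcm_result` with `outlier_flags` filled in.
#' @export
mark_outliers <- function(scores, result, quantile = 0.999) {
  if (!is.matrix(scores)) scores <- as.matrix(scores)
  k <- ncol(scores)
  cut <- stats::qchisq(quantile, df = k)
  flags <- rep(FALSE, nrow(scores))
  for (j in seq_len(result$c)) {
    idx <- which(result$labels == j)
    if (length(idx) <= k) next
    S <- regularized_cov(scores[idx, , drop = FALSE])
    d2 <- stats::mahalanobis(scores[idx, , drop = FALSE],
                             center = result$centroids[j, ], cov = S)
    flags[idx] <- d2 > cut
  }
  result$outlier_flags <- flags
  result
}

regularized_cov <- function(x) {
  S <- stats::cov(x)
  k <- ncol(S)
  ridge <- 1e-9 * max(sum(diag(S)) / k, .Machine$double.eps)
  ok <- FALSE
  for (i in 0:8) {
    Sr <- S + diag(ridge * 10^i, k)
    if (is.finite(rcond_sym(Sr)) && rcond_sym(Sr) > 1e-12) {
      S <- Sr
      ok <- TRUE
      break
    }
  }
  if (!ok) S <- S + diag(max(sum(diag(S)) / k, 1), k)
  S
}

rcond_sym <- function(S) {
  ev <- tryCatch(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) NA_real_)
  if (any(is.na(ev)) || max(ev) <= 0) return(NA_real_)
  max(min(ev), 0) / max(ev)
}
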