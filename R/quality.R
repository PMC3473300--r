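check_memberships <- function(u) {
  if (!is.matrix(u)) u <- as.matrix(u)
  if (any(u < -1e-12) || any(u > 1 + 1e-12)) {
    abort("memberships must lie in [0, 1]")
  }
  if (max(abs(rowSums(u) - 1)) > 1e-6) {
    abort("membership rows must sum to 1")
  }
  u
}

#' Partition coefficient
#'
#' Bezdek's partition coefficient `pc = (1/n) sum_ij u_ij^2`. Ranges from
#' 1/c (uniform memberships) to 1 (crisp partition); higher is crisper.
#'
#' @param memberships n x c membership matrix (rows sum to 1), or an
#'   `fcm_result`.
#' @return Scalar pc in \[1/c, 1\].
#' @export
partition_coefficient <- function(memberships) {
  if (inherits(memberships, "fcm_result")) memberships <- memberships$memberships
  u <- check_memberships(memberships)
  sum(u^2) / nrow(u)
}

#' Partition entropy
#'
#' `pe = -(1/n) sum_ij u_ij log(u_ij)` with `0 log 0 = 0`. Zero iff the
#' partition is crisp; larger values mean fuzzier partitions.
#'
#' @inheritParams partition_coefficient
#' @param base Logarithm base (default natural log).
#' @return Scalar pe >= 0.
#' @export
partition_entropy <- function(memberships, base = exp(1)) {
  if (inherits(memberships, "fcm_result")) memberships <- memberships$memberships
  u <- check_memberships(memberships)
  lu <- ifelse(u > 0, log(u, base = base), 0)
  -sum(u * lu) / nrow(u)
}

#' Proportion exponent
#'
#' Windham's proportion exponent: with `mu_i` the maximum membership of spike
#' i and c clusters,
#' `pex = -log2 prod_i [ sum_{j=1}^{floor(1/mu_i)} (-1)^(j+1) C(c,j) (1 - j mu_i)^(c-1) ]`,
#' computed as a sum of per-row logs for numerical stability. Larger values
#' indicate a crisper partition; any `mu_i = 1` makes pex infinite. Requires
#' every `mu_i > 1/c` strictly.
#'
#' @inheritParams partition_coefficient
#' @return Scalar pex (possibly `Inf`).
#' @export
proportion_exponent <- function(memberships) {
  if (inherits(memberships, "fcm_result")) memberships <- memberships$memberships
  u <- check_memberships(memberships)
  c <- ncol(u)
  if (c < 2L) abort("pex requires at least 2 clusters")
  mu <- apply(u, 1L, max)
  if (any(mu <= 1 / c + 1e-15)) {
    abort("pex undefined: some row's maximum membership is <= 1/c")
  }
  terms <- vapply(mu, function(m) {
    jmax <- floor(1 / m)
    j <- seq_len(jmax)
    sum((-1)^(j + 1) * choose(c, j) * (1 - j * m)^(c - 1))
  }, numeric(1))
  if (any(terms <= 0)) return(Inf)
  -sum(log2(terms))
}

#' L-ratio cluster isolation
#'
#' Schmitzer-Torbert/Redish isolation measure: for cluster C,
#' `L(C) = sum_{i not in C} (1 - CDF_chisq(df)(D2_iC))` where `D2_iC` is the
#' squared Mahalanobis distance of spike i to the cluster (its mean and
#' covariance), and `l_ratio = L(C) / n_C`. Low values mean the cluster is
#' well isolated from the rest of the recording.
#'
#' @param scores n x k feature matrix.
#' @param labels Integer crisp labels (length n).
#' @param cluster_id Which cluster to score.
#' @param df Chi-square degrees of freedom (default k, the number of
#'   retained features).
#' @return Scalar l_ratio >= 0.
#' @export
l_ratio <- function(scores, labels, cluster_id, df = NULL) {
  if (!is.matrix(scores)) scores <- as.matrix(scores)
  df <- df %||% ncol(scores)
  inside <- labels == cluster_id
  n_c <- sum(inside)
  if (n_c == 0L) abort("cluster is empty")
  if (!any(!inside)) return(0)
  Xc <- scores[inside, , drop = FALSE]
  mu <- colMeans(Xc)
  S <- if (n_c > 1L) regularized_cov(Xc) else diag(1, ncol(scores))
  d2 <- stats::mahalanobis(scores[!inside, , drop = FALSE], mu, S)
  sum(1 - stats::pchisq(d2, df = df)) / n_c
}

#' Fuzzy partition quality report
#'
#' Computes the membership-based validity indices (pc, pe, pex) and the
#' per-cluster L-ratio with its drift alarm in one tidy report.
#'
#' @param scores n x k feature matrix.
#' @param result An `fcm_result` for these scores.
#' @param l_ratio_threshold Alarm level for the L-ratio (default 5; values in
#'   3-6 are the recommended range).
#' @param df Chi-square degrees of freedom for the L-ratio (default k).
#' @return An object of class `quality_report`: list with scalars `pc`, `pe`,
#'   `pex`, a tibble `clusters` (`cluster`, `n`, `l_ratio`, `alarm`), and
#'   `l_ratio_threshold`.
#' @export
quality_report <- function(scores, result, l_ratio_threshold = 5, df = NULL) {
  if (!is.matrix(scores)) scores <- as.matrix(scores)
  u <- result$memberships
  lr <- vapply(seq_len(result$c),
               function(j) l_ratio(scores, result$labels, j, df = df),
               numeric(1))
  pex <- tryCatch(proportion_exponent(u), error = function(e) NA_real_)
  rep <- structure(
    list(pc = partition_coefficient(u),
         pe = partition_entropy(u),
         pex = pex,
         clusters = tibble(
           cluster = seq_len(result$c),
           n = as.integer(tabulate(result$labels, nbins = result$c)),
           l_ratio = lr,
           alarm = lr > l_ratio_threshold
         ),
         l_ratio_threshold = l_ratio_threshold),
    class = "quality_report"
  )
  rep
}

#' Drift alarm from L-ratio values
#'
#' Raises an alarm for every cluster whose L-ratio exceeds the threshold
#' (default 5; the recommended range is 3-6). Used online to signal that the
#' SVD model and FCM prototype should be recomputed.
#'
#' @param report A `quality_report`, or a numeric vector of L-ratio values.
#' @param threshold Alarm level (default 5).
#' @return Logical vector, one flag per cluster.
#' @export
check_drift <- function(report, threshold = 5) {
  lr <- if (inherits(report, "quality_report")) report$clusters$l_ratio else report
  lr > threshold
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> pc = %.5f, pe = %.5f, pex = %s\n",
              x$pc, x$pe, format(x$pex, digits = 4)))
  df <- as.data.frame(x$clusters)
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  cluster %d: n = %d, L_ratio = %.3f%s\n",
                df$cluster[i], df$n[i], df$l_ratio[i],
                if (df$alarm[i]) "  [ALARM]" else ""))
  }
  invisible(x)
}

#' @export
tidy.quality_report <- function(x, ...) x$clusters

#' @export
glance.quality_report <- function(x, ...) {
  tibble(pc = x$pc, pe = x$pe, pex = x$pex,
         max_l_ratio = max(x$clusters$l_ratio),
         any_alarm = any(x$clusters$alarm))
}
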