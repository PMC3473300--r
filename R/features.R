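#' Center waveforms across the second mode
#'
#' Subtracts each row's mean from the row (`X = A - n 1^T`), removing the
#' per-spike DC offset before SVD. Idempotent: re-centering a centered matrix
#' leaves it unchanged.
#'
#' @param A Numeric matrix (n x 24) or a `waveform_matrix`.
#' @return A list with `X` (centered matrix) and `row_means`.
#' @export
center_rows <- function(A) {
  if (inherits(A, "waveform_matrix")) A <- A$A
  if (!is.matrix(A) || nrow(A) < 1L) abort("`A` must be a non-empty matrix")
  mu <- rowMeans(A)
  list(X = A - mu, row_means = mu)
}

#' Fit the full SVD of a centered waveform matrix
#'
#' Factorizes `X = U S V^T`. The sign of each right singular vector is fixed
#' so that its largest-magnitude component is positive, making scores,
#' centroids and persisted models comparable across runs.
#'
#' @param X Centered waveform matrix (n x p, n >= 2), e.g. from
#'   [center_rows()].
#' @return An `svd_model`: list with `U` (n x p), `S` (length-p singular
#'   values, descending), `V` (p x p), `k` (retained components, chosen by
#'   [select_noc()]), `variance_fraction` (fraction of total variance in the
#'   first `k` components).
#' @export
fit_svd <- function(X) {
  if (!is.matrix(X) || nrow(X) < 2L) abort("`X` must have at least 2 rows")
  if (all(X == 0)) abort("rank-0 input: all-zero matrix")
  dec <- svd(X, nu = ncol(X), nv = ncol(X))
  # sign convention: largest-|.| component of each right vector positive
  for (j in seq_len(ncol(dec$v))) {
    mi <- which.max(abs(dec$v[, j]))
    if (dec$v[mi, j] < 0) {
      dec$v[, j] <- -dec$v[, j]
      dec$u[, j] <- -dec$u[, j]
    }
  }
  k <- select_noc(dec$d)
  lam <- dec$d^2
  structure(
    list(U = dec$u, S = dec$d, V = dec$v, k = k,
         variance_fraction = sum(lam[seq_len(k)]) / sum(lam)),
    class = "svd_model"
  )
}

#' @export
print.svd_model <- function(x, ...) {
  cat(sprintf(
    "<svd_model> %d x %d, k = %d components (%.1f%% of variance)\n",
    nrow(x$U), length(x$S), x$k, 100 * x$variance_fraction
  ))
  invisible(x)
}

#' Scree-test Optimal Coordinates choice of components
#'
#' Numerical version of Cattell's scree test. Operating on the variances
#' `lambda_i = s_i^2`, position `i` is retained while `lambda_i` strictly
#' exceeds both (a) the "optimal coordinate" predicted for it by the line
#' through the next point `(i+1, lambda_{i+1})` and the last point
#' `(p, lambda_p)`, and (b) the mean of the eigenvalues excluding the
#' largest — the Kaiser-style restriction of the standard
#' optimal-coordinates formulation, referenced to the non-dominant spectrum
#' because waveform matrices that are row-centered but not column-centered
#' carry a grand-mean shape component that dwarfs (and would otherwise
#' mask) every discriminative one. Scanning stops at the first failure; at
#' least one component is always retained.
#'
#' @param S Singular values (descending). Squared internally.
#' @param values Either `"singular"` (default: `S` are singular values) or
#'   `"variance"` (`S` are already eigenvalues/variances).
#' @return Integer `k`, `1 <= k <= length(S)`.
#' @export
select_noc <- function(S, values = c("singular", "variance")) {
  values <- match.arg(values)
  if (length(S) < 3L) abort("need at least 3 values")
  lam <- if (values == "singular") S^2 else S
  p <- length(lam)
  ref <- mean(lam[-1])
  tol <- 1e-9 * lam[1]  # guards exact-line spectra against FP round-off
  k <- 0L
  for (i in 1:(p - 2L)) {
    slope <- (lam[p] - lam[i + 1L]) / (p - (i + 1L))
    pred <- lam[i + 1L] - slope  # extrapolated back one position to i
    if (lam[i] > pred + tol && lam[i] > ref) k <- k + 1L else break
  }
  max(k, 1L)
}

#' Project waveforms onto the retained singular basis
#'
#' Partial-SVD projection `U_k = X V_k S_k^{-1}`: new centered waveforms are
#' mapped into the k-dimensional score space of an existing factorization
#' without refactorizing. Projecting the training matrix reproduces the first
#' k columns of U exactly.
#'
#' @param Xnew Centered waveform matrix (n x p) with the same number of
#'   columns as the training data.
#' @param model An `svd_model` from [fit_svd()], or any list providing `V`,
#'   `S` and `k` (a `sorter_model` stores `V_k` and `S_k` directly).
#' @param k Number of components; defaults to `model$k`.
#' @return n x k score matrix.
#' @export
project_psvd <- function(Xnew, model, k = NULL) {
  if (is.vector(Xnew)) Xnew <- matrix(Xnew, nrow = 1L)
  k <- k %||% model$k
  if (!is.null(model$V_k)) {
    Vk <- model$V_k
    sk <- model$S_k
  } else {
    Vk <- model$V[, seq_len(k), drop = FALSE]
    sk <- model$S[seq_len(k)]
  }
  if (ncol(Xnew) != nrow(Vk)) abort("waveform length does not match the model")
  if (any(sk == 0)) abort("retained singular value is zero; cannot invert")
  Xnew %*% Vk %*% diag(1 / sk, nrow = k)
}
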