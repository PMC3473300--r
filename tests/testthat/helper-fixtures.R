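# Shared fixtures built in code.

# three tight, well-separated Gaussian blobs in k dims
make_blobs <- function(n_per = 50, centers = rbind(c(0, 0), c(10, 0), c(0, 10)),
                       sd = 0.1, seed = 42) {
  set.seed(seed)
  k <- ncol(centers)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(j) {
    matrix(rnorm(n_per * k, sd = sd), ncol = k) +
      matrix(centers[j, ], n_per, k, byrow = TRUE)
  }))
  list(scores = x, labels = rep(seq_len(nrow(centers)), each = n_per),
       centers = centers)
}

# a small valid sorter model with orthonormal V_k
make_test_model <- function(k = 4, c = 4, p = 24, seed = 1) {
  set.seed(seed)
  V <- qr.Q(qr(matrix(rnorm(p * k), p, k)))
  sorter_model(
    V_k = V, S_k = seq(k, 1), centroids = matrix(rnorm(c * k), c, k),
    m = 1.1, sigma_noise = 0.1, threshold = 0.4,
    covariances = replicate(c, diag(0.01, k), simplify = FALSE),
    fs = 10000
  )
}

# nearest true blob center assignment (independent clustering oracle)
nearest_center_labels <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
  max.col(-d2)
}

# agreement between two labelings, maximized over label permutations
perm_agreement <- function(a, b) {
  la <- sort(unique(a))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- 0
  for (p in perms(la)) {
    m <- stats::setNames(p, la)
    best <- max(best, mean(m[as.character(a)] == b))
  }
  best
}
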