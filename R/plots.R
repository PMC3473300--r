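#' Plot the l1-norm histogram with its threshold and peaks
#'
#' @param object An `l1_histogram` from [estimate_cluster_count()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.l1_histogram <- function(object, ...) {
  if (is.null(object$breaks)) {
    abort("degenerate histogram (constant norms); nothing to plot")
  }
  df <- tibble(
    norm = object$breaks[-length(object$breaks)] + object$bin_width / 2,
    count = object$counts
  )
  pk <- df[object$peak_bins, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$norm, y = .data$count)) +
    ggplot2::geom_col(width = object$bin_width, fill = "grey70") +
    ggplot2::geom_hline(yintercept = object$valley_threshold,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::geom_point(data = pk, colour = "firebrick", size = 2) +
    ggplot2::labs(x = "l1-norm of feature scores", y = "count",
                  title = sprintf("l1-norm histogram: %d peak(s) above the valley threshold",
                                  object$c_hat)) +
    ggplot2::theme_minimal()
}

#' Plot sorted spikes in the first two feature dimensions
#'
#' @param object A `spike_sorting` from [sort_spikes()].
#' @param dims Which two score dimensions to show (default 1:2).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spike_sorting <- function(object, dims = c(1L, 2L), ...) {
  sc <- object$scores
  if (ncol(sc) < 2L) {
    sc <- cbind(sc, 0)
    dims <- c(1L, 2L)
  }
  df <- tibble(
    x = sc[, dims[1]], y = sc[, dims[2]],
    cluster = factor(object$fcm$labels),
    outlier = object$fcm$outlier_flags
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$cluster)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_point(data = df[df$outlier, , drop = FALSE],
                        colour = "red", size = 1.2) +
    ggplot2::labs(x = sprintf("PC%d", dims[1]), y = sprintf("PC%d", dims[2]),
                  colour = "cluster",
                  title = "Spike scores (outliers in red)") +
    ggplot2::theme_minimal()
}

#' Plot aligned waveforms coloured by cluster
#'
#' @param x A `spike_sorting` from [sort_spikes()].
#' @param max_per_cluster Waveforms drawn per cluster (default 50).
#' @return A ggplot.
#' @export
plot_waveforms <- function(x, max_per_cluster = 50L) {
  stopifnot(inherits(x, "spike_sorting"))
  A <- x$waveforms$A
  lab <- x$fcm$labels
  pick <- unlist(lapply(sort(unique(lab)), function(cl) {
    idx <- which(lab == cl)
    utils::head(idx, max_per_cluster)
  }))
  t_ms <- (seq_len(ncol(A)) - 1) * x$waveforms$dt * 1000
  df <- purrr::map_dfr(pick, function(i) {
    tibble(spike = i, t_ms = t_ms, amplitude = A[i, ],
           cluster = factor(lab[i]))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_ms, y = .data$amplitude,
                                   group = .data$spike,
                                   colour = .data$cluster)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::labs(x = "time (ms)", y = "amplitude", colour = "cluster",
                  title = "Aligned spike waveforms") +
    ggplot2::theme_minimal()
}

#' Plot the streaming L-ratio monitor
#'
#' @param x A `stream_result` from [stream_classify()].
#' @param threshold Alarm threshold to draw (default 5).
#' @return A ggplot.
#' @export
plot_monitor <- function(x, threshold = 5) {
  stopifnot(inherits(x, "stream_result"))
  ggplot2::ggplot(x$monitor,
                  ggplot2::aes(x = .data$time_s, y = .data$l_ratio,
                               colour = factor(.data$cluster))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "time (s)", y = "L-ratio", colour = "cluster",
                  title = "Sliding-window cluster isolation") +
    ggplot2::theme_minimal()
}
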