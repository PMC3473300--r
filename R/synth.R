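#' Simulation configuration
#'
#' Parameters of the synthetic benchmark: a few spike templates, each
#' peak-normalized to 1, fire as independent Poisson trains (with a
#' refractory floor on same-unit intervals) on top of background noise built
#' from superimposed randomly scaled spike shapes, rescaled to a target
#' standard deviation relative to the unit spike amplitude.
#'
#' @param fs Sampling rate in Hz (default 10000).
#' @param duration Recording length in seconds.
#' @param noise_level Background-noise standard deviation relative to the
#'   unit peak amplitude of 1 (benchmark grid: 0.05, 0.1, 0.15, 0.2;
#'   default 0.1). Zero disables noise (useful for exact-recovery tests).
#' @param firing_rate Mean firing rate of each unit in Hz: a scalar
#'   (recycled) or one value per unit. The default `c(8, 18, 34)` (mean
#'   20 Hz) gives the units distinct mean rates, the realistic regime of
#'   multi-unit recordings — and a requirement of the l1-norm histogram
#'   stage, which separates classes by their whitened-center norms and is
#'   blind to exactly equal-sized classes.
#' @param n_units Number of simulated neurons (default 3; 2-6 supported).
#' @param min_isi Minimum same-unit inter-spike interval in seconds
#'   (default 2.5 ms).
#' @param overlap_fraction Optional target fraction of spikes lying within
#'   0.7 ms of a spike from another unit. `NULL` (default) leaves the overlap
#'   rate at whatever the independent Poisson trains produce.
#' @param amplitude_jitter Relative s.d. of per-spike amplitude jitter
#'   (default 0: all unit spikes have peak exactly 1).
#' @param amplitude_trend Relative linear amplitude change over the recording
#'   (default 0; e.g. -0.5 decays unit amplitudes to half by the end). Used
#'   to emulate electrode drift for online-monitoring tests.
#' @param background_rate Rate of background spikes per second used to build
#'   the noise (default 5000).
#' @param background_amp Range of uniform random scaling of background spikes
#'   (default 0.2-1).
#' @param difficulty Template similarity regime, `"easy"` (markedly different
#'   shapes) or `"hard"` (similar shapes).
#' @param seed Integer seed fixing the full output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(fs = 10000, duration = 60, noise_level = 0.1,
                       firing_rate = c(8, 18, 34), n_units = 3L,
                       min_isi = 0.0025,
                       overlap_fraction = NULL, amplitude_jitter = 0,
                       amplitude_trend = 0, background_rate = 5000,
                       background_amp = c(0.2, 1),
                       difficulty = c("easy", "hard"), seed = 1L) {
  difficulty <- match.arg(difficulty)
  if (noise_level < 0) abort("`noise_level` must be >= 0")
  if (fs <= 0 || duration < 0) abort("invalid fs/duration")
  if (n_units < 2L || n_units > 6L) abort("`n_units` must be in 2..6")
  if (length(firing_rate) == 1L) firing_rate <- rep(firing_rate, n_units)
  if (length(firing_rate) != n_units) {
    firing_rate <- rep_len(firing_rate, n_units)
  }
  if (any(firing_rate <= 0)) abort("`firing_rate` must be > 0")
  structure(
    list(fs = fs, duration = duration, noise_level = noise_level,
         firing_rate = firing_rate, n_units = as.integer(n_units),
         min_isi = min_isi, overlap_fraction = overlap_fraction,
         amplitude_jitter = amplitude_jitter,
         amplitude_trend = amplitude_trend,
         background_rate = background_rate,
         background_amp = background_amp,
         difficulty = difficulty, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# one gamma-shaped lobe peaking at t = tau with value 1
gamma_lobe <- function(t, tau, p) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- (t[pos] / tau)^p * exp(p * (1 - t[pos] / tau))
  out
}

# two-lobe action-potential stand-in: sharp depolarization minus a slower
# after-wave; times in ms
template_shape <- function(t_ms, tau1, p1, r, tau2, p2) {
  gamma_lobe(t_ms, tau1, p1) - r * gamma_lobe(t_ms, tau2, p2)
}

template_params <- list(
  easy = list(
    list(tau1 = 0.15, p1 = 8, r = 0.45, tau2 = 0.45, p2 = 4),
    list(tau1 = 0.35, p1 = 3, r = 0.90, tau2 = 0.80, p2 = 6),
    list(tau1 = 0.60, p1 = 2, r = 0.20, tau2 = 1.10, p2 = 10),
    list(tau1 = 0.25, p1 = 5, r = 0.70, tau2 = 0.60, p2 = 3),
    list(tau1 = 0.47, p1 = 1.9, r = 0.90, tau2 = 1.02, p2 = 7),
    list(tau1 = 0.20, p1 = 14, r = 0.15, tau2 = 0.50, p2 = 8)
  ),
  hard = list(
    list(tau1 = 0.30, p1 = 4, r = 0.50, tau2 = 0.70, p2 = 5),
    list(tau1 = 0.32, p1 = 4, r = 0.54, tau2 = 0.73, p2 = 5),
    list(tau1 = 0.34, p1 = 4, r = 0.58, tau2 = 0.76, p2 = 5),
    list(tau1 = 0.36, p1 = 4, r = 0.62, tau2 = 0.79, p2 = 5),
    list(tau1 = 0.38, p1 = 4, r = 0.66, tau2 = 0.82, p2 = 5),
    list(tau1 = 0.40, p1 = 4, r = 0.70, tau2 = 0.85, p2 = 5)
  )
)

#' Normalized RMS difference between two waveforms
#'
#' `sqrt(mean((a-b)^2) / max(mean(a^2), mean(b^2)))` — the pairwise shape
#' dissimilarity used to grade template sets (easy sets > 0.5, hard < 0.3,
#' duplicates < 0.05 rejected).
#'
#' @param a,b Numeric waveforms of equal length.
#' @return Scalar >= 0.
#' @export
nrms_diff <- function(a, b) {
  sqrt(mean((a - b)^2) / max(mean(a^2), mean(b^2)))
}

#' Build a set of spike templates
#'
#' Samples `n_units` two-lobe parametric spike shapes (about 1.5 ms each) at
#' the configured rate and peak-normalizes each to 1. The `"easy"` parameter
#' sets have markedly different widths and after-waves; `"hard"` sets are
#' deliberately similar. Template sets whose members are near-duplicates
#' (normalized RMS difference < 0.05) are rejected.
#'
#' @param config A [sim_config()].
#' @param difficulty Overrides `config$difficulty` if given.
#' @param params Optional list of custom per-unit shape parameter lists
#'   (`tau1`, `p1`, `r`, `tau2`, `p2`, times in ms), overriding the built-in
#'   difficulty sets.
#' @return A list of class `template_set`: `W` (n_samples x n_units matrix,
#'   each column peak-normalized to 1), `fs`, `peak_idx` (1-based sample of
#'   each template's peak), `duration_ms`, `difficulty`.
#' @export
make_templates <- function(config, difficulty = NULL, params = NULL) {
  difficulty <- difficulty %||% config$difficulty
  fs <- config$fs
  duration_ms <- 1.5
  nt <- round(duration_ms * 1e-3 * fs)
  if (nt < 8L) abort(sprintf("fs = %g Hz is too low to represent a %.1f ms template", fs, duration_ms))
  t_ms <- (seq_len(nt) - 1) / fs * 1000
  params <- params %||% template_params[[difficulty]][seq_len(config$n_units)]
  W <- vapply(params, function(p) {
    w <- template_shape(t_ms, p$tau1, p$p1, p$r, p$tau2, p$p2)
    w / max(abs(w))
  }, numeric(nt))
  pairs <- utils::combn(ncol(W), 2)
  d <- apply(pairs, 2, function(ij) nrms_diff(W[, ij[1]], W[, ij[2]]))
  if (any(d < 0.05)) abort("duplicate templates: pairwise difference < 0.05")
  structure(
    list(W = W, fs = fs, peak_idx = apply(W, 2, which.max),
         duration_ms = duration_ms, difficulty = difficulty,
         pairwise_nrms = d),
    class = "template_set"
  )
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf(
    "<template_set> %d '%s' templates, %d samples (%.1f ms) @ %g Hz; pairwise nrms %.2f-%.2f\n",
    ncol(x$W), x$difficulty, nrow(x$W), x$duration_ms, x$fs,
    min(x$pairwise_nrms), max(x$pairwise_nrms)
  ))
  invisible(x)
}

#' Background noise from superimposed spikes
#'
#' Emulates colored extracellular background: many randomly chosen templates
#' are added at uniform random times with uniform random amplitudes, then the
#' sum is centered and rescaled so its empirical standard deviation equals
#' the configured noise level exactly.
#'
#' @param templates A [make_templates()] set.
#' @param config A [sim_config()].
#' @param n_samples Length of the returned trace (default
#'   `round(duration * fs)`).
#' @param seed Seed for this call (default `config$seed`); pass `NULL` to
#'   draw from the current RNG stream.
#' @return Numeric vector of length `n_samples` with sd equal to
#'   `config$noise_level`.
#' @export
generate_background_noise <- function(templates, config, n_samples = NULL,
                                      seed = config$seed) {
  n <- n_samples %||% round(config$duration * config$fs)
  if (n < 1L) abort("zero-duration noise requested")
  if (!is.null(seed)) set.seed(seed)
  K <- max(round(config$background_rate * n / config$fs), 1L)
  nt <- nrow(templates$W)
  nu <- ncol(templates$W)
  which_tpl <- sample.int(nu, K, replace = TRUE)
  pos <- sample.int(n, K, replace = TRUE)
  amp <- runif(K, config$background_amp[1], config$background_amp[2])
  noise <- numeric(n + nt)
  for (j in seq_len(nu)) {
    sel <- which_tpl == j
    if (!any(sel)) next
    imp <- numeric(n)
    agg <- rowsum(amp[sel], pos[sel])
    imp[as.integer(rownames(agg))] <- agg[, 1]
    # FFT convolution on a 2-3-5-smooth length: the exact n + nt - 1 can be
    # twice a prime, where the mixed-radix FFT degenerates badly
    nfft <- stats::nextn(n + nt - 1L, c(2L, 3L, 5L))
    fi <- stats::fft(c(imp, numeric(nfft - n)))
    ft <- stats::fft(c(templates$W[, j], numeric(nfft - nt)))
    conv <- Re(stats::fft(fi * ft, inverse = TRUE)) / nfft
    m <- min(length(noise), nfft)
    noise[seq_len(m)] <- noise[seq_len(m)] + conv[seq_len(m)]
  }
  noise <- noise[seq_len(n)]
  noise <- noise - mean(noise)
  s <- stats::sd(noise)
  if (s > 0 && config$noise_level > 0) {
    noise <- noise * (config$noise_level / s)
  } else {
    noise <- numeric(n)
  }
  noise
}

#' Generate a synthetic recording with ground truth
#'
#' Superimposes Poisson spike trains of the template units (peak amplitude 1,
#' optional jitter and linear drift) on the background noise. Ground-truth
#' events carry the unit id and an `is_overlapping` flag set when the nearest
#' spike of another unit is less than 0.7 ms away.
#'
#' @param config A [sim_config()].
#' @param templates Optional [make_templates()] set (built from `config` if
#'   omitted).
#' @return A list with `recording` ([raw_recording()]), `truth` (tibble
#'   `time_s`, `unit_id`, `is_overlapping`, `amplitude`, sorted by time) and
#'   `templates`.
#' @export
generate_recording <- function(config, templates = NULL) {
  set.seed(config$seed)
  fs <- config$fs
  n <- round(config$duration * fs)
  if (n < 1L) abort("zero-duration recording requested")
  templates <- templates %||% make_templates(config)
  nt <- nrow(templates$W)
  rates <- config$firing_rate
  if (any(rates * config$min_isi >= 1)) {
    abort("firing rate incompatible with the minimum ISI")
  }

  ev_time <- numeric(0); ev_unit <- integer(0)
  for (u in seq_len(config$n_units)) {
    rate <- rates[u]
    rate_adj <- rate / (1 - rate * config$min_isi)
    ng <- max(20L, ceiling(2 * rate * config$duration))
    gaps <- config$min_isi + rexp(ng, rate_adj)
    while (sum(gaps) < config$duration) {
      gaps <- c(gaps, config$min_isi + rexp(ng, rate_adj))
    }
    tt <- cumsum(gaps)
    tt <- tt[tt < config$duration]
    ev_time <- c(ev_time, tt)
    ev_unit <- c(ev_unit, rep(u, length(tt)))
  }

  # optional forced overlaps: inject paired spikes of another unit < 0.7 ms away
  if (!is.null(config$overlap_fraction)) {
    target <- config$overlap_fraction
    tries <- 0L
    while (overlap_fraction_of(ev_time) < target && tries < 20000L) {
      i <- sample.int(length(ev_time), 1L)
      b <- sample(setdiff(seq_len(config$n_units), ev_unit[i]), 1L)
      tc <- ev_time[i] + sample(c(-1, 1), 1L) * runif(1, 0.0001, 0.00065)
      same <- ev_time[ev_unit == b]
      if (tc > 0 && tc < config$duration &&
          (length(same) == 0L || min(abs(same - tc)) >= config$min_isi)) {
        ev_time <- c(ev_time, tc)
        ev_unit <- c(ev_unit, b)
      }
      tries <- tries + 1L
    }
  }

  # place spikes on the sample grid; truth time = placed peak-sample time
  sig <- numeric(n)
  keep <- logical(length(ev_time))
  amp_out <- numeric(length(ev_time))
  for (i in seq_along(ev_time)) {
    u <- ev_unit[i]
    pk <- templates$peak_idx[u]
    s <- round(ev_time[i] * fs) + 1L
    lo <- s - pk + 1L
    hi <- lo + nt - 1L
    if (lo < 1L || hi > n) next
    amp <- 1
    if (config$amplitude_jitter > 0) amp <- amp * (1 + config$amplitude_jitter * rnorm(1))
    if (config$amplitude_trend != 0) amp <- amp * (1 + config$amplitude_trend * ev_time[i] / config$duration)
    sig[lo:hi] <- sig[lo:hi] + amp * templates$W[, u]
    keep[i] <- TRUE
    ev_time[i] <- (s - 1L) / fs
    amp_out[i] <- amp
  }
  ev_time <- ev_time[keep]; ev_unit <- ev_unit[keep]; amp_out <- amp_out[keep]
  ord <- order(ev_time)
  ev_time <- ev_time[ord]; ev_unit <- ev_unit[ord]; amp_out <- amp_out[ord]

  noise <- if (config$noise_level > 0) {
    generate_background_noise(templates, config, n_samples = n, seed = NULL)
  } else {
    numeric(n)
  }

  truth <- tibble(
    time_s = ev_time,
    unit_id = as.integer(ev_unit),
    is_overlapping = overlap_flags(ev_time),
    amplitude = amp_out
  )
  list(
    recording = raw_recording(sig + noise, fs = fs),
    truth = truth,
    templates = templates
  )
}

overlap_flags <- function(times, window = 0.0007) {
  nta <- length(times)
  if (nta < 2L) return(rep(FALSE, nta))
  prev_gap <- c(Inf, diff(times))
  next_gap <- c(diff(times), Inf)
  prev_gap < window | next_gap < window
}

overlap_fraction_of <- function(times) {
  if (length(times) < 2L) return(0)
  mean(overlap_flags(sort(times)))
}
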