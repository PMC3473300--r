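#' Raw extracellular recording
#'
#' A single-channel sampled voltage trace with its sampling rate. This is the
#' container every other stage of the pipeline consumes: detection, waveform
#' extraction and streaming classification all operate on a `raw_recording`.
#'
#' @param samples Numeric vector of amplitudes (arbitrary units). All values
#'   must be finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds (default 0).
#' @param units Amplitude unit label, kept for provenance only.
#'
#' @return An object of class `raw_recording`: a list with elements
#'   `samples`, `fs`, `t0` and `units`.
#' @export
#' @examples
#' rec <- raw_recording(sin(seq(0, 1, length.out = 100)), fs = 1000)
#' rec
raw_recording <- function(samples, fs, t0 = 0, units = "uV") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    abort("`samples` must contain at least one value.")
  }
  if (!all(is.finite(samples))) {
    abort("`samples` must be finite.")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).")
  }
  structure(
    list(samples = samples, fs = as.numeric(fs), t0 = as.numeric(t0),
         units = as.character(units)),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf(
    "<raw_recording> %d samples @ %g Hz (%.3f s), t0 = %g s, units = %s\n",
    length(x$samples), x$fs, length(x$samples) / x$fs, x$t0, x$units
  ))
  invisible(x)
}

#' @export
length.raw_recording <- function(x) length(x$samples)

#' Sample times of a recording
#'
#' @param rec A [raw_recording()].
#' @return Numeric vector of times (s), one per sample.
#' @export
recording_times <- function(rec) {
  stopifnot(inherits(rec, "raw_recording"))
  rec$t0 + (seq_along(rec$samples) - 1) / rec$fs
}

#' Read / write a recording (float32 binary + sidecar)
#'
#' Recordings are stored as raw little-endian float32 samples next to a YAML
#' sidecar (`<path>.yml`) holding `fs`, `units` and `n_samples`. The format is
#' language-neutral and round-trips bit-exactly at float32 precision.
#'
#' @param path Path of the binary sample file. The sidecar is `<path>.yml`.
#' @param rec A [raw_recording()] (for `write_recording`).
#' @return `read_recording` returns a [raw_recording()]; `write_recording`
#'   returns `path` invisibly.
#' @export
read_recording <- function(path) {
  sidecar <- paste0(path, ".yml")
  if (!file.exists(path)) abort(sprintf("sample file not found: %s", path))
  if (!file.exists(sidecar)) abort(sprintf("missing sidecar: %s", sidecar))
  meta <- yaml::read_yaml(sidecar)
  if (is.null(meta$fs) || meta$fs <= 0) abort("sidecar `fs` must be > 0")
  n <- as.integer(meta$n_samples)
  x <- readBin(path, what = "numeric", n = n, size = 4L, endian = "little")
  if (length(x) != n) abort("sample file shorter than sidecar `n_samples`")
  if (!all(is.finite(x))) abort("non-finite samples in file")
  raw_recording(x, fs = meta$fs, t0 = meta$t0 %||% 0,
                units = meta$units %||% "uV")
}

#' @rdname read_recording
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  writeBin(rec$samples, path, size = 4L, endian = "little")
  yaml::write_yaml(
    list(fs = rec$fs, units = rec$units, n_samples = length(rec$samples),
         t0 = rec$t0),
    paste0(path, ".yml"), precision = 17L
  )
  invisible(path)
}

#' Read / write event lists (CSV)
#'
#' Detected spikes are stored as `time_s,amplitude`; ground-truth events as
#' `time_s,unit_id,is_overlapping`. Lists must be sorted by time; writers
#' refuse unsorted input so downstream consumers can rely on order.
#'
#' @param events A tibble of events, either detections (`time_s`, `amplitude`)
#'   or ground truth (`time_s`, `unit_id`, `is_overlapping`).
#' @param path CSV file path.
#' @return `read_events` returns a tibble; `write_events` returns `path`
#'   invisibly.
#' @export
write_events <- function(events, path) {
  events <- as_tibble(events)
  if (nrow(events) > 0 && is.unsorted(events$time_s, strictly = FALSE)) {
    abort("`events` must be sorted by `time_s`.")
  }
  keep <- intersect(c("time_s", "unit_id", "is_overlapping", "amplitude",
                      "label"), names(events))
  utils::write.csv(as.data.frame(events[keep]), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path)
  out <- as_tibble(df)
  if ("is_overlapping" %in% names(out)) {
    out$is_overlapping <- as.logical(out$is_overlapping)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
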