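#' EEG recording container
#'
#' A lightweight container for a single-channel sampled EEG trace. Values are
#' physical units (microvolts for clinical EEG), with the sampling rate and a
#' channel label attached.
#'
#' @param samples Numeric vector of sample values (µV). Must be non-empty and
#'   finite; non-finite samples are rejected rather than imputed.
#' @param fs Sampling rate in Hz (positive scalar; 200 for the Cz-A1 sleep
#'   recordings this package targets).
#' @param channel Channel label, e.g. `"Cz-A1"`.
#' @param start_offset Time of the first sample in seconds (default 0).
#'
#' @return An object of class `"eeg_recording"`: a list with elements
#'   `samples`, `fs`, `channel`, `start_offset`.
#' @export
#' @examples
#' rec <- eeg_recording(sin(2 * pi * 10 * (0:199) / 200), fs = 200)
#' rec
eeg_recording <- function(samples, fs, channel = "EEG", start_offset = 0) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L)
    stop("recording must contain at least one sample")
  if (!all(is.finite(samples)))
    stop("recording contains non-finite samples; clean the input first")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a positive finite scalar (Hz)")
  structure(
    list(samples = samples, fs = fs, channel = as.character(channel)[1L],
         start_offset = as.numeric(start_offset)[1L]),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> channel=%s fs=%g Hz n=%d (%.1f s)\n",
              x$channel, x$fs, length(x$samples), length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.eeg_recording <- function(x) length(x$samples)

#' Expert annotation set
#'
#' Scored event intervals (onset, duration) in seconds, as distributed with
#' sleep-EEG databases: one event per line, scored independently by experts.
#'
#' @param onset Numeric vector of event onsets (seconds, >= 0).
#' @param duration Numeric vector of event durations (seconds, > 0).
#' @param scorer Scorer label (default `"expert1"`).
#'
#' @return An object of class `"annotation_set"`: a data frame with columns
#'   `onset` and `duration`, sorted by onset, with a `scorer` attribute.
#' @export
annotation_set <- function(onset = numeric(), duration = numeric(),
                           scorer = "expert1") {
  onset <- as.numeric(onset); duration <- as.numeric(duration)
  if (length(onset) != length(duration))
    stop("'onset' and 'duration' must have the same length")
  if (any(!is.finite(onset)) || any(!is.finite(duration)))
    stop("annotations must be finite")
  if (any(onset < 0)) stop("event onsets must be >= 0 seconds")
  if (any(duration <= 0)) stop("event durations must be > 0 seconds")
  ord <- order(onset, duration)
  out <- data.frame(onset = onset[ord], duration = duration[ord])
  attr(out, "scorer") <- as.character(scorer)[1L]
  class(out) <- c("annotation_set", "data.frame")
  out
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d events, scorer=%s\n",
              nrow(x), attr(x, "scorer")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}
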