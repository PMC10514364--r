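#' Read a plain-text annotation file
#'
#' Parses expert k-complex scorings in the plain-text dialect used by sleep
#' databases: one event per line as "onset duration" in seconds, whitespace
#' or comma delimited. Header or comment lines (starting with `#`) are
#' tolerated; malformed lines are skipped with a warning naming the line.
#'
#' @param path Path to the annotation file.
#' @param scorer Scorer label recorded on the result (default `"expert1"`).
#' @return An [annotation_set] sorted by onset.
#' @export
read_annotations <- function(path, scorer = "expert1") {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  onsets <- durations <- numeric(0)
  bad <- integer(0)
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    if (!nzchar(trimws(ln))) next
    tok <- strsplit(trimws(ln), "[,[:space:]]+")[[1L]]
    vals <- suppressWarnings(as.numeric(tok))
    if (length(vals) < 2L || any(is.na(vals[1:2])) ||
        vals[1L] < 0 || vals[2L] <= 0) {
      bad <- c(bad, i)
      next
    }
    onsets <- c(onsets, vals[1L]); durations <- c(durations, vals[2L])
  }
  if (length(bad))
    warning("skipped ", length(bad), " malformed annotation line(s): ",
            paste(bad, collapse = ", "))
  if (!length(onsets)) stop("no parsable events in ", path)
  annotation_set(onsets, durations, scorer = scorer)
}

#' Band-pass filter specification
#'
#' @param low_hz,high_hz Band edges in Hz; `0 < low_hz < high_hz < fs/2`.
#' @param order Overall filter order of the Butterworth band-pass (even,
#'   default 4: the clinical preprocessing standard for sleep EEG).
#' @return A `"filter_spec"` object.
#' @export
filter_spec <- function(low_hz = 0.5, high_hz = 30, order = 4) {
  if (!(low_hz > 0 && high_hz > low_hz)) stop("need 0 < low_hz < high_hz")
  if (order < 2 || order %% 2 != 0)
    stop("'order' must be a positive even integer (band-pass pole pairs)")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order)),
            class = "filter_spec")
}

#' Band-pass filter a recording
#'
#' Applies a Butterworth band-pass of the stated overall order (a cascade of
#' `order/2` pole pairs per skirt, designed with [signal::butter]). The
#' default is the causal forward-only realization; `zero_phase = TRUE`
#' switches to forward-backward filtering ([signal::filtfilt]), which removes
#' phase distortion but doubles the effective order.
#'
#' @param recording An [eeg_recording].
#' @param spec A [filter_spec]; default 0.5–30 Hz, 4th order.
#' @param zero_phase Logical; use forward-backward filtering (default FALSE).
#' @return The filtered [eeg_recording] (same length and fs).
#' @export
bandpass <- function(recording, spec = filter_spec(), zero_phase = FALSE) {
  stopifnot(inherits(recording, "eeg_recording"), inherits(spec, "filter_spec"))
  nyq <- recording$fs / 2
  if (spec$high_hz >= nyq)
    stop("upper band edge (", spec$high_hz, " Hz) must be below Nyquist (",
         nyq, " Hz)")
  bf <- signal::butter(spec$order / 2L,
                       c(spec$low_hz, spec$high_hz) / nyq, type = "pass")
  y <- if (zero_phase) signal::filtfilt(bf, recording$samples)
       else as.numeric(signal::filter(bf, recording$samples))
  eeg_recording(y, recording$fs, recording$channel, recording$start_offset)
}

#' Segment a recording with a sliding window
#'
#' Cuts the recording into fixed-length, half-open windows
#' `[start, start + W)` (samples, 0-based start), advancing by a fixed step.
#' The number of segments is `floor((N - W) / S) + 1`.
#'
#' @param recording An [eeg_recording].
#' @param window_s Window length in seconds (default 0.5).
#' @param step_s Step between window starts in seconds (default 0.1,
#'   i.e. 0.4 s overlap at the default window).
#' @return A `"segment_set"`: list with `values` (n_segments x W matrix),
#'   `start_sample` (0-based), `fs`, `window_s`, `step_s`, and `label`
#'   (factor, initially `"unlabeled"`).
#' @export
segment_recording <- function(recording, window_s = 0.5, step_s = 0.1) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  W <- round(window_s * fs); S <- round(step_s * fs)
  if (W < 1L || abs(window_s * fs - W) > 1e-6)
    stop("'window_s' times fs must round to a positive integer")
  if (S < 1L || abs(step_s * fs - S) > 1e-6)
    stop("'step_s' times fs must round to a positive integer")
  n <- length(recording$samples)
  if (n < W) stop("recording (", n, " samples) shorter than one window (", W, ")")
  n_seg <- (n - W) %/% S + 1L
  starts <- (seq_len(n_seg) - 1L) * S
  idx <- outer(starts, seq_len(W) - 1L, "+") + 1L
  values <- matrix(recording$samples[idx], nrow = n_seg)
  structure(
    list(values = values, start_sample = as.integer(starts), fs = fs,
         window_s = window_s, step_s = step_s,
         label = factor(rep("unlabeled", n_seg),
                        levels = c("non_kcomplex", "kcomplex", "unlabeled"))),
    class = "segment_set"
  )
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments of %d samples (%.2g s @ %g Hz)\n",
              nrow(x$values), ncol(x$values), x$window_s, x$fs))
  print(table(x$label))
  invisible(x)
}

#' @export
length.segment_set <- function(x) nrow(x$values)

#' @export
as.data.frame.segment_set <- function(x, ...) {
  data.frame(start_sample = x$start_sample,
             start_s = x$start_sample / x$fs,
             label = as.character(x$label))
}

#' Label segments against expert annotations
#'
#' A segment is labeled `kcomplex` when the fraction of its samples that fall
#' inside any single annotated event reaches `min_overlap`. Sample times and
#' event intervals are half-open, so abutting windows and events never
#' double-count a boundary. An empty annotation set labels everything
#' `non_kcomplex`.
#'
#' @param segments A `"segment_set"` from [segment_recording()].
#' @param annotations An [annotation_set] on the same time base.
#' @param min_overlap Minimum within-event sample fraction for a positive
#'   label (default 0.5).
#' @return The segment set with `label` filled in and an `overlap` element
#'   (best per-segment overlap fraction) attached.
#' @export
label_segments <- function(segments, annotations, min_overlap = 0.5) {
  stopifnot(inherits(segments, "segment_set"),
            inherits(annotations, "annotation_set"))
  fs <- segments$fs
  W <- ncol(segments$values)
  t0 <- segments$start_sample / fs
  best <- numeric(length(t0))
  for (i in seq_len(nrow(annotations))) {
    a <- annotations$onset[i]; b <- a + annotations$duration[i]
    # samples k = 0..W-1 at times t0 + k/fs; count those with a <= t < b
    kmin <- pmax(0, ceiling((a - t0) * fs - 1e-9))
    kmax <- pmin(W, ceiling((b - t0) * fs - 1e-9))
    frac <- pmax(0, kmax - kmin) / W
    best <- pmax(best, frac)
  }
  segments$label <- factor(
    ifelse(best >= min_overlap - 1e-12, "kcomplex", "non_kcomplex"),
    levels = c("non_kcomplex", "kcomplex", "unlabeled"))
  segments$overlap <- best
  segments
}
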