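# Seeded synthetic sleep-EEG generator: an N2-like colored-noise background
# (AR(2) with a delta-band spectral peak plus broadband noise, band-limited
# to 0.5-30 Hz) with biphasic k-complex transients embedded at known,
# non-overlapping onsets, so every pipeline stage can be exercised against
# exact ground truth.

#' Synthetic k-complex waveform
#'
#' A biphasic transient matching the AASM verbal morphology: a sharp
#' negative lobe over the first ~40% of the duration immediately followed by
#' a slower positive wave, built from two raised-cosine lobes with a 1.5:1
#' negative:positive amplitude ratio. The waveform starts and ends at zero
#' and its two lobe areas cancel, so it is (near) zero-mean.
#'
#' @param fs Sampling rate (Hz).
#' @param duration_s Event duration in seconds, within `[0.5, 2]` (the
#'   physiological range).
#' @param amplitude Peak (negative-lobe) amplitude in µV.
#' @return Numeric vector of `round(duration_s * fs)` samples.
#' @export
make_kcomplex_waveform <- function(fs, duration_s, amplitude = 100) {
  if (duration_s < 0.5 - 1e-9 || duration_s > 2 + 1e-9)
    stop("k-complex duration must lie in [0.5, 2] s")
  L <- round(duration_s * fs)
  n1 <- round(0.4 * L)
  n2 <- L - n1
  bump <- function(n) (1 - cos(2 * pi * (seq_len(n) - 0.5) / n)) / 2
  c(-amplitude * bump(n1), (amplitude / 1.5) * bump(n2))
}

#' Synthetic recording specification
#'
#' Defaults are the generator's reference study conditions: a 15-minute
#' 200 Hz recording with 60 non-overlapping k-complexes of 0.5–2 s riding on
#' an N2-like background of 15 µV standard deviation, with event peaks 8
#' times the background sd (~120 µV).
#'
#' @param fs Sampling rate (Hz, default 200).
#' @param duration_s Recording length in seconds (default 900).
#' @param n_events Number of k-complexes (default 60).
#' @param event_duration_range Event duration range in seconds
#'   (default `c(0.5, 2)`).
#' @param snr Event peak amplitude divided by background sd (default 8);
#'   `snr = 0` embeds zero-amplitude events, leaving pure background.
#' @param background_sd Background standard deviation in µV (default 15).
#' @param ar AR(2) coefficients of the background resonance (default places
#'   the spectral peak near 2 Hz at 200 Hz sampling).
#' @param noise_mix Proportion of broadband white noise mixed into the
#'   background before band-limiting (default 0.3).
#' @param spindles Number of 13 Hz spindle-like distractor bursts
#'   (default 0).
#' @param seed Seed controlling every random draw (default 1).
#' @return A `"synth_spec"` list.
#' @export
synth_spec <- function(fs = 200, duration_s = 900, n_events = 60,
                       event_duration_range = c(0.5, 2), snr = 8,
                       background_sd = 15, ar = NULL, noise_mix = 0.3,
                       spindles = 0, seed = 1L) {
  if (is.null(ar)) {
    rho <- 0.97; f0 <- 2
    ar <- c(2 * rho * cos(2 * pi * f0 / fs), -rho^2)
  }
  if (duration_s * fs < 1) stop("empty recording requested")
  if (event_duration_range[1L] < 0.5 || event_duration_range[2L] > 2)
    stop("event durations must lie within [0.5, 2] s")
  if (snr < 0) stop("'snr' must be >= 0")
  structure(list(fs = fs, duration_s = duration_s, n_events = n_events,
                 event_duration_range = event_duration_range, snr = snr,
                 background_sd = background_sd, ar = ar,
                 noise_mix = noise_mix, spindles = spindles,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a synthetic recording with ground-truth annotations
#'
#' Draws the background process, samples non-overlapping event onsets and
#' durations, superimposes the k-complex waveforms (peak amplitude
#' `snr * background_sd`), and returns the signal together with the exact
#' annotation set. Identical seeds give bit-identical output.
#'
#' @param spec A [synth_spec] (or arguments for one via `...`).
#' @param ... Passed to [synth_spec()] when `spec` is missing.
#' @return List with elements `recording` (an [eeg_recording], channel
#'   `"Cz-A1"`) and `annotations` (an [annotation_set]).
#' @export
generate_recording <- function(spec = NULL, ...) {
  if (is.null(spec)) spec <- synth_spec(...)
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  fs <- spec$fs
  n <- round(spec$duration_s * fs)

  # N2-like background: resonant AR(2) plus white noise, band-limited
  innov <- stats::rnorm(n + 4 * fs)
  arp <- as.numeric(stats::filter(innov, spec$ar, method = "recursive"))
  arp <- arp[-seq_len(4 * fs)]                       # drop warm-up
  bg <- (1 - spec$noise_mix) * arp / stats::sd(arp) +
        spec$noise_mix * stats::rnorm(n)
  bg <- bandpass(eeg_recording(bg, fs), filter_spec(0.5, 30, 4),
                 zero_phase = TRUE)$samples
  bg <- bg / stats::sd(bg) * spec$background_sd

  if (spec$spindles > 0) {
    t <- seq_len(round(fs)) / fs
    burst <- sin(2 * pi * 13 * t) *
      (1 - cos(2 * pi * (seq_along(t) - 0.5) / length(t))) / 2
    for (s in seq_len(spec$spindles)) {
      at <- sample.int(n - length(burst), 1L)
      bg[at + seq_along(burst) - 1L] <- bg[at + seq_along(burst) - 1L] +
        0.8 * spec$background_sd * burst
    }
  }

  # non-overlapping event placement with a 0.5 s refractory gap and 1 s
  # margins, by rejection sampling
  durs <- stats::runif(spec$n_events, spec$event_duration_range[1L],
                       spec$event_duration_range[2L])
  onsets <- numeric(0)
  gap <- 0.5; margin <- 1
  max_try <- 1000L * spec$n_events
  tries <- 0L
  for (i in seq_len(spec$n_events)) {
    repeat {
      tries <- tries + 1L
      if (tries > max_try)
        stop("could not place ", spec$n_events,
             " non-overlapping events in ", spec$duration_s, " s")
      cand <- stats::runif(1, margin, spec$duration_s - margin - durs[i])
      ok <- !length(onsets) ||
        all(cand + durs[i] + gap <= onsets |
            onsets + durs[seq_along(onsets)] + gap <= cand)
      if (ok) { onsets <- c(onsets, cand); break }
    }
  }
  ord <- order(onsets)
  onsets <- onsets[ord]; durs <- durs[ord]

  amp <- spec$snr * spec$background_sd
  x <- bg
  if (amp > 0) {
    for (i in seq_along(onsets)) {
      wf <- make_kcomplex_waveform(fs, durs[i], amp)
      at <- round(onsets[i] * fs)
      x[at + seq_along(wf)] <- x[at + seq_along(wf)] + wf
    }
  }
  list(recording = eeg_recording(x, fs, channel = "Cz-A1"),
       annotations = annotation_set(onsets, durs, scorer = "synthetic"))
}

#' Write a synthetic fixture to disk
#'
#' Emits an EDF file and a plain-text annotation file (`onset duration` per
#' line, seconds) in exactly the dialects [read_edf()] and
#' [read_annotations()] consume, for round-trip testing.
#'
#' @param recording An [eeg_recording].
#' @param annotations An [annotation_set].
#' @param dir Output directory (created if needed).
#' @param basename File stem (default `"synthetic"`); writes
#'   `<stem>.edf` and `<stem>_annot.txt`.
#' @return Named character vector with the two paths, invisibly.
#' @export
write_fixture <- function(recording, annotations, dir,
                          basename = "synthetic") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  edf_path <- file.path(dir, paste0(basename, ".edf"))
  ann_path <- file.path(dir, paste0(basename, "_annot.txt"))
  write_edf(recording, edf_path)
  writeLines(c("# onset_s duration_s (synthetic ground truth)",
               sprintf("%.6f %.6f", annotations$onset, annotations$duration)),
             ann_path)
  invisible(c(edf = edf_path, annotations = ann_path))
}
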