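test_that("EDF files round-trip through write_edf/read_edf", {
  sim <- small_synth(seed = 11)
  rec <- eeg_recording(sim$recording$samples[1:6000], 200, channel = "Cz-A1")
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(length(back$samples), 6000L)
  expect_equal(back$fs, 200)
  # quantization error bounded by one digitization step
  step <- 2 * ceiling(max(abs(rec$samples)) * 1.01) / 65535
  expect_lt(max(abs(back$samples - rec$samples)), step)

  # case-insensitive channel lookup
  expect_equal(read_edf(path, "CZ-A1")$channel, "Cz-A1")
  expect_error(read_edf(path, "F3-A2"), "not found")
  expect_error(read_edf(file.path(tempdir(), "nope.edf")), "not found")
})

test_that("multi-channel EDF returns the requested channel", {
  set.seed(3)
  ch1 <- eeg_recording(rnorm(1000, sd = 20), 100, channel = "Cz-A1")
  ch2 <- eeg_recording(sin(2 * pi * 3 * (0:999) / 100) * 50, 100,
                       channel = "C3-A2")
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(list(ch1, ch2), path)
  got <- read_edf(path, "c3-a2")
  expect_equal(got$channel, "C3-A2")
  expect_lt(max(abs(got$samples - ch2$samples)), 0.01)
})

test_that("annotation parsing sorts, skips bad lines, and fails when empty", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# header", "42.0 1.3", "10.5 0.9"), path)
  ann <- read_annotations(path)
  expect_equal(nrow(ann), 2L)
  expect_equal(ann$onset, c(10.5, 42.0))
  expect_equal(ann$duration[1L], 0.9)

  writeLines(c("10.5 0.9", "abc", "42.0 1.3"), path)
  expect_warning(ann2 <- read_annotations(path), "line")
  expect_equal(nrow(ann2), 2L)

  writeLines("no numbers here", path)
  expect_error(suppressWarnings(read_annotations(path)), "no parsable")
})

test_that("band-pass attenuation matches the analytic Butterworth response", {
  fs <- 200
  spec <- filter_spec(0.5, 30, 4)
  bf <- signal::butter(spec$order / 2, c(0.5, 30) / (fs / 2), type = "pass")
  gain_at <- function(f_hz) {
    # analytic |H(e^{jw})| straight from the transfer-function polynomials
    z <- exp(-1i * 2 * pi * f_hz / fs)
    Mod(sum(bf$b * z^(seq_along(bf$b) - 1)) /
        sum(bf$a * z^(seq_along(bf$a) - 1)))
  }
  t <- (0:(30 * fs - 1)) / fs
  # steady-state sine amplitude from RMS (phase-robust at coarse sampling)
  steady <- function(y) sqrt(2 * mean(y[(20 * fs):(30 * fs - 1)]^2))

  # DC rejected
  dc <- bandpass(eeg_recording(rep(100, length(t)), fs), spec)
  expect_lt(steady(dc$samples), 1)

  # in-band 10 Hz: measured amplitude within 5% of 1 and matches analytics
  y10 <- bandpass(eeg_recording(sin(2 * pi * 10 * t), fs), spec)
  expect_lt(abs(steady(y10$samples) - 1), 0.05)
  expect_lt(abs(steady(y10$samples) - gain_at(10)), 0.02)

  # out-of-band 50 Hz: causal response matches analytics; the zero-phase
  # option squares the magnitude response and attenuates below 0.2
  y50 <- bandpass(eeg_recording(sin(2 * pi * 50 * t), fs), spec)
  expect_lt(steady(y50$samples), 0.3)
  expect_lt(abs(steady(y50$samples) - gain_at(50)), 0.02)
  y50z <- bandpass(eeg_recording(sin(2 * pi * 50 * t), fs), spec,
                   zero_phase = TRUE)
  expect_lt(steady(y50z$samples), 0.2)
  expect_lt(abs(steady(y50z$samples) - gain_at(50)^2), 0.02)

  # filtering twice applies the magnitude response twice (composition)
  y10b <- bandpass(y10, spec)
  expect_lt(abs(steady(y10b$samples) - gain_at(10)^2), 0.02)

  expect_error(bandpass(eeg_recording(t, fs), filter_spec(0.5, 120, 4)),
               "Nyquist")
})

test_that("segment count matches the closed form and a loop oracle", {
  rec <- eeg_recording(seq_len(600), 200)
  segs <- segment_recording(rec, 100 / 200, 20 / 200)
  expect_equal(length(segs), 26L)

  expect_equal(length(segment_recording(eeg_recording(1:100, 200), 0.5, 0.1)),
               1L)
  expect_equal(length(segment_recording(eeg_recording(rnorm(6000), 200))),
               296L)
  expect_error(segment_recording(eeg_recording(1:50, 200), 0.5, 0.1),
               "shorter")

  # property: formula equals naive loop for random (N, W, S), S <= W
  set.seed(42)
  for (i in 1:50) {
    W <- sample(10:80, 1L)
    S <- sample(1:W, 1L)
    N <- sample(W:500, 1L)
    fs <- 100
    segs <- segment_recording(eeg_recording(rnorm(N), fs), W / fs, S / fs)
    expect_equal(length(segs), oracle_segment_count(N, W, S))
    expect_equal(segs$start_sample,
                 seq(0L, by = S, length.out = length(segs)))
  }
})

test_that("segments record provenance and exact window contents", {
  x <- rnorm(300)
  segs <- segment_recording(eeg_recording(x, 100), 0.5, 0.2)
  for (i in seq_len(length(segs)))
    expect_equal(segs$values[i, ], x[segs$start_sample[i] + 1:50])
})

test_that("labeling follows the half-open >= min_overlap rule", {
  fs <- 200
  rec <- eeg_recording(rnorm(fs * 20), fs)
  ann <- annotation_set(10.0, 1.0)
  segs <- segment_recording(rec, 0.5, 0.1)
  labeled <- label_segments(segs, ann, 0.5)
  lab_at <- function(t0) {
    as.character(labeled$label[which(abs(labeled$start_sample / fs - t0)
                                     < 1e-9)])
  }
  expect_equal(lab_at(10.1), "kcomplex")     # fully inside
  expect_equal(lab_at(9.8), "kcomplex")      # overlap 0.6
  expect_equal(lab_at(9.5), "non_kcomplex")  # disjoint (half-open)

  # the measured overlaps match a per-sample loop oracle
  for (t0 in c(9.5, 9.6, 9.8, 10.1, 10.6, 10.7)) {
    i <- which(abs(labeled$start_sample / fs - t0) < 1e-9)
    expect_equal(labeled$overlap[i], oracle_overlap(t0, 100, fs, 10, 1))
  }

  # empty annotations -> all negative
  none <- label_segments(segs, annotation_set(numeric(0), numeric(0)))
  expect_true(all(none$label == "non_kcomplex"))
})

test_that("labeling is monotone in min_overlap", {
  sim <- small_synth(seed = 9)
  segs <- segment_recording(sim$recording)
  thresholds <- c(0.9, 0.7, 0.5, 0.3, 0.1)
  prev <- NULL
  for (th in thresholds) {
    lab <- label_segments(segs, sim$annotations, th)
    pos <- which(lab$label == "kcomplex")
    if (!is.null(prev)) expect_true(all(prev %in% pos))
    prev <- pos
  }
})

test_that("recordings reject degenerate inputs", {
  expect_error(eeg_recording(numeric(0), 200), "at least one")
  expect_error(eeg_recording(c(1, NA), 200), "non-finite")
  expect_error(eeg_recording(1:10, -1), "positive")
  expect_error(annotation_set(-1, 2), ">= 0")
  expect_error(annotation_set(1, 0), "> 0")
})
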