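# Minimal European Data Format (EDF) reader/writer.
#
# EDF stores a 256-byte fixed header, 256 bytes of header per signal, then
# interleaved data records of 16-bit little-endian integers that are mapped
# to physical units by a per-signal linear calibration. Only the subset
# needed for single- or few-channel polysomnography fixtures is supported:
# one record per second, identical record count for all signals, no EDF+
# annotations channel.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x, type = "bytes") > width) x <- substr(x, 1L, width)
  formatC(x, width = -width, flag = " ")
}

.edf_num <- function(x, width) {
  s <- formatC(x, format = "fg", width = 1)
  if (nchar(s) > width) s <- substr(formatC(x, format = "g", digits = 6), 1L, width)
  .edf_pad(s, width)
}

#' Write recordings to an EDF file
#'
#' Writes one or more equal-length, equal-rate channels as a standard 16-bit
#' EDF file with 1-second data records. Physical calibration is symmetric
#' about zero and chosen per channel from the sample range, so quantization
#' error is at most one part in 2^16 of the full scale.
#'
#' @param recordings An [eeg_recording] or a list of them (same `fs` and
#'   length). Signals whose length is not a whole number of seconds are
#'   zero-padded to the next full record, with a warning.
#' @param path Output file path.
#' @param physical_dim Physical dimension string stored per channel
#'   (default `"uV"`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(recordings, path, physical_dim = "uV") {
  if (inherits(recordings, "eeg_recording")) recordings <- list(recordings)
  if (!length(recordings) || !all(vapply(recordings, inherits, TRUE, "eeg_recording")))
    stop("'recordings' must be an eeg_recording or a list of them")
  fs <- recordings[[1L]]$fs
  n <- length(recordings[[1L]]$samples)
  for (r in recordings) {
    if (r$fs != fs) stop("all channels must share the same sampling rate")
    if (length(r$samples) != n) stop("all channels must have the same length")
  }
  spr <- as.integer(round(fs))
  if (abs(fs - spr) > 1e-9)
    stop("EDF writer supports integer sampling rates only")
  n_rec <- ceiling(n / spr)
  if (n_rec * spr != n) {
    warning("signal length is not a whole number of 1-s records; padding with zeros")
  }
  ns <- length(recordings)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL, useBytes = TRUE)

  wr(.edf_pad("0", 8))                       # version
  wr(.edf_pad("X X X X", 80))                # patient id
  wr(.edf_pad("Startdate X X X X", 80))      # recording id
  wr(.edf_pad("01.01.00", 8))                # start date
  wr(.edf_pad("00.00.00", 8))                # start time
  wr(.edf_num(256L * (ns + 1L), 8))          # header bytes
  wr(.edf_pad("", 44))                       # reserved
  wr(.edf_num(n_rec, 8))                     # number of data records
  wr(.edf_num(1, 8))                         # record duration (s)
  wr(.edf_num(ns, 4))                        # number of signals

  pmaxs <- vapply(recordings, function(r) {
    m <- max(abs(r$samples))
    if (m == 0) 1 else ceiling(m * 1.01)
  }, 0)

  for (f in list(
    function(i) .edf_pad(recordings[[i]]$channel, 16),
    function(i) .edf_pad("", 80),                      # transducer
    function(i) .edf_pad(physical_dim, 8),
    function(i) .edf_num(-pmaxs[i], 8),                # physical min
    function(i) .edf_num(pmaxs[i], 8),                 # physical max
    function(i) .edf_num(-32768L, 8),                  # digital min
    function(i) .edf_num(32767L, 8),                   # digital max
    function(i) .edf_pad("", 80),                      # prefiltering
    function(i) .edf_num(spr, 8),                      # samples per record
    function(i) .edf_pad("", 32)
  )) for (i in seq_len(ns)) wr(f(i))

  # digitize: d = round((x - pmin) / (pmax - pmin) * (dmax - dmin) + dmin)
  dig <- lapply(seq_len(ns), function(i) {
    x <- c(recordings[[i]]$samples, rep(0, n_rec * spr - n))
    d <- round((x + pmaxs[i]) / (2 * pmaxs[i]) * 65535 - 32768)
    as.integer(pmin(pmax(d, -32768), 32767))
  })
  for (rec_i in seq_len(n_rec)) {
    sl <- ((rec_i - 1L) * spr + 1L):(rec_i * spr)
    for (i in seq_len(ns))
      writeBin(dig[[i]][sl], con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read a channel from an EDF file
#'
#' Parses a standard EDF header, applies the per-signal physical calibration,
#' and returns the requested channel. Channel matching is case-insensitive
#' and ignores surrounding whitespace.
#'
#' @param path Path to an EDF file.
#' @param channel Channel label to extract (case-insensitive). `NULL`
#'   (default) returns the first channel.
#' @return An [eeg_recording].
#' @export
read_edf <- function(path, channel = NULL) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    raw <- readBin(con, "raw", n = width)
    if (length(raw) < width) stop("corrupt EDF header: file truncated")
    trimws(rawToChar(raw))
  }
  rdnum <- function(width) {
    v <- suppressWarnings(as.numeric(rd(width)))
    if (is.na(v)) stop("corrupt EDF header: non-numeric field")
    v
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rdnum(8)                      # header bytes (recomputed from ns)
  rd(44)
  n_rec <- rdnum(8)
  rec_dur <- rdnum(8)
  ns <- as.integer(rdnum(4))
  if (ns < 1L || n_rec < 1L || rec_dur <= 0)
    stop("corrupt EDF header: implausible record structure")

  fld <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- fld(16); fld(80); fld(8)
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8)); fld(32)
  if (any(is.na(c(pmin, pmax, dmin, dmax, spr))))
    stop("corrupt EDF header: bad signal fields")

  idx <- if (is.null(channel)) 1L else {
    hit <- which(tolower(trimws(labels)) == tolower(trimws(channel)))
    if (!length(hit))
      stop("channel '", channel, "' not found; available: ",
           paste(labels, collapse = ", "))
    hit[1L]
  }

  total <- sum(spr)
  d <- readBin(con, "integer", n = n_rec * total, size = 2L,
               endian = "little", signed = TRUE)
  if (length(d) < n_rec * total) stop("corrupt EDF file: data truncated")
  d <- matrix(d, nrow = total)
  offsets <- cumsum(c(0L, spr))
  rows <- (offsets[idx] + 1L):offsets[idx + 1L]
  digital <- as.vector(d[rows, , drop = FALSE])
  gain <- (pmax[idx] - pmin[idx]) / (dmax[idx] - dmin[idx])
  samples <- pmin[idx] + (digital - dmin[idx]) * gain
  eeg_recording(samples, fs = spr[idx] / rec_dur, channel = trimws(labels[idx]))
}
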