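# Spectral descriptors f13-f19 computed from a one-sided FFT energy
# spectrum of each windowed segment.

.spectral_feature_names <- c(
  "f13_ber", "f14_flux", "f15_sc", "f16_bw", "f17_sfm", "f18_sro", "f19_si")

#' One-sided energy spectrum of a segment
#'
#' Computes `E(k) = |X(k)|^2` over 0..fs/2 from the discrete Fourier
#' transform, scaled so that the one-sided energies satisfy Parseval's
#' identity exactly: `sum(E) == sum(x^2)` (interior bins are doubled to fold
#' in the conjugate half; DC and Nyquist are not).
#'
#' @param x Numeric vector (one segment, length >= 4).
#' @param fs Sampling rate in Hz.
#' @param include_dc Keep the DC bin (default TRUE).
#' @return A `"power_spectrum"`: list with `energies`, `freqs` (Hz,
#'   ascending) and `fs`.
#' @export
segment_spectrum <- function(x, fs, include_dc = TRUE) {
  x <- as.numeric(x)
  N <- length(x)
  if (N < 4L) stop("need at least 4 samples for a spectrum")
  X <- stats::fft(x)
  K <- N %/% 2L + 1L                      # bins 0 .. floor(N/2)
  E <- Mod(X[seq_len(K)])^2 / N
  fold <- rep(2, K)
  fold[1L] <- 1
  if (N %% 2L == 0L) fold[K] <- 1         # Nyquist bin is unpaired
  E <- E * fold
  freqs <- (seq_len(K) - 1L) * fs / N
  if (!include_dc) { E <- E[-1L]; freqs <- freqs[-1L] }
  structure(list(energies = E, freqs = freqs, fs = fs),
            class = "power_spectrum")
}

#' Spectral features of an energy spectrum
#'
#' Computes the seven spectral descriptors: band energy ratio, spectral flux,
#' spectral centroid, bandwidth about the centroid (energy-weighted mean
#' absolute deviation), spectral flatness in dB (10 log10 of geometric /
#' arithmetic mean), spectral roll-off (smallest frequency whose cumulative
#' energy reaches `rolloff_c` of the total), and spectral irregularity.
#'
#' @param ps A `"power_spectrum"` from [segment_spectrum()].
#' @param band Two-element band (Hz) for the band energy ratio. Default
#'   `c(0.5, 4)`: the delta band, where k-complex energy concentrates.
#' @param rolloff_c Roll-off fraction `C` (conventionally 0.6–0.85;
#'   default 0.85).
#' @return A one-row data frame `f13_ber` ... `f19_si` with a logical
#'   `"degenerate"` attribute (TRUE when the spectrum has zero total energy,
#'   in which case all features are 0).
#' @export
#' @examples
#' ps <- structure(list(energies = c(1, 2, 1), freqs = c(10, 20, 30), fs = 200),
#'                 class = "power_spectrum")
#' spectral_features(ps)
spectral_features <- function(ps, band = c(0.5, 4), rolloff_c = 0.85) {
  stopifnot(inherits(ps, "power_spectrum"))
  E <- ps$energies; f <- ps$freqs
  K <- length(E)
  tot <- sum(E)
  if (tot <= 0) {
    out <- as.data.frame(as.list(stats::setNames(rep(0, 7L),
                                                 .spectral_feature_names)))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  in_band <- f >= band[1L] & f <= band[2L]
  ber <- sum(E[in_band]) / tot
  dE <- diff(E)
  flux <- sum(dE^2)
  sc <- sum(f * E) / tot
  bw <- sum(abs(sc - f) * E) / tot
  eps <- 1e-12 * max(E)
  geo <- exp(mean(log(pmax(E, eps))))
  sfm <- 10 * log10(geo / (tot / K))
  sro <- f[which(cumsum(E) >= rolloff_c * tot - 1e-12)[1L]]
  si <- sum(dE^2) / sum(E^2)
  out <- data.frame(f13_ber = ber, f14_flux = flux, f15_sc = sc, f16_bw = bw,
                    f17_sfm = sfm, f18_sro = sro, f19_si = si)
  attr(out, "degenerate") <- FALSE
  out
}
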