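# Time-domain descriptors f1-f12 of a windowed EEG segment.
#
# Conventions follow the detection literature rather than textbook factors:
# skewness/kurtosis are plain moment ratios scaled by the (N-1) standard
# deviation, kurtosis keeps its +3 offset, and the crest/impulse/margin
# factors use peak-to-peak (max - min) numerators. Degenerate inputs
# (constant segment, zero-sum segment) yield 0 for the affected features with
# a degeneracy flag instead of NaN, so downstream feature matrices stay
# finite.

.time_feature_names <- c(
  "f01_max", "f02_mean", "f03_std", "f04_skew", "f05_kurt", "f06_shape",
  "f07_crest", "f08_impulse", "f09_margin", "f10_energy", "f11_zcr", "f12_tc")

#' Time-domain features of EEG segments
#'
#' Computes the twelve time-domain descriptors per segment: maximum, mean,
#' standard deviation (N-1), skewness, kurtosis (non-excess), shape factor
#' (RMS / mean absolute), crest/impulse/margin factors with peak-to-peak
#' numerators, short energy, zero-crossing rate (with `sgn(0) = +1`), and the
#' time centroid `sum(n * x_n) / sum(x_n)` over 1-based sample index `n`.
#'
#' @param x A numeric vector (one segment, length >= 2), a matrix with one
#'   segment per row, or a `"segment_set"`.
#' @return A data frame with columns `f01_max` ... `f12_tc`, one row per
#'   segment, with a logical `"degenerate"` attribute (one row per segment,
#'   columns `std_zero` and `sum_zero`) marking features that were forced to
#'   0: skewness/kurtosis when the segment is constant, and the time centroid
#'   when the segment sums to zero.
#' @export
#' @examples
#' time_features(c(2, -1, 3, -2))
time_features <- function(x) {
  X <- if (inherits(x, "segment_set")) x$values
       else if (is.matrix(x)) x
       else matrix(as.numeric(x), nrow = 1L)
  N <- ncol(X)
  if (N < 2L) stop("segments must contain at least 2 samples")
  m <- rowMeans(X)
  C <- X - m
  ss <- rowSums(C^2)
  s <- sqrt(ss / (N - 1))
  std_zero <- s == 0
  s_safe <- ifelse(std_zero, 1, s)
  skew <- ifelse(std_zero, 0, rowMeans(C^3) / s_safe^3)
  kurt <- ifelse(std_zero, 0, rowMeans(C^4) / s_safe^4)

  energy <- rowSums(X^2)
  rms <- sqrt(energy / N)
  mabs <- rowMeans(abs(X))
  mx <- apply(X, 1L, max)
  mn <- apply(X, 1L, min)
  ptp <- mx - mn
  zero_amp <- mabs == 0
  shape <- ifelse(zero_amp, 0, rms / ifelse(zero_amp, 1, mabs))
  crest <- ifelse(zero_amp, 0, ptp / ifelse(zero_amp, 1, rms))
  impulse <- ifelse(zero_amp, 0, ptp / ifelse(zero_amp, 1, mabs))
  margin <- ifelse(zero_amp, 0, ptp / ifelse(zero_amp, 1, mabs)^2)

  sgn <- ifelse(X >= 0, 1, -1)
  num <- rowSums(abs(sgn[, -1L, drop = FALSE] - sgn[, -N, drop = FALSE])) / 2
  zcr <- num / N

  tot <- rowSums(X)
  sum_zero <- tot == 0
  tc <- ifelse(sum_zero, 0,
               as.vector(X %*% seq_len(N)) / ifelse(sum_zero, 1, tot))

  out <- data.frame(mx, m, s, skew, kurt, shape, crest, impulse, margin,
                    energy, zcr, tc)
  names(out) <- .time_feature_names
  attr(out, "degenerate") <- cbind(std_zero = std_zero, sum_zero = sum_zero)
  out
}
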