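# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's code paths: naive loops, split/table grouping, and
# bitmask enumeration.

# sliding-window count by explicit loop
oracle_segment_count <- function(n_total, W, S) {
  count <- 0L
  start <- 0L
  while (start + W <= n_total) {
    count <- count + 1L
    start <- start + S
  }
  count
}

# fraction of window samples inside [onset, onset+duration), by sample loop
oracle_overlap <- function(start_s, W, fs, onset, duration) {
  times <- start_s + (0:(W - 1)) / fs
  mean(times >= onset & times < onset + duration)
}

# inconsistency rate by split() grouping on a discrete matrix
oracle_incons <- function(Z, y) {
  key <- apply(as.matrix(Z), 1L, paste, collapse = "/")
  groups <- split(y, key)
  sum(vapply(groups, function(g) length(g) - max(table(g)), 0)) / length(y)
}

# exhaustive subset minimization by bitmask; ties -> smaller subset, then
# lexicographic by column order (matching the documented contract)
oracle_best_subset <- function(Z, y) {
  F <- ncol(Z)
  best <- NULL
  for (mask in 1:(2^F - 1)) {
    s <- which(bitwAnd(mask, 2^(seq_len(F) - 1L)) > 0)
    v <- oracle_incons(Z[, s, drop = FALSE], y)
    if (is.null(best)) { best <- list(set = s, value = v); next }
    better <- FALSE
    if (v < best$value - 1e-12) {
      better <- TRUE
    } else if (abs(v - best$value) <= 1e-12) {
      if (length(s) < length(best$set)) {
        better <- TRUE
      } else if (length(s) == length(best$set)) {
        d <- s - best$set
        nz <- which(d != 0)
        if (length(nz) && d[nz[1L]] < 0) better <- TRUE
      }
    }
    if (better) best <- list(set = s, value = v)
  }
  best
}

# entropy-based SU from a contingency table
oracle_su <- function(tab) {
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  n <- sum(tab)
  Hf <- H(rowSums(tab) / n)
  Hy <- H(colSums(tab) / n)
  Hfy <- H(as.numeric(tab) / n)
  2 * (Hf + Hy - Hfy) / (Hf + Hy)
}

# metric bundle from first principles, with 0-on-degenerate convention
oracle_metrics <- function(TP, FN, FP, TN, beta = 1) {
  n <- TP + FN + FP + TN
  sens <- if (TP + FN > 0) TP / (TP + FN) else 0
  spec <- if (TN + FP > 0) TN / (TN + FP) else 0
  acc <- (TP + TN) / n
  fden <- (1 + beta^2) * TP + beta^2 * FN + FP
  fs <- if (fden > 0) (1 + beta^2) * TP / fden else 0
  pe <- ((TP + FN) * (TP + FP) + (FP + TN) * (FN + TN)) / n^2
  kap <- if (pe < 1) (acc - pe) / (1 - pe) else 0
  c(sensitivity = sens, specificity = spec, accuracy = acc,
    fscore = fs, kappa = kap)
}

# small labeled gaussian feature matrix for selector/classifier tests
make_blobs <- function(n = 120, sep = 2, noise_features = 2, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- cbind(signal1 = y * sep + rnorm(n),
             signal2 = y * sep + rnorm(n))
  for (j in seq_len(noise_features))
    X <- cbind(X, rnorm(n))
  colnames(X) <- c("signal1", "signal2",
                   paste0("noise", seq_len(noise_features)))
  feature_matrix(X, y)
}

# short synthetic study fixture shared by several files (cheap: 60 s)
small_synth <- function(seed = 5, ...) {
  generate_recording(synth_spec(duration_s = 60, n_events = 8, seed = seed,
                                ...))
}
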