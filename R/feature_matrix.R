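#' Feature matrix container
#'
#' Holds the segments-by-features design matrix and the binary labels
#' (`kcomplex = 1`) used by the selection and detection stages.
#'
#' @param X Numeric matrix (segments x features) with column names; all
#'   entries must be finite.
#' @param y Integer/logical labels (1 = k-complex), or `NULL` for unlabeled
#'   data.
#' @param meta Optional per-feature data frame (`feature`, `domain`, `index`).
#' @return A `"feature_matrix"` object.
#' @export
feature_matrix <- function(X, y = NULL, meta = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!all(is.finite(X))) stop("feature matrix contains non-finite entries")
  if (!is.null(y)) {
    y <- as.integer(y)
    if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
    if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1 (kcomplex = 1)")
  }
  structure(list(X = X, y = y, meta = meta), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d segments x %d features\n",
              nrow(x$X), ncol(x$X)))
  if (!is.null(x$y))
    cat(sprintf("  labels: %d k-complex / %d non-k-complex\n",
                sum(x$y == 1L), sum(x$y == 0L)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$X)

# require both classes before selection / detection
.check_two_classes <- function(fm) {
  if (is.null(fm$y)) stop("feature matrix is unlabeled")
  if (length(unique(fm$y)) < 2L)
    stop("both classes must be present in the labels")
}

# restrict to a subset of features (by name or index)
.fm_subset <- function(fm, subset) {
  idx <- if (is.character(subset)) match(subset, colnames(fm$X)) else subset
  if (anyNA(idx)) stop("unknown feature(s): ",
                       paste(subset[is.na(idx)], collapse = ", "))
  feature_matrix(fm$X[, idx, drop = FALSE], fm$y)
}

#' Extract the 22-dimensional multi-domain feature vector per segment
#'
#' Runs the time (f1-f12), spectral (f13-f19) and chaotic (f20-f22) feature
#' extractors over every segment and assembles the labeled feature matrix.
#' Any feature that is non-finite for a segment (possible only for extreme
#' degeneracies) is forced to 0 and flagged.
#'
#' @param segments A `"segment_set"` (labeled or not).
#' @param time,spectral,chaotic Toggles for the three feature families.
#' @param band,rolloff_c Passed to [spectral_features()].
#' @param include_dc Passed to [segment_spectrum()].
#' @param m,tau,q,box_sizes Passed to the chaotic extractors.
#' @return A [feature_matrix] with columns `f01_max` ... `f22_gd` (for the
#'   enabled families), labels taken from the segment set (`NULL` if
#'   unlabeled), and per-feature metadata in `$meta`.
#' @export
extract_features <- function(segments, time = TRUE, spectral = TRUE,
                             chaotic = TRUE, band = c(0.5, 4),
                             rolloff_c = 0.85, include_dc = TRUE,
                             m = 3, tau = NULL, q = 2,
                             box_sizes = 1 / 2^(1:5)) {
  stopifnot(inherits(segments, "segment_set"))
  V <- segments$values
  n <- nrow(V)
  blocks <- list()
  domains <- character(0)
  if (time) {
    tf <- time_features(V)
    blocks <- c(blocks, list(as.matrix(tf)))
    domains <- c(domains, rep("time", ncol(tf)))
  }
  if (spectral) {
    sf <- t(vapply(seq_len(n), function(i) {
      ps <- segment_spectrum(V[i, ], segments$fs, include_dc = include_dc)
      as.numeric(spectral_features(ps, band = band, rolloff_c = rolloff_c))
    }, numeric(7L)))
    colnames(sf) <- .spectral_feature_names
    blocks <- c(blocks, list(sf))
    domains <- c(domains, rep("spectral", 7L))
  }
  if (chaotic) {
    cf <- t(vapply(seq_len(n), function(i) {
      as.numeric(chaotic_features(V[i, ], m = m, tau = tau, q = q,
                                  box_sizes = box_sizes))
    }, numeric(3L)))
    colnames(cf) <- c("f20_cd", "f21_bd", "f22_gd")
    blocks <- c(blocks, list(cf))
    domains <- c(domains, rep("chaotic", 3L))
  }
  if (!length(blocks)) stop("at least one feature family must be enabled")
  X <- do.call(cbind, blocks)
  bad <- !is.finite(X)
  if (any(bad)) {
    warning(sum(bad), " non-finite feature value(s) forced to 0")
    X[bad] <- 0
  }
  y <- if (all(segments$label == "unlabeled")) NULL
       else as.integer(segments$label == "kcomplex")
  meta <- data.frame(feature = colnames(X), domain = domains,
                     index = seq_along(domains))
  feature_matrix(X, y, meta)
}
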