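# Feature-selection algorithms: ReliefF weighting, correlation-based feature
# selection (CFS) with best-first search, subset search under consistency and
# classifier-error measures, and INTERACT (symmetrical-uncertainty ranking
# with backward elimination by consistency contribution).

#' Selection result container
#'
#' @param method Method name.
#' @param selected Character vector of selected feature names (ordered).
#' @param scores Named numeric scores (per feature or per subset, method
#'   dependent).
#' @param params List echoing thresholds/seeds used.
#' @return A `"selection_result"` object.
#' @export
selection_result <- function(method, selected, scores = numeric(), params = list()) {
  structure(list(method = method, selected = as.character(selected),
                 scores = scores, params = params),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d feature(s)\n  %s\n",
              x$method, length(x$selected),
              paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Equal-frequency discretization
#'
#' Bins a continuous feature into (at most) `bins` equal-frequency levels via
#' sample quantiles; used before the entropy- and consistency-based
#' criteria, which need discrete patterns. Features with few distinct values
#' keep their natural levels.
#'
#' @param x Numeric vector.
#' @param bins Target number of bins (default 10).
#' @return Integer codes in `1..bins`.
#' @export
discretize_ef <- function(x, bins = 10L) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                               names = FALSE, type = 7))
  if (length(br) < 2L) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE, labels = FALSE))
}

.discretize_matrix <- function(X, bins) {
  apply(X, 2L, discretize_ef, bins = bins)
}

# inconsistency rate of a discretized pattern matrix: group identical
# patterns, count occurrences minus the largest within-pattern class count,
# divide by n
.incons_rate <- function(Xd, y, subset) {
  Z <- Xd[, subset, drop = FALSE]
  key <- do.call(paste, c(as.data.frame(Z), sep = "\r"))
  n_g <- rowsum(rep(1, length(y)), key)
  pos_g <- rowsum(as.numeric(y == 1L), key)
  sum(n_g - pmax(pos_g, n_g - pos_g)) / length(y)
}

#' Inconsistency rate of a feature subset
#'
#' Discretizes the selected features into equal-frequency bins, groups
#' instances with identical discretized patterns, counts per pattern the
#' occurrences minus the largest single-class count, and divides the summed
#' counts by the number of instances. A rate of 0 means the subset explains
#' the labels perfectly; the rate never increases when features are added.
#'
#' @param fm A [feature_matrix] with labels.
#' @param subset Feature names or column indices (non-empty).
#' @param bins Equal-frequency bins for discretization (default 10).
#' @return The inconsistency rate in `[0, 1]`.
#' @export
inconsistency_rate <- function(fm, subset, bins = 10L) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(fm$y)) stop("feature matrix is unlabeled")
  idx <- if (is.character(subset)) match(subset, colnames(fm$X)) else subset
  if (!length(idx) || anyNA(idx)) stop("'subset' must name existing features")
  Xd <- .discretize_matrix(fm$X[, idx, drop = FALSE], bins)
  .incons_rate(as.matrix(Xd), fm$y, seq_along(idx))
}

#' ReliefF feature weighting
#'
#' Instance-based weighting: for each sampled instance, the per-feature
#' range-normalized difference to its `k` nearest hits (same class) lowers
#' the feature weight and the difference to its `k` nearest misses (other
#' class) raises it. Raw weights are min-max normalized to `[0, 1]` and
#' features whose normalized weight exceeds `threshold` are selected.
#'
#' @param fm A [feature_matrix] with both classes present.
#' @param num_samples Number of sampled instances, or `"all"` (default).
#' @param k_neighbors Nearest hits/misses per instance (default 10).
#' @param threshold Selection threshold on the normalized weight
#'   (default 0.7).
#' @param seed Seed for instance sampling (default 1).
#' @return A [selection_result]; `$scores` carries the normalized weights and
#'   `$params$raw_weights` the raw ones.
#' @export
relieff <- function(fm, num_samples = "all", k_neighbors = 10L,
                    threshold = 0.7, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  .check_two_classes(fm)
  X <- fm$X; y <- fm$y
  n <- nrow(X); F <- ncol(X)
  rng <- apply(X, 2L, function(col) diff(range(col)))
  rng[rng == 0] <- 1                       # constant feature: diff is 0 anyway
  Xn <- sweep(sweep(X, 2L, apply(X, 2L, min)), 2L, rng, "/")
  set.seed(seed)
  picks <- if (identical(num_samples, "all") || num_samples >= n) seq_len(n)
           else sort(sample.int(n, num_samples))
  num <- length(picks)
  W <- numeric(F)
  for (i in picks) {
    diffs <- abs(sweep(Xn, 2L, Xn[i, ]))   # n x F range-normalized diffs
    d <- rowSums(diffs)
    hits <- which(y == y[i]); hits <- hits[hits != i]
    miss <- which(y != y[i])
    kh <- min(k_neighbors, length(hits))
    km <- min(k_neighbors, length(miss))
    if (kh == 0L || km == 0L) next
    nh <- hits[order(d[hits])[seq_len(kh)]]
    nm <- miss[order(d[miss])[seq_len(km)]]
    W <- W - colSums(diffs[nh, , drop = FALSE]) / (num * kh) +
             colSums(diffs[nm, , drop = FALSE]) / (num * km)
  }
  span <- diff(range(W))
  Wn <- if (span == 0) rep(0, F) else (W - min(W)) / span
  names(W) <- names(Wn) <- colnames(X)
  selected <- colnames(X)[Wn > threshold]
  selection_result("relieff", selected[order(-Wn[selected])], scores = Wn,
                   params = list(num_samples = num, k_neighbors = k_neighbors,
                                 threshold = threshold, seed = seed,
                                 raw_weights = W))
}

# CFS merit of a subset: k * mean|corr(f, y)| / sqrt(k + k(k-1) mean|corr(f, f')|)
.cfs_merit <- function(idx, cfl, cff) {
  k <- length(idx)
  rfl <- mean(cfl[idx])
  if (k == 1L) return(rfl)
  rff <- mean(cff[idx, idx][upper.tri(diag(k))])
  k * rfl / sqrt(k + k * (k - 1) * rff)
}

# generic best-first subset search: start empty, expand by single-feature
# additions, stop after `stale` consecutive expansions without improvement
.best_first <- function(F, eval_fn, maximize = TRUE, stale = 5L) {
  sgn <- if (maximize) 1 else -1
  key <- function(s) paste(s, collapse = ",")
  open <- list(list(set = integer(0), score = -Inf))
  visited <- new.env(parent = emptyenv())
  best <- list(set = integer(0), score = -Inf)
  stale_count <- 0L
  while (length(open) && stale_count < stale) {
    scores <- vapply(open, function(nd) nd$score, 0)
    at <- which.max(scores)
    node <- open[[at]]; open[[at]] <- NULL
    improved <- FALSE
    for (f in setdiff(seq_len(F), node$set)) {
      s <- sort(c(node$set, f))
      k <- key(s)
      if (!is.null(visited[[k]])) next
      assign(k, TRUE, envir = visited)
      sc <- sgn * eval_fn(s)
      open[[length(open) + 1L]] <- list(set = s, score = sc)
      if (sc > best$score + 1e-12 ||
          (abs(sc - best$score) <= 1e-12 && length(s) < length(best$set))) {
        best <- list(set = s, score = sc)
        improved <- TRUE
      }
    }
    stale_count <- if (improved) 0L else stale_count + 1L
  }
  list(set = best$set, score = sgn * best$score)
}

#' Correlation-based feature selection (CFS)
#'
#' Scores a subset by the ratio of average (absolute Pearson) feature-class
#' correlation to average feature-feature inter-correlation,
#' `k r_fl / sqrt(k + k(k-1) r_ff)`, and searches subsets by best-first
#' search with a stale-expansion cap. Fully automatic: no threshold and no
#' preset subset size. Features are standardized internally; a zero-variance
#' feature's correlations are treated as 0 with a warning.
#'
#' @param fm A [feature_matrix] with both classes present.
#' @param stale Consecutive non-improving best-first expansions before the
#'   search stops (default 5).
#' @return A [selection_result] with the winning subset and its merit.
#' @export
cfs <- function(fm, stale = 5L) {
  stopifnot(inherits(fm, "feature_matrix"))
  .check_two_classes(fm)
  X <- scale(fm$X)
  zero_var <- apply(fm$X, 2L, stats::sd) == 0
  if (any(zero_var)) {
    warning("zero-variance feature(s) treated as uncorrelated: ",
            paste(colnames(fm$X)[zero_var], collapse = ", "))
    X[, zero_var] <- 0
  }
  cfl <- abs(as.vector(suppressWarnings(stats::cor(X, fm$y))))
  cfl[!is.finite(cfl)] <- 0
  cff <- abs(suppressWarnings(stats::cor(X)))
  cff[!is.finite(cff)] <- 0
  res <- .best_first(ncol(X), function(s) .cfs_merit(s, cfl, cff),
                     maximize = TRUE, stale = stale)
  selection_result("cfs", colnames(fm$X)[res$set],
                   scores = c(merit = res$score),
                   params = list(stale = stale))
}

# seeded k-fold CV error of one classifier on a feature subset; the wrapper
# measure for search-based selection
.cv_error <- function(fm, subset, model, k = 5L, seed = 1L) {
  sub <- .fm_subset(fm, subset)
  folds <- .make_folds(sub$y, k, seed)
  errs <- 0L
  for (fi in seq_len(k)) {
    test <- folds == fi
    pred <- train_predict(model, sub$X[!test, , drop = FALSE], sub$y[!test],
                          sub$X[test, , drop = FALSE], seed = seed)
    errs <- errs + sum(pred != sub$y[test])
  }
  errs / length(sub$y)
}

#' Subset search feature selection (consistency or classifier-error measure)
#'
#' Evaluates candidate feature subsets and returns the one minimizing the
#' chosen measure: the inconsistency rate of the discretized subset, or the
#' seeded internal cross-validation error of a classifier trained on it.
#' All `2^F - 1` non-empty subsets are enumerated when `F <=
#' max_exhaustive`; beyond that the search falls back to best-first with the
#' same measure (reported via a message). Ties are broken toward smaller
#' subsets, then lexicographically by column order.
#'
#' @param fm A [feature_matrix] with both classes present.
#' @param measure `"consistency"` (default) or `"classifier_error"`.
#' @param max_exhaustive Largest `F` for exhaustive enumeration (default 15).
#' @param bins Discretization bins for the consistency measure (default 10).
#' @param model Classifier for the error measure (default `"dt"`).
#' @param cv_k Internal CV folds for the error measure (default 5).
#' @param seed Seed for the internal CV (default 1).
#' @return A [selection_result]; `$scores` holds the winning measure value.
#' @export
sfs <- function(fm, measure = c("consistency", "classifier_error"),
                max_exhaustive = 15L, bins = 10L, model = "dt", cv_k = 5L,
                seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  .check_two_classes(fm)
  measure <- match.arg(measure)
  F <- ncol(fm$X)
  Xd <- if (measure == "consistency")
    as.matrix(.discretize_matrix(fm$X, bins)) else NULL
  eval_fn <- if (measure == "consistency") {
    function(s) .incons_rate(Xd, fm$y, s)
  } else {
    function(s) .cv_error(fm, s, model, k = cv_k, seed = seed)
  }
  if (F <= max_exhaustive) {
    best <- NULL
    for (size in seq_len(F)) {
      combs <- utils::combn(F, size)
      for (j in seq_len(ncol(combs))) {
        s <- combs[, j]
        v <- eval_fn(s)
        if (is.null(best) || v < best$value - 1e-12) best <- list(set = s, value = v)
        # combn order already visits smaller sizes first and lexicographic
        # within size, so strict improvement implements the tie-break
      }
    }
  } else {
    message("sfs: ", F, " features exceeds exhaustive cap (", max_exhaustive,
            "); falling back to best-first search")
    res <- .best_first(F, eval_fn, maximize = FALSE)
    best <- list(set = res$set, value = res$score)
  }
  selection_result(paste0("sfs-", sub("_error", "", measure)),
                   colnames(fm$X)[best$set],
                   scores = stats::setNames(best$value, measure),
                   params = list(measure = measure, bins = bins,
                                 max_exhaustive = max_exhaustive,
                                 model = model, seed = seed,
                                 exhaustive = F <= max_exhaustive))
}

#' Symmetrical uncertainty between a discrete feature and the labels
#'
#' `SU = 2 (H(f) + H(l) - H(f,l)) / (H(f) + H(l))`, with entropies from
#' empirical frequencies: a normalized mutual information in `[0, 1]`,
#' symmetric in its arguments. Defined as 0 when either variable is
#' constant.
#'
#' @param f Discrete vector (integer codes or factor).
#' @param y Discrete vector of the same length.
#' @return SU in `[0, 1]`.
#' @export
symmetrical_uncertainty <- function(f, y) {
  stopifnot(length(f) == length(y))
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  pf <- table(f) / length(f)
  py <- table(y) / length(y)
  Hf <- H(as.numeric(pf)); Hy <- H(as.numeric(py))
  if (Hf == 0 || Hy == 0) return(0)
  pfy <- table(f, y) / length(f)
  Hfy <- H(as.numeric(pfy))
  max(0, min(1, 2 * (Hf + Hy - Hfy) / (Hf + Hy)))
}

#' INTERACT feature selection
#'
#' Ranks features by symmetrical uncertainty with the labels (descending),
#' then scans from the tail of the ranking and removes each feature whose
#' consistency contribution — the increase in inconsistency rate caused by
#' dropping it from the current set — does not exceed `c_threshold`.
#' Interacting features that are individually weak but jointly predictive
#' (e.g. XOR pairs) survive because removing either collapses consistency.
#'
#' @param fm A [feature_matrix] with both classes present.
#' @param c_threshold Consistency-contribution threshold (default 1e-4).
#' @param bins Discretization bins (default 10).
#' @return A [selection_result]; survivors are returned in SU order and
#'   `$scores` carries the per-feature SU values.
#' @export
interact_select <- function(fm, c_threshold = 1e-4, bins = 10L) {
  stopifnot(inherits(fm, "feature_matrix"))
  .check_two_classes(fm)
  Xd <- as.matrix(.discretize_matrix(fm$X, bins))
  F <- ncol(Xd)
  su <- vapply(seq_len(F), function(j) symmetrical_uncertainty(Xd[, j], fm$y), 0)
  names(su) <- colnames(fm$X)
  ranked <- order(-su)                        # descending SU
  current <- ranked
  for (f in rev(ranked)) {                    # backward scan from the tail
    if (length(current) == 1L) {
      # removing the last feature leaves the empty subset, whose rate is the
      # majority-class error; its contribution decides survival
      base <- .incons_rate(Xd, fm$y, current)
      empty_rate <- min(mean(fm$y == 1L), mean(fm$y == 0L))
      cc <- empty_rate - base
    } else {
      cc <- .incons_rate(Xd, fm$y, setdiff(current, f)) -
            .incons_rate(Xd, fm$y, current)
    }
    if (cc <= c_threshold) current <- setdiff(current, f)
  }
  selection_result("interact", colnames(fm$X)[current], scores = su,
                   params = list(c_threshold = c_threshold, bins = bins))
}
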