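# Fractal / chaotic descriptors f20-f22: correlation dimension of the
# delay-embedded segment (Grassberger-Procaccia), box-counting dimension of
# the normalized signal graph, and the generalized (Renyi) dimension D_q.
#
# The defining limits r -> 0 are not usable on 0.5-s windows (~100 samples);
# each dimension is instead the least-squares slope of the appropriate
# log-log curve over an automatically chosen scaling region, returned with
# fit diagnostics.

#' Delay embedding of a scalar series
#'
#' Maps a series to points `(x_i, x_{i+tau}, ..., x_{i+(m-1)tau})` in R^m.
#'
#' @param x Numeric vector.
#' @param m Embedding dimension (>= 1).
#' @param tau Delay in samples (>= 1).
#' @return A `(length(x) - (m-1)*tau) x m` matrix, one point per row.
#' @export
delay_embed <- function(x, m, tau) {
  x <- as.numeric(x)
  N <- length(x)
  m <- as.integer(m); tau <- as.integer(tau)
  if (m < 1L || tau < 1L) stop("need m >= 1 and tau >= 1")
  if ((m - 1L) * tau >= N)
    stop("embedding window (m-1)*tau = ", (m - 1L) * tau,
         " must be shorter than the series (", N, ")")
  n_pts <- N - (m - 1L) * tau
  out <- matrix(0, n_pts, m)
  for (j in seq_len(m)) out[, j] <- x[(j - 1L) * tau + seq_len(n_pts)]
  out
}

# first zero crossing of the autocorrelation, capped; standard heuristic for
# the embedding delay when none is prescribed
.acf_delay <- function(x, cap) {
  cap <- max(1L, as.integer(cap))
  if (stats::sd(x) == 0) return(1L)
  a <- stats::acf(x, lag.max = cap, plot = FALSE, demean = TRUE)$acf[-1L]
  z <- which(a <= 0)
  if (length(z)) max(1L, z[1L]) else cap
}

# best least-squares line over contiguous windows of >= min_pts points,
# chosen to maximize r^2 (ties: wider window, then earlier); cumulative-sum
# arithmetic keeps the search cheap
.scaling_fit <- function(lx, ly, min_pts = 5L) {
  n <- length(lx)
  min_pts <- min(min_pts, n)
  cx <- cumsum(lx); cy <- cumsum(ly)
  cxx <- cumsum(lx^2); cyy <- cumsum(ly^2); cxy <- cumsum(lx * ly)
  seg <- function(c, i, j) c[j] - if (i > 1L) c[i - 1L] else 0
  best <- list(slope = 0, r2 = -Inf, fit_range = c(1L, n), width = -1L)
  for (i in seq_len(n - min_pts + 1L)) {
    for (j in (i + min_pts - 1L):n) {
      k <- j - i + 1L
      sxx <- seg(cxx, i, j) - seg(cx, i, j)^2 / k
      syy <- seg(cyy, i, j) - seg(cy, i, j)^2 / k
      sxy <- seg(cxy, i, j) - seg(cx, i, j) * seg(cy, i, j) / k
      if (sxx <= 0) next
      slope <- sxy / sxx
      r2 <- if (syy <= 1e-300) 1 else sxy^2 / (sxx * syy)
      if (r2 > best$r2 + 1e-9 ||
          (abs(r2 - best$r2) <= 1e-9 && k > best$width)) {
        best <- list(slope = slope, r2 = r2, fit_range = c(i, j), width = k)
      }
    }
  }
  if (!is.finite(best$r2)) best <- list(slope = 0, r2 = 0,
                                        fit_range = c(1L, n), width = n)
  list(slope = best$slope, r2 = best$r2, fit_range = best$fit_range)
}

.scaling_result <- function(value, r_grid, y_values, fit, degenerate = FALSE) {
  structure(list(value = value, r_grid = r_grid, y_values = y_values,
                 slope = fit$slope, fit_range = fit$fit_range, r2 = fit$r2,
                 degenerate = degenerate),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> value=%.4f r2=%.4f over grid points [%d, %d]%s\n",
              x$value, x$r2, x$fit_range[1L], x$fit_range[2L],
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Correlation dimension (Grassberger-Procaccia)
#'
#' Delay-embeds the segment, computes the correlation integral
#' `C(r)` = fraction of distinct point pairs closer than `r` (Chebyshev
#' metric), and estimates the dimension as the slope of `ln C(r)` versus
#' `ln r` over the best-fitting scaling region.
#'
#' @param x Numeric vector (>= 20 embedded points after embedding).
#' @param m Embedding dimension (default 3).
#' @param tau Delay in samples; `NULL` (default) uses the first
#'   zero-crossing of the autocorrelation, capped at `length(x)/8`.
#' @param r_grid Radii; `NULL` (default) uses 16 log-spaced radii between
#'   the 2nd and 30th percentiles of the pairwise distances — small enough
#'   to stay below the saturation of the correlation integral (which biases
#'   the slope low on higher-dimensional sets), large enough that every
#'   radius still has pair statistics behind it.
#' @param n_r Number of radii when `r_grid` is `NULL`.
#' @return A `"scaling_fit"` with the estimate in `$value`; degenerate
#'   inputs (all embedded points identical) return slope 0 with
#'   `degenerate = TRUE`.
#' @export
correlation_dimension <- function(x, m = 3, tau = NULL, r_grid = NULL,
                                  n_r = 16L) {
  x <- as.numeric(x)
  if (is.null(tau)) tau <- .acf_delay(x, length(x) %/% 8L)
  pts <- delay_embed(x, m, tau)
  if (nrow(pts) < 20L) stop("need at least 20 embedded points")
  d <- as.numeric(stats::dist(pts, method = "maximum"))
  if (max(d) == 0)
    return(.scaling_result(0, numeric(0), numeric(0),
                           list(slope = 0, r2 = 0, fit_range = c(1L, 1L)),
                           degenerate = TRUE))
  if (is.null(r_grid)) {
    dpos <- d[d > 0]
    q <- stats::quantile(dpos, c(0.02, 0.30), names = FALSE)
    if (q[1L] <= 0) q[1L] <- min(dpos)
    r_grid <- exp(seq(log(q[1L]), log(q[2L]), length.out = n_r))
  }
  ds <- sort(d)
  C <- findInterval(r_grid * (1 - 1e-12), ds) / length(d)  # P(dist < r)
  keep <- C > 0
  if (sum(keep) < 2L)
    return(.scaling_result(0, r_grid, C,
                           list(slope = 0, r2 = 0, fit_range = c(1L, 1L)),
                           degenerate = TRUE))
  fit <- .scaling_fit(log(r_grid[keep]), log(C[keep]))
  .scaling_result(fit$slope, r_grid[keep], log(C[keep]), fit)
}

# Normalize the signal graph to the unit square and count occupied boxes of
# side r on a dyadic grid. The graph is treated as a polyline and densely
# resampled so boxes crossed between samples are counted too; occupancy
# fractions over the resampled points give the measure for D_q.
.graph_box_counts <- function(x, box_sizes, n_resample = 4096L) {
  N <- length(x)
  u <- (seq_len(N) - 1) / (N - 1)
  rng <- range(x)
  constant <- diff(rng) == 0
  ynorm <- if (constant) rep(0.5, N) else (x - rng[1L]) / diff(rng)
  t <- seq(0, 1, length.out = n_resample)
  yi <- stats::approx(u, ynorm, xout = t)$y
  counts <- lapply(box_sizes, function(r) {
    s <- max(1L, as.integer(round(1 / r)))
    ix <- pmin(floor(t * s), s - 1L)
    iy <- pmin(floor(yi * s), s - 1L)
    tab <- tabulate(ix * s + iy + 1L, nbins = s * s)
    tab[tab > 0L]
  })
  list(counts = counts, constant = constant, total = n_resample)
}

#' Box-counting dimension of the signal graph
#'
#' Normalizes the segment's graph (index vs. value) to the unit square,
#' counts occupied boxes `N(r)` on dyadic grids, and fits the slope of
#' `log N(r)` versus `log(1/r)`.
#'
#' @param x Numeric vector (length >= 16).
#' @param box_sizes Box side lengths as fractions of the unit square
#'   (default `1/2^(1:5)`).
#' @return A `"scaling_fit"`; a constant segment yields the dimension of a
#'   horizontal line (about 1) flagged `degenerate = TRUE`, and inputs whose
#'   occupancy does not vary with `r` yield slope 0, flagged.
#' @export
box_dimension <- function(x, box_sizes = 1 / 2^(1:5)) {
  x <- as.numeric(x)
  if (length(x) < 16L) stop("need at least 16 samples")
  bc <- .graph_box_counts(x, box_sizes)
  Nr <- vapply(bc$counts, length, 0L)
  if (stats::sd(log(Nr)) == 0)
    return(.scaling_result(0, box_sizes, log10(Nr),
                           list(slope = 0, r2 = 0,
                                fit_range = c(1L, length(Nr))),
                           degenerate = TRUE))
  fit <- .scaling_fit(log10(1 / box_sizes), log10(Nr),
                      min_pts = min(5L, length(Nr)))
  .scaling_result(fit$slope, box_sizes, log10(Nr), fit,
                  degenerate = bc$constant)
}

#' Generalized (Renyi) dimension of the signal graph
#'
#' Computes box-occupancy probabilities `p_i` of the normalized signal graph
#' and fits `(1/(q-1)) log10 sum(p_i^q)` against `log10 r`; at `q = 0` this
#' reduces exactly to the box-counting dimension, and `D_q` is non-increasing
#' in `q`.
#'
#' @param x Numeric vector (length >= 16).
#' @param q Moment order (default 2, the correlation-dimension member of the
#'   family). `q = 1` is the information-dimension limit and is not
#'   supported; request it explicitly via the limit if needed.
#' @param box_sizes Box side lengths (default `1/2^(1:5)`).
#' @return A `"scaling_fit"`.
#' @export
generalized_dimension <- function(x, q = 2, box_sizes = 1 / 2^(1:5)) {
  if (q == 1)
    stop("q = 1 is the information-dimension limit of D_q and is not ",
         "supported; use q values away from 1")
  x <- as.numeric(x)
  if (length(x) < 16L) stop("need at least 16 samples")
  bc <- .graph_box_counts(x, box_sizes)
  y <- vapply(bc$counts, function(cnt) {
    p <- cnt / bc$total
    log10(sum(p^q)) / (q - 1)
  }, 0)
  if (stats::sd(y) == 0)
    return(.scaling_result(0, box_sizes, y,
                           list(slope = 0, r2 = 0,
                                fit_range = c(1L, length(y))),
                           degenerate = TRUE))
  fit <- .scaling_fit(log10(box_sizes), y, min_pts = min(5L, length(y)))
  .scaling_result(fit$slope, box_sizes, y, fit, degenerate = bc$constant)
}

#' Chaotic feature triplet of a segment
#'
#' Convenience wrapper returning `f20_cd` (correlation dimension), `f21_bd`
#' (box dimension) and `f22_gd` (generalized dimension) as a one-row data
#' frame, sharing the box-count work between f21 and f22.
#'
#' @inheritParams correlation_dimension
#' @inheritParams generalized_dimension
#' @return One-row data frame with columns `f20_cd`, `f21_bd`, `f22_gd` and a
#'   logical `"degenerate"` attribute per feature.
#' @export
chaotic_features <- function(x, m = 3, tau = NULL, q = 2,
                             box_sizes = 1 / 2^(1:5)) {
  cd <- correlation_dimension(x, m = m, tau = tau)
  bc <- .graph_box_counts(as.numeric(x), box_sizes)
  Nr <- vapply(bc$counts, length, 0L)
  if (stats::sd(log(Nr)) == 0) {
    bd <- list(value = 0, degenerate = TRUE)
  } else {
    fit <- .scaling_fit(log10(1 / box_sizes), log10(Nr),
                        min_pts = min(5L, length(Nr)))
    bd <- list(value = fit$slope, degenerate = bc$constant)
  }
  yq <- vapply(bc$counts, function(cnt) {
    p <- cnt / bc$total
    log10(sum(p^q)) / (q - 1)
  }, 0)
  if (stats::sd(yq) == 0) {
    gd <- list(value = 0, degenerate = TRUE)
  } else {
    fit <- .scaling_fit(log10(box_sizes), yq, min_pts = min(5L, length(yq)))
    gd <- list(value = fit$slope, degenerate = bc$constant)
  }
  out <- data.frame(f20_cd = cd$value, f21_bd = bd$value, f22_gd = gd$value)
  attr(out, "degenerate") <- c(f20_cd = cd$degenerate, f21_bd = bd$degenerate,
                               f22_gd = gd$degenerate)
  out
}
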