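# Classifier harness (LDA, linear SVM, decision tree), stratified k-fold
# cross-validation, the confusion-matrix metric suite (sensitivity,
# specificity, accuracy, F-score, Cohen's kappa), the Fisher-criterion J1
# separability value, and per-feature screening statistics.

# stratified fold assignment: shuffle each class separately (seeded) and
# deal indices round-robin so every fold keeps both classes
.make_folds <- function(y, k, seed) {
  if (length(y) < k) stop("need at least k = ", k, " instances")
  set.seed(seed)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  if (any(tabulate(folds[y == 1L], k) == 0L) ||
      any(tabulate(folds[y == 0L], k) == 0L))
    stop("too few instances per class for ", k, " stratified folds")
  folds
}

#' Train a classifier and predict test labels
#'
#' Supports linear discriminant analysis (`"lda"`), a linear support vector
#' machine (`"lsvm"`, cost `C`), and a CART decision tree (`"dt"`, Gini
#' impurity, depth unlimited). Features are standardized with statistics
#' from the training fold only.
#'
#' @param model One of `"lda"`, `"lsvm"`, `"dt"`.
#' @param X_train,y_train Training matrix and 0/1 labels (both classes
#'   required).
#' @param X_test Test matrix with the same columns.
#' @param seed Seed (classifiers here are deterministic given the data, but
#'   the seed is set for reproducibility of any internal randomness).
#' @param cost SVM cost parameter (default 1).
#' @return Integer vector of predicted 0/1 labels for `X_test`.
#' @export
train_predict <- function(model = c("lda", "lsvm", "dt"), X_train, y_train,
                          X_test, seed = 1L, cost = 1) {
  model <- match.arg(model)
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  y_train <- as.integer(y_train)
  if (length(unique(y_train)) < 2L)
    stop("training fold contains a single class; cannot fit '", model, "'")
  mu <- colMeans(X_train)
  sdev <- apply(X_train, 2L, stats::sd)
  sdev[sdev == 0] <- 1
  Ztr <- sweep(sweep(X_train, 2L, mu), 2L, sdev, "/")
  Zte <- sweep(sweep(X_test, 2L, mu), 2L, sdev, "/")
  set.seed(seed)
  yf <- factor(y_train, levels = c(0L, 1L))
  pred <- switch(model,
    lda = {
      fit <- suppressWarnings(MASS::lda(Ztr, grouping = yf))
      stats::predict(fit, Zte)$class
    },
    lsvm = {
      fit <- e1071::svm(Ztr, yf, kernel = "linear", cost = cost,
                        scale = FALSE)
      stats::predict(fit, Zte)
    },
    dt = {
      df <- as.data.frame(Ztr); df$.y <- yf
      fit <- rpart::rpart(.y ~ ., data = df, method = "class")
      stats::predict(fit, as.data.frame(Zte), type = "class")
    })
  as.integer(as.character(pred))
}

#' Confusion matrix from truth and predictions
#'
#' @param truth,pred 0/1 vectors (1 = k-complex), or pass counts directly
#'   via `TP`, `FN`, `FP`, `TN`.
#' @param TP,FN,FP,TN Optional explicit counts (used when `truth` is
#'   missing).
#' @return A `"confusion_matrix"`: list with integer `TP`, `FN`, `FP`, `TN`.
#' @export
confusion_matrix <- function(truth, pred, TP = 0L, FN = 0L, FP = 0L, TN = 0L) {
  if (!missing(truth)) {
    truth <- as.integer(truth); pred <- as.integer(pred)
    stopifnot(length(truth) == length(pred))
    TP <- sum(truth == 1L & pred == 1L)
    FN <- sum(truth == 1L & pred == 0L)
    FP <- sum(truth == 0L & pred == 1L)
    TN <- sum(truth == 0L & pred == 0L)
  }
  counts <- c(TP = TP, FN = FN, FP = FP, TN = TN)
  if (any(counts < 0) || sum(counts) == 0)
    stop("confusion counts must be non-negative with a positive total")
  structure(as.list(as.integer(counts)) |> stats::setNames(names(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP=%d FN=%d FP=%d TN=%d\n",
              x$TP, x$FN, x$FP, x$TN))
  invisible(x)
}

#' Detection metrics from a confusion matrix
#'
#' Computes sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy,
#' the F-score `(1+b^2) TP / ((1+b^2) TP + b^2 FN + FP)` with tunable
#' `beta`, and Cohen's kappa `(p_o - p_e)/(1 - p_e)` with the marginal
#' chance agreement `p_e`. Division-by-zero branches return 0 and are
#' flagged rather than propagating NaN.
#'
#' @param cm A [confusion_matrix].
#' @param beta F-score weight; `beta > 1` emphasizes recall of true
#'   k-complexes (default 1).
#' @return One-row data frame `sensitivity`, `specificity`, `accuracy`,
#'   `fscore`, `kappa`, with a logical `"flags"` attribute naming any
#'   degenerate (0-defaulted) entries.
#' @export
metrics <- function(cm, beta = 1) {
  stopifnot(inherits(cm, "confusion_matrix"))
  TP <- cm$TP; FN <- cm$FN; FP <- cm$FP; TN <- cm$TN
  n <- TP + FN + FP + TN
  sdiv <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- sdiv(TP, TP + FN)
  spec <- sdiv(TN, TN + FP)
  acc <- (TP + TN) / n
  fs <- sdiv((1 + beta^2) * TP, (1 + beta^2) * TP + beta^2 * FN + FP)
  pe <- ((TP + FN) * (TP + FP) + (FP + TN) * (FN + TN)) / n^2
  kap <- if (pe >= 1) NA_real_ else (acc - pe) / (1 - pe)
  vals <- c(sensitivity = sens, specificity = spec, accuracy = acc,
            fscore = fs, kappa = kap)
  flags <- names(vals)[is.na(vals)]
  vals[is.na(vals)] <- 0
  out <- as.data.frame(as.list(vals))
  attr(out, "flags") <- flags
  attr(out, "beta") <- beta
  out
}

#' Stratified k-fold cross-validated detection
#'
#' Splits instances into stratified folds, optionally runs a feature
#' selector on each training fold only (no test-fold leakage), standardizes
#' with training-fold statistics, trains the classifier, and scores the held
#' out fold. Reports per-fold metrics and their mean and standard deviation.
#'
#' @param fm A [feature_matrix] with labels.
#' @param model `"lda"`, `"lsvm"` or `"dt"` (default `"dt"`).
#' @param k Number of folds (default 5).
#' @param seed Seed controlling fold assignment and classifier internals.
#' @param selector Optional selector: a function taking a training-fold
#'   [feature_matrix] and returning a [selection_result] or a character
#'   vector of feature names.
#' @param beta F-score beta (default 1).
#' @return A `"metric_bundle"`: list with `folds` (per-fold metric data
#'   frame), `mean`, `sd`, `confusions`, `fold_assignment`, `selected`
#'   (per-fold selected features when a selector is used), `model`, `seed`.
#' @export
crossvalidate <- function(fm, model = "dt", k = 5L, seed = 1L,
                          selector = NULL, beta = 1) {
  stopifnot(inherits(fm, "feature_matrix"))
  .check_two_classes(fm)
  folds <- .make_folds(fm$y, k, seed)
  per_fold <- vector("list", k)
  confs <- vector("list", k)
  selected <- vector("list", k)
  for (fi in seq_len(k)) {
    test <- folds == fi
    Xtr <- fm$X[!test, , drop = FALSE]; ytr <- fm$y[!test]
    Xte <- fm$X[test, , drop = FALSE];  yte <- fm$y[test]
    feats <- colnames(fm$X)
    if (!is.null(selector)) {
      sel <- selector(feature_matrix(Xtr, ytr))
      feats <- if (inherits(sel, "selection_result")) sel$selected else sel
      if (!length(feats)) feats <- colnames(fm$X)   # empty selection: keep all
      selected[[fi]] <- feats
    }
    pred <- train_predict(model, Xtr[, feats, drop = FALSE], ytr,
                          Xte[, feats, drop = FALSE], seed = seed)
    confs[[fi]] <- confusion_matrix(yte, pred)
    per_fold[[fi]] <- metrics(confs[[fi]], beta = beta)
  }
  ftab <- do.call(rbind, per_fold)
  structure(list(folds = ftab,
                 mean = colMeans(ftab),
                 sd = apply(ftab, 2L, stats::sd),
                 confusions = confs,
                 fold_assignment = folds,
                 selected = if (is.null(selector)) NULL else selected,
                 model = model, k = k, seed = seed, beta = beta),
            class = "metric_bundle")
}

#' @export
print.metric_bundle <- function(x, ...) {
  cat(sprintf("<metric_bundle> %s, %d-fold CV (seed %d)\n",
              x$model, x$k, x$seed))
  for (m in names(x$mean))
    cat(sprintf("  %-12s %.4f +/- %.4f\n", m, x$mean[[m]], x$sd[[m]]))
  invisible(x)
}

#' Fisher separability criterion J1
#'
#' `J1 = tr(Sw^-1 Sm)` with `Sw` the pooled within-class scatter and `Sm`
#' the between-class scatter, both normalized by the number of instances so
#' the value is stable in sample size. Larger J1 means better class
#' separability of the feature subset.
#'
#' @param fm A [feature_matrix] with labels.
#' @param subset Optional feature names/indices (default all).
#' @return J1 (>= 0, up to numerical ridge effects). A singular `Sw` is
#'   ridged with `1e-8 * mean(diag(Sw)) * I` and flagged via a warning;
#'   single-class input returns 0.
#' @export
j1_value <- function(fm, subset = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(fm$y)) stop("feature matrix is unlabeled")
  X <- if (is.null(subset)) fm$X else .fm_subset(fm, subset)$X
  y <- fm$y
  if (length(unique(y)) < 2L) return(0)
  n <- nrow(X); p <- ncol(X)
  mu <- colMeans(X)
  Sw <- matrix(0, p, p); Sm <- matrix(0, p, p)
  for (cls in unique(y)) {
    Xi <- X[y == cls, , drop = FALSE]
    mi <- colMeans(Xi)
    Ci <- sweep(Xi, 2L, mi)
    Sw <- Sw + crossprod(Ci) / n
    Sm <- Sm + (nrow(Xi) / n) * tcrossprod(mi - mu)
  }
  inv <- tryCatch(solve(Sw), error = function(e) NULL)
  if (is.null(inv)) {
    warning("singular within-class scatter; adding ridge")
    Sw <- Sw + diag(1e-8 * mean(diag(Sw)) + 1e-12, p)
    inv <- solve(Sw)
  }
  sum(diag(inv %*% Sm))
}

#' Per-feature screening statistics
#'
#' For every feature: Spearman rank correlation with the binary label, the
#' one-way ANOVA F statistic and p-value across the two classes, and
#' significance flags at 0.05 (`sig_05`) and 0.005 (`sig_005`).
#'
#' @param fm A [feature_matrix] with labels (>= 3 instances per class).
#' @return Data frame with columns `feature`, `rho`, `F`, `p`, `sig_05`,
#'   `sig_005`, `degenerate` (TRUE for constant features, whose rho is
#'   reported as 0).
#' @export
screen_features <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  .check_two_classes(fm)
  if (min(table(fm$y)) < 3L) stop("need at least 3 instances per class")
  g <- factor(fm$y)
  rows <- lapply(seq_len(ncol(fm$X)), function(j) {
    x <- fm$X[, j]
    if (stats::sd(x) == 0) {
      return(data.frame(feature = colnames(fm$X)[j], rho = 0, F = 0, p = 1,
                        sig_05 = FALSE, sig_005 = FALSE, degenerate = TRUE))
    }
    rho <- suppressWarnings(stats::cor(x, fm$y, method = "spearman"))
    av <- stats::anova(stats::lm(x ~ g))
    data.frame(feature = colnames(fm$X)[j], rho = rho,
               F = av$`F value`[1L], p = av$`Pr(>F)`[1L],
               sig_05 = av$`Pr(>F)`[1L] < 0.05,
               sig_005 = av$`Pr(>F)`[1L] < 0.005, degenerate = FALSE)
  })
  do.call(rbind, rows)
}
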