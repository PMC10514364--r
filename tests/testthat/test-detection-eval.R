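test_that("metrics reproduce the hand-derived bundle and flag degeneracies", {
  m <- metrics(confusion_matrix(TP = 40, FN = 10, FP = 5, TN = 45))
  expect_equal(m$sensitivity, 0.80)
  expect_equal(m$specificity, 0.90)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$fscore, 80 / 95)
  expect_equal(m$kappa, 0.70)

  # all-positive predictions on all-positive truth: kappa degenerate
  mp <- metrics(confusion_matrix(TP = 10, FN = 0, FP = 0, TN = 0))
  expect_equal(mp$sensitivity, 1)
  expect_equal(mp$accuracy, 1)
  expect_equal(mp$fscore, 1)
  expect_true("kappa" %in% attr(mp, "flags"))
  expect_true("specificity" %in% attr(mp, "flags"))

  # perfect mixed-class agreement: kappa = 1
  expect_equal(metrics(confusion_matrix(c(1, 1, 0, 0), c(1, 1, 0, 0)))$kappa, 1)

  # beta weighting follows the F-score formula
  m2 <- metrics(confusion_matrix(TP = 30, FN = 20, FP = 10, TN = 40),
                beta = 2)
  expect_equal(m2$fscore, 5 * 30 / (5 * 30 + 4 * 20 + 10))
})

test_that("metrics agree with the oracle on every confusion matrix n <= 6", {
  for (n in 1:6) {
    for (TP in 0:n) for (FN in 0:(n - TP)) for (FP in 0:(n - TP - FN)) {
      TN <- n - TP - FN - FP
      m <- metrics(confusion_matrix(TP = TP, FN = FN, FP = FP, TN = TN))
      o <- oracle_metrics(TP, FN, FP, TN)
      expect_equal(unlist(m), o, ignore_attr = TRUE)
      # accuracy identity: acc * n = sens * P + spec * N (when defined)
      if (TP + FN > 0 && TN + FP > 0)
        expect_equal(m$accuracy * n,
                     m$sensitivity * (TP + FN) + m$specificity * (TN + FP))
    }
  }
})

test_that("kappa is near zero for label-independent predictions", {
  set.seed(50)
  kappas <- replicate(200, {
    truth <- rbinom(60, 1, 0.5)
    pred <- rbinom(60, 1, 0.5)
    metrics(confusion_matrix(truth, pred))$kappa
  })
  expect_lt(abs(mean(kappas)), 0.05)
})

test_that("all three classifiers separate well-spaced blobs perfectly", {
  set.seed(61)
  n <- 200
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(a = y * 10 + rnorm(n, sd = 0.3),
             b = -y * 10 + rnorm(n, sd = 0.3))
  tr <- c(1:50, 101:150); te <- setdiff(seq_len(n), tr)
  for (model in c("lda", "lsvm", "dt")) {
    pred <- train_predict(model, X[tr, ], y[tr], X[te, ], seed = 1)
    expect_equal(pred, y[te], info = model)
  }
  # decision tree memorizes a resubstituted labeled set
  pred <- train_predict("dt", X, y, X, seed = 1)
  expect_equal(pred, y)

  expect_error(train_predict("lda", X[1:50, ], y[1:50], X), "single class")
})

test_that("label-permuted blobs give chance-level CV accuracy", {
  set.seed(71)
  n <- 200
  y <- sample(rep(c(0L, 1L), each = n / 2))
  X <- cbind(a = rnorm(n), b = rnorm(n))
  b <- crossvalidate(feature_matrix(X, y), "lda", seed = 9)
  expect_lt(abs(b$mean[["accuracy"]] - 0.5), 0.15)  # binomial noise band
})

test_that("cross-validation partitions, stratifies, and is deterministic", {
  fm <- make_blobs(n = 100, seed = 5)
  b1 <- crossvalidate(fm, "dt", k = 5, seed = 3)
  b2 <- crossvalidate(fm, "dt", k = 5, seed = 3)
  expect_identical(b1, b2)

  folds <- b1$fold_assignment
  expect_equal(sort(unique(folds)), 1:5)
  expect_equal(length(folds), 100L)
  for (fi in 1:5) {
    expect_gt(sum(fm$y[folds == fi] == 1L), 0)
    expect_gt(sum(fm$y[folds == fi] == 0L), 0)
  }

  # perfect feature -> accuracy 1 in every fold
  yp <- rep(c(0L, 1L), each = 30)
  fmp <- feature_matrix(cbind(f = as.numeric(yp),
                              g = rnorm(60)), yp)
  bp <- crossvalidate(fmp, "dt", seed = 2)
  expect_true(all(bp$folds$accuracy == 1))

  expect_error(crossvalidate(make_blobs(n = 6, seed = 1), k = 5),
               "folds|instances")
})

test_that("selectors are fit on training folds only", {
  fm <- make_blobs(n = 100, seed = 8)
  seen <- list()
  spy <- function(fm_train) {
    seen[[length(seen) + 1L]] <<- fm_train
    colnames(fm_train$X)
  }
  b <- crossvalidate(fm, "dt", k = 5, seed = 4, selector = spy)
  expect_length(seen, 5L)
  for (fi in 1:5) {
    test_idx <- which(b$fold_assignment == fi)
    expect_equal(nrow(seen[[fi]]$X), 100L - length(test_idx))
    # altering test-fold rows cannot reach the selector: its input equals
    # the training rows exactly
    expect_equal(seen[[fi]]$X, fm$X[-test_idx, , drop = FALSE])
  }
})

test_that("J1 matches closed forms for Gaussian classes", {
  # identical distributions -> J1 ~ 0
  set.seed(81)
  X <- matrix(rnorm(2000), ncol = 2)
  y <- rep(c(0L, 1L), each = 500)
  expect_lt(j1_value(feature_matrix(X, y)), 0.02)

  # 1-D, means +/-1, unit variance, equal sizes -> J1 -> 1
  n <- 20000
  x1 <- matrix(c(rnorm(n / 2, 1), rnorm(n / 2, -1)), ncol = 1)
  yy <- rep(c(1L, 0L), each = n / 2)
  j1 <- j1_value(feature_matrix(x1, yy))
  expect_lt(abs(j1 - 1), 0.05)

  # doubling the separation quadruples J1 (ratio test on the same draws)
  base <- rnorm(n)
  mk <- function(d) matrix(base + d * (2 * yy - 1), ncol = 1)
  r <- j1_value(feature_matrix(mk(2), yy)) /
       j1_value(feature_matrix(mk(1), yy))
  expect_lt(abs(r - 4), 0.4)
})

test_that("feature screening flags discriminative features", {
  set.seed(91)
  n <- 100
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(strong = y * 3 + rnorm(n, sd = 0.2),
             none = rnorm(n),
             flat = rep(1, n))
  sc <- screen_features(feature_matrix(X, y))
  expect_equal(sc$feature, c("strong", "none", "flat"))

  # all class-1 values above all class-0 values -> maximal |rho| for binary y
  stopifnot(min(X[y == 1, 1]) > max(X[y == 0, 1]))
  expect_equal(abs(sc$rho[1]), cor(rank(X[, 1]), rank(y)))
  expect_true(sc$sig_005[1])
  expect_false(sc$sig_05[2] && sc$sig_005[2])
  expect_true(sc$degenerate[3])
  expect_equal(sc$rho[3], 0)

  # two-class ANOVA F equals the squared pooled t statistic
  tt <- t.test(X[y == 1, 1], X[y == 0, 1], var.equal = TRUE)
  expect_equal(sc$F[1], unname(tt$statistic^2))
})

test_that("screening p-values are uniform under the null", {
  set.seed(111)
  n <- 60
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * 200), n, 200)
  colnames(X) <- paste0("f", 1:200)
  sc <- screen_features(feature_matrix(X, y))
  expect_lt(abs(mean(sc$sig_05) - 0.05), 0.05)
  expect_gt(mean(sc$p > 0.5), 0.3)
})
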