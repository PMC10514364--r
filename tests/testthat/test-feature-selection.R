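test_that("relieff weights track class-discriminating features", {
  set.seed(2)
  n <- 150
  y <- rep(c(0L, 1L), length.out = n)
  X <- cbind(label_copy = as.numeric(y),
             noise1 = rnorm(n), noise2 = rnorm(n),
             constant = rep(3, n))
  fm <- feature_matrix(X, y)
  res <- relieff(fm, k_neighbors = 10, seed = 7)
  w <- res$params$raw_weights
  expect_equal(unname(w["constant"]), 0)           # diff identically 0
  expect_equal(names(which.max(w)), "label_copy")
  expect_true("label_copy" %in% res$selected)
  expect_equal(unname(res$scores["label_copy"]), 1) # top after min-max

  # permuting labels collapses the separation signal
  set.seed(99)
  fm_perm <- feature_matrix(X[, 1:3], sample(y))
  res_perm <- relieff(fm_perm, k_neighbors = 10, seed = 7)
  expect_lt(res_perm$params$raw_weights["label_copy"],
            w["label_copy"])
  expect_lte(length(res_perm$selected), length(res$selected))

  expect_error(relieff(feature_matrix(X, rep(1L, n))), "both classes")
})

test_that("relieff is deterministic under a seed and robust to column order", {
  fm <- make_blobs(seed = 12)
  a <- relieff(fm, num_samples = 50, seed = 5)
  b <- relieff(fm, num_samples = 50, seed = 5)
  expect_identical(a$scores, b$scores)

  perm <- c(3, 1, 4, 2)
  fm2 <- feature_matrix(fm$X[, perm], fm$y)
  c2 <- relieff(fm2, seed = 5)
  c1 <- relieff(fm, seed = 5)
  expect_equal(sort(c1$selected), sort(c2$selected))
  expect_equal(c1$scores[colnames(fm2$X)], c2$scores)
})

test_that("cfs merit matches hand evaluation and prefers complementarity", {
  # single feature: merit is the feature-class correlation
  expect_equal(kcdetect:::.cfs_merit(1, cfl = 0.8, cff = matrix(1)), 0.8)
  # two redundant features: no gain
  cff <- matrix(c(1, 1, 1, 1), 2)
  expect_equal(kcdetect:::.cfs_merit(1:2, c(0.8, 0.8), cff), 1.6 / sqrt(4))
  # two uncorrelated features: merit exceeds either singleton
  cff0 <- diag(2); cff0[1, 2] <- cff0[2, 1] <- 0
  expect_equal(kcdetect:::.cfs_merit(1:2, c(0.8, 0.8), cff0), 1.6 / sqrt(2))
  expect_gt(1.6 / sqrt(2), 0.8)

  # search finds the informative pair among noise
  set.seed(44)
  n <- 200
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(s1 = y + rnorm(n, sd = 0.5),
             s2 = -y + rnorm(n, sd = 0.5),
             n1 = rnorm(n), n2 = rnorm(n))
  res <- cfs(feature_matrix(X, y))
  expect_true(all(c("s1", "s2") %in% res$selected))
  expect_false(any(c("n1", "n2") %in% res$selected))

  # zero-variance feature warns and is ignored
  expect_warning(cfs(feature_matrix(cbind(X, z = rep(1, n)), y)),
                 "zero-variance")
})

test_that("inconsistency rate equals the grouping oracle on crafted patterns", {
  # patterns (A,1),(A,1),(A,0),(B,0) -> one inconsistent instance of 4
  fm <- feature_matrix(matrix(c(1, 1, 1, 2), ncol = 1,
                              dimnames = list(NULL, "f")),
                       c(1L, 1L, 0L, 0L))
  expect_equal(inconsistency_rate(fm, "f"), 1 / 4)

  # perfectly separating subset -> 0
  fm2 <- make_blobs(seed = 3, sep = 10)
  expect_equal(inconsistency_rate(fm2, "signal1", bins = 2), 0)

  # 50/50 patterns -> rate 0.5
  fm3 <- feature_matrix(matrix(rep(c(1, 2), each = 10), ncol = 1,
                               dimnames = list(NULL, "f")),
                        rep(c(0L, 1L), 10))
  expect_equal(inconsistency_rate(fm3, "f"), 0.5)
})

test_that("inconsistency rate matches the oracle and is monotone (random)", {
  set.seed(202)
  for (rep in 1:60) {
    n <- sample(10:50, 1L)
    F <- sample(2:5, 1L)
    X <- matrix(sample(1:3, n * F, replace = TRUE), n, F)
    colnames(X) <- paste0("f", seq_len(F))
    y <- sample(0:1, n, replace = TRUE)
    if (length(unique(y)) < 2) next
    fm <- feature_matrix(X, y)
    Xd <- apply(X, 2, discretize_ef, bins = 10)
    # oracle equality on a random subset
    s <- sample(F, sample(F, 1L))
    expect_equal(inconsistency_rate(fm, s),
                 oracle_incons(Xd[, s, drop = FALSE], y))
    # monotone non-increase as features are added
    rates <- vapply(seq_len(F), function(k)
      inconsistency_rate(fm, seq_len(k)), 0)
    expect_true(all(diff(rates) <= 1e-12))
  }
})

test_that("exhaustive subset search equals the brute-force oracle", {
  set.seed(303)
  for (rep in 1:25) {
    n <- sample(15:40, 1L)
    F <- sample(2:6, 1L)
    X <- matrix(sample(1:3, n * F, replace = TRUE), n, F)
    colnames(X) <- paste0("f", seq_len(F))
    y <- sample(0:1, n, replace = TRUE)
    if (length(unique(y)) < 2) next
    fm <- feature_matrix(X, y)
    res <- sfs(fm, "consistency")
    Xd <- apply(X, 2, discretize_ef, bins = 10)
    oracle <- oracle_best_subset(Xd, y)
    expect_equal(match(res$selected, colnames(X)), oracle$set)
    expect_equal(unname(res$scores), oracle$value)
  }
})

test_that("subset search solves XOR and singles out perfect features", {
  # XOR: individually useless, jointly perfect
  a <- rep(c(0, 1), 40); b <- rep(c(0, 0, 1, 1), 20)
  y <- as.integer(xor(a, b))
  set.seed(6)
  fm <- feature_matrix(cbind(fa = a, fb = b, fc = rnorm(80)), y)
  res <- sfs(fm, "consistency")
  expect_setequal(res$selected, c("fa", "fb"))
  expect_equal(unname(res$scores), 0)

  # one perfectly consistent feature -> singleton, rate 0
  fm2 <- feature_matrix(cbind(good = y, junk = rep(1:2, 40)), y)
  expect_equal(sfs(fm2, "consistency")$selected, "good")
})

test_that("classifier-error measure picks the informative feature", {
  fm <- make_blobs(n = 100, sep = 4, seed = 10)
  res <- sfs(fm, "classifier_error", model = "dt", seed = 3)
  expect_true(any(c("signal1", "signal2") %in% res$selected))
  expect_lt(unname(res$scores), 0.1)
})

test_that("best-first fallback engages above the exhaustive cap", {
  fm <- make_blobs(n = 80, sep = 6, noise_features = 4, seed = 2)
  expect_message(res <- sfs(fm, "consistency", max_exhaustive = 3),
                 "best-first")
  expect_false(res$params$exhaustive)
  expect_gt(length(res$selected), 0)
})

test_that("symmetrical uncertainty has its analytic values and symmetry", {
  y <- rep(c(0L, 1L), each = 20)
  expect_equal(symmetrical_uncertainty(y, y), 1)

  # exact product joint -> independence -> 0
  f <- rep(c(1, 2), 20)
  expect_equal(symmetrical_uncertainty(f, y), 0)

  # joint counts [[2,1],[1,2]]
  f2 <- c(1, 1, 1, 2, 2, 2); y2 <- c(0, 0, 1, 0, 1, 1)
  expect_equal(symmetrical_uncertainty(f2, y2),
               oracle_su(matrix(c(2, 1, 1, 2), 2)))

  # symmetry and [0,1] bounds on random tables
  set.seed(404)
  for (rep in 1:30) {
    f <- sample(1:3, 40, replace = TRUE)
    g <- sample(1:4, 40, replace = TRUE)
    su <- symmetrical_uncertainty(f, g)
    expect_equal(su, symmetrical_uncertainty(g, f))
    expect_gte(su, 0); expect_lte(su, 1)
  }
  expect_equal(symmetrical_uncertainty(rep(1, 10), rep(0:1, 5)), 0)
})

test_that("interact keeps interacting features and drops pure noise", {
  a <- rep(c(0, 1), 50); b <- rep(c(0, 0, 1, 1), 25)
  y <- as.integer(xor(a, b))
  set.seed(15)
  fm <- feature_matrix(cbind(fa = a, fb = b, noise = rnorm(100)), y)
  res <- interact_select(fm)
  expect_true(all(c("fa", "fb") %in% res$selected))
  expect_false("noise" %in% res$selected)

  # single informative feature survives
  y2 <- rep(c(0L, 1L), each = 30)
  fm2 <- feature_matrix(matrix(as.numeric(y2), ncol = 1,
                               dimnames = list(NULL, "f")), y2)
  expect_equal(interact_select(fm2)$selected, "f")
})

test_that("selection sets are invariant to feature column order", {
  a <- rep(c(0, 1), 50); b <- rep(c(0, 0, 1, 1), 25)
  y <- as.integer(xor(a, b))
  set.seed(25)
  X <- cbind(fa = a, fb = b, n1 = rnorm(100), n2 = rnorm(100))
  fm1 <- feature_matrix(X, y)
  fm2 <- feature_matrix(X[, c(4, 2, 1, 3)], y)
  for (fn in list(function(fm) sfs(fm, "consistency"),
                  interact_select,
                  cfs)) {
    expect_setequal(fn(fm1)$selected, fn(fm2)$selected)
  }
})
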