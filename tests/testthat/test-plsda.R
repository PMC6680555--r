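test_that("linearly separable two-class data is fit perfectly with A = 1", {
  d <- separable_classes(n_per = 15, p = 4, delta = 8)
  m <- fit_plsda(d$X, d$labels, A = 1)
  expect_identical(m$A, 1L)
  expect_equal(mean(plsda_classes(m, d$X) == d$labels), 1)
})

test_that("full-rank fit reproduces Y exactly (R2 = 1)", {
  set.seed(2)
  X <- matrix(rnorm(30), 6, 5)
  labels <- c(1, 1, 2, 2, 3, 3)
  m <- fit_plsda(X, labels, A = 5)
  q <- quality_metrics(m, X, labels, folds = 3)
  expect_equal(q$R2, 1, tolerance = 1e-8)
  expect_equal(q$RMSEE, 0, tolerance = 1e-8)
})

test_that("predictions agree with an independent PLS2 implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(3)
  X <- matrix(rnorm(24), 6, 4)
  colnames(X) <- paste0("V", 1:4)
  labels <- c(1, 1, 2, 2, 3, 3)
  A <- 2
  m <- fit_plsda(X, labels, A = A)
  Y <- irfuse:::one_hot(labels, 1:3)
  ref <- mixOmics::pls(X, Y, ncomp = A, scale = FALSE, mode = "regression")
  pred <- predict(ref, newdata = X)$predict[, , A]
  expect_equal(unname(irfuse:::predict_plsda_raw(m, X)), unname(pred),
               tolerance = 1e-8)
})

test_that("class scores are clipped, renormalised probabilities", {
  d <- separable_classes(n_per = 12, p = 5, delta = 6)
  m <- fit_plsda(d$X, d$labels, A = 2)
  s <- plsda_scores(m, d$X)
  expect_true(all(s >= 0))
  expect_equal(rowSums(s), rep(1, nrow(s)), tolerance = 1e-9)
  # near-one-hot for a well-fit calibration sample
  expect_gt(max(s[1, ]), 0.8)
  # argmax of scores equals argmax of raw Y when all entries are positive
  raw <- irfuse:::predict_plsda_raw(m, d$X)
  pos <- apply(raw, 1, function(r) all(r > 0))
  expect_identical(max.col(s[pos, , drop = FALSE]),
                   max.col(raw[pos, , drop = FALSE]))
})

test_that("RMSEP matches a hand computation", {
  d <- separable_classes(n_per = 10, p = 4, delta = 4)
  m <- fit_plsda(d$X, d$labels, A = 2)
  set.seed(8)
  Xv <- d$X + rnorm(length(d$X), 0, 0.1)
  q <- quality_metrics(m, d$X, d$labels, X_val = Xv, labels_val = d$labels,
                       folds = 5)
  Yv <- irfuse:::one_hot(d$labels, 1:2)
  Yhat <- irfuse:::predict_plsda_raw(m, Xv)
  expect_equal(q$RMSEP, sqrt(sum((Yv - Yhat)^2) / (nrow(Yv) * 2)))
  expect_gte(q$RMSEP, 0)
})

test_that("Q2 never exceeds R2 across random draws", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(30 * 8), 30, 8)
    labels <- rep(1:3, each = 10)
    X[, 1] <- X[, 1] + labels
    m <- fit_plsda(X, labels, A = 3, seed = seed)
    q <- quality_metrics(m, X, labels, folds = 5, seed = seed)
    expect_lte(q$Q2, q$R2 + 1e-10)
  }
})

test_that("VIP satisfies its sum identity and a brute-force evaluation", {
  set.seed(9)
  X <- matrix(rnorm(20 * 5), 20, 5)
  labels <- rep(1:2, each = 10)
  X[, 2] <- X[, 2] + labels * 2
  m <- fit_plsda(X, labels, A = 3)
  v <- vip(m)
  expect_equal(sum(v^2), 5, tolerance = 1e-8)
  # independent evaluation of the formula from the stored decomposition
  core <- m$core
  p <- nrow(core$W)
  ssy <- vapply(seq_len(core$A), function(a)
    core$TT[a] * sum(core$Q[, a]^2), numeric(1))
  brute <- vapply(seq_len(p), function(j) {
    num <- sum(vapply(seq_len(core$A), function(a)
      ssy[a] * (core$W[j, a] / sqrt(sum(core$W[, a]^2)))^2, numeric(1)))
    sqrt(p * num / sum(ssy))
  }, numeric(1))
  expect_equal(v, brute, tolerance = 1e-10)
  # single-component model: VIP = sqrt(p) * |w| for unit-norm weights
  m1 <- fit_plsda(X, labels, A = 1)
  expect_equal(vip(m1), sqrt(p) * abs(m1$core$W[, 1]) /
                 sqrt(sum(m1$core$W[, 1]^2)), tolerance = 1e-10)
})

test_that("permutation test includes the unpermuted point and flags overfit", {
  d <- separable_classes(n_per = 14, p = 6, delta = 5)
  pt <- permutation_test(d$X, d$labels, A = 2, n_perm = 20, seed = 1,
                         folds = 5)
  expect_error(permutation_test(d$X, d$labels, A = 2, n_perm = 5), "20")
  base <- pt$points[pt$points$perm == 0, ]
  expect_equal(unique(base$corr), 1)
  expect_equal(unique(base$R2), pt$R2)
  # separable data: permuted labels predict poorly at zero correlation
  expect_true(all(pt$intercepts$Q2_intercept < pt$Q2))
  expect_false(pt$overfit)
})
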