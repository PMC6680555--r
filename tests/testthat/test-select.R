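test_that("Kaiser-rule PCA keeps the expected components", {
  set.seed(1)
  z <- rnorm(50)
  X <- cbind(z, z + rnorm(50, 0, 1e-8))  # two perfectly correlated variables
  sel <- pca_extract(X)
  expect_identical(sel$n_kept, 1L)
  expect_equal(sel$eigenvalues[1], 2, tolerance = 1e-3)
  # eigenvalue sum equals p for correlation PCA with n > p
  set.seed(2)
  Xn <- matrix(rnorm(500 * 5), 500, 5)
  seln <- pca_extract(Xn)
  expect_equal(sum(seln$eigenvalues), 5, tolerance = 1e-10)
  expect_lte(seln$n_kept, 4)  # iid noise: roughly half, never all
  # zero-variance column dropped with a warning
  expect_warning(pca_extract(cbind(Xn, 0)), "zero-variance")
})

test_that("kept components match an independent eigendecomposition", {
  set.seed(3)
  X <- matrix(rnorm(60), 10, 6)
  sel <- pca_extract(X)
  Z <- scale(X)
  ev <- eigen(cor(X), symmetric = TRUE)
  k <- sum(ev$values > 1)
  expect_identical(sel$n_kept, as.integer(k))
  expect_equal(sel$eigenvalues, ev$values, tolerance = 1e-8)
  # reconstruction error of the kept subspace agrees with the oracle
  recon <- function(scores, load) scores %*% t(load)
  r1 <- sum((Z - recon(sel$scores, sel$loadings))^2)
  sc2 <- Z %*% ev$vectors[, 1:k]
  r2 <- sum((Z - sc2 %*% t(ev$vectors[, 1:k]))^2)
  expect_equal(r1, r2, tolerance = 1e-8)
  # projector reproduces the training scores
  expect_equal(unname(sel$project(X)), unname(sel$scores), tolerance = 1e-8)
})

test_that("number of kept PCs is invariant to column order", {
  set.seed(4)
  X <- matrix(rnorm(40 * 8), 40, 8)
  X[, 1:3] <- X[, 1:3] + rowMeans(X[, 4:6])
  a <- pca_extract(X)
  b <- pca_extract(X[, sample(8)])
  expect_identical(a$n_kept, b$n_kept)
})

test_that("RFE recovers planted informative variables and reports regions", {
  set.seed(5)
  n <- 90; p <- 210
  X <- matrix(rnorm(n * p), n, p)
  labels <- rep(1:3, each = 30)
  X[, 1:10] <- X[, 1:10] + outer(labels, rep(1, 10)) * 1.2
  sel <- rfe_select(X, labels, seed = 1, tune = FALSE, folds = 5)
  expect_gte(sum(1:10 %in% sel$indices), 8)
  expect_identical(nrow(sel$curve), length(seq(p, 5, by = -5)))
  expect_true(all(c("size", "error", "se") %in% names(sel$curve)))
  expect_true(all(sel$regions$region %in%
                    c("irrelevant", "interference", "important")))
  expect_error(rfe_select(X[, 1:4], labels, step = 5), "step")
  # same seed, same result
  sel2 <- rfe_select(X, labels, seed = 1, tune = FALSE, folds = 5)
  expect_identical(sel$indices, sel2$indices)
})

test_that("Boruta confirms planted signal and rejects pure noise", {
  set.seed(6)
  n <- 60; p <- 50
  noise <- matrix(rnorm(n * p), n, p)
  labels <- rep(1:2, each = 30)
  bo0 <- boruta_select(noise, labels, seed = 1)
  expect_length(bo0$confirmed, 0)
  # strongly informative variable is confirmed quickly
  X <- noise
  X[, 7] <- X[, 7] + labels * 3
  bo1 <- boruta_select(X, labels, seed = 1, max_iter = 20)
  expect_true(7 %in% bo1$confirmed)
  expect_lte(bo1$n_iter, 20)
  # confirmed/tentative/rejected partition all variables
  expect_setequal(c(bo1$confirmed, bo1$tentative, bo1$rejected), 1:p)
  expect_identical(sort(unique(c(bo1$confirmed, bo1$tentative))),
                   bo1$indices)
})

test_that("selected sets beat random sets of the same size on ground truth", {
  sc <- make_complementary_scenario(seed = 3, n_per_class = c(16, 16, 14, 16, 16))
  b <- apply_pretreatment(sc$ftmir, "SNV")
  truth <- which(sc$mask_ftmir)
  bo <- boruta_select(b$X, b$labels, seed = 1, rf_params = list(num_trees = 200))
  hit <- length(intersect(bo$indices, truth))
  set.seed(1)
  null <- replicate(200, length(intersect(
    sample(ncol(b$X), length(bo$indices)), truth)))
  expect_lt(mean(null >= hit), 0.05)
})

test_that("VIP selection is a strict threshold on the vip() vector", {
  set.seed(7)
  X <- matrix(rnorm(30 * 6), 30, 6)
  labels <- rep(1:2, each = 15)
  X[, 1] <- X[, 1] + labels
  m <- fit_plsda(X, labels, A = 2)
  sel <- vip_select(m)
  expect_identical(sel$indices, which(vip(m) > 1))
  expect_identical(vip_select(m, threshold = 0)$indices, 1:6)
  # identical columns give VIP exactly 1 everywhere: strict > selects none
  Xeq <- matrix(rep(rnorm(30) + labels, 4), ncol = 4)
  meq <- fit_plsda(Xeq, labels, A = 1)
  expect_equal(vip(meq), rep(1, 4), tolerance = 1e-10)
  expect_length(vip_select(meq)$indices, 0)
})
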