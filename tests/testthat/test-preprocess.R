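test_that("snv normalises to zero mean and unit sd, and is idempotent", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(snv(c(5, 5, 5)), "zero variance")
  expect_error(snv(5), "at least 2")
  set.seed(1)
  x <- rnorm(100, 3, 7)
  s <- snv(x)
  expect_lt(abs(mean(s)), 1e-12)
  expect_lt(abs(sd(s) - 1), 1e-12)
  expect_equal(snv(s), s, tolerance = 1e-12)
  # invariance to affine corruption
  expect_equal(snv(2.7 * x + 0.4), s, tolerance = 1e-12)
})

test_that("Savitzky-Golay derivatives are exact on polynomials, edges included", {
  x <- seq_len(40)
  expect_equal(derivative(rep(2, 40), order = 1), rep(0, 40))
  expect_equal(derivative(3.5 * x, order = 1), rep(3.5, 40))
  expect_equal(derivative(1.2 * x^2 - x + 3, order = 2), rep(2.4, 40))
  expect_error(derivative(x, window = 14), "odd")
  expect_error(derivative(x, order = 2, poly = 1), "poly")
  expect_error(derivative(x[1:10], window = 15), "shorter")
})

test_that("derivatives respect grid gaps (segments filtered separately)", {
  g <- make_grids(ftmir_n = 120)$ftmir
  # quadratic in the grid coordinate; derivative taken per index, so a
  # single filter bridging the gap would be badly wrong at the seam
  X <- rbind((g / 1000)^2)
  d <- derivative(X, order = 1, grid = g)
  seam <- max(which(g >= 2620))
  step1 <- abs(diff(g[1:2])); step2 <- abs(diff(g[c(seam + 1, seam + 2)]))
  expect_equal(d[1, seam], -2 * (g[seam] / 1e6) * step1, tolerance = 1e-6)
  expect_equal(d[1, seam + 1], -2 * (g[seam + 1] / 1e6) * step2, tolerance = 1e-6)
})

test_that("apply_pretreatment composes SNV and derivatives as named", {
  b <- toy_block(n = 4, p = 40)
  expect_equal(apply_pretreatment(b, "raw")$X, b$X)
  sd_ <- apply_pretreatment(b, "SD")
  expect_equal(sd_$X, derivative(b$X, order = 2, grid = b$grid))
  snvfd <- apply_pretreatment(b, "SNV-FD")
  expect_equal(snvfd$X,
               derivative(t(apply(b$X, 1, snv)), order = 1, grid = b$grid))
})

test_that("SNV removes multiplicative scatter between replicates", {
  g <- seq(1800, 650, length.out = 200)
  sig <- exp(-0.5 * ((g - 1200) / 40)^2)
  set.seed(4)
  X <- t(vapply(1:8, function(i)
    runif(1, 0.8, 1.2) * sig + runif(1, -0.05, 0.05), numeric(200)))
  b <- spectral_block("FTMIR", g, X, paste0("r", 1:8), rep(1L, 8))
  v_raw <- mean(apply(b$X, 2, var))
  v_snv <- mean(apply(apply_pretreatment(b, "SNV")$X, 2, var))
  expect_lt(v_snv, v_raw)
})

test_that("exclude_regions drops open intervals and keeps order", {
  b <- spectral_block("FTMIR", c(4000, 3500, 2000, 1000),
                      matrix(1:8, 2, 4), c("a", "b"), 1:2)
  out <- exclude_regions(b, list(c(4000, 3700)))
  # 4000 sits at the grid edge with no retained side: the region claims it
  expect_equal(out$grid, c(3500, 2000, 1000))
  # an interior boundary shared with a retained segment stays
  b2 <- spectral_block("FTMIR", c(4000, 3700, 3500, 2000, 1000),
                       matrix(1:10, 2, 5), c("a", "b"), 1:2)
  expect_true(3700 %in% exclude_regions(b2, list(c(4000, 3700)))$grid)
  expect_equal(exclude_regions(b, list())$grid, b$grid)
  expect_error(exclude_regions(b, list(c(5000, 500))), "every variable")
  # paper regions on a full-range FT-MIR grid
  g <- seq(4000, 650, length.out = 300)
  bf <- spectral_block("FTMIR", g, matrix(rnorm(600), 2, 300),
                       c("a", "b"), 1:2)
  kept <- exclude_regions(bf, list(c(4000, 3700), c(2620, 1800)))$grid
  expect_true(all((kept >= 650 & kept <= 1800) | (kept >= 2620 & kept <= 3700)))
  # brute-force count oracle (4000 is edge-claimed by its region)
  expect_identical(length(kept),
                   sum(!(g > 3700 & g <= 4000) & !(g > 1800 & g < 2620)))
})

test_that("pretreatment ranking prefers a dominating method", {
  b <- small_blocks(seed = 9)$ftmir
  sp <- split_by_class(b)
  one <- rank_pretreatments(b, sp, methods = "SNV")
  expect_identical(one$best, "SNV")
  rk <- rank_pretreatments(b, sp, methods = c("raw", "SNV"))
  expect_identical(nrow(rk$reports), 2L)
  dominating <- with(rk$reports,
    which(R2 == max(R2) & Q2 == max(Q2) & accuracy == max(accuracy) &
          RMSEE == min(RMSEE) & RMSECV == min(RMSECV)))
  if (length(dominating) == 1)
    expect_identical(rk$best, rk$reports$method[dominating])
})

test_that("under variable-shape drift the second derivative wins the predictive criteria", {
  # resubstitution criteria (R2, RMSEE) structurally favour raw data, which
  # retains the most fittable variance; the cross-validated criteria are
  # where baseline removal pays off
  noisy <- noise_model(additive_sd = 0.002, baseline_amplitude = 0.3,
                       height_jitter_sd = 0.02, baseline_degree = 8)
  b <- simulate_blocks(n_per_class = c(10, 10, 8, 10, 10), noise = noisy,
                       grids = make_grids(150, 180), seed = 21)$ftmir
  sp <- split_by_class(b)
  rk <- rank_pretreatments(b, sp, methods = c("raw", "FD", "SD"), seed = 1)
  r <- rk$reports
  expect_gt(r$Q2[r$method == "SD"], r$Q2[r$method == "raw"])
  expect_lt(r$RMSECV[r$method == "SD"], r$RMSECV[r$method == "raw"])
})
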