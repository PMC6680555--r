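test_that("low-level fusion concatenates row-aligned blocks with provenance", {
  blocks <- simulate_blocks(seed = 2)
  fused <- low_level_fuse(blocks$ftmir, blocks$nir)
  expect_identical(dim(fused), c(196L, 2695L))
  prov <- attr(fused, "provenance")
  expect_identical(table(prov$modality)[["FTMIR"]], 1150L)
  expect_identical(table(prov$modality)[["NIR"]], 1545L)
  other <- blocks$nir
  other$sample_ids <- rev(other$sample_ids)
  expect_error(low_level_fuse(blocks$ftmir, other), "row-aligned")
})

test_that("concatenation order does not change model accuracy", {
  b <- small_blocks(seed = 4)
  sp <- split_by_class(list(b$ftmir, b$nir))
  cal <- sp$role == "calibration"
  y <- b$ftmir$labels
  acc <- function(X) {
    rf <- fit_rf(X[cal, ], y[cal], n_tree = 300, seed = 9)
    mean(rf_classes(rf, X[!cal, ]) == y[!cal])
  }
  a1 <- acc(low_level_fuse(b$ftmir, b$nir))
  a2 <- acc(low_level_fuse(b$nir, b$ftmir))
  expect_lt(abs(a1 - a2), 0.15)
})

test_that("mid-level widths add across blocks", {
  b <- small_blocks(seed = 5)
  selA <- pca_extract(b$ftmir$X)
  selB <- pca_extract(b$nir$X)
  fused <- mid_level_fuse(b$ftmir$X, selA, b$nir$X, selB)
  expect_identical(ncol(fused), selA$n_kept + selB$n_kept)
  # index selections reduce to plain column picks; all columns = low level
  all_f <- structure(list(method = "manual",
                          indices = seq_len(ncol(b$ftmir$X))),
                     class = "selection_result")
  all_n <- structure(list(method = "manual",
                          indices = seq_len(ncol(b$nir$X))),
                     class = "selection_result")
  wide <- mid_level_fuse(b$ftmir$X, all_f, b$nir$X, all_n)
  expect_equal(unname(wide), unname(cbind(b$ftmir$X, b$nir$X)))
  empty <- structure(list(method = "manual", indices = integer(0)),
                     class = "selection_result")
  expect_error(mid_level_fuse(b$ftmir$X, empty, b$nir$X, all_n), "empty")
})

test_that("fuzzy voting reproduces the worked decision semantics", {
  # unanimous operators -> singleton final set
  a <- c(0.9, 0.05, 0.03, 0.01, 0.01)
  d <- fuzzy_vote(a, a)
  expect_true(all(vapply(d$votes, identical, logical(1), 1L)))
  expect_identical(d$final, 1L)
  expect_false(d$multiple)
  # three operators for class 3, one for class 5 -> plurality class 3
  a <- c(0.05, 0.05, 0.60, 0.05, 0.25)
  b <- c(0.02, 0.03, 0.30, 0.05, 0.60)
  # product/min/average all favour 3; max favours 5
  d <- fuzzy_vote(a, b)
  tab <- table(unlist(d$votes))
  expect_identical(d$final, 3L)
  expect_gte(tab[["3"]], 3)
  # near-tied scores within eps: both classes in every vote set
  a <- c(0.505, 0.500, 0.050, 0, 0)
  d <- fuzzy_vote(a, a, eps = 0.01)
  expect_true(all(vapply(d$votes, identical, logical(1), c(1L, 2L))))
  expect_identical(d$final, c(1L, 2L))
  expect_true(d$multiple)
  expect_error(fuzzy_vote(a, a[1:3]), "length")
  expect_error(fuzzy_vote(a, a, eps = 0), "positive")
})

test_that("a difference of exactly eps is not a tie", {
  # the tie rule is strict: second score must be within (not at) eps
  d <- fuzzy_vote(c(0.512, 0.508, 0), c(0.512, 0.508, 0), eps = 0.01)
  expect_identical(d$final, c(1L, 2L))  # gap 0.004 (0.0042 after product)
  d2 <- fuzzy_vote(c(0.52, 0.5, 0), c(0.52, 0.5, 0), eps = 0.01)
  expect_identical(d2$final, 1L)        # gap exactly 0.02: no tie
})

test_that("voting is equivariant under class permutation and monotone", {
  a <- c(0.4, 0.3, 0.2, 0.08, 0.02)
  b <- c(0.25, 0.35, 0.2, 0.1, 0.1)
  d <- fuzzy_vote(a, b)
  perm <- c(3, 1, 5, 2, 4)  # new position of each class
  dp <- fuzzy_vote(a[order(perm)], b[order(perm)])
  for (op in names(d$votes))
    expect_identical(as.integer(sort(perm[d$votes[[op]]])), dp$votes[[op]])
  # raising one class's score in both inputs never drops it from a vote set
  a2 <- a; b2 <- b
  a2[2] <- a2[2] + 0.2; b2[2] <- b2[2] + 0.2
  d2 <- fuzzy_vote(a2, b2)
  for (op in names(d$votes))
    if (2L %in% d$votes[[op]]) expect_true(2L %in% d2$votes[[op]])
})

test_that("tiny eps with unique maxima reduces to argmax of the average", {
  set.seed(11)
  for (i in 1:20) {
    a <- runif(5); a <- a / sum(a)
    b <- runif(5); b <- b / sum(b)
    d <- fuzzy_vote(a, b, eps = 1e-12)
    expect_identical(d$votes$average, which.max((a + b) / 2))
  }
})

test_that("high-level fusion counts multiple discrimination as designed", {
  # sample truly class 1, voted into {1, 4}: correct, but class 4 gains a FP
  sA <- rbind(c(0.5, 0, 0, 0.5, 0), c(1, 0, 0, 0, 0))
  sB <- rbind(c(0.5, 0, 0, 0.5, 0), c(1, 0, 0, 0, 0))
  hv <- high_level_fuse(sA, sB, eps = 0.01)
  expect_identical(hv$predicted_sets[[1]], c(1L, 4L))
  expect_true(hv$multiple[1])
  truth <- c(1L, 1L)
  expect_equal(accuracy(truth, hv$predicted_sets), 1)
  cc <- confusion_counts(truth, hv$predicted_sets, classes = 1:5)
  expect_identical(cc$FP[cc$class == 4], 1L)
  expect_identical(cc$TP[cc$class == 1], 2L)
  # accuracy equals a brute-force recount over the decision list
  recount <- mean(vapply(seq_along(truth), function(i)
    truth[i] %in% hv$predicted_sets[[i]], logical(1)))
  expect_equal(accuracy(truth, hv$predicted_sets), recount)
  expect_error(high_level_fuse(sA, sB[1, , drop = FALSE]), "shape")
})

test_that("agreeing confident models fuse to perfect singleton accuracy", {
  S <- diag(5)[c(1, 2, 3, 4, 5), ]
  hv <- high_level_fuse(S, S)
  expect_equal(accuracy(1:5, hv$predicted_sets), 1)
  expect_false(any(hv$multiple))
  cc <- confusion_counts(1:5, hv$predicted_sets)
  expect_true(all(cc$FP == 0))
})
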