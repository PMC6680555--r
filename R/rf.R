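#' Fit a random-forest classifier
#'
#' Bagged CART classification forest (via randomForest). The out-of-bag
#' error is the fraction of calibration samples misclassified by the
#' majority vote of the trees for which they are out of bag; samples that
#' are in-bag for every tree are excluded from the denominator.
#'
#' @param X Calibration matrix.
#' @param labels Integer class labels.
#' @param n_tree Number of trees.
#' @param m_try Candidate variables per split (default `floor(sqrt(p))`).
#' @param seed RNG seed.
#' @return Object of class `rf_model`: the forest, `oob_error`, and the
#'   class levels.
#' @export
fit_rf <- function(X, labels, n_tree = 500, m_try = NULL, seed = 1) {
  X <- as.matrix(X)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least two classes")
  if (is.null(m_try)) m_try <- max(1L, floor(sqrt(ncol(X))))
  m_try <- as.integer(m_try)
  if (m_try > ncol(X)) stop("m_try exceeds the number of variables")
  colnames(X) <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  y <- factor(labels, levels = classes)
  forest <- with_substream(seed, "rf-fit",
    randomForest::randomForest(x = X, y = y, ntree = n_tree, mtry = m_try))
  oob_pred <- forest$predicted  # OOB majority vote; NA when never OOB
  ok <- !is.na(oob_pred)
  structure(list(forest = forest, classes = classes,
                 n_tree = n_tree, m_try = m_try,
                 oob_error = mean(oob_pred[ok] != y[ok]),
                 oob_defined = mean(ok)),
            class = "rf_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rf_model <- function(x, ...) {
  cat(sprintf("<rf_model: %d trees, m_try %d, OOB error %.4f>\n",
              x$n_tree, x$m_try, x$oob_error))
  invisible(x)
}

#' Class-membership scores from a random forest
#'
#' Scores are tree-vote fractions, so every row sums to 1. With `X = NULL`
#' the calibration samples are scored by their out-of-bag votes.
#'
#' @param model An `rf_model`.
#' @param X New data on the model's variables, or `NULL` for OOB scores.
#' @return Matrix `n x K` of vote fractions.
#' @export
rf_scores <- function(model, X = NULL) {
  if (is.null(X)) {
    v <- model$forest$votes  # already normalised vote fractions
    out <- unclass(v)
  } else {
    X <- as.matrix(X)
    colnames(X) <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
    out <- stats::predict(model$forest, X, type = "vote", norm.votes = TRUE)
  }
  out <- unname(as.matrix(out))
  out / rowSums(out)
}

#' Hard class predictions from a random forest
#' @param model An `rf_model`.
#' @param X New data, or `NULL` for OOB predictions on the calibration set.
#' @return Integer class labels.
#' @export
rf_classes <- function(model, X = NULL) {
  if (is.null(X)) return(model$classes[as.integer(model$forest$predicted)])
  X <- as.matrix(X)
  colnames(X) <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  model$classes[as.integer(stats::predict(model$forest, X, type = "response"))]
}

#' Tune n_tree and m_try by out-of-bag error
#'
#' Stage one fits a forest at `n_tree0` trees and `floor(sqrt(p))`
#' candidate variables and reads the cumulative OOB error after each tree
#' count. Candidate tree counts achieve the global minimum; the chosen
#' `n_tree` is the earliest candidate inside the longest consecutive run of
#' counts whose error stays within half a misclassification
#' (`1/(2 n_cal)`) of the minimum -- the "smooth region" of the curve.
#' Stage two rescans `m_try` over a geometric grid from `sqrt(p)/4` to
#' `4 sqrt(p)` (12 points, deduplicated, clipped to `[1, p]`) at the chosen
#' `n_tree`, picking the lowest OOB error (ties -> smaller `m_try`).
#'
#' @param X Calibration matrix.
#' @param labels Integer class labels.
#' @param seed RNG seed.
#' @param n_tree0 Initial forest size (default 2000).
#' @return List of class `rf_config`: `n_tree`, `m_try`, `oob_curve`
#'   (error vs tree count), `mtry_grid` (error vs m_try), and the initial
#'   settings.
#' @export
tune_rf <- function(X, labels, seed = 1, n_tree0 = 2000) {
  X <- as.matrix(X)
  colnames(X) <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  p <- ncol(X); n <- nrow(X)
  classes <- sort(unique(labels))
  y <- factor(labels, levels = classes)
  mtry0 <- max(1L, floor(sqrt(p)))
  forest <- with_substream(seed, "rf-tune-ntree",
    randomForest::randomForest(x = X, y = y, ntree = n_tree0, mtry = mtry0))
  curve <- forest$err.rate[, "OOB"]
  tol <- 1 / (2 * n)
  lo <- min(curve)
  ok <- curve <= lo + tol
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  true_runs <- which(runs$values)
  longest <- true_runs[which.max(runs$lengths[true_runs])]
  span <- starts[longest]:ends[longest]
  exact <- span[curve[span] == lo]
  n_tree <- if (length(exact)) exact[1] else span[1]
  grid <- unique(pmin(p, pmax(1L, floor(
    exp(seq(log(max(1, sqrt(p) / 4)), log(min(p, 4 * sqrt(p))),
            length.out = 12))))))
  # the scan only needs the final OOB error at each m_try, not the curve,
  # so it runs on ranger (same bagged-CART OOB statistic, much faster)
  scan <- vapply(seq_along(grid), function(i) {
    f <- ranger::ranger(x = X, y = y, num.trees = n_tree, mtry = grid[i],
                        num.threads = 1,
                        seed = substream_seed(seed, paste0("mtry-", grid[i])))
    f$prediction.error
  }, numeric(1))
  m_try <- grid[order(scan, grid)[1]]
  structure(list(n_tree = as.integer(n_tree), m_try = as.integer(m_try),
                 n_tree0 = n_tree0, mtry0 = mtry0,
                 oob_curve = curve,
                 mtry_grid = data.frame(m_try = grid, oob = scan),
                 oob_min = lo, tol = tol),
            class = "rf_config")
}

#' @export
print.rf_config <- function(x, ...) {
  cat(sprintf("<rf_config: n_tree %d, m_try %d (initial %d/%d), OOB min %.4f>\n",
              x$n_tree, x$m_try, x$n_tree0, x$mtry0, x$oob_min))
  invisible(x)
}
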