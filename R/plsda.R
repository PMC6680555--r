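# PLS2 core: NIPALS-equivalent fit via the dominant singular vector of the
# X'Y cross-covariance at each step, deflating both blocks. Deterministic
# (svd-based, sign-fixed), equivalent to NIPALS at convergence.
pls_core <- function(X, Y, A) {
  E <- X; F_ <- Y
  p <- ncol(X); q <- ncol(Y)
  W <- matrix(0, p, A); P <- matrix(0, p, A); Q <- matrix(0, q, A)
  TT <- numeric(A)
  a_used <- 0
  for (a in seq_len(A)) {
    S <- crossprod(E, F_)
    sv <- svd(S, nu = 1, nv = 0)
    if (sv$d[1] < 1e-12) break  # residual rank exhausted
    w <- sv$u[, 1]
    j <- which.max(abs(w))
    if (w[j] < 0) w <- -w
    t <- E %*% w
    tt <- sum(t * t)
    if (tt < 1e-12) break
    pvec <- crossprod(E, t) / tt
    qvec <- crossprod(F_, t) / tt
    E <- E - t %*% t(pvec)
    F_ <- F_ - t %*% t(qvec)
    W[, a] <- w; P[, a] <- pvec; Q[, a] <- qvec; TT[a] <- tt
    a_used <- a
  }
  if (a_used == 0) stop("X has no covariance with Y; cannot fit PLS")
  list(W = W[, 1:a_used, drop = FALSE], P = P[, 1:a_used, drop = FALSE],
       Q = Q[, 1:a_used, drop = FALSE], TT = TT[1:a_used], A = a_used)
}

pls_coef <- function(core, A = core$A) {
  W <- core$W[, 1:A, drop = FALSE]
  P <- core$P[, 1:A, drop = FALSE]
  Q <- core$Q[, 1:A, drop = FALSE]
  W %*% solve(crossprod(P, W), t(Q))
}

one_hot <- function(labels, classes) {
  Y <- matrix(0, length(labels), length(classes),
              dimnames = list(NULL, paste0("class", classes)))
  Y[cbind(seq_along(labels), match(labels, classes))] <- 1
  Y
}

stratified_folds <- function(labels, folds, seed) {
  fold <- integer(length(labels))
  with_substream(seed, "folds", {
    for (k in unique(labels)) {
      i <- which(labels == k)
      fold[i] <- sample(rep_len(seq_len(folds), length(i)))
    }
  })
  fold
}

#' Fit a PLS-DA classifier
#'
#' Partial least squares regression (PLS2) of the one-hot class indicator
#' matrix on the mean-centered spectra; class membership of a sample is the
#' indicator column with the highest prediction. With `A = "auto"` the
#' number of latent variables is chosen by 7-fold cross-validated Q2,
#' adding components while the Q2 gain is at least 0.01 (capped at 15 and
#' at the residual rank).
#'
#' @param X Calibration matrix (samples x variables).
#' @param labels Integer class labels (at least two distinct).
#' @param A Number of latent variables, or `"auto"`.
#' @param max_a Cap for the automatic choice.
#' @param folds CV folds used by the automatic choice.
#' @param seed Seed for the fold assignment.
#' @return An object of class `plsda` (weights, loadings, coefficients,
#'   centering vectors, class levels).
#' @export
fit_plsda <- function(X, labels, A = "auto", max_a = 15, folds = 7, seed = 1) {
  X <- as.matrix(X)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least two classes")
  Y <- one_hot(labels, classes)
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2, xm); Yc <- sweep(Y, 2, ym)
  rank_cap <- min(nrow(X) - 1, ncol(X))
  if (identical(A, "auto")) {
    cap <- min(max_a, rank_cap)
    q2 <- plsda_q2_curve(X, labels, cap, folds, seed)
    # smallest component count whose Q2 comes within 0.01 of the curve
    # maximum: parsimony without the underfitting a local flat spot causes
    A <- which(q2 >= max(q2) - 0.01)[1]
  } else {
    A <- as.integer(A)
    if (A < 1) stop("A must be >= 1")
    if (A > rank_cap) stop("A exceeds the rank bound of X")
  }
  core <- pls_core(Xc, Yc, A)
  structure(list(core = core, A = core$A, B = pls_coef(core),
                 x_center = xm, y_center = ym, classes = classes,
                 labels = labels),
            class = "plsda")
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("<plsda: %d latent variables, %d classes, %d variables>\n",
              x$A, length(x$classes), length(x$x_center)))
  invisible(x)
}

# raw indicator predictions (n x K), optionally with fewer components
predict_plsda_raw <- function(model, X, A = model$A) {
  X <- as.matrix(X)
  B <- if (A == model$A) model$B else pls_coef(model$core, A)
  sweep(sweep(X, 2, model$x_center) %*% B, 2, model$y_center, `+`)
}

# Q2(A) curve by stratified k-fold CV; PRESS accumulated per component count
plsda_q2_curve <- function(X, labels, cap, folds = 7, seed = 1) {
  classes <- sort(unique(labels))
  Y <- one_hot(labels, classes)
  fold <- stratified_folds(labels, folds, seed)
  press <- numeric(cap)
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (length(unique(labels[tr])) < length(classes)) next
    xm <- colMeans(X[tr, , drop = FALSE]); ym <- colMeans(Y[tr, , drop = FALSE])
    core <- pls_core(sweep(X[tr, , drop = FALSE], 2, xm),
                     sweep(Y[tr, , drop = FALSE], 2, ym),
                     min(cap, sum(tr) - 1))
    Xte <- sweep(X[!tr, , drop = FALSE], 2, xm)
    for (a in seq_len(cap)) {
      B <- pls_coef(core, min(a, core$A))
      Yhat <- sweep(Xte %*% B, 2, ym, `+`)
      press[a] <- press[a] + sum((Y[!tr, , drop = FALSE] - Yhat)^2)
    }
  }
  sstot <- sum(sweep(Y, 2, colMeans(Y))^2)
  1 - press / sstot
}

#' Class-membership scores from a PLS-DA model
#'
#' Predicted indicator rows are clipped at zero and renormalised to sum to
#' one, giving per-class membership scores; all-zero rows (no positive
#' prediction) fall back to a uniform row and are flagged.
#'
#' @param model A fitted `plsda`.
#' @param X New data matrix on the model's variables.
#' @return Matrix `n x K` of scores in `[0, 1]`, rows summing to 1, with a
#'   logical attribute `uniform_fallback` marking degenerate rows.
#' @export
plsda_scores <- function(model, X) {
  raw <- predict_plsda_raw(model, X)
  clipped <- pmax(raw, 0)
  rs <- rowSums(clipped)
  flat <- rs == 0
  clipped[flat, ] <- 1 / ncol(clipped)
  rs[flat] <- 1
  out <- clipped / rs
  attr(out, "uniform_fallback") <- flat
  out
}

#' Hard class predictions from a PLS-DA model
#' @param model A fitted `plsda`.
#' @param X New data matrix.
#' @return Integer class labels (argmax of the raw indicator predictions).
#' @export
plsda_classes <- function(model, X) {
  raw <- predict_plsda_raw(model, X)
  model$classes[max.col(raw, ties.method = "first")]
}

#' Calibration/validation quality metrics of a PLS-DA model
#'
#' R2 = 1 - SSres/SStot and RMSEE on the calibration fit; Q2 = 1 -
#' PRESS/SStot and RMSECV from stratified k-fold cross-validation refits at
#' the model's component count; RMSEP on the validation set when given.
#' All RMS errors pool the squared residuals of every indicator column.
#'
#' @param model A fitted `plsda`.
#' @param X_cal,labels_cal Calibration data (the data the model was fit on).
#' @param X_val,labels_val Optional validation data.
#' @param folds CV folds (default 7).
#' @param seed Seed for the fold assignment.
#' @return List with `R2`, `Q2`, `RMSEE`, `RMSECV`, `RMSEP` (NA when no
#'   validation data), and `A`.
#' @export
quality_metrics <- function(model, X_cal, labels_cal,
                            X_val = NULL, labels_val = NULL,
                            folds = 7, seed = 1) {
  classes <- model$classes
  Y <- one_hot(labels_cal, classes)
  if (nrow(Y) < folds) stop("fewer calibration samples than folds")
  Yhat <- predict_plsda_raw(model, X_cal)
  res2 <- sum((Y - Yhat)^2)
  sstot <- sum(sweep(Y, 2, colMeans(Y))^2)
  fold <- stratified_folds(labels_cal, folds, seed)
  press <- 0
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (length(unique(labels_cal[tr])) < length(classes)) next
    m <- fit_plsda(X_cal[tr, , drop = FALSE], labels_cal[tr],
                   A = min(model$A, sum(tr) - 1), seed = seed)
    Yp <- predict_plsda_raw(m, X_cal[!tr, , drop = FALSE])
    press <- press + sum((Y[!tr, , drop = FALSE] - Yp)^2)
  }
  rmsep <- NA_real_
  if (!is.null(X_val)) {
    Yv <- one_hot(labels_val, classes)
    Yvhat <- predict_plsda_raw(model, X_val)
    rmsep <- sqrt(mean((Yv - Yvhat)^2))
  }
  list(R2 = 1 - res2 / sstot, Q2 = 1 - press / sstot,
       RMSEE = sqrt(res2 / (nrow(Y) * ncol(Y))),
       RMSECV = sqrt(press / (nrow(Y) * ncol(Y))),
       RMSEP = rmsep, A = model$A)
}

#' Permutation test for PLS-DA overfitting
#'
#' Class labels are randomly permuted `n_perm` times; for every permutation
#' the model is refitted at the same component count and R2 and Q2 (k-fold
#' CV) recorded together with the correlation between each class's permuted
#' and original indicator column. Per class, least-squares lines of R2 and
#' Q2 against that correlation are read off at zero correlation; the
#' unpermuted model is included at correlation 1. A Q2 intercept at or
#' above 0.05 flags likely overfitting.
#'
#' @param X Calibration matrix.
#' @param labels Integer class labels.
#' @param A Number of latent variables for every refit.
#' @param n_perm Number of permutations (>= 20; the reference protocol
#'   uses 200).
#' @param seed RNG seed.
#' @param folds CV folds for Q2.
#' @return List: `intercepts` (per-class data.frame with `R2_intercept`,
#'   `Q2_intercept`), `points` (per-permutation records), `overfit` flag.
#' @export
permutation_test <- function(X, labels, A, n_perm = 200, seed = 1,
                             folds = 7) {
  if (n_perm < 20) stop("use at least 20 permutations")
  X <- as.matrix(X)
  classes <- sort(unique(labels))
  Y <- one_hot(labels, classes)
  base <- fit_plsda(X, labels, A = A, seed = seed)
  bq <- quality_metrics(base, X, labels, folds = folds, seed = seed)
  recs <- vector("list", n_perm)
  with_substream(seed, "permutation", {
    for (i in seq_len(n_perm)) {
      perm <- sample(length(labels))
      lp <- labels[perm]
      m <- fit_plsda(X, lp, A = A, seed = seed)
      q <- quality_metrics(m, X, lp, folds = folds, seed = seed)
      Yp <- one_hot(lp, classes)
      recs[[i]] <- data.frame(perm = i,
                              class = classes,
                              corr = vapply(seq_along(classes), function(k)
                                stats::cor(Yp[, k], Y[, k]), numeric(1)),
                              R2 = q$R2, Q2 = q$Q2)
    }
  })
  pts <- do.call(rbind, c(recs, list(
    data.frame(perm = 0, class = classes, corr = 1, R2 = bq$R2, Q2 = bq$Q2))))
  intercepts <- do.call(rbind, lapply(classes, function(k) {
    d <- pts[pts$class == k, ]
    data.frame(class = k,
               R2_intercept = unname(coef(lm(R2 ~ corr, data = d))[1]),
               Q2_intercept = unname(coef(lm(Q2 ~ corr, data = d))[1]))
  }))
  list(intercepts = intercepts, points = pts,
       R2 = bq$R2, Q2 = bq$Q2,
       overfit = any(intercepts$Q2_intercept >= 0.05))
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt( p * sum_a SSY_a (w_aj / ||w_a||)^2 / sum_a SSY_a )`,
#' where `SSY_a` is the Y sum of squares explained by component `a`. The
#' scores satisfy `sum_j VIP_j^2 = p`.
#'
#' @param model A fitted `plsda`.
#' @return Numeric vector of VIP scores, one per variable.
#' @export
vip <- function(model) {
  core <- model$core
  p <- nrow(core$W)
  ssy <- core$TT * colSums(core$Q^2)
  wn2 <- sweep(core$W, 2, sqrt(colSums(core$W^2)), `/`)^2
  sqrt(p * as.numeric(wn2 %*% ssy) / sum(ssy))
}
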