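#' Kaiser-rule principal component extraction
#'
#' PCA of the column-autoscaled matrix (correlation-matrix PCA); components
#' with eigenvalue greater than 1 are kept (the Kaiser rule, calibrated for
#' correlation PCA). Zero-variance columns are dropped with a warning
#' before autoscaling. The result carries a projector for new samples.
#'
#' @param X Numeric matrix (samples x variables).
#' @return A `selection_result` with method `"pcs"`: kept `scores`,
#'   `eigenvalues` (all, descending), `n_kept`, `loadings`, and a
#'   `project(newX)` closure.
#' @export
pca_extract <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least two samples")
  sds <- apply(X, 2, stats::sd)
  keep_cols <- sds > 0
  if (!all(keep_cols))
    warning(sum(!keep_cols), " zero-variance column(s) dropped before PCA")
  Xk <- X[, keep_cols, drop = FALSE]
  pc <- stats::prcomp(Xk, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  n_kept <- max(1L, sum(ev > 1))
  rot <- pc$rotation[, seq_len(n_kept), drop = FALSE]
  center <- pc$center; scale_ <- pc$scale
  project <- function(newX) {
    newX <- as.matrix(newX)[, keep_cols, drop = FALSE]
    scale(newX, center = center, scale = scale_) %*% rot
  }
  structure(list(method = "pcs",
                 scores = pc$x[, seq_len(n_kept), drop = FALSE],
                 eigenvalues = ev, n_kept = n_kept,
                 loadings = rot, kept_columns = which(keep_cols),
                 project = project),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  n <- if (x$method == "pcs") x$n_kept else length(x$indices)
  cat(sprintf("<selection_result %s: %d %s>\n", x$method, n,
              if (x$method == "pcs") "components" else "variables"))
  invisible(x)
}

# stratified k-fold CV error of a ranger forest on a column subset
rf_cv_error <- function(X, labels, folds, seed, num_trees) {
  fold <- stratified_folds(labels, folds, seed)
  y <- factor(labels)
  errs <- vapply(seq_len(folds), function(f) {
    tr <- fold != f
    fit <- ranger::ranger(x = X[tr, , drop = FALSE], y = y[tr],
                          num.trees = num_trees, num.threads = 1,
                          seed = substream_seed(seed, paste0("cvfit", f)))
    pred <- stats::predict(fit, X[!tr, , drop = FALSE],
                           num.threads = 1)$predictions
    mean(pred != y[!tr])
  }, numeric(1))
  c(error = mean(errs), se = stats::sd(errs) / sqrt(folds))
}

#' Recursive feature elimination with a random-forest backbone
#'
#' Variables are ranked once by permutation importance of a tuned forest,
#' then dropped from the bottom of the ranking `step` at a time; at each
#' retained size the stratified k-fold cross-validated error of a forest
#' refit is recorded. The retained-size axis is partitioned by the error
#' curve: the important region ends at the smallest size whose error is
#' within one standard error of the curve minimum; sizes inside the initial
#' error plateau (error within one standard error of the full-size error)
#' are the irrelevant region, anything between is interference. The
#' selected set is the top-ranked variables of the important size.
#'
#' @param X Matrix (samples x variables).
#' @param labels Integer class labels.
#' @param step Variables removed per elimination step (default 5).
#' @param folds CV folds (default 10).
#' @param seed RNG seed.
#' @param tune Run the full [tune_rf()] stage before ranking (default
#'   TRUE); with FALSE a `sqrt(p)`/500-tree forest ranks the variables.
#' @param num_trees Trees for the CV refits.
#' @return A `selection_result` with method `"rfe"`: `indices`, `ranking`
#'   (most important first), `curve` (size, error, se), `regions`.
#' @export
rfe_select <- function(X, labels, step = 5, folds = 10, seed = 1,
                       tune = TRUE, num_trees = 100) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (step >= p) stop("step must be smaller than the number of variables")
  colnames(X) <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  if (tune) {
    cfg <- tune_rf(X, labels, seed = substream_seed(seed, "rfe-tune"))
    nt <- max(cfg$n_tree, 500); mt <- cfg$m_try
  } else {
    nt <- 500; mt <- max(1L, floor(sqrt(p)))
  }
  imp_fit <- ranger::ranger(x = X, y = factor(labels), num.trees = nt,
                            mtry = mt, importance = "permutation",
                            scale.permutation.importance = TRUE,
                            num.threads = 1,
                            seed = substream_seed(seed, "rfe-imp"))
  ranking <- order(imp_fit$variable.importance, decreasing = TRUE)
  sizes <- seq(p, 5, by = -step)
  curve <- t(vapply(seq_along(sizes), function(i) {
    keep <- ranking[seq_len(sizes[i])]
    rf_cv_error(X[, keep, drop = FALSE], labels, folds,
                substream_seed(seed, paste0("rfe-cv-", sizes[i])), num_trees)
  }, numeric(2)))
  err <- curve[, "error"]; se <- curve[, "se"]
  i_min <- which.min(err)
  band <- err[i_min] + max(se[i_min], .Machine$double.eps)
  s_imp <- min(sizes[err <= band])
  # initial plateau: sizes (scanning from full p downward) whose error
  # stays within 1 SE of the full-size error
  full_band <- err[1] + max(se[1], .Machine$double.eps)
  plateau_end <- 1
  while (plateau_end < length(sizes) && err[plateau_end + 1] <= full_band)
    plateau_end <- plateau_end + 1
  s_plateau <- sizes[plateau_end]
  regions <- data.frame(
    region = c("irrelevant", "interference", "important"),
    from = c(p, s_plateau, s_imp),
    to = c(s_plateau, s_imp, min(sizes)))
  if (s_plateau <= s_imp)  # curve flat all the way down: two regions only
    regions <- regions[c(1, 3), ]
  structure(list(method = "rfe",
                 indices = sort(ranking[seq_len(s_imp)]),
                 ranking = ranking,
                 curve = data.frame(size = sizes, error = err, se = se),
                 regions = regions, n_selected = s_imp),
            class = "selection_result")
}

#' Boruta all-relevant variable selection
#'
#' Canonical Boruta on a random-forest backbone: each iteration extends the
#' data with shadow features (independently permuted copies of every
#' still-undecided variable), fits a forest with permutation importance,
#' and scores a hit for every real variable beating the best shadow.
#' Variables with significantly more hits than the binomial 50% expectation
#' (two one-sided tests at `alpha`, step-down Holm correction) are
#' confirmed, significantly fewer are rejected and removed; variables still
#' undecided after `max_iter` iterations are tentative. Confirmed and
#' tentative variables together form the selected set.
#'
#' @param X Matrix (samples x variables).
#' @param labels Integer class labels.
#' @param rf_params List of forest settings (`num_trees`, `m_try`).
#' @param alpha Significance level (default 0.01).
#' @param max_iter Maximum iterations (default 100).
#' @param seed RNG seed.
#' @return A `selection_result` with method `"boruta"`: `indices`
#'   (confirmed plus tentative, sorted), `confirmed`, `tentative`,
#'   `rejected`, `n_iter`.
#' @export
boruta_select <- function(X, labels, rf_params = list(), alpha = 0.01,
                          max_iter = 100, seed = 1) {
  X <- as.matrix(X)
  p <- ncol(X)
  num_trees <- rf_params$num_trees %||% 300
  y <- factor(labels)
  status <- rep("undecided", p)
  hits <- integer(p)
  iter <- 0
  while (any(status == "undecided") && iter < max_iter) {
    iter <- iter + 1
    active <- which(status != "rejected")
    und <- which(status == "undecided")
    Xa <- X[, active, drop = FALSE]
    # Shadows are fresh permutations of every original column, keeping the
    # max-shadow bar stationary across iterations. Shrinking the shadow
    # pool with the active set (as the rejection phase thins it) collapses
    # the bar and lets chance-correlated survivors ratchet up hits.
    shadow <- with_substream(seed, paste0("boruta-shadow-", iter),
      apply(X, 2, sample))
    Z <- cbind(Xa, shadow)
    colnames(Z) <- c(paste0("real", active), paste0("shadow", seq_len(p)))
    mt <- rf_params$m_try %||% max(1L, floor(sqrt(ncol(Z))))
    fit <- ranger::ranger(x = Z, y = y, num.trees = num_trees,
                          mtry = min(mt, ncol(Z)),
                          importance = "permutation",
                          scale.permutation.importance = TRUE,
                          num.threads = 1,
                          seed = substream_seed(seed, paste0("boruta-", iter)))
    imp <- fit$variable.importance
    shadow_max <- max(imp[(length(active) + 1):length(imp)])
    real_imp <- imp[seq_along(active)]
    hit_now <- active[real_imp > shadow_max]
    hits[intersect(hit_now, und)] <- hits[intersect(hit_now, und)] + 1L
    # two one-sided binomial tests, Holm step-down at the full-problem
    # multiplicity p (the hypotheses family is all original variables)
    p_conf <- stats::pbinom(hits[und] - 1L, iter, 0.5, lower.tail = FALSE)
    p_rej <- stats::pbinom(hits[und], iter, 0.5)
    conf <- und[stats::p.adjust(p_conf, "holm", n = p) < alpha]
    rej <- und[stats::p.adjust(p_rej, "holm", n = p) < alpha]
    status[conf] <- "confirmed"
    status[setdiff(rej, conf)] <- "rejected"
  }
  structure(list(method = "boruta",
                 indices = sort(which(status != "rejected")),
                 confirmed = which(status == "confirmed"),
                 tentative = which(status == "undecided"),
                 rejected = which(status == "rejected"),
                 hits = hits, n_iter = iter),
            class = "selection_result")
}

#' VIP-threshold variable selection
#'
#' Keeps variables whose VIP score strictly exceeds the threshold
#' (default 1), the usual rule on a PLS-DA fitted to the low-level fused
#' matrix.
#'
#' @param model A fitted `plsda`.
#' @param threshold VIP cutoff (strict inequality).
#' @return A `selection_result` with method `"vip"`: `indices`, `scores`,
#'   `threshold`.
#' @export
vip_select <- function(model, threshold = 1) {
  scores <- vip(model)
  structure(list(method = "vip",
                 indices = which(scores > threshold),
                 scores = scores, threshold = threshold),
            class = "selection_result")
}
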