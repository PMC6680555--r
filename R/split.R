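#' Kennard-Stone sample selection
#'
#' Classic max-min selection: start from the two mutually most distant
#' samples (Euclidean), then repeatedly add the sample whose minimum
#' distance to the selected set is largest. Deterministic; distance ties
#' break on the lowest row index.
#'
#' @param X Numeric matrix (samples x features).
#' @param k Number of samples to select, `2 <= k <= nrow(X)`.
#' @return Integer vector of `k` row indices in selection order.
#' @export
kennard_stone <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("k exceeds the number of samples")
  D <- as.matrix(stats::dist(X))
  # farthest pair, lowest indices on ties
  far <- which(D == max(D), arr.ind = TRUE)
  far <- far[far[, 1] < far[, 2], , drop = FALSE]
  far <- far[order(far[, 1], far[, 2]), , drop = FALSE]
  sel <- as.integer(far[1, ])
  left <- setdiff(seq_len(n), sel)
  while (length(sel) < k) {
    dmin <- apply(D[left, sel, drop = FALSE], 1, min)
    pick <- left[which.max(dmin)]  # which.max takes the first (lowest index) tie
    sel <- c(sel, pick)
    left <- setdiff(left, pick)
  }
  sel
}

#' Per-class Kennard-Stone calibration/validation split
#'
#' Runs Kennard-Stone independently inside every class on the per-variable
#' autoscaled concatenation of both (pretreated) blocks, assigning the
#' selected `floor(ratio * n_class)` samples to the calibration set. With
#' the study's class sizes (40, 40, 36, 40, 40) and ratio 2/3 this yields
#' calibration counts (26, 26, 24, 26, 26) and validation counts
#' (14, 14, 12, 14, 14). The assignment is keyed by sample id and invariant
#' to row order (class members are processed in sample-id order). One
#' split is produced per dataset and reused by every downstream model.
#'
#' @param blocks List of row-aligned [spectral_block()]s (typically
#'   `list(ftmir, nir)`); a single block is also accepted.
#' @param ratio Calibration fraction (default 2/3, i.e. 2:1).
#' @return A `split_assignment`: list with `sample_id`, `role`
#'   (calibration/validation), `class_counts` (per-class table) and
#'   `feature_space` metadata.
#' @export
split_by_class <- function(blocks, ratio = 2 / 3) {
  if (inherits(blocks, "spectral_block")) blocks <- list(blocks)
  stopifnot(length(blocks) >= 1, ratio > 0, ratio < 1)
  ids <- blocks[[1]]$sample_ids
  labels <- blocks[[1]]$labels
  for (b in blocks[-1]) {
    if (!identical(b$sample_ids, ids))
      stop("blocks are not row-aligned (sample ids differ)")
    if (!identical(b$labels, labels))
      stop("blocks disagree on class labels")
  }
  X <- do.call(cbind, lapply(blocks, function(b) b$X))
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- 1
  X <- scale(X, center = TRUE, scale = sds)
  role <- setNames(rep("validation", length(ids)), ids)
  classes <- sort(unique(labels))
  counts <- matrix(0L, length(classes), 2,
                   dimnames = list(classes, c("calibration", "validation")))
  for (k in classes) {
    member <- which(labels == k)
    if (length(member) < 3) stop("class ", k, " has fewer than 3 samples")
    member <- member[order(ids[member])]
    n_cal <- as.integer(floor(ratio * length(member)))
    if (n_cal < 2) stop("class ", k, " too small for a Kennard-Stone split")
    sel <- kennard_stone(X[member, , drop = FALSE], n_cal)
    role[ids[member[sel]]] <- "calibration"
    counts[as.character(k), ] <- c(n_cal, length(member) - n_cal)
  }
  structure(list(sample_id = ids, role = unname(role[ids]),
                 class_counts = counts,
                 feature_space = sprintf(
                   "autoscaled concatenation of %d block(s), %d variables",
                   length(blocks), ncol(X))),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat("<split_assignment>", sum(x$role == "calibration"), "calibration /",
      sum(x$role == "validation"), "validation\n")
  print(x$class_counts)
  invisible(x)
}

# logical calibration mask for a block under a split
calibration_mask <- function(block, split) {
  role <- split$role[match(block$sample_ids, split$sample_id)]
  if (anyNA(role)) stop("split does not cover all samples of the block")
  role == "calibration"
}
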