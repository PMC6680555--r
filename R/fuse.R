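#' Low-level fusion: concatenate two blocks
#'
#' Column-wise concatenation of two row-aligned blocks into one matrix;
#' column provenance (modality, wavenumber) is kept in the `provenance`
#' attribute.
#'
#' @param blockA,blockB Row-aligned [spectral_block()]s.
#' @return Matrix `n x (pA + pB)` with a `provenance` data.frame attribute.
#' @export
low_level_fuse <- function(blockA, blockB) {
  validate_block(blockA); validate_block(blockB)
  if (ncol(blockA$X) == 0 || ncol(blockB$X) == 0)
    stop("cannot fuse an empty block")
  if (!identical(blockA$sample_ids, blockB$sample_ids))
    stop("blocks are not row-aligned (sample ids differ)")
  out <- cbind(blockA$X, blockB$X)
  colnames(out) <- c(sprintf("%s_%.6g", blockA$modality, blockA$grid),
                     sprintf("%s_%.6g", blockB$modality, blockB$grid))
  attr(out, "provenance") <- data.frame(
    modality = c(rep(blockA$modality, ncol(blockA$X)),
                 rep(blockB$modality, ncol(blockB$X))),
    wavenumber = c(blockA$grid, blockB$grid))
  out
}

#' Feature matrix of one block under a selection
#'
#' Selected columns for index-based methods (RFE, Boruta, VIP), projected
#' component scores for PCs.
#'
#' @param X Block data matrix.
#' @param selection A `selection_result`.
#' @return Feature matrix for modelling.
#' @export
feature_matrix <- function(X, selection) {
  X <- as.matrix(X)
  if (selection$method == "pcs") return(selection$project(X))
  if (length(selection$indices) == 0) stop("empty selection")
  X[, selection$indices, drop = FALSE]
}

#' Mid-level fusion: concatenate per-block feature matrices
#'
#' Concatenates the selected columns (RFE/Boruta/VIP) or kept component
#' scores (PCs) of the two blocks; width is the sum of the two selected
#' widths.
#'
#' @param XA,XB Per-block data matrices (row-aligned).
#' @param selA,selB `selection_result`s for the two blocks.
#' @return Fused feature matrix.
#' @export
mid_level_fuse <- function(XA, selA, XB, selB) {
  FA <- feature_matrix(XA, selA)
  FB <- feature_matrix(XB, selB)
  if (nrow(FA) != nrow(FB)) stop("blocks are not row-aligned")
  if (ncol(FA) == 0 || ncol(FB) == 0) stop("empty selection")
  colnames(FA) <- paste0("A", seq_len(ncol(FA)))
  colnames(FB) <- paste0("B", seq_len(ncol(FB)))
  cbind(FA, FB)
}

#' Fuzzy-operator decision vote for one sample
#'
#' The two class-membership score vectors are combined element-wise by four
#' fuzzy aggregation operators (minimum, maximum, product, average). Each
#' operator votes for its maximal class, expanded by every class whose
#' combined score is within `eps` of that maximum (near-ties count as
#' maxima). The final class set is the plurality winner over the four
#' operator vote sets; a tied plurality returns the union of the tied
#' classes. More than one final class marks the sample as multiple
#' discriminated.
#'
#' @param scoreA,scoreB Numeric length-K score vectors in `[0, 1]`.
#' @param eps Tie width (default 0.01).
#' @return A `fusion_decision`: `votes` (list of class-index sets per
#'   operator), `final` (class indices), `multiple` flag.
#' @export
fuzzy_vote <- function(scoreA, scoreB, eps = 0.01) {
  if (length(scoreA) != length(scoreB))
    stop("score vectors differ in length")
  if (eps <= 0) stop("eps must be positive")
  ops <- list(minimum = pmin(scoreA, scoreB),
              maximum = pmax(scoreA, scoreB),
              product = scoreA * scoreB,
              average = (scoreA + scoreB) / 2)
  votes <- lapply(ops, function(v) which(v > max(v) - eps))
  counts <- tabulate(unlist(votes), nbins = length(scoreA))
  final <- which(counts == max(counts))
  structure(list(votes = votes, final = final,
                 multiple = length(final) > 1),
            class = "fusion_decision")
}

#' High-level fusion of two score matrices
#'
#' Applies [fuzzy_vote()] row by row. A sample counts as correct when its
#' true class is in the final set (multiple discrimination does not lower
#' accuracy); per-class confusion counts treat every class of the final
#' set as a positive prediction, so multiple discrimination can add false
#' positives and depress per-class efficiency.
#'
#' @param scoresA,scoresB Row-aligned `n x K` score matrices.
#' @param eps Tie width (default 0.01).
#' @return List: `decisions` (per-sample `fusion_decision`s),
#'   `predicted_sets` (list of class-index sets), `multiple` (logical
#'   vector).
#' @export
high_level_fuse <- function(scoresA, scoresB, eps = 0.01) {
  scoresA <- as.matrix(scoresA); scoresB <- as.matrix(scoresB)
  if (!all(dim(scoresA) == dim(scoresB)))
    stop("score matrices differ in shape")
  decisions <- lapply(seq_len(nrow(scoresA)), function(i)
    fuzzy_vote(scoresA[i, ], scoresB[i, ], eps))
  list(decisions = decisions,
       predicted_sets = lapply(decisions, `[[`, "final"),
       multiple = vapply(decisions, `[[`, logical(1), "multiple"))
}
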