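#' Standard normal variate
#'
#' Centers one spectrum to mean 0 and scales it to unit sample standard
#' deviation (n-1 denominator), removing per-spectrum additive offset and
#' multiplicative scatter.
#'
#' @param x Numeric vector, length >= 2.
#' @return Transformed vector with mean 0 and sd 1.
#' @export
snv <- function(x) {
  if (length(x) < 2) stop("snv needs at least 2 points")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("zero variance spectrum: SNV undefined")
  (x - mean(x)) / s
}

#' Savitzky-Golay derivative
#'
#' Applies a Savitzky-Golay polynomial derivative filter along the
#' wavenumber axis of each row. Output has the same shape as the input:
#' edge points use the asymmetric polynomial fits from the full filter
#' matrix rather than being truncated. The derivative is taken with respect
#' to column index (one grid step), the usual chemometric convention. When
#' the grid contains gaps (the excised FT-MIR regions), each contiguous
#' segment is filtered separately; pass `grid` to enable gap detection.
#'
#' @param X Numeric matrix (samples x variables) or a single vector.
#' @param order Derivative order, 1 or 2.
#' @param window Odd filter length, greater than `poly`.
#' @param poly Polynomial degree, `order <= poly < window`.
#' @param grid Optional wavenumber vector used only to locate gaps between
#'   contiguous segments.
#' @return Matrix (or vector) of derivatives, same shape as `X`.
#' @export
derivative <- function(X, order = 1, window = 15, poly = 2, grid = NULL) {
  vec <- is.null(dim(X))
  X <- rbind(X)
  if (window %% 2 != 1) stop("window must be odd")
  if (poly < order) stop("poly must be >= derivative order")
  if (poly >= window) stop("window must exceed poly")
  p <- ncol(X)
  segs <- list(seq_len(p))
  if (!is.null(grid) && length(grid) == p) {
    step <- stats::median(abs(diff(grid)))
    cut <- which(abs(diff(grid)) > 3 * step)
    if (length(cut)) {
      bounds <- c(0, cut, p)
      segs <- lapply(seq_len(length(bounds) - 1),
                     function(i) (bounds[i] + 1):bounds[i + 1])
    }
  }
  out <- X
  for (idx in segs) {
    if (length(idx) < window)
      stop("segment of length ", length(idx), " shorter than window ", window)
    # sgolayfilt applies the full Savitzky-Golay filter matrix: central
    # filter in the interior, asymmetric polynomial fits at the edges, so
    # the output keeps the input shape and is exact on polynomials of
    # degree <= poly.
    for (r in seq_len(nrow(X)))
      out[r, idx] <- signal::sgolayfilt(X[r, idx], p = poly, n = window,
                                        m = order)
  }
  if (vec) drop(out) else out
}

#' Apply a named pretreatment to a block
#'
#' Supported methods: `raw`, `SNV`, `FD`, `SD`, `SNV-FD`, `SNV-SD`.
#' Composite names read left to right: SNV first, then the derivative.
#'
#' @param block A [spectral_block()].
#' @param method Pretreatment name.
#' @param window,poly Savitzky-Golay settings for the derivative steps.
#' @return A pretreated [spectral_block()] on the same grid.
#' @export
apply_pretreatment <- function(block, method = c("raw", "SNV", "FD", "SD",
                                                 "SNV-FD", "SNV-SD"),
                               window = 15, poly = 2) {
  method <- match.arg(method)
  validate_block(block)
  X <- block$X
  steps <- strsplit(method, "-", fixed = TRUE)[[1]]
  for (s in steps) {
    X <- switch(s,
      raw = X,
      SNV = t(apply(X, 1, snv)),
      FD = derivative(X, order = 1, window = window, poly = poly,
                      grid = block$grid),
      SD = derivative(X, order = 2, window = window, poly = poly,
                      grid = block$grid))
  }
  spectral_block(block$modality, block$grid, X, block$sample_ids, block$labels)
}

#' Remove wavenumber regions from a block
#'
#' Drops every column whose wavenumber lies strictly inside one of the
#' given intervals. Shared boundary points (for instance 3700, 2620 and
#' 1800 cm^-1, which belong to both an excluded and a retained region of
#' the FT-MIR range) stay in the retained set, so intervals are treated as
#' open. Column order is preserved.
#'
#' @param block A [spectral_block()].
#' @param regions List of `c(lo, hi)` wavenumber intervals (cm^-1).
#' @return A [spectral_block()] without the excluded columns.
#' @export
exclude_regions <- function(block, regions) {
  validate_block(block)
  if (length(regions) == 0) return(block)
  if (is.numeric(regions) && length(regions) == 2) regions <- list(regions)
  g <- block$grid
  drop <- rep(FALSE, length(g))
  for (rg in regions) {
    rg <- sort(as.numeric(rg))
    drop <- drop | (g > rg[1] & g < rg[2])
    # a boundary point stays with the retained side when one exists; at the
    # grid edge there is no retained side, so the excluded region claims it
    if (!any(g < rg[1])) drop <- drop | g == rg[1]
    if (!any(g > rg[2])) drop <- drop | g == rg[2]
  }
  if (all(drop)) stop("excluding these regions would remove every variable")
  keep <- which(!drop)
  spectral_block(block$modality, block$grid[keep],
                 block$X[, keep, drop = FALSE],
                 block$sample_ids, block$labels)
}

#' Rank pretreatment methods by PLS-DA calibration quality
#'
#' For each candidate method the block is pretreated, a PLS-DA is fitted on
#' the calibration samples, and five criteria are computed: R2, Q2
#' (7-fold CV), RMSEE, RMSECV and calibration accuracy. Methods are ranked
#' per criterion (higher R2/Q2/accuracy better; lower RMSEE/RMSECV better)
#' and aggregated by rank sum; ties break on accuracy.
#'
#' @param block A [spectral_block()].
#' @param split A `split_assignment` from [split_by_class()].
#' @param methods Character vector of pretreatment names.
#' @param seed Seed for the CV fold assignment.
#' @return List: `reports` (one row per method) and `best` (method name).
#' @export
rank_pretreatments <- function(block, split,
                               methods = c("raw", "SNV", "FD", "SD",
                                           "SNV-FD", "SNV-SD"),
                               seed = 1) {
  stopifnot(length(methods) >= 1)
  cal <- split$role[match(block$sample_ids, split$sample_id)] == "calibration"
  if (!any(cal)) stop("split assigns no calibration samples to this block")
  rows <- lapply(methods, function(m) {
    pb <- apply_pretreatment(block, m)
    Xc <- pb$X[cal, , drop = FALSE]
    yc <- pb$labels[cal]
    fit <- fit_plsda(Xc, yc, A = "auto", seed = substream_seed(seed, m))
    q <- quality_metrics(fit, Xc, yc, folds = 7,
                         seed = substream_seed(seed, paste0("cv-", m)))
    pred <- plsda_classes(fit, Xc)
    data.frame(method = m, A = fit$A, R2 = q$R2, Q2 = q$Q2,
               RMSEE = q$RMSEE, RMSECV = q$RMSECV,
               accuracy = mean(pred == yc))
  })
  rep <- do.call(rbind, rows)
  rk <- rank(-rep$R2) + rank(-rep$Q2) + rank(-rep$accuracy) +
    rank(rep$RMSEE) + rank(rep$RMSECV)
  best <- order(rk, -rep$accuracy)[1]
  list(reports = rep, best = rep$method[best])
}
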