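#' Spectral block container
#'
#' A `spectral_block` bundles one modality's absorbance matrix with its
#' wavenumber grid, sample identifiers and class labels. The grid is stored
#' in descending wavenumber order (spectroscopic convention); rows of `X`
#' follow `sample_ids`.
#'
#' @param modality `"FTMIR"` or `"NIR"`.
#' @param grid Numeric vector of wavenumbers (cm^-1), strictly monotonic.
#' @param X Numeric matrix, `n_samples x length(grid)`, no missing values.
#' @param sample_ids Unique character vector, one per row of `X`.
#' @param labels Integer class labels in `1..K`, aligned with rows.
#' @return An object of class `spectral_block`.
#' @export
spectral_block <- function(modality, grid, X, sample_ids, labels) {
  modality <- match.arg(toupper(modality), c("FTMIR", "NIR"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  grid <- as.numeric(grid)
  b <- structure(
    list(modality = modality, grid = grid, X = X,
         sample_ids = as.character(sample_ids),
         labels = as.integer(labels)),
    class = "spectral_block")
  validate_block(b)
  b
}

validate_block <- function(b) {
  stopifnot(inherits(b, "spectral_block"))
  if (length(b$grid) != ncol(b$X))
    stop("grid length (", length(b$grid), ") != number of columns (",
         ncol(b$X), ")")
  d <- diff(b$grid)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("wavenumber grid is not strictly monotonic")
  if (anyDuplicated(b$sample_ids))
    stop("duplicated sample ids: ",
         paste(unique(b$sample_ids[duplicated(b$sample_ids)]), collapse = ", "))
  if (length(b$sample_ids) != nrow(b$X))
    stop("sample_ids length != number of rows")
  if (length(b$labels) != nrow(b$X))
    stop("labels length != number of rows")
  if (anyNA(b$X) || any(!is.finite(b$X)))
    stop("absorbance matrix contains missing or non-finite values")
  invisible(b)
}

#' @export
print.spectral_block <- function(x, ...) {
  cat(sprintf("<spectral_block %s: %d samples x %d variables, %g-%g cm-1, %d classes>\n",
              x$modality, nrow(x$X), ncol(x$X), max(x$grid), min(x$grid),
              length(unique(x$labels))))
  invisible(x)
}

#' @export
dim.spectral_block <- function(x) dim(x$X)

#' Read a spectral block from wide CSV
#'
#' Expected layout: column `sample_id`, column `class` (integer), then one
#' numeric column per wavenumber (header is the wavenumber in cm^-1).
#' Columns are reordered to descending wavenumber; the original header order
#' is kept in the `original_order` attribute. Samples are never reordered.
#'
#' @param path CSV file path.
#' @param modality `"FTMIR"` or `"NIR"`.
#' @return A [spectral_block()].
#' @export
read_block <- function(path, modality) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "class")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  ids <- as.character(df$sample_id)
  if (anyDuplicated(ids))
    stop("duplicated sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  wn_cols <- setdiff(names(df), need)
  grid <- suppressWarnings(as.numeric(wn_cols))
  if (anyNA(grid))
    stop("non-numeric wavenumber header(s): ",
         paste(wn_cols[is.na(grid)], collapse = ", "))
  X <- as.matrix(df[, wn_cols, drop = FALSE])
  if (!is.numeric(X)) {
    bad <- wn_cols[!vapply(df[wn_cols], is.numeric, logical(1))]
    stop("non-numeric absorbance values in column(s): ",
         paste(bad, collapse = ", "))
  }
  if (anyNA(X)) {
    bad <- which(apply(X, 1, anyNA))
    stop("missing absorbance values in row(s): ",
         paste(ids[bad], collapse = ", "))
  }
  ord <- order(grid, decreasing = TRUE)
  b <- spectral_block(modality, grid[ord], X[, ord, drop = FALSE],
                      ids, as.integer(df$class))
  attr(b, "original_order") <- wn_cols
  b
}

#' Write a spectral block to wide CSV
#'
#' Values are serialised with 17 significant digits so that
#' `read_block(write_block(b))` round-trips exactly.
#'
#' @param block A [spectral_block()].
#' @param path Output path.
#' @export
write_block <- function(block, path) {
  validate_block(block)
  header <- c("sample_id", "class", sprintf("%.10g", block$grid))
  body <- matrix(sprintf("%.17g", block$X), nrow = nrow(block$X))
  lines <- c(paste(header, collapse = ","),
             paste(block$sample_ids, block$labels,
                   apply(body, 1, paste, collapse = ","), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Average analytical replicates
#'
#' Optional helper collapsing replicate rows (same group key) to their mean
#' spectrum. Replicates of one sample must share a class label.
#'
#' @param block A [spectral_block()].
#' @param groups Character vector, one entry per row; rows sharing a value
#'   are averaged and the value becomes the new sample id.
#' @return A [spectral_block()] with one row per group, in first-appearance
#'   order.
#' @export
average_replicates <- function(block, groups) {
  validate_block(block)
  stopifnot(length(groups) == nrow(block$X))
  groups <- as.character(groups)
  keys <- unique(groups)
  X <- matrix(0, length(keys), ncol(block$X))
  labels <- integer(length(keys))
  for (i in seq_along(keys)) {
    rows <- which(groups == keys[i])
    lab <- unique(block$labels[rows])
    if (length(lab) != 1)
      stop("replicate group ", keys[i], " has conflicting class labels")
    labels[i] <- lab
    X[i, ] <- colMeans(block$X[rows, , drop = FALSE])
  }
  spectral_block(block$modality, block$grid, X, keys, labels)
}
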