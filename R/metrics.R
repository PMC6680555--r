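#' One-vs-rest confusion counts for set-valued predictions
#'
#' A sample counts as a positive prediction for class `c` iff `c` is in its
#' predicted set (singleton sets for ordinary classifiers). Under multiple
#' discrimination a sample can be positive for several classes, so the
#' counts across classes may sum to more than `n`.
#'
#' @param true_labels Integer class labels.
#' @param predicted_sets List of non-empty integer class sets (a plain
#'   vector of single predictions is also accepted).
#' @param classes Class universe (default: sorted unique true labels).
#' @return data.frame with one row per class: TP, FP, TN, FN.
#' @export
confusion_counts <- function(true_labels, predicted_sets,
                             classes = sort(unique(true_labels))) {
  if (!is.list(predicted_sets)) predicted_sets <- as.list(predicted_sets)
  if (length(true_labels) != length(predicted_sets))
    stop("true labels and predictions differ in length")
  if (any(lengths(predicted_sets) == 0)) stop("empty predicted set")
  out <- do.call(rbind, lapply(classes, function(cl) {
    pos <- vapply(predicted_sets, function(s) cl %in% s, logical(1))
    is_cl <- true_labels == cl
    data.frame(class = cl,
               TP = sum(pos & is_cl), FP = sum(pos & !is_cl),
               TN = sum(!pos & !is_cl), FN = sum(!pos & is_cl))
  }))
  rownames(out) <- NULL
  out
}

#' Geometric-mean efficiency of a class
#'
#' `efficiency = sqrt(SEN * SPE)`, bounded by the two inputs.
#'
#' @param sen Sensitivity `TP/(TP+FN)` in `[0, 1]`.
#' @param spe Specificity `TN/(TN+FP)` in `[0, 1]`.
#' @return `sqrt(sen * spe)`.
#' @export
efficiency <- function(sen, spe) {
  stopifnot(all(sen >= 0 & sen <= 1), all(spe >= 0 & spe <= 1))
  sqrt(sen * spe)
}

#' Set-inclusion accuracy
#'
#' Fraction of samples whose true class is contained in the predicted set;
#' multiple discrimination therefore never lowers accuracy.
#'
#' @inheritParams confusion_counts
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(true_labels, predicted_sets) {
  if (!is.list(predicted_sets)) predicted_sets <- as.list(predicted_sets)
  stopifnot(length(true_labels) == length(predicted_sets))
  mean(mapply(function(t, s) t %in% s, true_labels, predicted_sets))
}

#' Per-class metrics of one model on one sample set
#'
#' @inheritParams confusion_counts
#' @return List: `counts` (confusion data.frame with SEN, SPE, efficiency
#'   columns appended) and `accuracy`.
#' @export
class_metrics <- function(true_labels, predicted_sets,
                          classes = sort(unique(true_labels))) {
  cc <- confusion_counts(true_labels, predicted_sets, classes)
  cc$SEN <- cc$TP / (cc$TP + cc$FN)
  cc$SPE <- cc$TN / (cc$TN + cc$FP)
  cc$efficiency <- efficiency(cc$SEN, cc$SPE)
  list(counts = cc, accuracy = accuracy(true_labels, predicted_sets))
}

#' Assemble a per-model, per-set report table
#'
#' One row per entry: per-class efficiency columns plus total accuracy,
#' the layout used for calibration/validation report tables. Entries are
#' lists with `dataset`, `model`, `set`, `true`, `predicted_sets`.
#'
#' @param entries List of entries (see above).
#' @param classes Class universe.
#' @return data.frame with columns dataset, model, set, class<k>_efficiency
#'   ..., accuracy.
#' @export
build_report <- function(entries, classes = NULL) {
  if (is.null(classes))
    classes <- sort(unique(unlist(lapply(entries, `[[`, "true"))))
  rows <- lapply(entries, function(e) {
    m <- class_metrics(e$true, e$predicted_sets, classes)
    eff <- as.list(setNames(m$counts$efficiency,
                            paste0("class", classes, "_efficiency")))
    cbind(data.frame(dataset = e$dataset, model = e$model, set = e$set),
          as.data.frame(eff),
          data.frame(accuracy = m$accuracy))
  })
  do.call(rbind, rows)
}

#' Format a fraction as a percentage string
#' @param x Fraction in `[0, 1]`.
#' @param digits Decimal places (default 2, e.g. `"95.59%"`).
#' @return Character vector.
#' @export
format_percent <- function(x, digits = 2) {
  sprintf(paste0("%.", digits, "f%%"), 100 * x)
}
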