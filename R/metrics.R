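#' One-vs-rest confusion counts
#'
#' Counts true/false positives/negatives for one positive class.
#'
#' @param true,predicted Label vectors of equal length.
#' @param positive The class counted as positive.
#' @return A tibble row with `class`, `TP`, `TN`, `FP`, `FN`
#'   (`TP + TN + FP + FN` equals the number of samples).
#' @export
confusion <- function(true, predicted, positive) {
  true <- as.character(true)
  predicted <- as.character(predicted)
  if (length(true) != length(predicted)) abort("label vectors differ in length")
  tp <- sum(true == positive & predicted == positive)
  fn <- sum(true == positive & predicted != positive)
  fp <- sum(true != positive & predicted == positive)
  tn <- sum(true != positive & predicted != positive)
  tibble::tibble(class = positive, TP = tp, TN = tn, FP = fp, FN = fn)
}

#' Metrics from confusion counts
#'
#' Computes sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, accuracy `(TP+TN)/(TP+TN+FP+FN)`, F1
#' `2*precision*sensitivity/(precision+sensitivity)` and `error_rate =
#' 1 - accuracy`. A ratio with zero denominator is reported as `NA` and
#' named in the `undefined` column (comma-separated), never coerced to 0.
#'
#' @param counts A one-row tibble from [confusion()] (or any list with
#'   `TP`, `TN`, `FP`, `FN`).
#' @return A one-row tibble of the six metrics plus `undefined`.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  prec <- ratio(tp, tp + fp)
  acc <- ratio(tp + tn, tp + tn + fp + fn)
  f1 <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) {
    NA_real_
  } else {
    2 * prec * sens / (prec + sens)
  }
  vals <- c(sensitivity = sens, specificity = spec, precision = prec,
            f1 = f1, accuracy = acc, error_rate = if (is.na(acc)) NA_real_ else 1 - acc)
  tibble::tibble(class = counts$class %||% NA_character_,
                 sensitivity = vals[["sensitivity"]],
                 specificity = vals[["specificity"]],
                 precision = vals[["precision"]],
                 f1 = vals[["f1"]],
                 accuracy = vals[["accuracy"]],
                 error_rate = vals[["error_rate"]],
                 undefined = paste(names(vals)[is.na(vals)], collapse = ","))
}

#' Per-class and macro-averaged evaluation report
#'
#' One-vs-rest metrics for every class present in `true` or `predicted`
#' (restricted to the four phases when the labels are phases), a
#' macro-average row, and the multi-class accuracy/error rate computed from
#' the diagonal of the full confusion table (rows `class = "overall"`).
#'
#' @param true,predicted Label vectors of equal length.
#' @return A tibble of class `topo_metrics`: one row per class, one
#'   `"macro"` row (unweighted mean of the defined per-class values), one
#'   `"overall"` row where `accuracy` is the multi-class accuracy.
#' @export
metrics_report <- function(true, predicted) {
  true <- as.character(true)
  predicted <- as.character(predicted)
  classes <- unique(c(true, predicted))
  classes <- if (all(classes %in% phase_levels)) {
    intersect(phase_levels, classes)
  } else {
    sort(classes)
  }
  per <- dplyr::bind_rows(lapply(classes, function(cls) {
    compute_metrics(confusion(true, predicted, cls))
  }))
  macro <- dplyr::summarise(per, dplyr::across(
    c("sensitivity", "specificity", "precision", "f1", "accuracy", "error_rate"),
    ~ mean(.x, na.rm = TRUE)))
  macro <- dplyr::mutate(macro, class = "macro", undefined = "", .before = 1)
  overall_acc <- mean(true == predicted)
  overall <- tibble::tibble(class = "overall", sensitivity = NA_real_,
                            specificity = NA_real_, precision = NA_real_,
                            f1 = NA_real_, accuracy = overall_acc,
                            error_rate = 1 - overall_acc, undefined = "")
  out <- dplyr::bind_rows(per, macro, overall)
  structure(out, class = c("topo_metrics", class(out)))
}
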