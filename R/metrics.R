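# Pixel-wise evaluation: confusion counts, AAC/Dice and the six
# characteristic values, batch summaries.

#' Confusion counts between a predicted and a ground-truth mask
#'
#' Positive = object (polyp) pixel.
#'
#' @param pred,truth binary 0/1 matrices of equal dimensions.
#' @return object of class `confusion_counts`: list with `tp`, `fp`, `fn`,
#'   `tn` (their sum is the pixel count).
#' @export
confusion <- function(pred, truth) {
  check_mask(pred, "pred"); check_mask(truth, "truth")
  if (!identical(dim(pred), dim(truth))) {
    ap_stop("pred and truth must have identical dimensions", "apseg_invalid_input")
  }
  structure(list(tp = sum(pred == 1 & truth == 1),
                 fp = sum(pred == 1 & truth == 0),
                 fn = sum(pred == 0 & truth == 1),
                 tn = sum(pred == 0 & truth == 0)),
            class = "confusion_counts")
}

safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' Metric report from confusion counts
#'
#' Computes AAC = TP / (TP + FN) (identical to recall), Dice = 2 TP /
#' (2 TP + FP + FN), precision, recall, accuracy, specificity, fallout and
#' the F2-measure 5 TP / (5 TP + 4 FN + FP). Zero-denominator cases are
#' reported as NA, never silently as 0.
#'
#' @param counts a `confusion_counts`.
#' @return named list with `aac`, `dice`, `precision`, `recall`, `accuracy`,
#'   `specificity`, `fallout`, `f2`.
#' @export
metric_report <- function(counts) {
  if (!inherits(counts, "confusion_counts")) {
    ap_stop("counts must be a confusion_counts", "apseg_invalid_input")
  }
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  recall <- safe_div(tp, tp + fn)
  list(aac = recall,
       dice = safe_div(2 * tp, 2 * tp + fp + fn),
       precision = safe_div(tp, tp + fp),
       recall = recall,
       accuracy = safe_div(tp + tn, tp + tn + fp + fn),
       specificity = safe_div(tn, tn + fp),
       fallout = safe_div(fp, tn + fp),
       f2 = safe_div(5 * tp, 5 * tp + 4 * fn + fp))
}

#' Evaluate a batch of (prediction, truth) pairs
#'
#' @param preds,truths lists of binary masks, matched by position.
#' @param ids optional identifiers (default `seq_along`).
#' @param csv optional path: writes the per-image table as CSV.
#' @return list with `per_image` (data frame, one row per pair), `means`
#'   (arithmetic means over defined values) and `n_excluded` (per metric, how
#'   many NA values were excluded from the mean).
#' @export
batch_evaluate <- function(preds, truths, ids = NULL, csv = NULL) {
  if (!is.list(preds) || !is.list(truths) || length(preds) == 0 ||
      length(preds) != length(truths)) {
    ap_stop("preds and truths must be nonempty lists of equal length",
            "apseg_invalid_input")
  }
  if (is.null(ids)) ids <- as.character(seq_along(preds))
  rows <- lapply(seq_along(preds), function(k) {
    rep <- tryCatch(metric_report(confusion(preds[[k]], truths[[k]])),
                    error = function(e) ap_stop(
                      sprintf("pair %s: %s", ids[k], conditionMessage(e)),
                      "apseg_invalid_input"))
    data.frame(id = ids[k], as.data.frame(rep), stringsAsFactors = FALSE)
  })
  per_image <- do.call(rbind, rows)
  metric_cols <- setdiff(names(per_image), "id")
  means <- vapply(per_image[metric_cols],
                  function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE),
                  numeric(1))
  n_excluded <- vapply(per_image[metric_cols], function(v) sum(is.na(v)), integer(1))
  if (!is.null(csv)) write.csv(per_image, csv, row.names = FALSE)
  list(per_image = per_image, means = means, n_excluded = n_excluded)
}
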