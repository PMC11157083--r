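# Segmentation validation: confusion matrix and the five derived scores
# (accuracy, precision, recall, F1, Jaccard) between predicted and reference
# masks, optionally restricted to an evaluation region (e.g. the fully
# annotated z-sections of a test image).

#' Confusion matrix between two binary masks
#'
#' @param pred,ref Logical/0-1 arrays of identical shape.
#' @param eval_region Optional logical array of the same shape restricting
#'   the evaluated voxels (default: all).
#' @return List of class `confusion_matrix` with counts `tp`, `tn`, `fp`,
#'   `fn` and `n = tp + tn + fp + fn`.
#' @export
confusion_matrix <- function(pred, ref, eval_region = NULL) {
  if (!identical(dim(pred), dim(ref)) ||
      (is.null(dim(pred)) && length(pred) != length(ref)))
    stop("shape mismatch between pred and ref")
  p <- as.logical(pred); r <- as.logical(ref)
  if (!is.null(eval_region)) {
    if (!identical(dim(eval_region), dim(ref)) &&
        !(is.null(dim(eval_region)) && length(eval_region) == length(r)))
      stop("shape mismatch between eval_region and ref")
    keep <- as.logical(eval_region)
    p <- p[keep]; r <- r[keep]
  }
  cm <- list(tp = sum(p & r), tn = sum(!p & !r),
             fp = sum(p & !r), fn = sum(!p & r))
  cm$n <- cm$tp + cm$tn + cm$fp + cm$fn
  structure(cm, class = "confusion_matrix")
}

#' Score panel from a confusion matrix
#'
#' accuracy = (TP+TN)/(TP+TN+FP+FN); precision = TP/(TP+FP);
#' recall = TP/(TP+FN); F1 = 2PR/(P+R); Jaccard = TP/(TP+FP+FN).
#' A score whose denominator is zero is returned as `NA` (undefined), not 0;
#' with `tp == 0` but positives present, precision/recall/F1/Jaccard are 0.
#'
#' @param cm A `confusion_matrix`.
#' @return Named numeric vector `accuracy`, `precision`, `recall`, `f1`,
#'   `jaccard`, each in `[0, 1]` or `NA`.
#' @export
segmentation_scores <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$n == 0) stop("all-zero confusion matrix")
  tp <- cm$tp; tn <- cm$tn; fp <- cm$fp; fn <- cm$fn
  div <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- div(tp, tp + fp)
  recall <- div(tp, tp + fn)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall)
  else if (isTRUE(precision == 0) || isTRUE(recall == 0)) 0
  else NA_real_
  c(accuracy = div(tp + tn, cm$n),
    precision = precision,
    recall = recall,
    f1 = f1,
    jaccard = div(tp, tp + fp + fn))
}

#' Validate predictions across a test set
#'
#' Scores each predicted/reference mask pair and reports both the
#' macro-average (mean of per-image scores, the headline number) and the
#' micro-average (scores of the summed confusion matrix).
#'
#' @param preds,refs Lists of masks of equal length.
#' @param eval_regions Optional list of evaluation-region masks.
#' @return List with `per_image` (data.frame), `macro` and `micro`
#'   (named numeric vectors).
#' @export
validate_masks <- function(preds, refs, eval_regions = NULL) {
  stopifnot(length(preds) == length(refs))
  cms <- lapply(seq_along(preds), function(i)
    confusion_matrix(preds[[i]], refs[[i]],
                     if (is.null(eval_regions)) NULL else eval_regions[[i]]))
  per <- do.call(rbind, lapply(cms, function(cm)
    as.data.frame(as.list(segmentation_scores(cm)))))
  per$image <- seq_along(preds)
  total <- structure(list(tp = sum(vapply(cms, `[[`, 0, "tp")),
                          tn = sum(vapply(cms, `[[`, 0, "tn")),
                          fp = sum(vapply(cms, `[[`, 0, "fp")),
                          fn = sum(vapply(cms, `[[`, 0, "fn"))),
                     class = "confusion_matrix")
  total$n <- total$tp + total$tn + total$fp + total$fn
  list(per_image = per,
       macro = colMeans(per[, c("accuracy", "precision", "recall", "f1",
                                "jaccard")], na.rm = TRUE),
       micro = segmentation_scores(total))
}
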