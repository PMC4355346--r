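## Pixel-wise evaluation against manual ground truth: confusion counts
## over the field of view (vessel = positive class) and the
## sensitivity/specificity/accuracy metrics, with per-image and
## dataset-average reports.

#' Pixel-wise confusion counts
#'
#' Counted only over FOV-true pixels when \code{fov} is given (the
#' default evaluation region; full-frame evaluation dilutes specificity
#' and accuracy with the trivially dark surround). Vessel is the positive
#' class.
#'
#' @param pred,truth \code{BinaryMask}s (or logical matrices) of the
#'   prediction and the manual ground truth.
#' @param fov optional \code{BinaryMask} restricting the evaluated
#'   region.
#' @return A \code{\link{ConfusionCounts-class}} object.
#' @export
confusionCounts <- function(pred, truth, fov = NULL) {
  p <- as.matrix(pred); g <- as.matrix(truth)
  if (!all(dim(p) == dim(g))) stop("prediction and truth shapes differ")
  sel <- if (is.null(fov)) matrix(TRUE, nrow(p), ncol(p)) else as.matrix(fov)
  if (!all(dim(sel) == dim(p))) stop("FOV shape differs")
  new("ConfusionCounts",
      tp = sum(p & g & sel), fp = sum(p & !g & sel),
      tn = sum(!p & !g & sel), fn = sum(!p & g & sel))
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' \code{Se = TP/(TP+FN)}, \code{Sp = TN/(TN+FP)},
#' \code{Acc = (TP+TN)/(TP+FN+TN+FP)}. A zero denominator yields NA for
#' that metric, flagged in \code{undefined}; all-zero counts are an
#' error (nothing was evaluated).
#'
#' @param counts a \code{\link{ConfusionCounts-class}} object.
#' @param imageId identifier carried into reports.
#' @return A \code{\link{MetricReport-class}} object.
#' @export
segMetrics <- function(counts, imageId = "image") {
  tp <- counts@tp; fp <- counts@fp; tn <- counts@tn; fn <- counts@fn
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty evaluation: all confusion counts are zero")
  undef <- character(0)
  se <- if (tp + fn > 0) tp / (tp + fn) else { undef <- c(undef, "sensitivity"); NA_real_ }
  sp <- if (tn + fp > 0) tn / (tn + fp) else { undef <- c(undef, "specificity"); NA_real_ }
  acc <- (tp + tn) / total
  new("MetricReport", sensitivity = se, specificity = sp, accuracy = acc,
      counts = counts, imageId = as.character(imageId), undefined = undef)
}

#' Dataset-average report
#'
#' Unweighted (macro) arithmetic mean of per-image Se/Sp/Acc, as printed
#' in an "Average" row under the per-image table.
#'
#' @param reports list of \code{\link{MetricReport-class}} objects.
#' @return A data.frame with one row per image (id, Se, Sp, Acc, TP, FP,
#'   TN, FN) plus a final \code{"Average"} row (counts NA there).
#' @export
datasetReport <- function(reports) {
  if (length(reports) < 1L) stop("at least one report is required")
  rows <- lapply(reports, function(r) {
    data.frame(id = r@imageId, sensitivity = r@sensitivity,
               specificity = r@specificity, accuracy = r@accuracy,
               tp = r@counts@tp, fp = r@counts@fp, tn = r@counts@tn,
               fn = r@counts@fn, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  avg <- data.frame(id = "Average",
                    sensitivity = mean(tab$sensitivity, na.rm = TRUE),
                    specificity = mean(tab$specificity, na.rm = TRUE),
                    accuracy = mean(tab$accuracy, na.rm = TRUE),
                    tp = NA_real_, fp = NA_real_, tn = NA_real_,
                    fn = NA_real_, stringsAsFactors = FALSE)
  rbind(tab, avg)
}
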