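# Per-class pixel confusion counting and the three segmentation metrics:
# IoU = TP / (TP + FN + FP), Precision = TP / (TP + FP),
# Recall = TP / (TP + FN), evaluated one-vs-rest per class and aggregated
# over a test set either micro (pool counts, then compute) or macro (average
# per-slice metrics).

#' Per-class confusion counts
#'
#' One-vs-rest binarization at class `cls`: TP counts pixels predicted and
#' labeled `cls`, FP pixels predicted `cls` but labeled otherwise, FN pixels
#' labeled `cls` but predicted otherwise.  Counts are additive under dataset
#' concatenation.
#'
#' @param pred,gt integer label matrices of identical shape over `{0, 1, 2}`.
#' @param cls the class label to score (1 = liver, 2 = tumor).
#' @return named numeric vector `c(tp, fp, fn)`.
#' @export
count_confusion <- function(pred, gt, cls) {
  if (!identical(dim(pred), dim(gt)))
    stop(sprintf("prediction %s and ground truth %s have mismatched shapes",
                 paste(dim(pred), collapse = "x"), paste(dim(gt), collapse = "x")))
  p <- pred == cls
  g <- gt == cls
  c(tp = sum(p & g), fp = sum(p & !g), fn = sum(!p & g))
}

metric_from_counts <- function(counts, den_terms) {
  den <- sum(counts[den_terms])
  if (den == 0) 1.0 else unname(counts["tp"] / den)
}

#' Segmentation metrics from confusion counts
#'
#' `iou(c) = TP / (TP + FN + FP)`, `precision(c) = TP / (TP + FP)`,
#' `recall(c) = TP / (TP + FN)`.  All three lie in `[0, 1]` and
#' `iou <= min(precision, recall)`.  When the denominator is empty (the
#' class absent from both masks) the convention is 1.0 — perfect agreement
#' on an absent class; [evaluate_dataset()] flags this case in its report.
#'
#' @param counts named vector with elements `tp`, `fp`, `fn` (as returned by
#'   [count_confusion()]).
#' @return a number in `[0, 1]`.
#' @export
iou <- function(counts) metric_from_counts(counts, c("tp", "fn", "fp"))

#' @rdname iou
#' @export
precision <- function(counts) metric_from_counts(counts, c("tp", "fp"))

#' @rdname iou
#' @export
recall <- function(counts) metric_from_counts(counts, c("tp", "fn"))

#' Evaluate a set of predicted masks
#'
#' Scores liver (label 1) and tumor (label 2) over a list of
#' prediction/ground-truth pairs.  Micro aggregation (the default, and the
#' common LiTS convention) sums confusion counts over all slices and applies
#' the metric formulas once per class; it is invariant under slice
#' duplication.  Macro aggregation averages per-slice metrics over the
#' slices in which the class occurs (in either mask).
#'
#' @param pairs non-empty list of `list(pred =, gt =)` label-matrix pairs.
#' @param mode `"micro"` (default) or `"macro"`.
#' @param classes named integer vector of class labels to score.
#' @return an object of class `spaunet_metrics`: per class the three metrics,
#'   the pooled counts, and an `empty_class` flag marking the absent-class
#'   convention; plus the aggregation mode.
#' @export
evaluate_dataset <- function(pairs, mode = c("micro", "macro"),
                             classes = c(liver = 1L, tumor = 2L)) {
  mode <- match.arg(mode)
  if (length(pairs) == 0L) stop("cannot evaluate an empty dataset")
  out <- list(aggregation = mode, n_slices = length(pairs), classes = list())
  for (nm in names(classes)) {
    cl <- classes[[nm]]
    per <- lapply(pairs, function(p) count_confusion(p$pred, p$gt, cl))
    pooled <- Reduce(`+`, per)
    if (mode == "micro") {
      res <- list(iou = iou(pooled), precision = precision(pooled),
                  recall = recall(pooled))
    } else {
      present <- vapply(per, function(cc) sum(cc) > 0, logical(1))
      use <- if (any(present)) per[present] else per
      res <- list(iou = mean(vapply(use, iou, 1)),
                  precision = mean(vapply(use, precision, 1)),
                  recall = mean(vapply(use, recall, 1)))
    }
    res$counts <- pooled
    res$empty_class <- sum(pooled) == 0
    out$classes[[nm]] <- res
  }
  class(out) <- "spaunet_metrics"
  out
}

#' @export
print.spaunet_metrics <- function(x, ...) {
  cat(sprintf("Segmentation metrics (%s aggregation over %d slices)\n",
              x$aggregation, x$n_slices))
  for (nm in names(x$classes)) {
    cl <- x$classes[[nm]]
    cat(sprintf("  %-6s IoU %.3f  Precision %.3f  Recall %.3f%s\n",
                nm, cl$iou, cl$precision, cl$recall,
                if (cl$empty_class) "  [class absent]" else ""))
  }
  invisible(x)
}

#' Serialize a metrics report to JSON
#'
#' Writes counts, per-class metrics, the aggregation mode and a content hash
#' of the report so runs can be compared.
#'
#' @param report a `spaunet_metrics` object from [evaluate_dataset()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  obj <- unclass(report)
  for (nm in names(obj$classes))
    obj$classes[[nm]]$counts <- as.list(obj$classes[[nm]]$counts)
  txt <- paste(format(unlist(obj), digits = 10), collapse = "|")
  obj$content_hash <- sprintf("%08x",
    Reduce(function(h, ch) (h * 31 + ch) %% 2^31, utf8ToInt(txt), accumulate = FALSE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
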