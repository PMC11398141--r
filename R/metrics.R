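# Overlap metrics: Dice, Jaccard, precision, recall from pixel confusion
# counts, aggregated over an evaluation set either per case or pooled.

#' Pixel confusion counts
#'
#' @param pred_mask,true_mask Binary (logical or 0/1) arrays of equal shape.
#' @return List of class `confusion_counts` with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(pred_mask, true_mask) {
  if (length(pred_mask) != length(true_mask) ||
      !identical(dim(pred_mask), dim(true_mask))) {
    stop("pred_mask and true_mask must have identical shapes")
  }
  p <- as.logical(pred_mask)
  t <- as.logical(true_mask)
  tp <- sum(p & t)
  fp <- sum(p & !t)
  fn <- sum(!p & t)
  structure(list(tp = tp, fp = fp, fn = fn,
                 tn = length(p) - tp - fp - fn),
            class = "confusion_counts")
}

#' Dice, Jaccard, precision and recall from confusion counts
#'
#' Degenerate cases follow common liver-segmentation practice: if both the
#' truth and the prediction are empty all metrics are 1; if the truth is
#' empty but the prediction is not, all are 0; an empty prediction against a
#' non-empty truth scores 0 on every ratio whose denominator vanishes.
#'
#' @param counts A `confusion_counts` object (or list with tp/fp/fn).
#' @return Named list with `dice`, `jaccard`, `precision`, `recall` in
#'   \[0, 1\]. The identity `jaccard = dice / (2 - dice)` holds.
#' @export
metric_suite <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (tp + fp + fn == 0) {
    return(list(dice = 1, jaccard = 1, precision = 1, recall = 1))
  }
  if (tp + fn == 0) {          # empty truth, non-empty prediction
    return(list(dice = 0, jaccard = 0, precision = 0, recall = 0))
  }
  list(dice = 2 * tp / (2 * tp + fp + fn),
       jaccard = tp / (tp + fp + fn),
       precision = if (tp + fp > 0) tp / (tp + fp) else 0,
       recall = tp / (tp + fn))
}

#' Aggregate per-case confusion counts into a metric report
#'
#' @param cases A list of cases; each case is a named list mapping class name
#'   (e.g. `"liver"`, `"tumor"`) to a `confusion_counts`.
#' @param mode `"per_case_mean"` (mean of per-case metrics, the default) or
#'   `"pooled"` (metrics of summed counts).
#' @return A `metric_report`: list with `per_class` (data frame of
#'   percentages), `n_cases` and `mode`.
#' @export
aggregate_metrics <- function(cases, mode = c("per_case_mean", "pooled")) {
  mode <- match.arg(mode)
  if (length(cases) == 0) stop("cannot aggregate an empty set of cases")
  classes <- names(cases[[1L]])
  rows <- lapply(classes, function(cl) {
    if (mode == "per_case_mean") {
      per <- vapply(cases, function(cs) unlist(metric_suite(cs[[cl]])), numeric(4))
      m <- rowMeans(per)
    } else {
      tot <- list(tp = 0, fp = 0, fn = 0, tn = 0)
      for (cs in cases) {
        tot$tp <- tot$tp + cs[[cl]]$tp; tot$fp <- tot$fp + cs[[cl]]$fp
        tot$fn <- tot$fn + cs[[cl]]$fn; tot$tn <- tot$tn + cs[[cl]]$tn
      }
      m <- unlist(metric_suite(tot))
    }
    data.frame(class = cl, dice = 100 * m[["dice"]], jaccard = 100 * m[["jaccard"]],
               precision = 100 * m[["precision"]], recall = 100 * m[["recall"]],
               stringsAsFactors = FALSE)
  })
  structure(list(per_class = do.call(rbind, rows),
                 n_cases = length(cases), mode = mode),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Metric report (%s over %d case%s)\n", x$mode, x$n_cases,
              if (x$n_cases == 1) "" else "s"))
  df <- x$per_class
  df[, -1] <- round(df[, -1], 2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a metric report as a tab-separated table
#'
#' Columns mirror the usual reporting layout: class, Dice, Jaccard,
#' Precision, Recall (percentages).
#'
#' @param report A `metric_report`.
#' @param path Output file.
#' @export
write_metric_report <- function(report, path) {
  stopifnot(inherits(report, "metric_report"))
  df <- report$per_class
  names(df) <- c("Class", "Dice", "Jaccard", "Precision", "Recall")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
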