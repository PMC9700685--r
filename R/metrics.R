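# Overlap metrics for binary segmentation masks. Degenerate-case
# conventions (the formulas are silent there): if both masks are empty all
# four metrics are 1; an empty prediction against a non-empty ground truth
# scores 0; an empty ground truth makes sensitivity 1 by convention.

.check_pair <- function(gt, pred) {
  if (is.null(dim(gt)) || is.null(dim(pred)) || !all(dim(gt) == dim(pred)))
    stop("ground truth and prediction must have identical shape")
  if (!all(gt %in% c(0, 1)) || !all(pred %in% c(0, 1)))
    stop("masks must be binary (0/1)")
  list(ng = sum(gt), np = sum(pred), ni = sum(gt * pred))
}

#' Dice similarity coefficient
#'
#' `2 |G intersect P| / (|G| + |P|)` between a ground-truth mask `gt` and a
#' predicted mask `pred`; 1 when both masks are empty.
#'
#' @param gt,pred Binary (0/1) masks of identical shape.
#' @return Value in \[0, 1\].
#' @examples
#' g <- matrix(0, 4, 4); g[1:2, 1:2] <- 1
#' dsc(g, g)  # 1
#' @export
dsc <- function(gt, pred) {
  k <- .check_pair(gt, pred)
  if (k$ng + k$np == 0) return(1)
  2 * k$ni / (k$ng + k$np)
}

#' Intersection over union (Jaccard index)
#'
#' `|G intersect P| / |G union P|`; 1 when both masks are empty.
#'
#' @inheritParams dsc
#' @return Value in \[0, 1\].
#' @export
iou <- function(gt, pred) {
  k <- .check_pair(gt, pred)
  u <- k$ng + k$np - k$ni
  if (u == 0) return(1)
  k$ni / u
}

#' Sensitivity (pixel recall)
#'
#' Proportion of ground-truth foreground pixels that the prediction
#' recovers: `|G intersect P| / |G|`; 1 when the ground truth is empty.
#'
#' @inheritParams dsc
#' @return Value in \[0, 1\].
#' @export
sensitivity <- function(gt, pred) {
  k <- .check_pair(gt, pred)
  if (k$ng == 0) return(1)
  k$ni / k$ng
}

#' Precision (pixel positive predictive value)
#'
#' Proportion of predicted foreground pixels that are correct:
#' `|G intersect P| / |P|`; 1 when both masks are empty, 0 when the
#' prediction is empty but the ground truth is not.
#'
#' @inheritParams dsc
#' @return Value in \[0, 1\].
#' @export
precision <- function(gt, pred) {
  k <- .check_pair(gt, pred)
  if (k$np == 0) return(if (k$ng == 0) 1 else 0)
  k$ni / k$np
}

#' All four overlap metrics of one mask pair
#'
#' @inheritParams dsc
#' @return A `seg_metrics` list: `dsc`, `iou`, `sensitivity`, `precision`,
#'   and the pixel counts `n_gt`, `n_pred`, `n_intersection`.
#' @export
seg_metrics <- function(gt, pred) {
  k <- .check_pair(gt, pred)
  structure(list(dsc = dsc(gt, pred), iou = iou(gt, pred),
                 sensitivity = sensitivity(gt, pred),
                 precision = precision(gt, pred),
                 n_gt = k$ng, n_pred = k$np, n_intersection = k$ni),
            class = "seg_metrics")
}

#' Aggregate overlap metrics over a batch of mask pairs
#'
#' Computes per-pair metrics and two aggregates: the macro average (mean of
#' per-pair metrics; the headline aggregate) and the micro average (metrics
#' of the pooled pixel counts). Both are reported because published results
#' rarely state which average was used.
#'
#' @param gts,preds Lists of binary masks, pairwise of identical shape.
#' @param ids Optional character ids for the per-pair table.
#' @return A `seg_report`: list with `per_sample` (data.frame), `macro`,
#'   `micro`, and `n`.
#' @export
batch_report <- function(gts, preds, ids = NULL) {
  stopifnot(is.list(gts), is.list(preds))
  if (length(gts) == 0) stop("empty list of mask pairs")
  if (length(gts) != length(preds)) stop("gts and preds differ in length")
  if (is.null(ids)) ids <- sprintf("pair%04d", seq_along(gts))
  rows <- lapply(seq_along(gts), function(i) {
    m <- seg_metrics(gts[[i]], preds[[i]])
    data.frame(id = ids[i], dsc = m$dsc, iou = m$iou,
               sensitivity = m$sensitivity, precision = m$precision,
               n_gt = m$n_gt, n_pred = m$n_pred,
               n_intersection = m$n_intersection, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  macro <- colMeans(per[c("dsc", "iou", "sensitivity", "precision")])
  ng <- sum(per$n_gt); np <- sum(per$n_pred); ni <- sum(per$n_intersection)
  micro <- c(
    dsc = if (ng + np == 0) 1 else 2 * ni / (ng + np),
    iou = if (ng + np - ni == 0) 1 else ni / (ng + np - ni),
    sensitivity = if (ng == 0) 1 else ni / ng,
    precision = if (np == 0) (if (ng == 0) 1 else 0) else ni / np)
  structure(list(per_sample = per, macro = as.list(macro),
                 micro = as.list(micro), n = length(gts)),
            class = "seg_report")
}

#' Write a segmentation report to disk
#'
#' Writes the per-sample table as CSV and the macro/micro aggregates as
#' JSON next to it.
#'
#' @param report A `seg_report` from [batch_report()].
#' @param path Output path without extension; `<path>.csv` and
#'   `<path>.json` are written.
#' @return The two file paths, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "seg_report"))
  csv <- paste0(path, ".csv"); js <- paste0(path, ".json")
  utils::write.csv(report$per_sample, csv, row.names = FALSE)
  jsonlite::write_json(list(n = report$n, macro = report$macro,
                            micro = report$micro),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("DSC %.4f  IoU %.4f  sensitivity %.4f  precision %.4f  (|G|=%d |P|=%d |G&P|=%d)\n",
              x$dsc, x$iou, x$sensitivity, x$precision,
              x$n_gt, x$n_pred, x$n_intersection))
  invisible(x)
}

#' @export
print.seg_report <- function(x, ...) {
  cat("<seg_report> n =", x$n, "\n")
  cat(sprintf("  macro: DSC %.4f  IoU %.4f  sens %.4f  prec %.4f\n",
              x$macro$dsc, x$macro$iou, x$macro$sensitivity, x$macro$precision))
  cat(sprintf("  micro: DSC %.4f  IoU %.4f  sens %.4f  prec %.4f\n",
              x$micro$dsc, x$micro$iou, x$micro$sensitivity, x$micro$precision))
  invisible(x)
}
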