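# AP from a score-ordered TP/FP flag sequence: all-points interpolation of the
# precision-recall curve (monotone precision envelope), with the boundary
# convention P = 1 at R = 0 contributing nothing to the sum.
ap_from_flags <- function(tp_flags, n_gt) {
  if (n_gt <= 0) stop("average precision needs at least one ground-truth box",
                      call. = FALSE)
  if (!length(tp_flags)) return(0)
  cum_tp <- cumsum(tp_flags)
  cum_fp <- cumsum(!tp_flags)
  recall <- cum_tp / n_gt
  precision <- cum_tp / (cum_tp + cum_fp)
  mrec <- c(0, recall)
  mpre <- c(0, precision)
  for (i in rev(seq_len(length(mpre) - 1L))) {
    mpre[i] <- max(mpre[i], mpre[i + 1L])
  }
  sum(diff(mrec) * mpre[-1L])
}

pr_points_from_flags <- function(tp_flags, n_gt) {
  if (!length(tp_flags)) {
    return(data.frame(recall = numeric(), precision = numeric()))
  }
  cum_tp <- cumsum(tp_flags)
  cum_fp <- cumsum(!tp_flags)
  data.frame(recall = cum_tp / n_gt,
             precision = cum_tp / (cum_tp + cum_fp))
}

undefined_ap_error <- function(class) {
  stop(errorCondition(
    sprintf("class '%s' has no ground-truth boxes: AP undefined", class),
    class = c("boxfusion_undefined_ap", "error", "condition")
  ))
}

#' Average precision for one class
#'
#' Summarizes the precision-recall curve of one class at a fixed IoU
#' threshold. Predictions are sorted by descending confidence, matched
#' greedily to ground truth ([match_detections()]), and AP is the area under
#' the monotone (interpolated) precision envelope over recall — the all-points
#' summary `sum((R_k - R_(k+1)) * P_k)` with the `R = 0, P = 1` boundary.
#'
#' @param preds Box `data.frame` with scores.
#' @param gt A [ground_truth()] object; must contain at least one box of
#'   `class`.
#' @param class Class label to evaluate.
#' @param iou_threshold IoU cutoff for a true positive (default 0.5).
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(preds, gt, class, iou_threshold = 0.5) {
  stopifnot(inherits(gt, "ground_truth"))
  class <- as.character(class)
  n_gt <- sum(gt$boxes$label == class)
  if (n_gt == 0L) undefined_ap_error(class)
  preds <- validate_boxes(preds, require_score = TRUE)
  p <- preds[preds$label == class, , drop = FALSE]
  if (!nrow(p)) return(0)
  m <- match_detections(p, subset_ground_truth(gt, classes = class),
                        iou_threshold)
  ap_from_flags(m$flags$tp, n_gt)
}

#' Mean average precision over the ground-truth classes
#'
#' Computes per-class AP for every class present in the ground truth and
#' averages them with equal weight. Classes with ground truth but no
#' predictions score AP 0; classes predicted but absent from the ground truth
#' are excluded from the mean and reported in `ignored_classes`.
#'
#' @inheritParams average_precision
#' @return An object of class `eval_result`: `per_class_ap` (named numeric),
#'   `map`, `pr_points` (per class, recall/precision `data.frame`s),
#'   `iou_threshold`, `ignored_classes`.
#' @export
mean_average_precision <- function(preds, gt, iou_threshold = 0.5) {
  stopifnot(inherits(gt, "ground_truth"))
  if (!nrow(gt$boxes)) stop("ground truth is empty", call. = FALSE)
  preds <- validate_boxes(preds, require_score = TRUE)
  classes <- sort(unique(gt$boxes$label))
  ignored <- sort(setdiff(unique(preds$label), classes))

  m <- match_detections(preds, gt, iou_threshold)
  per_class <- stats::setNames(numeric(length(classes)), classes)
  pr <- stats::setNames(vector("list", length(classes)), classes)
  for (cl in classes) {
    n_gt <- sum(gt$boxes$label == cl)
    fl <- m$flags$tp[m$flags$label == cl]
    per_class[[cl]] <- ap_from_flags(fl, n_gt)
    pr[[cl]] <- pr_points_from_flags(fl, n_gt)
  }
  structure(
    list(per_class_ap = per_class, map = mean(per_class), pr_points = pr,
         iou_threshold = iou_threshold, ignored_classes = ignored),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, digits = 2, ...) {
  cat(sprintf("<eval_result> AP@%.2f IoU\n", x$iou_threshold))
  tab <- data.frame(class = names(x$per_class_ap),
                    AP = round(unname(x$per_class_ap), digits))
  print(tab, row.names = FALSE)
  cat(sprintf("mAP: %.*f\n", digits, x$map))
  if (length(x$ignored_classes)) {
    cat("ignored classes (no ground truth): ",
        paste(x$ignored_classes, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
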