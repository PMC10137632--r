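#' FROC curve: TPR against false positives per image
#'
#' Sweeps a confidence threshold over the detections (default 0 to 1 in steps
#' of 0.02) and records, at each threshold, the pooled true positive rate
#' `TP / (TP + FN)` and the false positives per image `FPPI = FP / n_images`
#' across all classes. Matching follows [match_detections()]; because greedy
#' matching processes predictions in descending score order, the matches of
#' any score-thresholded subset are the corresponding prefix of the full
#' match, so the sweep is computed from one matching pass (identical to
#' re-matching at every threshold).
#'
#' @param preds Box `data.frame` with scores.
#' @param gt A [ground_truth()] object with at least one box (after any class
#'   filter) and at least one image.
#' @param iou_threshold IoU cutoff for a true positive (default 0.5).
#' @param sweep Strictly increasing confidence thresholds in `[0, 1]`.
#' @param classes Optional class filter: restrict the curve to these labels
#'   (default: pool all classes into a single curve).
#' @param normalization Upper FPPI bound for the area summary; default the
#'   largest FPPI observed on the curve. Supply a shared bound when comparing
#'   several curves.
#' @return An object of class `froc_curve`: `points` (a `data.frame` of
#'   `threshold`, `fppi`, `tpr`), `fauc` in `[0, 1]`, and `normalization`.
#' @export
froc_curve <- function(preds, gt, iou_threshold = 0.5,
                       sweep = seq(0, 1, by = 0.02),
                       classes = NULL, normalization = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  if (!length(sweep)) stop("empty confidence sweep", call. = FALSE)
  if (any(diff(sweep) <= 0) || min(sweep) < 0 || max(sweep) > 1) {
    stop("sweep must be strictly increasing within [0, 1]", call. = FALSE)
  }
  n_images <- length(gt$images)
  if (n_images == 0L) stop("ground truth contains zero images", call. = FALSE)
  preds <- validate_boxes(preds, require_score = TRUE)
  if (!is.null(classes)) {
    gt <- subset_ground_truth(gt, classes = classes)
    preds <- preds[preds$label %in% as.character(classes), , drop = FALSE]
  }
  n_gt <- nrow(gt$boxes)
  if (n_gt == 0L) stop("no ground-truth boxes to sweep against", call. = FALSE)

  m <- match_detections(preds, gt, iou_threshold)
  sc <- m$flags$score # descending
  cum_tp <- cumsum(m$flags$tp)
  cum_fp <- cumsum(!m$flags$tp)
  # retained set at threshold t = predictions with score >= t (a prefix)
  k <- vapply(sweep, function(t) sum(sc >= t), integer(1))
  tp <- ifelse(k > 0, cum_tp[pmax(k, 1L)], 0)
  fp <- ifelse(k > 0, cum_fp[pmax(k, 1L)], 0)
  pts <- data.frame(
    threshold = sweep,
    fppi = fp / n_images,
    tpr = tp / n_gt
  )
  norm <- normalization %||% max(pts$fppi)
  structure(
    list(points = pts,
         fauc = froc_auc(pts$fppi, pts$tpr, norm),
         normalization = norm),
    class = "froc_curve"
  )
}

#' Area under a TPR-vs-FPPI curve
#'
#' Trapezoidal integration of TPR over FPPI on `[0, normalization]`, divided
#' by `normalization` so the result lies in `[0, 1]`. The curve is read as the
#' best TPR attained at each FPPI; if the lowest observed FPPI is positive the
#' curve is anchored at `(0, 0)`, and beyond the largest observed FPPI the
#' last TPR is carried flat. A curve that never leaves FPPI 0 (no false
#' positive at any threshold) has area equal to its best TPR.
#'
#' @param fppi,tpr Numeric vectors of curve coordinates.
#' @param normalization Positive FPPI upper bound, or 0 for a degenerate
#'   all-zero-FPPI curve.
#' @return Normalized area in `[0, 1]`.
#' @export
froc_auc <- function(fppi, tpr, normalization = max(fppi)) {
  stopifnot(length(fppi) == length(tpr), length(fppi) > 0)
  if (normalization < 0) stop("normalization must be >= 0", call. = FALSE)
  if (normalization == 0) {
    if (any(fppi > 0)) stop("normalization 0 but curve has positive FPPI",
                            call. = FALSE)
    return(max(tpr))
  }
  # best tpr at each distinct fppi, ascending
  f <- sort(unique(fppi))
  t <- vapply(f, function(v) max(tpr[fppi == v]), numeric(1))
  if (f[1] > 0) {
    f <- c(0, f)
    t <- c(0, t)
  }
  if (max(f) < normalization) {
    f <- c(f, normalization)
    t <- c(t, t[length(t)])
  } else if (max(f) > normalization) {
    t_at <- stats::approx(f, t, xout = normalization, rule = 2)$y
    keep <- f < normalization
    f <- c(f[keep], normalization)
    t <- c(t[keep], t_at)
  }
  pracma::trapz(f, t) / normalization
}

#' @export
print.froc_curve <- function(x, ...) {
  cat(sprintf(
    "<froc_curve> %d thresholds, FAUC %.3f over FPPI [0, %.3g]\n",
    nrow(x$points), x$fauc, x$normalization
  ))
  invisible(x)
}

#' Plot a FROC curve
#'
#' @param x A `froc_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.froc_curve <- function(x, ...) {
  o <- order(x$points$fppi)
  graphics::plot(x$points$fppi[o], x$points$tpr[o], type = "s",
                 xlab = "False positives per image (FPPI)",
                 ylab = "True positive rate (TPR)",
                 ylim = c(0, 1), ...)
  invisible(x)
}
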