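#' Match predictions to ground truth
#'
#' Greedy assignment in descending score order, class-wise and image-wise: a
#' prediction is a true positive iff it reaches at least `iou_threshold` IoU
#' with a not-yet-matched ground-truth box of the same class on the same image
#' (the highest-IoU such box; ties broken by earliest annotation index). Each
#' ground-truth box is matched at most once. Remaining predictions are false
#' positives; unmatched ground-truth boxes are false negatives. Predictions of
#' a class absent from the ground truth are flagged and counted as false
#' positives.
#'
#' @param preds Box `data.frame` with scores.
#' @param gt A [ground_truth()] object.
#' @param iou_threshold IoU cutoff in `[0, 1]` for a positive match.
#' @return An object of class `match_result` with elements:
#'   \describe{
#'     \item{counts}{per-class `data.frame` of `n_gt`, `tp`, `fp`, `fn`;}
#'     \item{flags}{per-prediction `data.frame` (`image_id`, `label`, `score`,
#'       `tp`, `known_class`, `pred_row`) ordered by descending score;}
#'     \item{pairs}{assigned (prediction row, ground-truth row, IoU) triples;}
#'     \item{iou_threshold}{the cutoff used.}
#'   }
#' @export
match_detections <- function(preds, gt, iou_threshold = 0.5) {
  preds <- validate_boxes(preds, require_score = TRUE)
  stopifnot(inherits(gt, "ground_truth"))
  stopifnot(is.numeric(iou_threshold), iou_threshold >= 0, iou_threshold <= 1)
  gtb <- gt$boxes
  known <- unique(gtb$label)

  ord <- order(-preds$score, seq_len(nrow(preds)))
  p <- preds[ord, , drop = FALSE]
  n <- nrow(p)
  tp <- logical(n)
  pair_gt <- rep(NA_integer_, n)
  pair_iou <- rep(NA_real_, n)
  gt_taken <- logical(nrow(gtb))

  gmat <- as.matrix(gtb[, c("x1", "y1", "x2", "y2"), drop = FALSE])
  # candidate gt rows per (image, class) cell, computed once
  if (nrow(gtb)) {
    cell <- split(seq_len(nrow(gtb)), paste(gtb$image_id, gtb$label, sep = "\r"))
  } else {
    cell <- list()
  }
  for (i in seq_len(n)) {
    cand <- cell[[paste(p$image_id[i], p$label[i], sep = "\r")]]
    cand <- cand[!gt_taken[cand]]
    if (!length(cand)) next
    ious <- iou_many(as.numeric(p[i, c("x1", "y1", "x2", "y2")]),
                     gmat[cand, , drop = FALSE])
    best <- which.max(ious) # first max -> earliest-index tie-break
    if (ious[best] >= iou_threshold) {
      tp[i] <- TRUE
      gt_taken[cand[best]] <- TRUE
      pair_gt[i] <- cand[best]
      pair_iou[i] <- ious[best]
    }
  }

  flags <- data.frame(
    image_id = p$image_id, label = p$label, score = p$score,
    tp = tp, known_class = p$label %in% known,
    pred_row = ord, stringsAsFactors = FALSE
  )
  classes <- sort(unique(c(gtb$label, p$label)))
  n_gt <- vapply(classes, function(cl) sum(gtb$label == cl), integer(1))
  tp_c <- vapply(classes, function(cl) sum(tp[p$label == cl]), integer(1))
  fp_c <- vapply(classes, function(cl) sum(!tp[p$label == cl]), integer(1))
  counts <- data.frame(
    label = classes, n_gt = n_gt, tp = tp_c, fp = fp_c, fn = n_gt - tp_c,
    stringsAsFactors = FALSE, row.names = NULL
  )
  pairs <- data.frame(
    pred_row = ord[tp], gt_row = pair_gt[tp], iou = pair_iou[tp]
  )
  structure(
    list(counts = counts, flags = flags, pairs = pairs,
         iou_threshold = iou_threshold),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> IoU threshold %.2f\n", x$iou_threshold))
  print(x$counts, row.names = FALSE)
  invisible(x)
}
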