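# Independent brute-force oracles and random-instance generators. These share
# no code with the package internals: IoU, matching and AP are recomputed with
# explicit loops and an explicit precision-envelope integration so the fast
# paths can be checked against them.

oracle_iou <- function(a, b) {
  ix1 <- max(a[1], b[1]); iy1 <- max(a[2], b[2])
  ix2 <- min(a[3], b[3]); iy2 <- min(a[4], b[4])
  if (ix2 <= ix1 || iy2 <= iy1) return(0)
  inter <- (ix2 - ix1) * (iy2 - iy1)
  inter / ((a[3] - a[1]) * (a[4] - a[2]) +
             (b[3] - b[1]) * (b[4] - b[2]) - inter)
}

# Greedy matching by descending score, explicit O(n * m) scan per prediction.
# Returns TP flags in descending-score order.
oracle_match_flags <- function(preds, gtb, thr) {
  ord <- order(-preds$score, seq_len(nrow(preds)))
  p <- preds[ord, , drop = FALSE]
  taken <- rep(FALSE, nrow(gtb))
  flags <- logical(nrow(p))
  for (i in seq_len(nrow(p))) {
    best_j <- 0L
    best_iou <- -1
    for (j in seq_len(nrow(gtb))) {
      if (taken[j]) next
      if (gtb$label[j] != p$label[i] || gtb$image_id[j] != p$image_id[i]) next
      v <- oracle_iou(as.numeric(p[i, c("x1", "y1", "x2", "y2")]),
                      as.numeric(gtb[j, c("x1", "y1", "x2", "y2")]))
      if (v > best_iou) {
        best_iou <- v
        best_j <- j
      }
    }
    if (best_j > 0L && best_iou >= thr) {
      flags[i] <- TRUE
      taken[best_j] <- TRUE
    }
  }
  flags
}

# All-cutoff AP oracle: re-match the top-k predictions for every cutoff k,
# record (recall, precision), then integrate the precision envelope over the
# distinct recall levels down to zero.
oracle_ap <- function(preds, gtb, thr) {
  n_gt <- nrow(gtb)
  stopifnot(n_gt > 0)
  if (!nrow(preds)) return(0)
  ord <- order(-preds$score, seq_len(nrow(preds)))
  p <- preds[ord, , drop = FALSE]
  R <- P <- numeric(nrow(p))
  for (k in seq_len(nrow(p))) {
    fl <- oracle_match_flags(p[seq_len(k), , drop = FALSE], gtb, thr)
    tp <- sum(fl)
    R[k] <- tp / n_gt
    P[k] <- tp / k
  }
  recs <- c(sort(unique(R), decreasing = TRUE), 0)
  ap <- 0
  for (i in seq_len(length(recs) - 1L)) {
    r <- recs[i]
    if (r == 0) break
    ap <- ap + (recs[i] - recs[i + 1L]) * max(P[R >= r - 1e-12])
  }
  ap
}

# Random box with continuous coordinates (continuous coords make exact IoU
# ties measure-zero, so tie-break conventions cannot diverge).
random_box_row <- function(image_id = "img1", label = "a", score = NULL,
                           span = 20) {
  x1 <- runif(1, 0, span * 0.7)
  y1 <- runif(1, 0, span * 0.7)
  w <- runif(1, span * 0.1, span * 0.5)
  h <- runif(1, span * 0.1, span * 0.5)
  df <- data.frame(image_id = image_id, label = label,
                   x1 = x1, y1 = y1, x2 = x1 + w, y2 = y1 + h,
                   stringsAsFactors = FALSE)
  if (!is.null(score)) df$score <- score
  df
}

random_instance <- function(max_boxes = 8) {
  n_gt <- sample(1:4, 1)
  n_pred <- sample(0:max_boxes, 1)
  gtb <- do.call(rbind, lapply(seq_len(n_gt), function(i)
    random_box_row(image_id = sample(c("img1", "img2"), 1),
                   label = sample(c("a", "b"), 1))))
  preds <- if (n_pred) {
    do.call(rbind, lapply(seq_len(n_pred), function(i)
      random_box_row(image_id = sample(c("img1", "img2"), 1),
                     label = sample(c("a", "b"), 1),
                     score = runif(1))))
  } else {
    empty_boxes(score = TRUE)
  }
  list(gtb = gtb, preds = preds,
       gt = ground_truth(gtb, images = c("img1", "img2")))
}

# A tight cluster of boxes jittered around one base box: pairwise IoU stays
# high, so weighted boxes fusion assigns them all to a single cluster.
random_cluster <- function(n = NULL, image_id = "img1", label = "a") {
  n <- n %||% sample(2:5, 1)
  x1 <- runif(1, 0, 50); y1 <- runif(1, 0, 50)
  w <- runif(1, 20, 60); h <- runif(1, 20, 60)
  jit <- function(side) runif(n, -0.04 * side, 0.04 * side)
  data.frame(image_id = image_id, label = label,
             x1 = x1 + jit(w), y1 = y1 + jit(h),
             x2 = x1 + w + jit(w), y2 = y1 + h + jit(h),
             score = runif(n, 0.2, 1),
             stringsAsFactors = FALSE)
}
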