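#' Non-maximum suppression configuration
#'
#' Defaults follow the detection post-processing used throughout the package:
#' 0.6 IoU and 0.1 score threshold.
#'
#' @param iou_threshold Overlap above which a lower-scored same-class box is
#'   suppressed.
#' @param score_threshold Boxes scoring below this are discarded up front.
#' @return An `nms_config` list.
#' @export
nms_config <- function(iou_threshold = 0.6, score_threshold = 0.1) {
  stopifnot(iou_threshold >= 0, iou_threshold <= 1,
            score_threshold >= 0, score_threshold <= 1)
  structure(list(iou_threshold = iou_threshold,
                 score_threshold = score_threshold),
            class = "nms_config")
}

#' Weighted boxes fusion configuration
#'
#' Defaults: 0.6 IoU threshold, 0.16 skip-box threshold, equal source weights.
#'
#' @param iou_threshold Overlap above which a box joins an existing cluster.
#' @param skip_box_threshold Boxes whose (weighted) score falls below this
#'   never participate in fusion.
#' @param weights Per-source non-negative multipliers; a single value is
#'   recycled. Weights are normalized to mean 1, so scaling all weights by a
#'   constant changes nothing.
#' @param score_rescale If `TRUE`, multiply each fused confidence by
#'   `min(T, S) / S` where `T` is the cluster size and `S` the number of
#'   sources, down-weighting boxes few sources agreed on. Off by default.
#' @return A `fusion_config` list.
#' @export
fusion_config <- function(iou_threshold = 0.6, skip_box_threshold = 0.16,
                          weights = 1, score_rescale = FALSE) {
  stopifnot(iou_threshold >= 0, iou_threshold <= 1,
            skip_box_threshold >= 0, skip_box_threshold <= 1,
            is.numeric(weights), all(weights >= 0))
  structure(list(iou_threshold = iou_threshold,
                 skip_box_threshold = skip_box_threshold,
                 weights = weights,
                 score_rescale = isTRUE(score_rescale)),
            class = "fusion_config")
}

#' Non-maximum suppression
#'
#' Class-wise and image-wise: boxes scoring below the score threshold are
#' dropped; the remainder are visited in descending score order, each kept box
#' suppressing any later same-class box whose IoU with it exceeds the IoU
#' threshold. After suppression no two retained same-class boxes on one image
#' overlap beyond the threshold.
#'
#' @param preds Box `data.frame` with scores.
#' @param cfg An [nms_config()].
#' @return The retained boxes, ordered by descending score.
#' @export
nms <- function(preds, cfg = nms_config()) {
  stopifnot(inherits(cfg, "nms_config"))
  preds <- validate_boxes(preds, require_score = TRUE)
  preds <- preds[preds$score >= cfg$score_threshold, , drop = FALSE]
  if (!nrow(preds)) return(preds)
  ord <- order(-preds$score, seq_len(nrow(preds)))
  p <- preds[ord, , drop = FALSE]
  groups <- split(seq_len(nrow(p)), paste(p$image_id, p$label, sep = "\r"))
  keep <- logical(nrow(p))
  coords <- as.matrix(p[, c("x1", "y1", "x2", "y2")])
  for (idx in groups) {
    alive <- idx
    while (length(alive)) {
      top <- alive[1L] # highest score in group (rows are score-ordered)
      keep[top] <- TRUE
      alive <- alive[-1L]
      if (length(alive)) {
        ious <- iou_many(coords[top, ], coords[alive, , drop = FALSE])
        alive <- alive[ious <= cfg$iou_threshold]
      }
    }
  }
  out <- p[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Fused coordinates and confidence of a cluster from its members' (weighted)
# scores: corners are confidence-weighted means, confidence is the plain mean.
fuse_cluster <- function(coords, scores) {
  ci <- scores
  list(
    coords = c(
      sum(ci * coords[, 1]) / sum(ci),
      sum(ci * coords[, 2]) / sum(ci),
      sum(ci * coords[, 3]) / sum(ci),
      sum(ci * coords[, 4]) / sum(ci)
    ),
    conf = mean(ci)
  )
}

#' Weighted boxes fusion
#'
#' Combines detections from several sources (models, folds) into one consensus
#' set, class-wise and image-wise. Scores are first multiplied by the
#' per-source weights (normalized to mean 1); boxes below the skip-box
#' threshold are discarded. The survivors are visited in descending score
#' order and compared against the running list of fused boxes of the same
#' class: if the best IoU exceeds the IoU threshold the box joins that
#' cluster, otherwise it seeds a new one. A cluster's fused corners are the
#' confidence-weighted means of its members' corners
#' (`X = sum(Ci * Xi) / sum(Ci)`, likewise `Y`) and its confidence is the mean
#' member score (`C = sum(Ci) / T`), so higher-confidence members pull the
#' fused box toward themselves.
#'
#' @param sources A list of box `data.frame`s, one per source, each with
#'   scores.
#' @param cfg A [fusion_config()]; `cfg$weights` must be length 1 or match
#'   `length(sources)`.
#' @return One fused box per cluster, ordered by descending confidence, with
#'   an `n_members` column giving the cluster size.
#' @examples
#' a <- boxes(0, 0, 10, 10, "tumor", "img1", score = 0.9)
#' b <- boxes(2, 0, 12, 10, "tumor", "img1", score = 0.3)
#' wbf(list(a, b)) # -> (0.5, 0, 10.5, 10) with confidence 0.6
#' @export
wbf <- function(sources, cfg = fusion_config()) {
  stopifnot(inherits(cfg, "fusion_config"), is.list(sources))
  n_src <- length(sources)
  out_empty <- cbind(empty_boxes(score = TRUE), n_members = integer())
  if (!n_src) return(out_empty)
  w <- cfg$weights
  if (length(w) == 1L) w <- rep(w, n_src)
  if (length(w) != n_src) {
    stop(sprintf("weights length (%d) does not match number of sources (%d)",
                 length(w), n_src), call. = FALSE)
  }
  if (all(w == 0)) stop("at least one source weight must be positive",
                        call. = FALSE)
  w <- w / mean(w)

  pool <- do.call(rbind, lapply(seq_len(n_src), function(s) {
    b <- validate_boxes(sources[[s]], require_score = TRUE)
    if (!nrow(b)) return(NULL)
    b <- b[, c("image_id", "label", "x1", "y1", "x2", "y2", "score")]
    b$score <- b$score * w[s]
    b$source <- s
    b
  }))
  if (is.null(pool) || !nrow(pool)) return(out_empty)
  pool <- pool[pool$score >= cfg$skip_box_threshold, , drop = FALSE]
  if (!nrow(pool)) return(out_empty)
  pool <- pool[order(-pool$score, pool$source, seq_len(nrow(pool))), ,
               drop = FALSE]

  groups <- split(seq_len(nrow(pool)),
                  paste(pool$image_id, pool$label, sep = "\r"))
  coords <- as.matrix(pool[, c("x1", "y1", "x2", "y2")])
  res <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    fused_coords <- matrix(numeric(), ncol = 4L, nrow = 0L)
    members <- list()
    confs <- numeric()
    for (i in idx) {
      assign_to <- 0L
      if (nrow(fused_coords)) {
        ious <- iou_many(coords[i, ], fused_coords)
        best <- which.max(ious)
        if (ious[best] > cfg$iou_threshold) assign_to <- best
      }
      if (assign_to == 0L) {
        members[[length(members) + 1L]] <- i
        fused_coords <- rbind(fused_coords, coords[i, ])
        confs <- c(confs, pool$score[i])
      } else {
        members[[assign_to]] <- c(members[[assign_to]], i)
        fc <- fuse_cluster(coords[members[[assign_to]], , drop = FALSE],
                           pool$score[members[[assign_to]]])
        fused_coords[assign_to, ] <- fc$coords
        confs[assign_to] <- fc$conf
      }
    }
    sizes <- lengths(members)
    if (cfg$score_rescale) confs <- confs * pmin(sizes, n_src) / n_src
    # uneven weights can push a weighted score past 1; keep scores valid
    confs <- pmin(confs, 1)
    res[[g]] <- data.frame(
      image_id = pool$image_id[idx[1L]], label = pool$label[idx[1L]],
      x1 = fused_coords[, 1], y1 = fused_coords[, 2],
      x2 = fused_coords[, 3], y2 = fused_coords[, 4],
      score = confs, n_members = as.integer(sizes),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  out <- out[order(-out$score, seq_len(nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  out
}
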