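#' Construct a table of bounding boxes
#'
#' Boxes are stored as a plain `data.frame` with one row per box and the
#' columns `image_id`, `label`, `x1`, `y1`, `x2`, `y2` and (for detections)
#' `score`. Coordinates are continuous corner coordinates in pixels; areas are
#' computed as `(x2 - x1) * (y2 - y1)` with no pixel (+1) correction. Every
#' box must have strictly positive area and scores, when present, must lie in
#' `[0, 1]`.
#'
#' @param x1,y1,x2,y2 Numeric vectors of corner coordinates, `x1 < x2`,
#'   `y1 < y2`.
#' @param label Class identifiers (coerced to character).
#' @param image_id Opaque image keys (coerced to character).
#' @param score Optional confidence scores in `[0, 1]`; omit for ground-truth
#'   annotations.
#' @return A validated `data.frame` of boxes.
#' @examples
#' boxes(0, 0, 10, 10, label = "eye", image_id = "img1", score = 0.9)
#' @export
boxes <- function(x1, y1, x2, y2, label, image_id, score = NULL) {
  df <- data.frame(
    image_id = as.character(image_id),
    label = as.character(label),
    x1 = as.numeric(x1), y1 = as.numeric(y1),
    x2 = as.numeric(x2), y2 = as.numeric(y2),
    stringsAsFactors = FALSE
  )
  if (!is.null(score)) df$score <- as.numeric(score)
  validate_boxes(df, require_score = !is.null(score))
}

#' Validate a box table
#'
#' @param df A `data.frame` as produced by [boxes()].
#' @param require_score If `TRUE`, a `score` column must be present.
#' @return `df`, invisibly validated (returned unchanged on success).
#' @export
validate_boxes <- function(df, require_score = FALSE) {
  if (!is.data.frame(df)) stop("boxes must be a data.frame", call. = FALSE)
  needed <- c("image_id", "label", "x1", "y1", "x2", "y2")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("box table is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (require_score && !"score" %in% names(df)) {
    stop("box table must carry a 'score' column", call. = FALSE)
  }
  if (nrow(df)) {
    bad <- which(!(df$x1 < df$x2 & df$y1 < df$y2))
    if (length(bad)) {
      stop("invalid box (zero or negative area) at row ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    if ("score" %in% names(df)) {
      bad_s <- which(!is.na(df$score) & (df$score < 0 | df$score > 1))
      if (length(bad_s)) {
        stop("score outside [0, 1] at row ",
             paste(utils::head(bad_s, 5L), collapse = ", "), call. = FALSE)
      }
      if (require_score && anyNA(df$score)) {
        stop("missing score on a detection box", call. = FALSE)
      }
    }
  }
  df
}

#' An empty box table
#'
#' @param score Include a `score` column?
#' @return A zero-row box `data.frame`.
#' @export
empty_boxes <- function(score = TRUE) {
  df <- data.frame(
    image_id = character(), label = character(),
    x1 = numeric(), y1 = numeric(), x2 = numeric(), y2 = numeric(),
    stringsAsFactors = FALSE
  )
  if (score) df$score <- numeric()
  df
}

box_coords <- function(b) {
  if (is.data.frame(b)) {
    if (nrow(b) != 1L) stop("expected a single box", call. = FALSE)
    as.numeric(b[1L, c("x1", "y1", "x2", "y2")])
  } else {
    b <- as.numeric(b)
    if (length(b) != 4L) stop("a box is 4 numbers: x1, y1, x2, y2", call. = FALSE)
    b
  }
}

#' Intersection over union of two boxes
#'
#' The localization agreement score: area of overlap divided by area of union,
#' `|A inter B| / (|A| + |B| - |A inter B|)`. Symmetric, bounded in `[0, 1]`,
#' zero for disjoint boxes and one only for identical boxes.
#'
#' @param a,b Single boxes: either a length-4 numeric `c(x1, y1, x2, y2)` or a
#'   one-row box `data.frame`.
#' @return A number in `[0, 1]`.
#' @examples
#' iou(c(0, 0, 10, 10), c(5, 0, 15, 10)) # 1/3
#' @export
iou <- function(a, b) {
  a <- box_coords(a)
  b <- box_coords(b)
  if (a[1] >= a[3] || a[2] >= a[4] || b[1] >= b[3] || b[2] >= b[4]) {
    stop("invalid box: zero or negative area", call. = FALSE)
  }
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

# IoU of one box against each row of a coordinate matrix/data.frame.
iou_many <- function(a, mat) {
  if (is.data.frame(mat)) mat <- as.matrix(mat[, c("x1", "y1", "x2", "y2")])
  if (!nrow(mat)) return(numeric())
  iw <- pmin(a[3], mat[, 3]) - pmax(a[1], mat[, 1])
  ih <- pmin(a[4], mat[, 4]) - pmax(a[2], mat[, 2])
  inter <- pmax(iw, 0) * pmax(ih, 0)
  union <- (a[3] - a[1]) * (a[4] - a[2]) +
    (mat[, 3] - mat[, 1]) * (mat[, 4] - mat[, 2]) - inter
  ifelse(inter > 0, inter / union, 0)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
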