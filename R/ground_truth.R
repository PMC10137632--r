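#' Ground-truth annotations
#'
#' Bundles annotation boxes (no scores) with the full set of image keys, so
#' images with zero objects still count in per-image rates such as FPPI.
#'
#' @param boxes A box `data.frame` without scores (a `score` column, if
#'   present, is dropped).
#' @param images Character vector of image keys. Defaults to the images seen
#'   in `boxes`; supply explicitly when some images have no annotations.
#' @param image_size Optional frame side length in pixels, kept as an
#'   attribute for simulators and writers.
#' @return An object of class `ground_truth` with elements `boxes` and
#'   `images`.
#' @export
ground_truth <- function(boxes, images = NULL, image_size = NULL) {
  boxes <- validate_boxes(boxes, require_score = FALSE)
  boxes$score <- NULL
  images <- as.character(images %||% unique(boxes$image_id))
  dangling <- setdiff(boxes$image_id, images)
  if (length(dangling)) {
    stop("annotation references image(s) not in the image set: ",
         paste(utils::head(dangling, 5L), collapse = ", "), call. = FALSE)
  }
  out <- structure(
    list(boxes = boxes, images = unique(images)),
    class = "ground_truth"
  )
  attr(out, "image_size") <- image_size
  out
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d boxes on %d images, %d classes\n",
    nrow(x$boxes), length(x$images), length(unique(x$boxes$label))
  ))
  if (nrow(x$boxes)) {
    tab <- sort(table(x$boxes$label), decreasing = TRUE)
    cat(paste(sprintf("  %-18s %d", names(tab), as.integer(tab)),
              collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Restrict ground truth to a subset of images or classes
#'
#' @param gt A `ground_truth` object.
#' @param images,classes Keep only these image keys / class labels
#'   (`NULL` keeps all).
#' @return A `ground_truth` object.
#' @export
subset_ground_truth <- function(gt, images = NULL, classes = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  keep_img <- gt$images
  if (!is.null(images)) keep_img <- intersect(keep_img, as.character(images))
  b <- gt$boxes[gt$boxes$image_id %in% keep_img, , drop = FALSE]
  if (!is.null(classes)) b <- b[b$label %in% as.character(classes), , drop = FALSE]
  out <- ground_truth(b, images = keep_img,
                      image_size = attr(gt, "image_size"))
  out
}
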