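# COCO-dialect JSON. Annotations use [x, y, width, height] boxes and category
# ids; internally everything is corner-based (x1, y1, x2, y2). Image and
# category ids are opaque (integer or string), with no contiguity assumption.

#' Read ground-truth annotations from COCO-style JSON
#'
#' Expects the usual annotation layout: `images` (with `id`), `categories`
#' (with `id`, `name`) and `annotations` (with `image_id`, `category_id`,
#' `bbox` as `[x, y, width, height]`). Category ids are mapped to their names
#' as class labels; images with zero annotations are preserved.
#'
#' @param path Path to a JSON file.
#' @return A [ground_truth()] object.
#' @export
read_ground_truth <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("malformed JSON in ", path, ": ", conditionMessage(e),
                         call. = FALSE)
                  })
  for (fld in c("images", "categories", "annotations")) {
    if (is.null(doc[[fld]])) {
      stop("annotation file lacks a '", fld, "' field: ", path, call. = FALSE)
    }
  }
  images <- as.character(doc$images$id)
  cats <- doc$categories
  cat_map <- stats::setNames(as.character(cats$name), as.character(cats$id))
  ann <- doc$annotations
  if (is.data.frame(ann) && nrow(ann)) {
    bb <- bbox_matrix(ann$bbox, path)
    if (any(bb[, 3] <= 0) || any(bb[, 4] <= 0)) {
      stop("annotation with non-positive width/height in ", path,
           call. = FALSE)
    }
    img_id <- as.character(ann$image_id)
    cat_id <- as.character(ann$category_id)
    if (!all(img_id %in% images)) {
      stop("annotation references unknown image id(s): ",
           paste(utils::head(setdiff(img_id, images), 5L), collapse = ", "),
           call. = FALSE)
    }
    if (!all(cat_id %in% names(cat_map))) {
      stop("annotation references unknown category id(s): ",
           paste(utils::head(setdiff(cat_id, names(cat_map)), 5L),
                 collapse = ", "),
           call. = FALSE)
    }
    b <- data.frame(
      image_id = img_id, label = unname(cat_map[cat_id]),
      x1 = bb[, 1], y1 = bb[, 2],
      x2 = bb[, 1] + bb[, 3], y2 = bb[, 2] + bb[, 4],
      stringsAsFactors = FALSE
    )
  } else {
    b <- empty_boxes(score = FALSE)
  }
  size <- if (!is.null(doc$images$width)) max(doc$images$width) else NULL
  ground_truth(b, images = images, image_size = size)
}

bbox_matrix <- function(bbox, path) {
  m <- if (is.list(bbox)) do.call(rbind, lapply(bbox, as.numeric)) else bbox
  if (!is.matrix(m) || ncol(m) != 4L) {
    stop("bbox entries must be [x, y, width, height] in ", path, call. = FALSE)
  }
  m
}

#' Write ground truth as COCO-style JSON
#'
#' @param gt A [ground_truth()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  size <- attr(gt, "image_size") %||% NA
  classes <- sort(unique(gt$boxes$label))
  cat_ids <- stats::setNames(seq_along(classes), classes)
  b <- gt$boxes
  doc <- list(
    images = lapply(gt$images, function(id) {
      img <- list(id = id)
      if (!is.na(size)) {
        img$width <- size
        img$height <- size
      }
      img
    }),
    categories = lapply(classes, function(cl) {
      list(id = unname(cat_ids[[cl]]), name = cl)
    }),
    annotations = lapply(seq_len(nrow(b)), function(i) {
      list(
        id = i,
        image_id = b$image_id[i],
        category_id = unname(cat_ids[[b$label[i]]]),
        bbox = c(b$x1[i], b$y1[i], b$x2[i] - b$x1[i], b$y2[i] - b$y1[i]),
        area = (b$x2[i] - b$x1[i]) * (b$y2[i] - b$y1[i])
      )
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read detections from COCO-results-style JSON
#'
#' Expects an array of records with `image_id`, `category_id`, `bbox`
#' (`[x, y, width, height]`) and `score`. Scores are validated into `[0, 1]`;
#' an offending record is named in the error.
#'
#' @param path Path to a JSON file.
#' @param categories Optional mapping from category id to class label: a
#'   `data.frame` with columns `id` and `name` (as read from an annotation
#'   file). When omitted, category ids themselves are used as labels.
#' @return A box `data.frame` with scores.
#' @export
read_detections <- function(path, categories = NULL) {
  rec <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("malformed JSON in ", path, ": ", conditionMessage(e),
                         call. = FALSE)
                  })
  if (is.null(rec) || (is.data.frame(rec) && !nrow(rec)) || !length(rec)) {
    return(empty_boxes(score = TRUE))
  }
  if (!is.data.frame(rec)) {
    stop("detection file must be an array of records: ", path, call. = FALSE)
  }
  for (fld in c("image_id", "category_id", "bbox", "score")) {
    if (is.null(rec[[fld]])) {
      stop("detection records lack a '", fld, "' field: ", path, call. = FALSE)
    }
  }
  score <- as.numeric(rec$score)
  bad <- which(is.na(score) | score < 0 | score > 1)
  if (length(bad)) {
    stop(sprintf("record %d of %s has score %s outside [0, 1]",
                 bad[1L], path, format(rec$score[bad[1L]])), call. = FALSE)
  }
  bb <- bbox_matrix(rec$bbox, path)
  if (any(bb[, 3] <= 0) || any(bb[, 4] <= 0)) {
    stop("detection with non-positive width/height in ", path, call. = FALSE)
  }
  label <- as.character(rec$category_id)
  if (!is.null(categories)) {
    cmap <- stats::setNames(as.character(categories$name),
                            as.character(categories$id))
    hit <- label %in% names(cmap)
    label[hit] <- unname(cmap[label[hit]])
  }
  data.frame(
    image_id = as.character(rec$image_id), label = label,
    x1 = bb[, 1], y1 = bb[, 2],
    x2 = bb[, 1] + bb[, 3], y2 = bb[, 2] + bb[, 4],
    score = score, stringsAsFactors = FALSE
  )
}

#' Write detections as COCO-results-style JSON
#'
#' Labels are written as `category_id` verbatim, which round-trips through
#' [read_detections()] without a category table.
#'
#' @param dets Box `data.frame` with scores.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(dets, path) {
  dets <- validate_boxes(dets, require_score = TRUE)
  doc <- lapply(seq_len(nrow(dets)), function(i) {
    list(
      image_id = dets$image_id[i],
      category_id = dets$label[i],
      bbox = c(dets$x1[i], dets$y1[i],
               dets$x2[i] - dets$x1[i], dets$y2[i] - dets$y1[i]),
      score = dets$score[i]
    )
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a detection bundle and its manifest
#'
#' One detection file per (model, fold) plus a `manifest.json` listing the
#' grid and relative file paths.
#'
#' @param bundle A [detection_bundle()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "detection_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (m in bundle$models) {
    for (f in bundle$folds) {
      file <- sprintf("det_%s_fold_%s.json", m, f)
      write_detections(bundle_detections(bundle, m, f), file.path(dir, file))
      entries[[length(entries) + 1L]] <- list(model = m, fold = f, path = file)
    }
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(models = bundle$models, folds = bundle$folds, files = entries),
    manifest, auto_unbox = TRUE, digits = NA
  )
  invisible(manifest)
}

#' Read a detection bundle from a manifest
#'
#' @param manifest Path to a `manifest.json` written by [write_bundle()].
#'   Relative detection paths are resolved against the manifest's directory.
#' @param categories Optional category table passed to [read_detections()].
#' @return A [detection_bundle()].
#' @export
read_bundle <- function(manifest, categories = NULL) {
  doc <- jsonlite::fromJSON(manifest, simplifyVector = TRUE)
  if (is.null(doc$files) || !nrow(doc$files)) {
    stop("manifest lists no detection files: ", manifest, call. = FALSE)
  }
  base <- dirname(manifest)
  files <- doc$files
  detections <- stats::setNames(
    lapply(seq_len(nrow(files)), function(i) {
      p <- files$path[i]
      if (!file.exists(p)) p <- file.path(base, files$path[i])
      read_detections(p, categories)
    }),
    bundle_key(files$model, files$fold)
  )
  detection_bundle(detections,
                   models = as.character(doc$models),
                   folds = as.character(doc$folds))
}

#' Pipeline run configuration
#'
#' Bundles every tunable of the pipeline with its default: NMS at 0.6 IoU and
#' 0.1 score threshold, weighted boxes fusion at 0.6 IoU and 0.16 skip-box
#' threshold with equal weights, evaluation at 0.5 IoU, and a confidence
#' sweep from 0 to 1 in steps of 0.02 for FROC analysis.
#'
#' @param overrides Named list (e.g. parsed from a YAML/JSON file) overriding
#'   any of the nested defaults; unknown names are an error.
#' @return A `run_config` list with elements `nms`, `fusion`, `eval`,
#'   `strategy`, `seed`.
#' @export
run_config <- function(overrides = list()) {
  cfg <- list(
    nms = list(iou_threshold = 0.6, score_threshold = 0.1),
    fusion = list(iou_threshold = 0.6, skip_box_threshold = 0.16,
                  weights = 1, score_rescale = FALSE),
    eval = list(iou_threshold = 0.5, sweep_step = 0.02),
    strategy = list(id = 3L, model = NULL, fold = NULL),
    seed = 1L
  )
  merge_into(cfg, overrides)
}

merge_into <- function(base, overrides) {
  for (nm in names(overrides)) {
    if (!nm %in% names(base)) {
      stop("unknown configuration field: ", nm, call. = FALSE)
    }
    if (is.list(base[[nm]]) && is.list(overrides[[nm]])) {
      base[[nm]] <- merge_into(base[[nm]], overrides[[nm]])
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

#' Read a run configuration from YAML or JSON
#'
#' @param path File path; `.json` is parsed as JSON, anything else as YAML.
#' @return A `run_config` list (defaults filled in).
#' @export
read_run_config <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  run_config(doc %||% list())
}
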