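bundle_key <- function(model, fold) paste(model, fold, sep = "/")

#' A grid of detections indexed by (model, fold)
#'
#' The unit all ensemble strategies consume: one prediction set per model and
#' cross-validation fold, as produced by k-fold training of several detector
#' architectures.
#'
#' @param detections Named list of box `data.frame`s (with scores), keyed
#'   `"model/fold"`. Every model x fold combination must be present (a
#'   prediction set may be empty).
#' @param models,folds Ordered identifiers; inferred from the keys when
#'   omitted. Identifiers must not contain `"/"`.
#' @return A `detection_bundle` with elements `detections`, `models`,
#'   `folds`.
#' @export
detection_bundle <- function(detections, models = NULL, folds = NULL) {
  stopifnot(is.list(detections), length(detections) > 0)
  keys <- names(detections)
  if (is.null(keys) || any(keys == "") || anyDuplicated(keys)) {
    stop("detections must be uniquely named 'model/fold'", call. = FALSE)
  }
  parts <- strsplit(keys, "/", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("detection keys must have the form 'model/fold'", call. = FALSE)
  }
  key_models <- vapply(parts, `[`, character(1), 1L)
  key_folds <- vapply(parts, `[`, character(1), 2L)
  models <- as.character(models %||% unique(key_models))
  folds <- as.character(folds %||% unique(key_folds))
  expected <- as.vector(outer(models, folds, bundle_key))
  missing_keys <- setdiff(expected, keys)
  if (length(missing_keys)) {
    stop("bundle is missing (model, fold) entries: ",
         paste(utils::head(missing_keys, 5L), collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(keys, expected)
  if (length(extra)) {
    stop("bundle has entries outside the model x fold grid: ",
         paste(utils::head(extra, 5L), collapse = ", "), call. = FALSE)
  }
  detections <- lapply(detections, validate_boxes, require_score = TRUE)
  structure(list(detections = detections[expected], models = models,
                 folds = folds),
            class = "detection_bundle")
}

#' @export
print.detection_bundle <- function(x, ...) {
  cat(sprintf("<detection_bundle> %d models x %d folds\n",
              length(x$models), length(x$folds)))
  cat("models:", paste(x$models, collapse = ", "), "\n")
  cat("folds: ", paste(x$folds, collapse = ", "), "\n")
  invisible(x)
}

#' Extract one prediction set from a bundle
#'
#' @param bundle A [detection_bundle()].
#' @param model,fold Identifiers present in the bundle.
#' @return A box `data.frame`.
#' @export
bundle_detections <- function(bundle, model, fold) {
  stopifnot(inherits(bundle, "detection_bundle"))
  if (!model %in% bundle$models) stop("unknown model: ", model, call. = FALSE)
  if (!fold %in% bundle$folds) stop("unknown fold: ", fold, call. = FALSE)
  bundle$detections[[bundle_key(model, fold)]]
}

#' Selection scores for models and folds
#'
#' mAP of each (model, fold) prediction set on a selection split, used by the
#' fold- and model-selection strategies. Keep selection and evaluation splits
#' separate: selecting on the split you report invites leakage.
#'
#' @param scores `data.frame` with columns `model`, `fold`, `map`
#'   (all mAP values in `[0, 1]`).
#' @param split_tag Which split the scores came from (e.g. `"validation"`).
#' @return A `selection_table`.
#' @export
selection_table <- function(scores, split_tag = "validation") {
  stopifnot(is.data.frame(scores),
            all(c("model", "fold", "map") %in% names(scores)))
  if (any(scores$map < 0 | scores$map > 1)) {
    stop("selection mAP scores must lie in [0, 1]", call. = FALSE)
  }
  scores$model <- as.character(scores$model)
  scores$fold <- as.character(scores$fold)
  if (anyDuplicated(scores[c("model", "fold")])) {
    stop("duplicate (model, fold) rows in selection scores", call. = FALSE)
  }
  structure(list(scores = scores[c("model", "fold", "map")],
                 split_tag = split_tag),
            class = "selection_table")
}

#' @export
print.selection_table <- function(x, ...) {
  cat(sprintf("<selection_table> split: %s\n", x$split_tag))
  wide <- stats::reshape(x$scores, idvar = "model", timevar = "fold",
                         direction = "wide")
  print(wide, row.names = FALSE)
  invisible(x)
}

#' Score every (model, fold) prediction set against a selection split
#'
#' Restricts each prediction set to the images of `gt` and computes its mAP.
#'
#' @param bundle A [detection_bundle()].
#' @param gt [ground_truth()] of the selection split.
#' @param iou_threshold IoU cutoff for AP (default 0.5).
#' @param split_tag Label recorded in the resulting table.
#' @return A [selection_table()].
#' @export
compute_selection_table <- function(bundle, gt, iou_threshold = 0.5,
                                    split_tag = "validation") {
  stopifnot(inherits(bundle, "detection_bundle"), inherits(gt, "ground_truth"))
  grid <- expand.grid(model = bundle$models, fold = bundle$folds,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$map <- vapply(seq_len(nrow(grid)), function(i) {
    p <- bundle_detections(bundle, grid$model[i], grid$fold[i])
    p <- p[p$image_id %in% gt$images, , drop = FALSE]
    mean_average_precision(p, gt, iou_threshold)$map
  }, numeric(1))
  selection_table(grid, split_tag = split_tag)
}

table_score <- function(table, model, fold) {
  s <- table$scores
  hit <- s$model == model & s$fold == fold
  if (!any(hit)) {
    stop(sprintf("selection table has no score for (%s, %s)", model, fold),
         call. = FALSE)
  }
  s$map[hit][1L]
}

strategy_result <- function(fused, provenance, strategy) {
  structure(list(fused = fused, provenance = provenance, strategy = strategy),
            class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("<strategy_result> strategy %d: %d fused boxes from %d sources\n",
              x$strategy, nrow(x$fused), nrow(x$provenance)))
  print(x$provenance, row.names = FALSE)
  invisible(x)
}

#' Strategy 1: fuse all cross-validation folds of one model
#'
#' Every fold's prediction set for `model` is fused with [wbf()] into a single
#' consensus set, with no fold selection.
#'
#' @param bundle A [detection_bundle()]; `model` must have at least two folds.
#' @param model Model identifier.
#' @param cfg A [fusion_config()].
#' @return A `strategy_result` with the fused boxes and per-source
#'   provenance.
#' @export
strategy1_all_folds <- function(bundle, model, cfg = fusion_config()) {
  stopifnot(inherits(bundle, "detection_bundle"))
  if (!model %in% bundle$models) stop("unknown model: ", model, call. = FALSE)
  if (length(bundle$folds) < 2L) {
    stop("strategy 1 needs at least two folds", call. = FALSE)
  }
  src <- lapply(bundle$folds, function(f) bundle_detections(bundle, model, f))
  strategy_result(
    fused = wbf(src, cfg),
    provenance = data.frame(model = model, fold = bundle$folds,
                            stringsAsFactors = FALSE),
    strategy = 1L
  )
}

#' Strategy 2: fuse the above-mean folds of one model
#'
#' Computes the mean of the model's per-fold selection mAPs and fuses only the
#' folds scoring strictly above that mean. When no fold is strictly above (all
#' folds equal), all folds are fused.
#'
#' @inheritParams strategy1_all_folds
#' @param table A [selection_table()] holding a score for every fold of the
#'   model.
#' @return A `strategy_result`; `provenance` lists the selected folds.
#' @export
strategy2_above_mean_folds <- function(bundle, model, table,
                                       cfg = fusion_config()) {
  stopifnot(inherits(bundle, "detection_bundle"),
            inherits(table, "selection_table"))
  if (!model %in% bundle$models) stop("unknown model: ", model, call. = FALSE)
  scores <- vapply(bundle$folds, function(f) table_score(table, model, f),
                   numeric(1))
  sel <- bundle$folds[scores > mean(scores)]
  if (!length(sel)) sel <- bundle$folds
  src <- lapply(sel, function(f) bundle_detections(bundle, model, f))
  strategy_result(
    fused = wbf(src, cfg),
    provenance = data.frame(model = model, fold = sel,
                            map = scores[match(sel, bundle$folds)],
                            stringsAsFactors = FALSE),
    strategy = 2L
  )
}

#' Strategy 3: fuse all models within one fold
#'
#' Keeps the fold fixed and fuses every model's prediction set for it; applied
#' over all folds this yields one ensemble result per fold.
#'
#' @param bundle A [detection_bundle()] with at least two models.
#' @param fold Fold identifier.
#' @param cfg A [fusion_config()].
#' @return A `strategy_result`.
#' @export
strategy3_cross_model_per_fold <- function(bundle, fold,
                                           cfg = fusion_config()) {
  stopifnot(inherits(bundle, "detection_bundle"))
  if (!fold %in% bundle$folds) stop("unknown fold: ", fold, call. = FALSE)
  if (length(bundle$models) < 2L) {
    stop("strategy 3 needs at least two models", call. = FALSE)
  }
  src <- lapply(bundle$models, function(m) bundle_detections(bundle, m, fold))
  strategy_result(
    fused = wbf(src, cfg),
    provenance = data.frame(model = bundle$models, fold = fold,
                            stringsAsFactors = FALSE),
    strategy = 3L
  )
}

#' Strategy 4: fuse the best model of each fold
#'
#' For every fold, the model with the highest selection mAP is picked (ties
#' broken by the bundle's model order); the winners' per-fold prediction sets
#' are fused into one consensus result.
#'
#' @param bundle A [detection_bundle()].
#' @param table A [selection_table()] with a score for every (model, fold).
#' @param cfg A [fusion_config()].
#' @return A `strategy_result`; `provenance` records the winning model per
#'   fold.
#' @export
strategy4_best_model_per_fold <- function(bundle, table,
                                          cfg = fusion_config()) {
  stopifnot(inherits(bundle, "detection_bundle"),
            inherits(table, "selection_table"))
  winners <- vapply(bundle$folds, function(f) {
    scores <- vapply(bundle$models, function(m) table_score(table, m, f),
                     numeric(1))
    bundle$models[which.max(scores)]
  }, character(1))
  src <- lapply(seq_along(bundle$folds), function(i) {
    bundle_detections(bundle, winners[i], bundle$folds[i])
  })
  strategy_result(
    fused = wbf(src, cfg),
    provenance = data.frame(model = unname(winners), fold = bundle$folds,
                            stringsAsFactors = FALSE),
    strategy = 4L
  )
}
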