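#' Default class specification for synthetic brain MRI slice scenes
#'
#' Six detection classes on an axial slice: brain region of interest, eye,
#' optic nerve, lateral ventricle, third ventricle and whole tumor. Presence
#' probabilities and per-slice counts approximate the per-slice object
#' statistics of expert-annotated brain MRI slice collections: the brain ROI
#' appears on every slice; eyes and lateral ventricles are paired structures
#' that occur two (or, for ventricle sections, up to three) at a time; the
#' optic nerve and third ventricle are rare and small — exactly the classes
#' ensembling helps most with; a tumor appears on roughly a quarter of
#' slices. Sizes and allowed regions are fractions of the frame and place
#' eyes anteriorly and ventricles centrally.
#'
#' @return A `data.frame` with one row per class and columns `label`,
#'   `p_present`, `count_min`, `count_max`, `size_min`, `size_max`,
#'   `region_x1`, `region_y1`, `region_x2`, `region_y2`.
#' @export
brain_class_spec <- function() {
  data.frame(
    label = c("brain_roi", "eye", "optic_nerve", "lateral_ventricle",
              "third_ventricle", "whole_tumor"),
    p_present = c(1.00, 0.21, 0.11, 0.36, 0.18, 0.25),
    count_min = c(1L, 2L, 1L, 2L, 1L, 1L),
    count_max = c(1L, 2L, 2L, 3L, 1L, 1L),
    size_min  = c(0.45, 0.05, 0.03, 0.06, 0.04, 0.08),
    size_max  = c(0.80, 0.11, 0.07, 0.20, 0.09, 0.30),
    region_x1 = c(0.08, 0.25, 0.30, 0.25, 0.35, 0.10),
    region_y1 = c(0.08, 0.02, 0.15, 0.30, 0.35, 0.10),
    region_x2 = c(0.92, 0.75, 0.70, 0.75, 0.65, 0.90),
    region_y2 = c(0.92, 0.35, 0.50, 0.80, 0.70, 0.90),
    stringsAsFactors = FALSE
  )
}

#' Scene generator configuration
#'
#' @param n_images Number of slices to generate.
#' @param image_size Frame side length in pixels (default 512).
#' @param class_spec Per-class presence/count/size/region table; see
#'   [brain_class_spec()] for the format and defaults.
#' @param seed Integer seed; scenes are reproducible given the seed.
#' @return A `scene_config` list.
#' @export
scene_config <- function(n_images, image_size = 512,
                         class_spec = brain_class_spec(), seed = 1L) {
  stopifnot(is.numeric(n_images), n_images >= 1, image_size > 0)
  needed <- c("label", "p_present", "count_min", "count_max",
              "size_min", "size_max",
              "region_x1", "region_y1", "region_x2", "region_y2")
  missing_cols <- setdiff(needed, names(class_spec))
  if (length(missing_cols)) {
    stop("class_spec is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  with(class_spec, {
    if (any(p_present < 0 | p_present > 1)) {
      stop("presence probabilities must lie in [0, 1]", call. = FALSE)
    }
    if (any(size_min <= 0) || any(size_max > 1) || any(size_min > size_max)) {
      stop("box size fractions must satisfy 0 < size_min <= size_max <= 1",
           call. = FALSE)
    }
    if (any(count_min < 0) || any(count_min > count_max)) {
      stop("invalid per-image count range", call. = FALSE)
    }
    if (any(size_max > region_x2 - region_x1) ||
        any(size_max > region_y2 - region_y1)) {
      stop("infeasible spec: size_max exceeds the allowed region extent",
           call. = FALSE)
    }
  })
  structure(list(n_images = as.integer(n_images),
                 image_size = image_size,
                 class_spec = class_spec,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Generate a synthetic ground-truth scene set
#'
#' For each image and class, the class is present with its configured
#' probability; when present, a per-image object count is drawn uniformly
#' from its count range and each object gets a box with side lengths drawn
#' from the size range (fractions of the frame), placed uniformly inside the
#' class's allowed region. All boxes lie fully inside the frame. The global
#' RNG state is untouched; the same seed always yields the same scenes.
#'
#' @param cfg A [scene_config()].
#' @return A [ground_truth()] object covering all `n_images` images
#'   (including any with zero objects).
#' @export
generate_ground_truth <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  spec <- cfg$class_spec
  S <- cfg$image_size
  image_ids <- sprintf("img_%04d", seq_len(cfg$n_images))
  withr::with_seed(cfg$seed, {
    rows <- vector("list", cfg$n_images * nrow(spec))
    k <- 0L
    for (img in image_ids) {
      for (j in seq_len(nrow(spec))) {
        if (stats::runif(1) > spec$p_present[j]) next
        count <- if (spec$count_min[j] == spec$count_max[j]) spec$count_min[j]
                 else sample(spec$count_min[j]:spec$count_max[j], 1L)
        if (count == 0L) next
        w <- stats::runif(count, spec$size_min[j], spec$size_max[j]) * S
        h <- stats::runif(count, spec$size_min[j], spec$size_max[j]) * S
        rx1 <- spec$region_x1[j] * S
        ry1 <- spec$region_y1[j] * S
        rx2 <- spec$region_x2[j] * S
        ry2 <- spec$region_y2[j] * S
        x1 <- stats::runif(count, rx1, rx2 - w)
        y1 <- stats::runif(count, ry1, ry2 - h)
        k <- k + 1L
        rows[[k]] <- data.frame(
          image_id = img, label = spec$label[j],
          x1 = x1, y1 = y1, x2 = x1 + w, y2 = y1 + h,
          stringsAsFactors = FALSE
        )
      }
    }
    b <- if (k) do.call(rbind, rows[seq_len(k)]) else empty_boxes(score = FALSE)
    ground_truth(b, images = image_ids, image_size = S)
  })
}

#' Detector noise profile
#'
#' Describes one synthetic detector. Each ground-truth box is detected with
#' probability `1 - miss_rate`; a detected box has every corner jittered by
#' independent Gaussian noise whose standard deviation is `jitter_sigma`
#' times the corresponding box side. The detection's confidence is its
#' realized IoU with the source box plus Gaussian noise of sd
#' `score_noise_sd`, clipped to `[0, 1]` — confidence is informative about
#' localization quality, the regime in which confidence-weighted fusion
#' helps. Spurious (false positive) boxes arrive as a Poisson process with
#' mean `fp_rate` per image and draw confidences uniformly from
#' `[0, fp_score_max]`.
#'
#' @param jitter_sigma Corner noise as a fraction of the box side
#'   (default 0.05).
#' @param miss_rate Probability a ground-truth box goes undetected
#'   (default 0.1).
#' @param fp_rate Expected spurious boxes per image (default 0.5).
#' @param score_noise_sd Gaussian noise on the IoU-based confidence
#'   (default 0.1).
#' @param fp_score_max Upper bound of the spurious-box confidence
#'   (default 0.5).
#' @param seed Integer seed for this detector's noise stream.
#' @return A `detector_profile` list.
#' @export
detector_profile <- function(jitter_sigma = 0.05, miss_rate = 0.1,
                             fp_rate = 0.5, score_noise_sd = 0.1,
                             fp_score_max = 0.5, seed = 1L) {
  stopifnot(jitter_sigma >= 0, miss_rate >= 0, miss_rate <= 1, fp_rate >= 0,
            score_noise_sd >= 0, fp_score_max >= 0, fp_score_max <= 1)
  structure(list(jitter_sigma = jitter_sigma, miss_rate = miss_rate,
                 fp_rate = fp_rate, score_noise_sd = score_noise_sd,
                 fp_score_max = fp_score_max, seed = as.integer(seed)),
            class = "detector_profile")
}

#' Simulate one detector's predictions on a scene set
#'
#' @param gt A [ground_truth()] object (typically from
#'   [generate_ground_truth()], which records the frame size).
#' @param profile A [detector_profile()].
#' @param image_size Frame side length for clipping; defaults to the size
#'   recorded on `gt`, else 512.
#' @return A box `data.frame` with scores; reproducible given the profile's
#'   seed, with the global RNG state untouched.
#' @export
simulate_detector <- function(gt, profile,
                              image_size = attr(gt, "image_size") %||% 512) {
  stopifnot(inherits(gt, "ground_truth"), inherits(profile, "detector_profile"))
  gtb <- gt$boxes
  S <- image_size
  classes <- unique(gtb$label)
  withr::with_seed(profile$seed, {
    det <- NULL
    if (nrow(gtb)) {
      detected <- stats::runif(nrow(gtb)) >= profile$miss_rate
      d <- gtb[detected, , drop = FALSE]
      if (nrow(d)) {
        w <- d$x2 - d$x1
        h <- d$y2 - d$y1
        x1 <- d$x1 + stats::rnorm(nrow(d), 0, profile$jitter_sigma * w)
        x2 <- d$x2 + stats::rnorm(nrow(d), 0, profile$jitter_sigma * w)
        y1 <- d$y1 + stats::rnorm(nrow(d), 0, profile$jitter_sigma * h)
        y2 <- d$y2 + stats::rnorm(nrow(d), 0, profile$jitter_sigma * h)
        x1 <- pmin(pmax(x1, 0), S)
        x2 <- pmin(pmax(x2, 0), S)
        y1 <- pmin(pmax(y1, 0), S)
        y2 <- pmin(pmax(y2, 0), S)
        # keep the area strictly positive after clipping
        lo_x <- pmin(x1, x2); hi_x <- pmax(x1, x2)
        lo_y <- pmin(y1, y2); hi_y <- pmax(y1, y2)
        hi_x <- ifelse(hi_x - lo_x < 1, pmin(lo_x + 1, S), hi_x)
        lo_x <- ifelse(hi_x - lo_x < 1, hi_x - 1, lo_x)
        hi_y <- ifelse(hi_y - lo_y < 1, pmin(lo_y + 1, S), hi_y)
        lo_y <- ifelse(hi_y - lo_y < 1, hi_y - 1, lo_y)
        realized_iou <- vapply(seq_len(nrow(d)), function(i) {
          iou(c(lo_x[i], lo_y[i], hi_x[i], hi_y[i]),
              c(d$x1[i], d$y1[i], d$x2[i], d$y2[i]))
        }, numeric(1))
        score <- realized_iou +
          stats::rnorm(nrow(d), 0, profile$score_noise_sd)
        det <- data.frame(
          image_id = d$image_id, label = d$label,
          x1 = lo_x, y1 = lo_y, x2 = hi_x, y2 = hi_y,
          score = pmin(pmax(score, 0), 1),
          stringsAsFactors = FALSE
        )
      }
    }
    fp <- NULL
    if (profile$fp_rate > 0 && length(classes)) {
      n_fp <- stats::rpois(length(gt$images), profile$fp_rate)
      total <- sum(n_fp)
      if (total > 0) {
        w <- stats::runif(total, 0.05, 0.30) * S
        h <- stats::runif(total, 0.05, 0.30) * S
        x1 <- stats::runif(total, 0, S - w)
        y1 <- stats::runif(total, 0, S - h)
        fp <- data.frame(
          image_id = rep(gt$images, n_fp),
          label = sample(classes, total, replace = TRUE),
          x1 = x1, y1 = y1, x2 = x1 + w, y2 = y1 + h,
          score = stats::runif(total, 0, profile$fp_score_max),
          stringsAsFactors = FALSE
        )
      }
    }
    out <- rbind(det, fp)
    if (is.null(out)) out <- empty_boxes(score = TRUE)
    rownames(out) <- NULL
    validate_boxes(out, require_score = TRUE)
  })
}

#' Expand a base profile into a (model, fold) grid with derived seeds
#'
#' A single master seed deterministically expands into one independent seed
#' per (model, fold) cell, so a whole bundle is reproducible while its
#' detectors remain independent.
#'
#' @param models,folds Identifier vectors.
#' @param base A [detector_profile()] template (its own seed is ignored), or
#'   a named list of templates keyed by model to give architectures different
#'   noise levels.
#' @param master_seed Integer master seed.
#' @return A named list of profiles keyed `"model/fold"`, suitable for
#'   [simulate_bundle()].
#' @export
detector_grid <- function(models, folds, base = detector_profile(),
                          master_seed = 1L) {
  models <- as.character(models)
  folds <- as.character(folds)
  keys <- as.vector(outer(models, folds, bundle_key))
  seeds <- withr::with_seed(as.integer(master_seed),
                            sample.int(.Machine$integer.max, length(keys)))
  profiles <- stats::setNames(vector("list", length(keys)), keys)
  for (i in seq_along(keys)) {
    model <- sub("/.*$", "", keys[i])
    tmpl <- if (inherits(base, "detector_profile")) base else base[[model]]
    if (is.null(tmpl)) stop("no profile template for model ", model,
                            call. = FALSE)
    tmpl$seed <- seeds[i]
    profiles[[i]] <- tmpl
  }
  profiles
}

#' Simulate a full (model, fold) detection bundle
#'
#' @param gt A [ground_truth()] object.
#' @param profiles Named list of [detector_profile()]s keyed `"model/fold"`,
#'   e.g. from [detector_grid()]. Keys must be unique.
#' @return A [detection_bundle()].
#' @export
simulate_bundle <- function(gt, profiles) {
  stopifnot(inherits(gt, "ground_truth"), is.list(profiles),
            length(profiles) > 0)
  keys <- names(profiles)
  if (is.null(keys) || any(keys == "")) {
    stop("profiles must be named 'model/fold'", call. = FALSE)
  }
  if (anyDuplicated(keys)) {
    stop("duplicate (model, fold) keys: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "),
         call. = FALSE)
  }
  detections <- lapply(profiles, function(p) simulate_detector(gt, p))
  detection_bundle(detections)
}
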