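gt1 <- function() {
  ground_truth(boxes(0, 0, 10, 10, "a", "img1"))
}

test_that("iou handles identical, disjoint and partially overlapping boxes", {
  expect_equal(iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1.0)
  expect_equal(iou(c(0, 0, 10, 10), c(20, 20, 30, 30)), 0.0)
  expect_equal(iou(c(0, 0, 10, 10), c(5, 0, 15, 10)), 1 / 3)
  expect_error(iou(c(0, 0, 0, 10), c(0, 0, 10, 10)), "invalid box")
})

test_that("iou is symmetric, bounded, and 1 only for identical boxes", {
  set.seed(41)
  for (i in 1:200) {
    a <- as.numeric(random_box_row()[, c("x1", "y1", "x2", "y2")])
    b <- as.numeric(random_box_row()[, c("x1", "y1", "x2", "y2")])
    v <- iou(a, b)
    expect_identical(v, iou(b, a))
    expect_gte(v, 0)
    expect_lte(v, 1)
    expect_equal(v, oracle_iou(a, b))
    if (isTRUE(all.equal(v, 1))) expect_equal(a, b)
    expect_equal(iou(a, a), 1.0)
  }
})

test_that("matching follows greedy descending-score assignment", {
  gt <- gt1()
  perfect <- boxes(0, 0, 10, 10, "a", "img1", score = 0.9)
  m <- match_detections(perfect, gt, 0.5)
  expect_equal(m$counts[, c("tp", "fp", "fn")],
               data.frame(tp = 1L, fp = 0L, fn = 0L))

  gt3 <- ground_truth(boxes(c(0, 20, 40), c(0, 0, 0), c(10, 30, 50),
                            c(10, 10, 10), "a", "img1"))
  m0 <- match_detections(empty_boxes(score = TRUE), gt3, 0.5)
  expect_equal(m0$counts[, c("tp", "fp", "fn")],
               data.frame(tp = 0L, fp = 0L, fn = 3L))

  # two predictions on one ground-truth box: greedy-by-score keeps the 0.9
  two <- boxes(c(0, 1), c(0, 0), c(10, 11), c(10, 10), "a", "img1",
               score = c(0.9, 0.8))
  m2 <- match_detections(two, gt, 0.5)
  expect_equal(m2$counts[, c("tp", "fp", "fn")],
               data.frame(tp = 1L, fp = 1L, fn = 0L))
  expect_true(m2$flags$tp[m2$flags$score == 0.9])
  expect_false(m2$flags$tp[m2$flags$score == 0.8])
})

test_that("predictions of a class unknown to the ground truth are flagged FP", {
  m <- match_detections(boxes(0, 0, 10, 10, "mystery", "img1", score = 0.8),
                        gt1(), 0.5)
  expect_false(m$flags$known_class)
  expect_equal(m$counts$fp[m$counts$label == "mystery"], 1L)
  expect_equal(sum(m$counts$tp), 0L)
})

test_that("match counts satisfy the per-class conservation identities", {
  set.seed(42)
  for (i in 1:50) {
    inst <- random_instance()
    m <- match_detections(inst$preds, inst$gt, runif(1, 0.3, 0.7))
    for (k in seq_len(nrow(m$counts))) {
      cl <- m$counts$label[k]
      expect_identical(m$counts$tp[k] + m$counts$fn[k],
                       sum(inst$gtb$label == cl))
      expect_identical(m$counts$tp[k] + m$counts$fp[k],
                       as.integer(sum(inst$preds$label == cl)))
    }
  }
})

test_that("average precision reproduces hand-computed P-R envelopes", {
  gt <- gt1()
  expect_equal(average_precision(
    boxes(0, 0, 10, 10, "a", "img1", score = 0.7), gt, "a", 0.5), 1.0)
  expect_equal(average_precision(empty_boxes(score = TRUE), gt, "a", 0.5), 0)
  expect_error(average_precision(empty_boxes(score = TRUE), gt, "zzz", 0.5),
               class = "boxfusion_undefined_ap")

  # flag sequence TP, FP, TP against 2 gt boxes -> AP = 0.5 * 1 + 0.5 * 2/3
  gt2 <- ground_truth(boxes(c(0, 100), c(0, 0), c(10, 110), c(10, 10),
                            "a", "img1"))
  preds <- boxes(c(0, 50, 100), c(0, 0, 0), c(10, 60, 110), c(10, 10, 10),
                 "a", "img1", score = c(0.9, 0.8, 0.7))
  expect_equal(average_precision(preds, gt2, "a", 0.5), 5 / 6)
})

test_that("average precision agrees with the all-cutoff brute-force oracle", {
  set.seed(7)
  for (i in 1:80) {
    inst <- random_instance()
    cl <- sample(unique(inst$gtb$label), 1)
    thr <- runif(1, 0.25, 0.75)
    expect_equal(
      average_precision(inst$preds, inst$gt, cl, thr),
      oracle_ap(inst$preds[inst$preds$label == cl, , drop = FALSE],
                inst$gtb[inst$gtb$label == cl, , drop = FALSE], thr),
      tolerance = 1e-12
    )
  }
})

test_that("mAP is the unweighted mean over ground-truth classes", {
  gtb <- rbind(boxes(0, 0, 10, 10, "a", "img1"),
               boxes(50, 50, 60, 60, "b", "img1"))
  gt <- ground_truth(gtb)
  # class a detected perfectly, class b missed entirely
  ev <- mean_average_precision(boxes(0, 0, 10, 10, "a", "img1", score = 0.9),
                               gt, 0.5)
  expect_equal(unname(ev$per_class_ap), c(1, 0))
  expect_equal(ev$map, 0.5)

  single <- ground_truth(boxes(0, 0, 10, 10, "a", "img1"))
  ev1 <- mean_average_precision(boxes(1, 0, 11, 10, "a", "img1", score = 0.4),
                                single, 0.5)
  expect_equal(ev1$map, unname(ev1$per_class_ap["a"]))
})

test_that("a perfect 6-class synthetic detector scores mAP 1", {
  gt <- generate_ground_truth(scene_config(12, seed = 99))
  preds <- gt$boxes
  preds$score <- 0.9
  expect_equal(mean_average_precision(preds, gt, 0.5)$map, 1.0)
})

test_that("mAP is invariant to class relabeling and input permutation", {
  set.seed(13)
  for (i in 1:20) {
    inst <- random_instance()
    ev <- mean_average_precision(inst$preds, inst$gt, 0.5)

    perm <- sample(nrow(inst$preds))
    ev_perm <- mean_average_precision(inst$preds[perm, , drop = FALSE],
                                      inst$gt, 0.5)
    expect_equal(ev_perm$map, ev$map)

    relabel <- c(a = "zz_a", b = "aa_b")
    pr <- inst$preds; pr$label <- unname(relabel[pr$label])
    gb <- inst$gtb; gb$label <- unname(relabel[gb$label])
    ev_rel <- mean_average_precision(
      pr, ground_truth(gb, images = inst$gt$images), 0.5)
    expect_equal(sort(unname(ev_rel$per_class_ap)),
                 sort(unname(ev$per_class_ap)))
    expect_equal(ev_rel$map, ev$map)
  }
})

test_that("classes predicted but absent from gt are excluded from the mean", {
  gt <- gt1()
  preds <- rbind(boxes(0, 0, 10, 10, "a", "img1", score = 0.9),
                 boxes(30, 30, 40, 40, "ghost", "img1", score = 0.8))
  ev <- mean_average_precision(preds, gt, 0.5)
  expect_equal(names(ev$per_class_ap), "a")
  expect_equal(ev$ignored_classes, "ghost")
  expect_equal(ev$map, 1.0)
})

test_that("FROC: perfect detector sits at TPR 1, FPPI 0, FAUC 1", {
  gt <- gt1()
  fr <- froc_curve(boxes(0, 0, 10, 10, "a", "img1", score = 1.0), gt)
  expect_true(all(fr$points$tpr == 1))
  expect_true(all(fr$points$fppi == 0))
  expect_identical(fr$fauc, 1.0)
})

test_that("FPPI divides pooled false positives by the image count", {
  gtb <- boxes(0, 0, 10, 10, "a", "img1")
  gt <- ground_truth(gtb, images = c("img1", "img2", "img3"))
  # 6 disjoint false positives spread over the 3 images
  x <- seq(100, 600, by = 100)
  fps <- boxes(x, 0, x + 10, 10, "a", rep(c("img1", "img2", "img3"), 2),
               score = 0.9)
  fr <- froc_curve(fps, gt)
  expect_equal(fr$points$fppi[fr$points$threshold == 0], 2.0)
})

test_that("a constant-score detector collapses above its score", {
  gtb <- rbind(boxes(0, 0, 10, 10, "a", "img1"),
               boxes(30, 30, 45, 45, "a", "img2"))
  gt <- ground_truth(gtb)
  preds <- gtb
  preds$score <- 0.5
  preds <- rbind(preds, boxes(200, 200, 240, 240, "a", "img1", score = 0.5))
  fr <- froc_curve(preds, gt)
  lo <- fr$points[fr$points$threshold <= 0.5, ]
  hi <- fr$points[fr$points$threshold > 0.5, ]
  expect_true(all(lo$tpr == lo$tpr[1]) && all(lo$fppi == lo$fppi[1]))
  expect_true(all(hi$tpr == 0) && all(hi$fppi == 0))
})

test_that("the single-pass FROC sweep equals explicit re-matching", {
  set.seed(23)
  inst <- random_instance()
  thr <- 0.4
  fr <- froc_curve(inst$preds, inst$gt, thr, sweep = seq(0, 1, 0.1))
  n_gt <- nrow(inst$gtb)
  for (k in seq_len(nrow(fr$points))) {
    t <- fr$points$threshold[k]
    sub <- inst$preds[inst$preds$score >= t, , drop = FALSE]
    fl <- oracle_match_flags(sub, inst$gtb, thr)
    expect_equal(fr$points$tpr[k], sum(fl) / n_gt)
    expect_equal(fr$points$fppi[k], sum(!fl) / length(inst$gt$images))
  }
})

test_that("FROC rejects degenerate sweeps and empty image sets", {
  gt <- gt1()
  p <- boxes(0, 0, 10, 10, "a", "img1", score = 0.5)
  expect_error(froc_curve(p, gt, sweep = numeric()), "empty")
  expect_error(froc_curve(p, gt, sweep = c(0.5, 0.2)), "increasing")
  gt0 <- ground_truth(empty_boxes(score = FALSE), images = character())
  expect_error(froc_curve(p, gt0), "zero images")
})

test_that("froc_auc normalization: flat extension, truncation, degenerate 0", {
  # step curve reaching tpr 0.8 at fppi 1, flat beyond
  expect_equal(froc_auc(c(0, 1), c(0.8, 0.8), normalization = 2), 0.8)
  # truncating at half the observed range ignores what lies beyond
  expect_equal(froc_auc(c(0, 2), c(0, 1), normalization = 1), 0.25)
  expect_error(froc_auc(c(0, 1), c(0.5, 0.9), normalization = 0),
               "positive FPPI")
})
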