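gt1 <- data.frame(class = c("pod2", "leaf"),
                  x_min = c(0, 20), y_min = c(0, 20),
                  x_max = c(10, 40), y_max = c(10, 45))

test_that("perfect predictions give all true positives", {
  preds <- transform(gt1, confidence = c(0.7, 0.95))
  m <- match_detections(preds, gt1)
  ov <- m[m$class == "overall", ]
  expect_equal(c(ov$tp, ov$fp, ov$fn), c(2L, 0L, 0L))
})

test_that("missing predictions become false negatives", {
  m <- match_detections(NULL, gt1)
  ov <- m[m$class == "overall", ]
  expect_equal(c(ov$tp, ov$fp, ov$fn), c(0L, 0L, 2L))
})

test_that("duplicate detections of one object are penalized", {
  gt <- data.frame(class = "pod2", x_min = 0, y_min = 0, x_max = 10,
                   y_max = 10)
  preds <- data.frame(class = "pod2", x_min = c(0, 0), y_min = 0,
                      x_max = 10, y_max = 10, confidence = c(0.9, 0.8))
  m <- match_detections(preds, gt)
  row <- m[m$class == "pod2", ]
  expect_equal(c(row$tp, row$fp, row$fn), c(1L, 1L, 0L))
})

test_that("matching is class-strict unless pod classes are pooled", {
  gt <- data.frame(class = "pod3", x_min = 0, y_min = 0, x_max = 10,
                   y_max = 10)
  pred <- data.frame(class = "pod2", x_min = 0, y_min = 0, x_max = 10,
                     y_max = 10, confidence = 0.9)
  strictly <- match_detections(pred, gt)
  expect_equal(strictly[strictly$class == "overall", ]$tp, 0L)
  pooled <- match_detections(pred, gt, class_agnostic_pods = TRUE)
  expect_equal(pooled[pooled$class == "pod", ]$tp, 1L)
  expect_error(match_detections(transform(pred, class = "fruit"), gt),
               "unknown class")
})

test_that("the exact-threshold boundary counts by default and not in strict mode", {
  gt <- data.frame(class = "pod1", x_min = 0, y_min = 0, x_max = 2,
                   y_max = 2)
  # IoU exactly 0.5: 2x2 box vs 2x1 half
  pred <- data.frame(class = "pod1", x_min = 0, y_min = 0, x_max = 2,
                     y_max = 1, confidence = 0.9)
  expect_equal(iou(box(0, 0, 2, 2), box(0, 0, 2, 1)), 0.5)
  m_ge <- match_detections(pred, gt, iou_thresh = 0.5)
  expect_equal(m_ge[m_ge$class == "pod1", ]$tp, 1L)
  m_gt <- match_detections(pred, gt, iou_thresh = 0.5, strict = TRUE)
  expect_equal(m_gt[m_gt$class == "pod1", ]$tp, 0L)
})

test_that("match counts conserve predictions and ground truths per class", {
  set.seed(71)
  for (i in 1:500) {
    sc <- random_scene(sample(0:8, 1), sample(0:8, 1))
    m <- match_detections(sc$preds, sc$gts, iou_thresh = 0.5)
    per <- m[m$class != "overall", ]
    for (cl in per$class) {
      row <- per[per$class == cl, ]
      expect_identical(row$tp + row$fn, sum(sc$gts$class == cl))
      expect_identical(row$tp + row$fp, sum(sc$preds$class == cl))
    }
  }
})

test_that("raising the IoU threshold never increases true positives", {
  set.seed(73)
  for (i in 1:50) {
    sc <- random_scene(6, 6)
    tps <- vapply(seq(0.1, 0.9, by = 0.1), function(th)
      match_detections(sc$preds, sc$gts, th)[7L, "tp"], integer(1))
    expect_true(all(diff(tps) <= 0L))
  }
})

test_that("greedy matching attains the optimum on benign small instances", {
  set.seed(79)
  checked <- 0L
  for (i in 1:300) {
    np <- sample(1:4, 1); ng <- sample(1:4, 1)
    b_pred <- t(vapply(seq_len(np), function(j)
      unclass(random_box(30, 4)), numeric(4)))
    b_gt <- t(vapply(seq_len(ng), function(j)
      unclass(random_box(30, 4)), numeric(4)))
    im <- iou_matrix(b_pred, b_gt)
    # benign: no prediction clears the threshold with two ground truths
    if (any(rowSums(im >= 0.5) > 1)) next
    checked <- checked + 1L
    preds <- data.frame(class = "pod1", x_min = b_pred[, 1],
                        y_min = b_pred[, 2], x_max = b_pred[, 3],
                        y_max = b_pred[, 4],
                        confidence = sample(seq(0.5, 0.99, length.out = np)))
    gts <- data.frame(class = "pod1", x_min = b_gt[, 1], y_min = b_gt[, 2],
                      x_max = b_gt[, 3], y_max = b_gt[, 4])
    m <- match_detections(preds, gts, 0.5)
    expect_identical(m[m$class == "pod1", ]$tp,
                     brute_force_max_matching(im, 0.5))
  }
  expect_gt(checked, 50L)
})

test_that("a constructed ambiguous scene shows the known greedy/optimal gap", {
  # the confident prediction overlaps both objects and greedily claims the
  # one the weaker prediction needed; one detection is lost
  gts <- data.frame(class = "pod1", x_min = c(0, 2), y_min = 0,
                    x_max = c(10, 12), y_max = 1)
  preds <- data.frame(class = "pod1", x_min = c(0.5, 0), y_min = 0,
                      x_max = c(10.5, 6), y_max = 1,
                      confidence = c(0.9, 0.8))
  im <- iou_matrix(preds[, 2:5], gts[, 2:5])
  m <- match_detections(preds, gts, 0.5)
  expect_identical(m[m$class == "pod1", ]$tp, 1L)
  expect_identical(brute_force_max_matching(im, 0.5), 2L)
})

test_that("precision, recall and F1 follow their defining ratios", {
  counts <- data.frame(class = c("pod1", "overall"), tp = c(6L, 6L),
                       fp = c(2L, 2L), fn = c(4L, 4L))
  met <- precision_recall_f1(counts)
  expect_equal(met$precision[1], 0.75)
  expect_equal(met$recall[1], 0.6)
  expect_equal(met$f1[1], 2 * 0.75 * 0.6 / 1.35)
  degen <- data.frame(class = "overall", tp = 0L, fp = 0L, fn = 0L)
  expect_message(met0 <- precision_recall_f1(degen), "zero-denominator")
  expect_equal(unlist(met0[, c("precision", "recall", "f1")]),
               c(precision = 0, recall = 0, f1 = 0))
})

test_that("mean average precision is the arithmetic per-class mean", {
  expect_equal(mean_average_precision(c(0.8, 0.6)), 0.7)
  expect_equal(mean_average_precision(0.42), 0.42)
  p6 <- c(0.91, 0.88, 0.83, 0.79, 0.86, 0.9)
  expect_equal(mean_average_precision(p6), sum(p6) / 6)
  expect_error(mean_average_precision(numeric(0)), "non-empty")
})

test_that("11-point AP is 1 for perfect ranked detections and 0 without ground truth", {
  gt <- data.frame(class = "pod2", x_min = c(0, 20), y_min = 0,
                   x_max = c(10, 30), y_max = 10)
  perfect <- transform(gt, confidence = c(0.9, 0.8))
  expect_equal(average_precision_11pt(perfect, gt), 1)
  expect_equal(average_precision_11pt(perfect, gt[0, ]), 0)
})

test_that("fps is samples over seconds", {
  expect_equal(fps(100, 4), 25)
  expect_equal(fps(0, 1), 0)
  expect_equal(fps(39, 1), 39)
  expect_error(fps(10, 0), "positive")
})

test_that("dataset evaluation pools counts before computing ratios", {
  gt_a <- data.frame(class = "pod1", x_min = 0, y_min = 0, x_max = 10,
                     y_max = 10)
  gt_b <- data.frame(class = "pod1", x_min = c(0, 20), y_min = 0,
                     x_max = c(10, 30), y_max = 10)
  pred_a <- transform(gt_a, confidence = 0.9)         # 1/1 found
  pred_b <- transform(gt_b[1, ], confidence = 0.8)    # 1/2 found
  ev <- evaluate_detections(list(pred_a, pred_b), list(gt_a, gt_b))
  ov <- ev$per_class[ev$per_class$class == "overall", ]
  expect_equal(ov$recall, 2 / 3)  # micro average, not mean(1, 0.5)
  expect_equal(ov$precision, 1)
})
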