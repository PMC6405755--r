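# Evaluation suite: greedy matching, precision/recall, mean IOU, AP/mAP.

gt_box <- function(xmin, ymin, xmax, ymax, label) {
  data.frame(xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax,
             label = label, stringsAsFactors = FALSE)
}

det_box <- function(xmin, ymin, xmax, ymax, label, score = 1) {
  cbind(gt_box(xmin, ymin, xmax, ymax, label), score = score)
}

test_that("greedy matching pairs identical sets with IOU 1", {
  set.seed(2)
  gts <- random_boxes(5, with_scores = FALSE)
  dets <- cbind(gts, score = runif(5))
  m <- greedy_match(dets, gts)
  expect_equal(nrow(m$pairs), 5)
  expect_true(all(m$pairs$iou == 1))
  expect_length(m$unmatched_det, 0)
  expect_length(m$unmatched_gt, 0)
})

test_that("one detection overlapping two ground truths takes the higher IOU", {
  gts <- rbind(gt_box(0, 0, 100, 100, "11"), gt_box(80, 0, 180, 100, "12"))
  d <- det_box(5, 0, 105, 100, "11")
  m <- greedy_match(d, gts)
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$gt, 1)
  expect_equal(m$unmatched_gt, 2)
})

test_that("pairs at or below the threshold never match", {
  gts <- gt_box(0, 0, 100, 100, "11")
  d <- det_box(50, 0, 150, 100, "11")  # IOU = 1/3
  m <- greedy_match(d, gts)
  expect_equal(nrow(m$pairs), 0)
  # IOU exactly 0.7 is not a match (strict "exceeding")
  d2 <- det_box(0, 0, 10, 70, "11")
  g2 <- gt_box(0, 0, 10, 100, "11")
  expect_equal(box_iou(d2[, 1:4], g2[, 1:4]), 0.7)
  expect_equal(nrow(greedy_match(d2, g2)$pairs), 0)
})

test_that("greedy matching is invariant to input ordering and equals brute force", {
  set.seed(44)
  for (trial in 1:100) {
    gts <- random_cluster(sample(2:6, 1))[, -6]
    dets <- random_cluster(sample(2:6, 1))
    m <- greedy_match(dets, gts)
    ref <- oracle_greedy_match(dets, gts)
    expect_equal(m$pairs$iou, ref$iou, label = paste("trial", trial))
    expect_equal(m$pairs$det, ref$det, label = paste("trial", trial))
    expect_equal(m$pairs$gt, ref$gt, label = paste("trial", trial))
    # permuting detection rows permutes indices but not the matched IOUs
    perm <- sample(nrow(dets))
    m2 <- greedy_match(dets[perm, ], gts)
    expect_equal(sort(m2$pairs$iou), sort(m$pairs$iou))
  }
})

test_that("detection precision/recall follow the matched-count ratios", {
  set.seed(8)
  gts <- random_boxes(10, with_scores = FALSE)
  dets <- cbind(gts, score = 1)
  # break one detection so it cannot match
  dets$xmin[10] <- dets$xmax[10] - 1
  m <- greedy_match(dets, gts)
  expect_equal(nrow(m$pairs), 9)
  pr <- detection_pr(m)
  expect_equal(pr$precision, 0.9)
  expect_equal(pr$recall, 0.9)
  # perfect detection
  mp <- greedy_match(cbind(gts, score = 1), gts)
  expect_equal(detection_pr(mp)$precision, 1)
  expect_equal(detection_pr(mp)$recall, 1)
})

test_that("empty denominators report 0 with an undefined flag", {
  gts <- gt_box(0, 0, 100, 100, "11")
  m <- greedy_match(gts[0, ], gts)  # no detections
  pr <- detection_pr(m)
  expect_equal(pr$precision, 0)
  expect_false(pr$precision_defined)
  expect_equal(pr$recall, 0)
  expect_true(pr$recall_defined)
})

test_that("mean IOU averages matched pairs and flags the empty case", {
  m <- structure(list(pairs = data.frame(det = 1:2, gt = 1:2,
                                         iou = c(0.8, 1.0)),
                      unmatched_det = integer(0), unmatched_gt = integer(0),
                      n_db = 2L, n_gtb = 2L), class = "match_result")
  expect_equal(mean_iou(m), 0.9)
  m$pairs <- m$pairs[0, ]
  expect_warning(v <- mean_iou(m), "undefined")
  expect_true(is.na(v))
})

test_that("numbering precision counts label-agreeing matches", {
  set.seed(12)
  gts <- random_boxes(4, with_scores = FALSE)
  gts$label <- c("11", "12", "13", "14")
  dets <- cbind(gts, score = 1)
  dets$label <- c("11", "12", "23", "24")  # half correct
  m <- greedy_match(dets, gts)
  npr <- numbering_pr(m, dets, gts)
  expect_equal(npr$precision, 0.5)
  expect_equal(npr$recall, 0.5)
  # all wrong
  dets$label <- c("21", "22", "23", "24")
  expect_equal(numbering_pr(m, dets, gts)$precision, 0)
  # all right: equals detection precision/recall
  dets$label <- gts$label
  expect_equal(numbering_pr(m, dets, gts)$precision,
               detection_pr(m)$precision)
})

test_that("numbering P/R never exceed detection P/R on random inputs", {
  set.seed(66)
  for (trial in 1:60) {
    gts <- random_cluster(sample(2:6, 1))[, -6]
    dets <- random_cluster(sample(2:6, 1))
    m <- greedy_match(dets, gts)
    dpr <- detection_pr(m)
    npr <- numbering_pr(m, dets, gts)
    expect_lte(npr$precision, dpr$precision)
    expect_lte(npr$recall, dpr$recall)
  }
})

test_that("11-point AP reproduces hand-computed cases", {
  # one perfect detection
  r1 <- image_record("a", 200, 200,
                     detections = det_box(0, 0, 100, 100, "11", 0.9),
                     ground_truth = gt_box(0, 0, 100, 100, "11"))
  expect_equal(average_precision(list(r1), "11")$ap, 1)
  # TP at score 0.9, FP at 0.8, one gt: precision at recall 1 is 1,
  # so every interpolated point is 1
  r2 <- image_record("b", 400, 200,
                     detections = rbind(det_box(0, 0, 100, 100, "11", 0.9),
                                        det_box(200, 0, 300, 100, "11", 0.8)),
                     ground_truth = gt_box(0, 0, 100, 100, "11"))
  expect_equal(average_precision(list(r2), "11")$ap, 1)
  # FP outranks the TP: recall 0 point interpolates to 1, the rest to 1/2
  r3 <- image_record("c", 400, 200,
                     detections = rbind(det_box(200, 0, 300, 100, "11", 0.9),
                                        det_box(0, 0, 100, 100, "11", 0.8)),
                     ground_truth = gt_box(0, 0, 100, 100, "11"))
  expect_equal(average_precision(list(r3), "11")$ap, mean(rep(0.5, 11)))
  # no correct detections
  r4 <- image_record("d", 400, 200,
                     detections = det_box(200, 0, 300, 100, "11", 0.9),
                     ground_truth = gt_box(0, 0, 100, 100, "11"))
  expect_equal(average_precision(list(r4), "11")$ap, 0)
  # duplicate detections of one gt: second is a false positive
  r5 <- image_record("e", 400, 200,
                     detections = rbind(det_box(0, 0, 100, 100, "11", 0.9),
                                        det_box(1, 0, 101, 100, "11", 0.8)),
                     ground_truth = gt_box(0, 0, 100, 100, "11"))
  res5 <- average_precision(list(r5), "11")
  expect_equal(res5$ap, 1)  # full recall reached at precision 1 first
  expect_equal(res5$n_det, 2)
})

test_that("mAP averages classes present in ground truth", {
  r <- image_record("a", 600, 200,
                    detections = rbind(det_box(0, 0, 100, 100, "11", 0.9),
                                       det_box(400, 0, 500, 100, "13", 0.8)),
                    ground_truth = rbind(gt_box(0, 0, 100, 100, "11"),
                                         gt_box(200, 0, 300, 100, "12")))
  mm <- mean_average_precision(list(r))
  # class 11: AP 1; class 12: AP 0; class 13 has no gt and is excluded
  expect_equal(sort(mm$per_class$label), c("11", "12"))
  expect_equal(mm$map, 0.5)
  # empty ground truth everywhere
  r0 <- image_record("b", 100, 100)
  expect_true(is.na(mean_average_precision(list(r0))$map))
})

test_that("a perfect synthetic detector scores 1.0 on every metric", {
  set.seed(100)
  films <- lapply(1:20, function(i) {
    corrupt_detections(generate_film(image_id = paste0("f", i)),
                       noise_config(jitter_sd = 0, p_confusion = 0,
                                    p_duplicate = 0, p_dropout = 0,
                                    score_correct_range = c(1, 1)))
  })
  rep <- evaluate_records(films)
  expect_equal(rep$detection_precision, 1)
  expect_equal(rep$detection_recall, 1)
  expect_equal(rep$numbering_precision, 1)
  expect_equal(rep$numbering_recall, 1)
  expect_equal(rep$mean_iou, 1)
  expect_equal(rep$map, 1)
})

test_that("lowering a false positive's score below all true positives cannot lower AP", {
  gts <- rbind(gt_box(0, 0, 100, 100, "11"), gt_box(200, 0, 300, 100, "11"))
  dets_hi <- rbind(det_box(0, 0, 100, 100, "11", 0.6),
                   det_box(400, 0, 500, 100, "11", 0.9),   # FP on top
                   det_box(200, 0, 300, 100, "11", 0.5))
  dets_lo <- dets_hi
  dets_lo$score[2] <- 0.1                                   # FP at the bottom
  ap_hi <- average_precision(list(image_record("a", 600, 200, dets_hi,
                                               gts)), "11")$ap
  ap_lo <- average_precision(list(image_record("a", 600, 200, dets_lo,
                                               gts)), "11")$ap
  expect_gte(ap_lo, ap_hi)
})
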