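# Synthetic film and detector-noise generator.

test_that("generation is reproducible given a seed", {
  f1 <- generate_film(seed = 77)
  f2 <- generate_film(seed = 77)
  expect_equal(f1$ground_truth, f2$ground_truth)
  expect_equal(attr(f1, "film_truth"), attr(f2, "film_truth"))
  d1 <- corrupt_detections(f1, seed = 78)
  d2 <- corrupt_detections(f2, seed = 78)
  expect_equal(d1$detections, d2$detections)
  g1 <- generate_gap_training_set(arch_config(), 50, seed = 79)
  g2 <- generate_gap_training_set(arch_config(), 50, seed = 79)
  expect_equal(g1, g2)
})

test_that("zero missing probability yields a contiguous template window", {
  set.seed(10)
  for (trial in 1:25) {
    film <- generate_film(arch_config(p_missing = 0))
    truth <- attr(film, "film_truth")
    labels <- film$ground_truth$label
    tmpl <- fdi_template(truth$dentition)
    idx <- match(labels, tmpl)
    expect_false(anyNA(idx))
    expect_true(all(diff(idx) == 1))
    expect_true(all(truth$gap_missing == 0))
  }
})

test_that("generated labels are always an ordered template subsequence", {
  set.seed(20)
  for (trial in 1:25) {
    film <- generate_film()
    truth <- attr(film, "film_truth")
    idx <- match(film$ground_truth$label, fdi_template(truth$dentition))
    expect_false(anyNA(idx))
    expect_true(all(diff(idx) >= 1))
    # gap sizes in slots equal 1 + realized missing counts
    expect_equal(diff(idx), 1L + truth$gap_missing)
    expect_true(all(truth$gap_missing <= 3))
  }
})

test_that("a forced two-tooth gap without incline is about two teeth wide", {
  cfg <- arch_config(p_missing = 1, missing_count_probs = c(0, 1, 0),
                     p_incline = 0, width_cv = 0, n_teeth_range = c(2, 2))
  set.seed(30)
  for (trial in 1:10) {
    film <- generate_film(cfg)
    truth <- attr(film, "film_truth")
    gt <- film$ground_truth
    expect_equal(truth$gap_missing, 2L)
    margin <- gt$xmin[2] - gt$xmax[1]
    tmpl <- fdi_template(truth$dentition)
    missing_slots <- tmpl[(truth$offset + 2):(truth$offset + 3)]
    nominal <- sum(cfg$tooth_width_mm[tooth_category(missing_slots)] *
                     cfg$px_per_mm)
    spacing <- cfg$spacing_mm * cfg$px_per_mm
    expect_equal(margin, nominal + 3 * spacing, tolerance = 1e-8)
  }
})

test_that("inclined neighbors close the margin but not the center distance", {
  cfg_in <- arch_config(p_missing = 1, missing_count_probs = c(1, 0, 0),
                        p_incline = 1, width_cv = 0, n_teeth_range = c(2, 2))
  cfg_out <- arch_config(p_missing = 1, missing_count_probs = c(1, 0, 0),
                         p_incline = 0, width_cv = 0, n_teeth_range = c(2, 2))
  set.seed(40)
  f_in <- extract_gap_features(generate_film(cfg_in)$ground_truth)
  f_out <- extract_gap_features(generate_film(cfg_out)$ground_truth)
  expect_lt(f_in$margin, f_out$margin)
  # an inclined one-tooth gap still has a larger center distance than the
  # no-gap case (about half the gap survives in the centers)
  expect_gt(f_in$center_distance, f_in$normalizer)
})

test_that("zero-noise corruption copies ground truth with score 1", {
  film <- generate_film(seed = 50)
  det <- corrupt_detections(film, noise_config(jitter_sd = 0,
                                               p_confusion = 0,
                                               p_duplicate = 0,
                                               p_dropout = 0,
                                               score_correct_range = c(1, 1)))
  expect_equal(det$detections[, c("xmin", "ymin", "xmax", "ymax", "label")],
               film$ground_truth)
  expect_true(all(det$detections$score == 1))
  expect_equal(nrow(attr(det, "corruption_log")), 0)
})

test_that("full dropout empties the detections", {
  film <- generate_film(seed = 51)
  det <- corrupt_detections(film, noise_config(p_dropout = 1))
  expect_equal(nrow(det$detections), 0)
  log <- attr(det, "corruption_log")
  expect_equal(nrow(log), nrow(film$ground_truth))
  expect_true(all(log$event == "dropout"))
})

test_that("forced duplicates create overlapping pairs with different labels", {
  film <- generate_film(seed = 52)
  det <- corrupt_detections(film, noise_config(p_duplicate = 1,
                                               p_dropout = 0,
                                               p_confusion = 0),
                            seed = 53)
  log <- attr(det, "corruption_log")
  dup_rows <- log[log$event == "duplicate", ]
  expect_equal(nrow(dup_rows), nrow(film$ground_truth))
  d <- det$detections
  m <- iou_matrix(d, d)
  diag(m) <- 0
  found <- which(m > 0.7, arr.ind = TRUE)
  expect_gte(nrow(found), nrow(dup_rows))
  # at least one such pair disagrees on the label, as logged
  expect_true(any(d$label[found[, 1]] != d$label[found[, 2]]))
  expect_true(all(dup_rows$det_label != dup_rows$true_label))
})

test_that("every corruption event is recorded in the log", {
  set.seed(60)
  films <- generate_dataset(30)
  for (f in films) {
    log <- attr(f, "corruption_log")
    truth_labels <- f$ground_truth$label
    n_dropped <- sum(log$event == "dropout")
    n_dup <- sum(log$event == "duplicate")
    expect_equal(nrow(f$detections),
                 length(truth_labels) - n_dropped + n_dup)
    confusions <- log[grepl("^confusion", log$event), ]
    if (nrow(confusions)) {
      expect_true(all(confusions$det_label != confusions$true_label))
      expect_true(all(is_fdi_label(confusions$det_label)))
    }
  }
})

test_that("realized missing-count rates converge to the configured rates", {
  cfg <- arch_config()
  gaps <- generate_gap_training_set(cfg, 5000, seed = 70)
  n <- length(gaps$labels)
  p_class <- c(1 - cfg$p_missing, cfg$p_missing * cfg$missing_count_probs /
                 sum(cfg$missing_count_probs))
  for (k in 0:3) {
    p <- p_class[k + 1]
    p_hat <- mean(gaps$labels == k)
    tol <- 3 * sqrt(p * (1 - p) / n)
    expect_lt(abs(p_hat - p), tol + 1e-12,
              label = sprintf("class %d rate %.4f vs %.4f", k, p_hat, p))
  }
})

test_that("generated records always satisfy the data-model invariants", {
  set.seed(80)
  films <- generate_dataset(20)
  for (f in films) {
    expect_s3_class(f, "image_record")
    d <- f$detections
    g <- f$ground_truth
    expect_true(all(d$xmin < d$xmax & d$ymin < d$ymax))
    expect_true(all(d$xmax <= f$width & d$ymax <= f$height))
    expect_true(all(g$xmax <= f$width & g$ymax <= f$height))
    expect_true(all(is_fdi_label(c(d$label, g$label))))
    expect_true(all(d$score >= 0 & d$score <= 1))
  }
})
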