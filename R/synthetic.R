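# Synthetic periapical-film generator: paired ground truth and noisy
# detections with the statistical structure the post-processing pipeline
# assumes, so training and evaluation need no clinical data.
#
# A film shows 3-7 consecutive teeth of a single dentition, laid out left
# to right in pixel coordinates at 12.5 px/mm. Gaps left by missing teeth
# (0-3 per gap) are about as wide as the absent teeth unless the
# neighbors are inclined, in which case the margin closes while the
# center distance stays large. Detector noise emulates the classic error
# modes: corner jitter, label confusion (contralateral, adjacent-position,
# same-category), duplicate overlapping boxes with a different label, and
# dropped boxes.

#' Arch (film geometry) configuration
#'
#' Defaults are plausibility choices for adult permanent dentition at a
#' film resolution of 12.5 px/mm, not measurements from any dataset:
#' nominal mesiodistal widths per tooth category (mm), 3--7 visible teeth
#' per film, and film sizes of roughly 300--500 x 300--400 px.
#'
#' @param p_upper probability that a film shows the upper dentition.
#' @param n_teeth_range inclusive range of visible teeth per film.
#' @param p_missing probability that a gap between adjacent visible teeth
#'   contains missing teeth.
#' @param missing_count_probs distribution of the missing count 1..3,
#'   given that a gap has missing teeth.
#' @param p_incline probability that the neighbors of a missing-tooth gap
#'   lean in and close the margin.
#' @param px_per_mm film resolution.
#' @param tooth_width_mm named nominal widths per category (mm).
#' @param tooth_height_mm_range film-level crown+root height range (mm).
#' @param width_cv coefficient of variation of individual tooth widths.
#' @param spacing_mm interproximal spacing between adjacent teeth (mm).
#' @param image_width_range,image_height_range nominal film size (px);
#'   widened when the laid-out arch needs more room.
#' @param edge_margin_px range of the margin between the outermost boxes
#'   and the film edge.
#' @return a list of class `arch_config`.
#' @export
arch_config <- function(p_upper = 0.5,
                        n_teeth_range = c(3, 7),
                        p_missing = 0.05,
                        missing_count_probs = c(0.7, 0.2, 0.1),
                        p_incline = 0.25,
                        px_per_mm = 12.5,
                        tooth_width_mm = c(W = 10.0, M = 10.5, P = 7.0,
                                           Ca = 7.5, La = 6.5, Ce = 8.5,
                                           I = 5.5),
                        tooth_height_mm_range = c(18, 24),
                        width_cv = 0.06,
                        spacing_mm = 0.3,
                        image_width_range = c(300, 500),
                        image_height_range = c(300, 400),
                        edge_margin_px = c(10, 40)) {
  stopifnot(p_upper >= 0, p_upper <= 1,
            p_missing >= 0, p_missing <= 1,
            p_incline >= 0, p_incline <= 1,
            length(missing_count_probs) == 3, all(missing_count_probs >= 0),
            sum(missing_count_probs) > 0,
            all(tooth_width_mm > 0), px_per_mm > 0,
            n_teeth_range[1] >= 1, n_teeth_range[2] <= 16,
            n_teeth_range[1] <= n_teeth_range[2])
  structure(as.list(environment()), class = "arch_config")
}

#' Detector-noise configuration
#'
#' Controls how ground-truth boxes are corrupted into synthetic
#' detections. The confusion modes mirror the characteristic numbering
#' errors of a tooth detector: mislabeling a tooth as its contralateral
#' mirror (e.g. 25 as 15), as an adjacent position, or as another tooth
#' of the same category.
#'
#' @param jitter_sd SD of Gaussian corner jitter (px).
#' @param p_confusion probability that a detection carries a wrong label.
#' @param confusion_mode_probs weights of the modes `contralateral`,
#'   `adjacent`, `similar`.
#' @param p_duplicate probability of adding a duplicate box (IOU > 0.7
#'   with the original, different label, lower score).
#' @param p_dropout probability that a tooth is not detected at all.
#' @param score_correct_range,score_confused_range uniform score ranges
#'   for correctly and wrongly labeled detections.
#' @param duplicate_score_factor range of the multiplicative score
#'   penalty of a duplicate box.
#' @return a list of class `noise_config`.
#' @export
noise_config <- function(jitter_sd = 1.5,
                         p_confusion = 0.25,
                         confusion_mode_probs = c(contralateral = 0.5,
                                                  adjacent = 0.3,
                                                  similar = 0.2),
                         p_duplicate = 0.10,
                         p_dropout = 0.04,
                         score_correct_range = c(0.75, 0.98),
                         score_confused_range = c(0.40, 0.80),
                         duplicate_score_factor = c(0.60, 0.95)) {
  stopifnot(jitter_sd >= 0,
            all(c(p_confusion, p_duplicate, p_dropout) >= 0),
            all(c(p_confusion, p_duplicate, p_dropout) <= 1),
            length(confusion_mode_probs) == 3)
  structure(as.list(environment()), class = "noise_config")
}

.zero_noise_config <- function() {
  noise_config(jitter_sd = 0, p_confusion = 0, p_duplicate = 0,
               p_dropout = 0, score_correct_range = c(1, 1))
}

#' Generate one synthetic film (ground truth only)
#'
#' Draws a dentition, a contiguous window of the arrangement template, and
#' per-gap missing-tooth counts, then lays out the visible teeth left to
#' right. The realized generation choices are attached as the
#' `"film_truth"` attribute (dentition, 0-based template offset, per-gap
#' missing counts, incline flags), enabling exact expected-outcome checks
#' downstream.
#'
#' @param config an [arch_config()].
#' @param seed optional integer seed; `NULL` continues the current RNG
#'   stream.
#' @param image_id identifier of the generated record.
#' @return an [image_record()] with ground truth and no detections.
#' @export
generate_film <- function(config = arch_config(), seed = NULL,
                          image_id = "synthetic-film") {
  stopifnot(inherits(config, "arch_config"))
  if (!is.null(seed)) set.seed(seed)
  dentition <- if (stats::runif(1) < config$p_upper) "upper" else "lower"
  template <- fdi_template(dentition)
  n_choices <- config$n_teeth_range[1]:config$n_teeth_range[2]
  n_visible <- n_choices[sample.int(length(n_choices), 1)]
  n_gaps <- n_visible - 1
  repeat {
    miss <- integer(max(n_gaps, 0))
    if (n_gaps > 0) {
      has <- stats::runif(n_gaps) < config$p_missing
      miss[has] <- sample(1:3, sum(has), replace = TRUE,
                          prob = config$missing_count_probs)
    }
    span <- n_visible + sum(miss)
    if (span <= 16) break
  }
  offset <- sample.int(16 - span + 1, 1) - 1L
  slots <- offset + seq_len(span)
  # present mask along the window: tooth, then miss[i] absent slots, ...
  present <- logical(span)
  pos <- 1L
  present[pos] <- TRUE
  for (g in seq_len(n_gaps)) {
    pos <- pos + miss[g] + 1L
    present[pos] <- TRUE
  }
  labels_window <- template[slots]
  cats <- tooth_category(labels_window)
  nominal <- config$tooth_width_mm[cats] * config$px_per_mm
  widths <- nominal * pmax(stats::rnorm(span, 1, config$width_cv), 0.7)
  spacing <- config$spacing_mm * config$px_per_mm

  x <- stats::runif(1, config$edge_margin_px[1], config$edge_margin_px[2])
  xmin <- numeric(span)
  xmax <- numeric(span)
  for (i in seq_len(span)) {
    xmin[i] <- x
    xmax[i] <- x + widths[i]
    x <- xmax[i] + spacing
  }
  keep <- which(present)
  boxes <- data.frame(xmin = xmin[keep], xmax = xmax[keep],
                      label = labels_window[keep],
                      stringsAsFactors = FALSE)
  # inclined neighbors lean into a missing-tooth gap: the flanking boxes
  # extend toward each other, shrinking the margin while the center
  # distance shrinks only half as much
  inclined <- logical(max(n_gaps, 0))
  if (n_gaps > 0) {
    for (g in which(miss > 0)) {
      if (stats::runif(1) < config$p_incline) {
        inclined[g] <- TRUE
        gap_px <- boxes$xmin[g + 1] - boxes$xmax[g]
        boxes$xmax[g] <- boxes$xmax[g] + stats::runif(1, 0.20, 0.42) * gap_px
        boxes$xmin[g + 1] <- boxes$xmin[g + 1] -
          stats::runif(1, 0.20, 0.42) * gap_px
      }
    }
  }
  height <- stats::runif(1, config$tooth_height_mm_range[1],
                         config$tooth_height_mm_range[2]) * config$px_per_mm
  ytop <- stats::runif(1, config$edge_margin_px[1], config$edge_margin_px[2])
  n_teeth <- nrow(boxes)
  boxes$ymin <- pmax(ytop + stats::rnorm(n_teeth, 0, 2), 0)
  boxes$ymax <- boxes$ymin + height * stats::runif(n_teeth, 0.95, 1.05)

  need_w <- max(boxes$xmax) +
    stats::runif(1, config$edge_margin_px[1], config$edge_margin_px[2])
  need_h <- max(boxes$ymax) +
    stats::runif(1, config$edge_margin_px[1], config$edge_margin_px[2])
  width_px <- max(round(stats::runif(1, config$image_width_range[1],
                                     config$image_width_range[2])),
                  ceiling(need_w))
  height_px <- max(round(stats::runif(1, config$image_height_range[1],
                                      config$image_height_range[2])),
                   ceiling(need_h))
  record <- image_record(
    image_id = image_id, width = width_px, height = height_px,
    ground_truth = boxes[, c("xmin", "ymin", "xmax", "ymax", "label")]
  )
  attr(record, "film_truth") <- list(
    dentition = dentition, offset = offset, span = span,
    labels = boxes$label, gap_missing = miss, inclined = inclined
  )
  record
}

.contralateral <- function(label) {
  quad <- substr(label, 1, 1)
  mirror <- c("1" = "2", "2" = "1", "3" = "4", "4" = "3")[quad]
  paste0(mirror, substr(label, 2, 2))
}

.confused_label <- function(label, mode) {
  switch(mode,
    contralateral = .contralateral(label),
    adjacent = {
      template <- fdi_template(fdi_dentition(label))
      i <- match(label, template)
      cand <- template[intersect(c(i - 1, i + 1), 1:16)]
      if (length(cand) == 1) cand else sample(cand, 1)
    },
    similar = {
      dent <- fdi_dentition(label)
      template <- fdi_template(dent)
      cand <- setdiff(template[tooth_category(template) ==
                                 tooth_category(label)], label)
      if (length(cand) == 1) cand else sample(cand, 1)
    },
    stop("unknown confusion mode: ", mode, call. = FALSE)
  )
}

.jitter_box <- function(b, sd, width, height) {
  repeat {
    j <- stats::rnorm(4, 0, sd)
    out <- c(xmin = max(0, b$xmin + j[1]), ymin = max(0, b$ymin + j[2]),
             xmax = min(width, b$xmax + j[3]),
             ymax = min(height, b$ymax + j[4]))
    if (sd == 0 || (out["xmin"] < out["xmax"] && out["ymin"] < out["ymax"])) {
      return(out)
    }
  }
}

#' Corrupt ground truth into synthetic detections
#'
#' Derives detections from a film's ground-truth boxes by applying, per
#' box: dropout, corner jitter, label confusion, a confidence score drawn
#' from the correct or confused score range, and optionally a duplicate
#' box with IOU > 0.7, a different label and a lower score. Every realized
#' corruption is recorded in the `"corruption_log"` attribute so tests can
#' assert exact expected outcomes.
#'
#' @param record an [image_record()] with ground truth.
#' @param noise a [noise_config()]; the zero-noise configuration turns
#'   detections into exact copies of the ground truth with score 1.
#' @param seed optional integer seed.
#' @return the record with `detections` filled in.
#' @export
corrupt_detections <- function(record, noise = noise_config(), seed = NULL) {
  stopifnot(inherits(record, "image_record"), inherits(noise, "noise_config"))
  if (!is.null(seed)) set.seed(seed)
  gt <- record$ground_truth
  dets <- list()
  log <- list()
  for (i in seq_len(nrow(gt))) {
    if (stats::runif(1) < noise$p_dropout) {
      log[[length(log) + 1]] <- data.frame(
        gt_row = i, event = "dropout", true_label = gt$label[i],
        det_label = NA_character_, stringsAsFactors = FALSE)
      next
    }
    confused <- stats::runif(1) < noise$p_confusion
    if (confused) {
      mode <- sample(c("contralateral", "adjacent", "similar"), 1,
                     prob = noise$confusion_mode_probs)
      lab <- .confused_label(gt$label[i], mode)
      score <- stats::runif(1, noise$score_confused_range[1],
                            noise$score_confused_range[2])
      log[[length(log) + 1]] <- data.frame(
        gt_row = i, event = paste0("confusion:", mode),
        true_label = gt$label[i], det_label = lab, stringsAsFactors = FALSE)
    } else {
      lab <- gt$label[i]
      score <- stats::runif(1, noise$score_correct_range[1],
                            noise$score_correct_range[2])
    }
    box <- .jitter_box(gt[i, ], noise$jitter_sd, record$width, record$height)
    det <- data.frame(xmin = box[["xmin"]], ymin = box[["ymin"]],
                      xmax = box[["xmax"]], ymax = box[["ymax"]],
                      label = lab, score = score, stringsAsFactors = FALSE)
    dets[[length(dets) + 1]] <- det
    if (stats::runif(1) < noise$p_duplicate) {
      dup_lab <- lab
      tries <- 0
      while (dup_lab == lab && tries < 10) {
        dup_lab <- .confused_label(
          gt$label[i], sample(c("contralateral", "adjacent", "similar"), 1,
                              prob = noise$confusion_mode_probs))
        tries <- tries + 1
      }
      repeat {
        dup_box <- .jitter_box(gt[i, ], max(noise$jitter_sd, 1),
                               record$width, record$height)
        if (box_iou(dup_box, det[1, 1:4]) > 0.7) break
      }
      dets[[length(dets) + 1]] <- data.frame(
        xmin = dup_box[["xmin"]], ymin = dup_box[["ymin"]],
        xmax = dup_box[["xmax"]], ymax = dup_box[["ymax"]],
        label = dup_lab,
        score = score * stats::runif(1, noise$duplicate_score_factor[1],
                                     noise$duplicate_score_factor[2]),
        stringsAsFactors = FALSE)
      log[[length(log) + 1]] <- data.frame(
        gt_row = i, event = "duplicate", true_label = gt$label[i],
        det_label = dup_lab, stringsAsFactors = FALSE)
    }
  }
  detections <- if (length(dets)) do.call(rbind, dets) else NULL
  out <- image_record(record$image_id, record$width, record$height,
                      detections = detections, ground_truth = gt)
  attr(out, "film_truth") <- attr(record, "film_truth")
  attr(out, "corruption_log") <-
    if (length(log)) do.call(rbind, log)
    else data.frame(gt_row = integer(0), event = character(0),
                    true_label = character(0), det_label = character(0))
  out
}

#' Generate a labeled gap-feature training set
#'
#' Draws synthetic films and extracts one training example per adjacent
#' pair of ground-truth boxes: the geometric gap features paired with the
#' generator's realized missing-tooth count for that gap.
#'
#' @param config an [arch_config()].
#' @param n number of gap examples.
#' @param seed optional integer seed.
#' @return list with `features` (see [extract_gap_features()]) and
#'   integer `labels` in 0..3.
#' @export
generate_gap_training_set <- function(config = arch_config(), n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  feats <- list()
  labs <- list()
  total <- 0L
  while (total < n) {
    film <- generate_film(config)
    truth <- attr(film, "film_truth")
    if (length(truth$gap_missing) == 0) next
    f <- extract_gap_features(film$ground_truth)
    feats[[length(feats) + 1]] <- f
    labs[[length(labs) + 1]] <- truth$gap_missing
    total <- total + nrow(f)
  }
  features <- do.call(rbind, feats)[seq_len(n), ]
  rownames(features) <- NULL
  list(features = features, labels = unlist(labs)[seq_len(n)])
}

#' Generate a full synthetic detection dataset
#'
#' @param n_films number of films.
#' @param config an [arch_config()].
#' @param noise a [noise_config()].
#' @param seed optional integer seed.
#' @return list of [image_record()]s with ground truth and noisy
#'   detections; each carries its `"film_truth"` and `"corruption_log"`
#'   attributes.
#' @export
generate_dataset <- function(n_films, config = arch_config(),
                             noise = noise_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_films), function(i) {
    film <- generate_film(config, image_id = sprintf("syn-%05d", i))
    corrupt_detections(film, noise)
  })
}
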