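# Staged post-processing pipeline:
#   stage 1  raw detector output
#   stage 2  overlap filtering (within-class NMS, then cross-label)
#   stage 3  template matching and relabeling, no placeholders
#   stage 4  missing-teeth placeholders inserted, then template matching
# Stage 3 is computed from stage 2 (not chained through stage 4) so the
# two correction strategies can be compared independently.

#' Pipeline configuration
#'
#' @param within_class_threshold IOU threshold of the per-label NMS pass
#'   (default 0.6).
#' @param cross_label_threshold IOU threshold of the cross-label
#'   suppression pass (default 0.7).
#' @param enable_within_class,enable_cross_label enable flags for the two
#'   stage-2 passes.
#' @param enable_reversal score reversed sequences during template
#'   matching?
#' @param match_threshold IOU threshold of the evaluation matching
#'   (default 0.7).
#' @param map_threshold IOU threshold of AP computation (default 0.5).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(within_class_threshold = 0.6,
                            cross_label_threshold = 0.7,
                            enable_within_class = TRUE,
                            enable_cross_label = TRUE,
                            enable_reversal = TRUE,
                            match_threshold = 0.7,
                            map_threshold = 0.5) {
  structure(as.list(environment()), class = "pipeline_config")
}

# Template-match one stage-2 detection table; optionally insert
# placeholders first. Returns the relabeled table (geometry and scores
# untouched).
.match_stage <- function(dets, similarity, config, gap_model = NULL) {
  if (nrow(dets) == 0) return(dets)
  ord <- order_detections(dets)
  labels <- ord$label
  if (!is.null(gap_model) && nrow(ord) >= 2) {
    feats <- extract_gap_features(ord)
    counts <- predict_missing(gap_model, feats)
    # an augmented sequence cannot exceed the 16-slot template; shed
    # placeholders from the widest predictions first if it would
    while (length(labels) + sum(counts) > 16) {
      counts[which.max(counts)] <- counts[which.max(counts)] - 1L
    }
    labels <- insert_placeholders(labels, counts)
  }
  aln <- best_alignment(labels, .scores_for(labels, ord$score),
                        model = similarity,
                        enable_reversal = config$enable_reversal)
  out <- relabel(ord, labels, aln)
  attr(out, "alignment") <- aln
  out
}

# expand box scores to the augmented sequence (placeholders score 0;
# their score is never used since placeholders neither match nor carry
# similarity, but the vectors must align)
.scores_for <- function(labels, box_scores) {
  scores <- numeric(length(labels))
  scores[labels != fdi_placeholder] <- box_scores
  scores
}

#' Run the staged post-processing pipeline on one image
#'
#' Applies the full stage 1 to 4 cascade to an image's detections. Stage
#' outputs modify only membership (stage 2) and labels (stages 3--4); box
#' geometry and confidence scores are never altered. Without a gap model
#' only stages 1--3 are produced (with a warning).
#'
#' @param record an [image_record()] with detections.
#' @param gap_model a trained [train_gap_classifier()] model, or `NULL`.
#' @param config a [pipeline_config()].
#' @param similarity a [similarity_model()].
#' @return list of detection tables `stage1`, `stage2`, `stage3` and (with
#'   a gap model) `stage4`; stages 3 and 4 carry their chosen
#'   [best_alignment()] as the `"alignment"` attribute.
#' @export
postprocess <- function(record, gap_model = NULL,
                        config = pipeline_config(),
                        similarity = similarity_model()) {
  stopifnot(inherits(record, "image_record"),
            inherits(config, "pipeline_config"))
  stage1 <- record$detections
  stage2 <- stage1
  if (config$enable_within_class) {
    stage2 <- suppress_within_class(stage2, config$within_class_threshold)
  }
  if (config$enable_cross_label) {
    stage2 <- suppress_cross_label(stage2, config$cross_label_threshold)
  }
  out <- list(stage1 = stage1, stage2 = stage2,
              stage3 = .match_stage(stage2, similarity, config))
  if (is.null(gap_model)) {
    warning("no gap model supplied; stage 4 skipped", call. = FALSE)
  } else {
    out$stage4 <- .match_stage(stage2, similarity, config, gap_model)
  }
  out
}

#' Run the pipeline over a dataset
#'
#' @param records list of [image_record()]s.
#' @inheritParams postprocess
#' @return list (one element per record) of [postprocess()] outputs.
#' @export
postprocess_dataset <- function(records, gap_model = NULL,
                                config = pipeline_config(),
                                similarity = similarity_model()) {
  if (is.null(gap_model)) {
    warning("no gap model supplied; stage 4 skipped", call. = FALSE)
    # warn once, not per image
    gap_missing <- TRUE
  } else gap_missing <- FALSE
  lapply(records, function(r) {
    suppressWarnings(postprocess(r, gap_model, config, similarity))
  })
}

#' Evaluate every pipeline stage against ground truth
#'
#' Replaces each record's detections by the output of each stage in turn
#' and computes the pooled [evaluate_records()] metrics, yielding one
#' report row per stage: boxes detected, detection precision/recall, mean
#' IOU (with SD), numbering precision/recall, and mAP.
#'
#' @param records the original records (ground truth is read from these).
#' @param staged output of [postprocess_dataset()].
#' @param config a [pipeline_config()] (thresholds for the evaluation).
#' @param compute_map include 11-point mAP per stage?
#' @return data frame with one row per stage.
#' @export
evaluate_stages <- function(records, staged, config = pipeline_config(),
                            compute_map = TRUE) {
  stopifnot(length(records) == length(staged))
  stages <- intersect(c("stage1", "stage2", "stage3", "stage4"),
                      unique(unlist(lapply(staged, names))))
  rows <- lapply(stages, function(st) {
    stage_records <- mapply(function(r, s) {
      image_record(r$image_id, r$width, r$height,
                   detections = s[[st]], ground_truth = r$ground_truth)
    }, records, staged, SIMPLIFY = FALSE)
    rep <- evaluate_records(stage_records,
                            match_threshold = config$match_threshold,
                            map_threshold = config$map_threshold,
                            compute_map = compute_map)
    data.frame(stage = st, n_images = rep$n_images, gt_boxes = rep$n_gtb,
               boxes_detected = rep$n_db,
               detection_precision = rep$detection_precision,
               detection_recall = rep$detection_recall,
               mean_iou = rep$mean_iou, sd_iou = rep$sd_iou,
               numbering_precision = rep$numbering_precision,
               numbering_recall = rep$numbering_recall,
               map = if (compute_map) rep$map else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
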