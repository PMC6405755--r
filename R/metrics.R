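# Evaluation suite: greedy IOU-matrix matching of detections to ground
# truth, detection and numbering precision/recall, mean IOU over matches,
# and 11-point interpolated per-class AP / mAP.

#' Greedy IOU matching of detections to ground truth
#'
#' Forms the full IOU matrix between one image's detected and ground-truth
#' boxes, then iteratively selects the global maximum entry; while that
#' maximum exceeds the threshold the pair is recorded as a match and its
#' row and column removed. Each detection and each ground-truth box
#' therefore appears in at most one pair, every matched pair has IOU above
#' the threshold, and the result does not depend on input row order.
#'
#' @param dets data frame of detected boxes.
#' @param gts data frame of ground-truth boxes.
#' @param threshold IOU that a pair must exceed (strict `>`) to match;
#'   default 0.7.
#' @return an object of class `match_result`: list with `pairs` (data
#'   frame `det`, `gt`, `iou` of matched row indices), `unmatched_det`,
#'   `unmatched_gt`, `n_db`, `n_gtb`.
#' @export
greedy_match <- function(dets, gts, threshold = 0.7) {
  n_db <- nrow(dets)
  n_gtb <- nrow(gts)
  pairs <- data.frame(det = integer(0), gt = integer(0), iou = numeric(0))
  if (n_db > 0 && n_gtb > 0) {
    m <- iou_matrix(dets, gts)
    repeat {
      best <- max(m)
      if (best <= threshold) break
      hit <- which(m == best, arr.ind = TRUE)[1, ]
      pairs <- rbind(pairs, data.frame(det = hit[["row"]], gt = hit[["col"]],
                                       iou = best))
      m[hit[["row"]], ] <- -1
      m[, hit[["col"]]] <- -1
    }
  }
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 unmatched_det = setdiff(seq_len(n_db), pairs$det),
                 unmatched_gt = setdiff(seq_len(n_gtb), pairs$gt),
                 n_db = n_db, n_gtb = n_gtb),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result: %d/%d detections matched to %d ground truth>\n",
              nrow(x$pairs), x$n_db, x$n_gtb))
  invisible(x)
}

.safe_ratio <- function(num, den) {
  if (den == 0) list(value = 0, defined = FALSE)
  else list(value = num / den, defined = TRUE)
}

#' Detection precision and recall
#'
#' Precision is the number of matched pairs over the number of detected
#' boxes; recall is matched pairs over ground-truth boxes. An empty
#' denominator yields 0 with the corresponding `*_defined` flag set to
#' `FALSE` rather than an error.
#'
#' @param match a [greedy_match()] result.
#' @return list with `precision`, `recall`, `precision_defined`,
#'   `recall_defined`.
#' @export
detection_pr <- function(match) {
  stopifnot(inherits(match, "match_result"))
  p <- .safe_ratio(nrow(match$pairs), match$n_db)
  r <- .safe_ratio(nrow(match$pairs), match$n_gtb)
  list(precision = p$value, recall = r$value,
       precision_defined = p$defined, recall_defined = r$defined)
}

#' Mean IOU over matched pairs
#'
#' @param match a [greedy_match()] result.
#' @return arithmetic mean of the matched IOUs; `NA` with a warning when
#'   there are no matches.
#' @export
mean_iou <- function(match) {
  stopifnot(inherits(match, "match_result"))
  if (!nrow(match$pairs)) {
    warning("no matched pairs; mean IOU is undefined", call. = FALSE)
    return(NA_real_)
  }
  mean(match$pairs$iou)
}

#' Numbering precision and recall
#'
#' A matched pair whose detected and ground-truth FDI labels agree is a
#' true positive numbering. Precision divides by the number of detected
#' boxes, recall by the number of ground-truth boxes, so numbering
#' precision/recall can never exceed detection precision/recall.
#'
#' @param match a [greedy_match()] result for `dets` vs `gts`.
#' @param dets,gts the box tables that were matched (labels are read from
#'   these).
#' @return list with `precision`, `recall`, `n_tpn`, and definedness
#'   flags.
#' @export
numbering_pr <- function(match, dets, gts) {
  stopifnot(inherits(match, "match_result"))
  n_tpn <- if (nrow(match$pairs)) {
    sum(dets$label[match$pairs$det] == gts$label[match$pairs$gt])
  } else 0L
  p <- .safe_ratio(n_tpn, match$n_db)
  r <- .safe_ratio(n_tpn, match$n_gtb)
  list(precision = p$value, recall = r$value, n_tpn = n_tpn,
       precision_defined = p$defined, recall_defined = r$defined)
}

# Score-ranked TP/FP assignment for one class across the dataset: each
# detection, in descending score order, greedily claims the unclaimed
# same-image ground-truth box with the highest IOU if that IOU exceeds the
# threshold; otherwise (or when the best box is already claimed) it is a
# false positive.
.class_tp_fp <- function(records, class, iou_threshold) {
  det_rows <- list()
  n_gt <- 0L
  claimed <- list()
  for (k in seq_along(records)) {
    r <- records[[k]]
    gts <- r$ground_truth[r$ground_truth$label == class, , drop = FALSE]
    dts <- r$detections[r$detections$label == class, , drop = FALSE]
    n_gt <- n_gt + nrow(gts)
    claimed[[k]] <- rep(FALSE, nrow(gts))
    if (nrow(dts)) {
      det_rows[[length(det_rows) + 1]] <-
        data.frame(img = k, row = seq_len(nrow(dts)), score = dts$score)
    }
  }
  dets_all <- do.call(rbind, det_rows)
  if (is.null(dets_all) || !nrow(dets_all)) {
    return(list(tp = logical(0), n_gt = n_gt, n_det = 0L))
  }
  dets_all <- dets_all[order(-dets_all$score, dets_all$img, dets_all$row), ]
  tp <- logical(nrow(dets_all))
  for (i in seq_len(nrow(dets_all))) {
    k <- dets_all$img[i]
    r <- records[[k]]
    gts <- r$ground_truth[r$ground_truth$label == class, , drop = FALSE]
    if (!nrow(gts)) next
    dts <- r$detections[r$detections$label == class, , drop = FALSE]
    ious <- iou_matrix(dts[dets_all$row[i], , drop = FALSE], gts)[1, ]
    free <- which(!claimed[[k]] & ious > iou_threshold)
    if (length(free)) {
      j <- free[which.max(ious[free])]
      claimed[[k]][j] <- TRUE
      tp[i] <- TRUE
    }
  }
  list(tp = tp, n_gt = n_gt, n_det = nrow(dets_all))
}

.ap_11point <- function(tp, n_gt) {
  if (n_gt == 0) return(NA_real_)
  if (!length(tp)) return(0)
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  precision <- cum_tp / (cum_tp + cum_fp)
  recall <- cum_tp / n_gt
  mean(vapply(seq(0, 1, by = 0.1), function(r) {
    p <- precision[recall >= r]
    if (length(p)) max(p) else 0
  }, numeric(1)))
}

#' 11-point interpolated average precision for one class
#'
#' Detections of the class are pooled dataset-wide and ranked by
#' descending score; each greedily claims the highest-IOU unclaimed
#' ground-truth box of its image with IOU strictly above the threshold
#' (a true positive), otherwise it is a false positive (including
#' duplicate detections of an already-claimed box). AP is the mean of the
#' interpolated precision, the maximum precision at any recall at or above
#' `r`, over the 11 recall points 0.0, 0.1, ..., 1.0.
#'
#' @param records list of [image_record()] objects with detections and
#'   ground truth.
#' @param class FDI label of the class to evaluate.
#' @param iou_threshold IOU a detection must exceed to count as a true
#'   positive; default 0.5.
#' @return list with `ap` (`NA` when the class has no ground truth),
#'   `n_gt`, `n_det`.
#' @export
average_precision <- function(records, class, iou_threshold = 0.5) {
  res <- .class_tp_fp(records, class, iou_threshold)
  list(ap = .ap_11point(res$tp, res$n_gt), n_gt = res$n_gt,
       n_det = res$n_det)
}

#' Mean average precision over ground-truth classes
#'
#' Unweighted mean of per-class 11-point AP over every FDI class with at
#' least one ground-truth instance in the dataset. Classes that appear
#' only among detections contribute false positives to their own
#' (absent) class and are excluded from the average.
#'
#' @inheritParams average_precision
#' @return list with `map` and a `per_class` data frame (`label`, `ap`,
#'   `n_gt`, `n_det`).
#' @export
mean_average_precision <- function(records, iou_threshold = 0.5) {
  gt_classes <- sort(unique(unlist(lapply(records, function(r) {
    r$ground_truth$label
  }))))
  if (!length(gt_classes)) {
    return(list(map = NA_real_,
                per_class = data.frame(label = character(0), ap = numeric(0),
                                       n_gt = integer(0), n_det = integer(0))))
  }
  per <- lapply(gt_classes, function(cl) {
    res <- average_precision(records, cl, iou_threshold)
    data.frame(label = cl, ap = res$ap, n_gt = res$n_gt, n_det = res$n_det,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(map = mean(per$ap), per_class = per)
}

#' Pooled evaluation of a detection dataset
#'
#' Matches detections to ground truth per image with [greedy_match()] and
#' micro-averages the counts across images (counts are pooled before
#' dividing, so large films weigh more): detection precision/recall, mean
#' and SD of matched IOUs, numbering precision/recall, and optionally
#' 11-point mAP.
#'
#' @param records list of [image_record()] objects.
#' @param match_threshold IOU threshold for the greedy matching
#'   (default 0.7).
#' @param map_threshold IOU threshold for AP (default 0.5).
#' @param compute_map also compute per-class AP and mAP?
#' @return an object of class `metric_report`.
#' @export
evaluate_records <- function(records, match_threshold = 0.7,
                             map_threshold = 0.5, compute_map = TRUE) {
  if (inherits(records, "image_record")) records <- list(records)
  n_db <- 0L
  n_gtb <- 0L
  n_match <- 0L
  n_tpn <- 0L
  ious <- numeric(0)
  for (r in records) {
    m <- greedy_match(r$detections, r$ground_truth, match_threshold)
    n_db <- n_db + m$n_db
    n_gtb <- n_gtb + m$n_gtb
    n_match <- n_match + nrow(m$pairs)
    ious <- c(ious, m$pairs$iou)
    n_tpn <- n_tpn +
      numbering_pr(m, r$detections, r$ground_truth)$n_tpn
  }
  dp <- .safe_ratio(n_match, n_db)
  dr <- .safe_ratio(n_match, n_gtb)
  np <- .safe_ratio(n_tpn, n_db)
  nr <- .safe_ratio(n_tpn, n_gtb)
  report <- list(
    n_images = length(records), n_db = n_db, n_gtb = n_gtb,
    n_match = n_match, n_tpn = n_tpn,
    detection_precision = dp$value, detection_recall = dr$value,
    mean_iou = if (n_match) mean(ious) else NA_real_,
    sd_iou = if (n_match > 1) stats::sd(ious) else NA_real_,
    numbering_precision = np$value, numbering_recall = nr$value,
    precision_defined = dp$defined, recall_defined = dr$defined
  )
  if (compute_map) {
    mm <- mean_average_precision(records, map_threshold)
    report$map <- mm$map
    report$per_class_ap <- mm$per_class
  }
  structure(report, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report: %d images, %d GT boxes, %d detected>\n",
              x$n_images, x$n_gtb, x$n_db))
  cat(sprintf("  detection  P %.3f  R %.3f\n",
              x$detection_precision, x$detection_recall))
  cat(sprintf("  numbering  P %.3f  R %.3f\n",
              x$numbering_precision, x$numbering_recall))
  if (!is.na(x$mean_iou)) {
    cat(sprintf("  mean IOU %.3f%s\n", x$mean_iou,
                if (!is.na(x$sd_iou)) sprintf(" ± %.3f", x$sd_iou)
                else ""))
  }
  if (!is.null(x$map) && !is.na(x$map)) {
    cat(sprintf("  mAP (11-point, IOU > 0.5) %.3f\n", x$map))
  }
  invisible(x)
}
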