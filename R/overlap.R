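# Stage-2 filtering of excessively overlapping detected boxes:
# within-class non-maximum suppression followed by cross-label suppression
# of duplicate boxes that carry different predicted tooth numbers.

#' Intersection-over-union of two boxes
#'
#' Ratio of the intersection area to the union area of two axis-aligned
#' boxes, with the continuous area convention width = xmax - xmin. Disjoint
#' boxes have IOU 0, identical boxes IOU 1.
#'
#' @param a,b boxes: numeric vectors or one-row data frames with elements
#'   `xmin`, `ymin`, `xmax`, `ymax`.
#' @return IOU value in `[0, 1]`.
#' @examples
#' box_iou(c(xmin = 0, ymin = 0, xmax = 10, ymax = 10),
#'         c(xmin = 5, ymin = 0, xmax = 15, ymax = 10))  # 1/3
#' @export
box_iou <- function(a, b) {
  a <- as.list(a)
  b <- as.list(b)
  iw <- max(0, min(a$xmax, b$xmax) - max(a$xmin, b$xmin))
  ih <- max(0, min(a$ymax, b$ymax) - max(a$ymin, b$ymin))
  inter <- iw * ih
  area_a <- (a$xmax - a$xmin) * (a$ymax - a$ymin)
  area_b <- (b$xmax - b$xmin) * (b$ymax - b$ymin)
  inter / (area_a + area_b - inter)
}

#' Pairwise IOU matrix between two box tables
#'
#' @param a,b data frames of boxes with columns `xmin`, `ymin`, `xmax`,
#'   `ymax` (rows of `a` index the matrix rows).
#' @return numeric `nrow(a)` x `nrow(b)` matrix of IOU values.
#' @export
iou_matrix <- function(a, b) {
  na <- nrow(a)
  nb <- nrow(b)
  if (na == 0 || nb == 0) return(matrix(numeric(0), na, nb))
  iw <- pmax(outer(a$xmax, b$xmax, pmin) - outer(a$xmin, b$xmin, pmax), 0)
  ih <- pmax(outer(a$ymax, b$ymax, pmin) - outer(a$ymin, b$ymin, pmax), 0)
  inter <- iw * ih
  area_a <- (a$xmax - a$xmin) * (a$ymax - a$ymin)
  area_b <- (b$xmax - b$xmin) * (b$ymax - b$ymin)
  inter / (outer(area_a, area_b, `+`) - inter)
}

#' Within-class non-maximum suppression
#'
#' For each predicted label independently: greedily keep the highest-score
#' box and delete every remaining same-label box whose IOU with a kept box
#' exceeds the threshold, repeating until the label group is exhausted.
#' Score ties keep the earlier input row. Box geometry and scores are
#' never modified -- only membership changes.
#'
#' @param dets data frame of one image's detections
#'   (`xmin, ymin, xmax, ymax, label, score`).
#' @param threshold IOU above which a same-label box is deleted
#'   (strict `>`); default 0.6.
#' @return the surviving rows of `dets`, in original order.
#' @export
suppress_within_class <- function(dets, threshold = 0.6) {
  if (nrow(dets) < 2) return(dets)
  keep <- integer(0)
  for (lab in unique(dets$label)) {
    idx <- which(dets$label == lab)
    ord <- idx[order(-dets$score[idx], seq_along(idx))]
    while (length(ord)) {
      top <- ord[1]
      keep <- c(keep, top)
      ord <- ord[-1]
      if (length(ord)) {
        ious <- iou_matrix(dets[top, , drop = FALSE],
                           dets[ord, , drop = FALSE])[1, ]
        ord <- ord[ious <= threshold]
      }
    }
  }
  dets[sort(keep), , drop = FALSE]
}

#' Cross-label suppression of duplicate overlapping boxes
#'
#' Detector-side NMS cannot remove duplicate boxes that carry *different*
#' predicted tooth numbers. This pass repeatedly finds the box pair with
#' the largest IOU regardless of label and, while that IOU exceeds the
#' threshold, deletes the lower-score member, rescanning after each
#' deletion. The surviving set therefore has all pairwise IOU at or below
#' the threshold, and the highest-score box of any overlap cluster always
#' survives. Ties on IOU are processed lowest pair index first; ties on
#' score delete the later input row.
#'
#' @inheritParams suppress_within_class
#' @param threshold IOU above which the lower-score member of a pair is
#'   deleted (strict `>`); default 0.7.
#' @return the surviving rows of `dets`, in original order.
#' @export
suppress_cross_label <- function(dets, threshold = 0.7) {
  n <- nrow(dets)
  if (n < 2) return(dets)
  m <- iou_matrix(dets, dets)
  m[lower.tri(m, diag = TRUE)] <- 0
  alive <- rep(TRUE, n)
  repeat {
    best <- max(m)
    if (best <= threshold) break
    hit <- which(m == best, arr.ind = TRUE)[1, ]
    i <- hit[["row"]]
    j <- hit[["col"]]
    del <- if (dets$score[i] < dets$score[j]) i
           else if (dets$score[j] < dets$score[i]) j
           else max(i, j)
    alive[del] <- FALSE
    m[del, ] <- 0
    m[, del] <- 0
  }
  dets[alive, , drop = FALSE]
}
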