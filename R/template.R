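# Stage-3/4 core: slide the (placeholder-augmented) predicted label
# sequence along the 16-slot FDI arrangement template, score each
# alignment as match score + similarity-weighted mismatch score, and
# relabel the boxes from the best alignment.

#' Order detections left to right
#'
#' Sorts one image's detections by ascending horizontal box center, with
#' ties broken by ascending `ymin` and then input row order. This is the
#' order in which the label sequence is slid along the arrangement
#' template.
#'
#' @param dets data frame of detections.
#' @return the same rows, reordered.
#' @export
order_detections <- function(dets) {
  n <- nrow(dets)
  if (n < 2) return(dets)
  cx <- (dets$xmin + dets$xmax) / 2
  dets[order(cx, dets$ymin, seq_len(n)), , drop = FALSE]
}

.check_alignment_range <- function(n_seq, offset) {
  offset <- as.integer(offset)
  if (length(offset) != 1 || is.na(offset) || offset < 0 ||
      offset + n_seq > 16) {
    stop("offset ", offset, " puts a length-", n_seq,
         " sequence outside the 16-slot template", call. = FALSE)
  }
  offset
}

#' Match score of an alignment
#'
#' Sum of the prediction scores at sequence positions whose predicted
#' label equals the template label at the aligned slot. Placeholders never
#' match.
#'
#' @param labels character sequence of predicted FDI labels, possibly
#'   containing the placeholder `"M"`.
#' @param scores prediction scores, one per label.
#' @param template a 16-slot template from [fdi_template()].
#' @param offset 0-based slot offset of the sequence start
#'   (`0 <= offset <= 16 - length(labels)`).
#' @return non-negative match score.
#' @export
match_score <- function(labels, scores, template, offset) {
  n <- length(labels)
  stopifnot(length(scores) == n, length(template) == 16)
  offset <- .check_alignment_range(n, offset)
  slots <- template[offset + seq_len(n)]
  sum(scores[labels == slots])
}

#' Mismatch score of an alignment
#'
#' Sum over mismatched positions of prediction score times the
#' category-pair similarity between the predicted label and the template
#' label at the aligned slot. Placeholders contribute 0.
#'
#' @inheritParams match_score
#' @param model a [similarity_model()].
#' @return non-negative mismatch score.
#' @export
mismatch_score <- function(labels, scores, template, offset,
                           model = similarity_model()) {
  n <- length(labels)
  stopifnot(length(scores) == n, length(template) == 16)
  offset <- .check_alignment_range(n, offset)
  slots <- template[offset + seq_len(n)]
  mis <- which(labels != slots)
  if (!length(mis)) return(0)
  sum(scores[mis] * tooth_similarity(labels[mis], slots[mis], model))
}

#' Comparison score of an alignment
#'
#' The alignment objective: match score plus mismatch score.
#'
#' @inheritParams mismatch_score
#' @return non-negative comparison score.
#' @export
comparison_score <- function(labels, scores, template, offset,
                             model = similarity_model()) {
  match_score(labels, scores, template, offset) +
    mismatch_score(labels, scores, template, offset, model)
}

#' Best alignment of a label sequence against the FDI templates
#'
#' Evaluates the comparison score of the sequence at every admissible slot
#' offset of both the upper and the lower arrangement template, in both
#' reading directions (intraoral films can be mirrored, so the reversed
#' sequence is scored too unless `enable_reversal = FALSE`), and returns
#' the maximizer. Ties are broken deterministically: upper before lower,
#' forward before reversed, smaller offset first. Scores within 1e-9 of
#' each other count as tied -- the bilateral symmetry of the FDI templates
#' makes an alignment with no exact label match score *exactly* equal to
#' its mirrored reversed counterpart, and the tolerance keeps the
#' tie-break independent of floating-point summation order.
#'
#' @inheritParams mismatch_score
#' @param enable_reversal also score the reversed sequence?
#' @return an object of class `alignment`: list with `dentition`,
#'   `offset` (0-based), `direction` (`"forward"`/`"reversed"`),
#'   `comparison_score`, `match_score`, `mismatch_score`.
#' @examples
#' aln <- best_alignment(c("17", "16", "14", "15", "13"), rep(1, 5))
#' aln$dentition  # "upper"
#' aln$offset     # 1: slots 17..13
#' @export
best_alignment <- function(labels, scores, model = similarity_model(),
                           enable_reversal = TRUE) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n < 1) stop("cannot align an empty sequence", call. = FALSE)
  if (n > 16) {
    stop("sequence of length ", n, " exceeds the 16-slot template; ",
         "filter duplicate boxes upstream before aligning", call. = FALSE)
  }
  stopifnot(length(scores) == n)
  .assert_fdi(labels, allow_placeholder = TRUE)
  directions <- if (enable_reversal) c("forward", "reversed") else "forward"
  best <- NULL
  for (dent in c("upper", "lower")) {
    template <- fdi_template(dent)
    for (dir in directions) {
      lab <- if (dir == "forward") labels else rev(labels)
      sc <- if (dir == "forward") scores else rev(scores)
      for (offset in 0:(16 - n)) {
        ms <- match_score(lab, sc, template, offset)
        mm <- mismatch_score(lab, sc, template, offset, model)
        total <- ms + mm
        if (is.null(best) || total > best$comparison_score + 1e-9) {
          best <- structure(list(dentition = dent, offset = offset,
                                 direction = dir, comparison_score = total,
                                 match_score = ms, mismatch_score = mm),
                            class = "alignment")
        }
      }
    }
  }
  best
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment: %s template, offset %d, %s, score %.3f>\n",
              x$dentition, x$offset, x$direction, x$comparison_score))
  invisible(x)
}

#' Relabel boxes from a template alignment
#'
#' Replaces each real box's label with the template label at its aligned
#' slot. Placeholder elements of the augmented sequence consume template
#' slots but emit no box. Box geometry and scores are unchanged.
#'
#' @param ordered_dets detections ordered left to right (see
#'   [order_detections()]); one row per non-placeholder element of
#'   `augmented_labels`.
#' @param augmented_labels the label sequence that was aligned, including
#'   any placeholders.
#' @param alignment result of [best_alignment()] for `augmented_labels`.
#' @return `ordered_dets` with corrected labels.
#' @export
relabel <- function(ordered_dets, augmented_labels, alignment) {
  stopifnot(inherits(alignment, "alignment"))
  augmented_labels <- as.character(augmented_labels)
  n <- length(augmented_labels)
  real <- augmented_labels != fdi_placeholder
  if (sum(real) != nrow(ordered_dets)) {
    stop("augmented sequence has ", sum(real), " real labels but ",
         nrow(ordered_dets), " boxes were supplied", call. = FALSE)
  }
  .check_alignment_range(n, alignment$offset)
  template <- fdi_template(alignment$dentition)
  slots <- if (alignment$direction == "forward") {
    alignment$offset + seq_len(n)
  } else {
    # element i sits at position n + 1 - i of the reversed sequence
    alignment$offset + (n:1)
  }
  ordered_dets$label <- template[slots[real]]
  ordered_dets
}
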