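# Core data model: boxes, detections, ground truth, per-image records,
# and JSON/CSV readers/writers.
#
# Boxes live in pixel coordinates with the origin at the image's top-left
# corner, x rightward and y downward, recorded via their top-left and
# bottom-right corners (xmin, ymin, xmax, ymax). Area uses the continuous
# convention width = xmax - xmin; zero-area boxes are invalid.

.BOX_COLS <- c("xmin", "ymin", "xmax", "ymax")

.empty_boxes <- function(role = c("detection", "ground_truth")) {
  role <- match.arg(role)
  df <- data.frame(xmin = numeric(0), ymin = numeric(0),
                   xmax = numeric(0), ymax = numeric(0),
                   label = character(0), stringsAsFactors = FALSE)
  if (role == "detection") df$score <- numeric(0)
  df
}

#' Validate a table of boxes
#'
#' Checks the geometric and label invariants of a detection or ground-truth
#' box table: finite non-negative coordinates with `xmin < xmax` and
#' `ymin < ymax`, valid FDI labels, and (for detections) scores in
#' `[0, 1]`.
#'
#' @param boxes data frame with columns `xmin`, `ymin`, `xmax`, `ymax`,
#'   `label`, and `score` for detections.
#' @param role `"detection"` or `"ground_truth"`.
#' @param where context string used in error messages.
#' @return the validated data frame, invisibly, with labels as character.
#' @export
validate_boxes <- function(boxes, role = c("detection", "ground_truth"),
                           where = "boxes") {
  role <- match.arg(role)
  need <- c(.BOX_COLS, "label", if (role == "detection") "score")
  missing_cols <- setdiff(need, names(boxes))
  if (length(missing_cols)) {
    stop(where, ": missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  boxes$label <- as.character(boxes$label)
  for (col in .BOX_COLS) {
    v <- boxes[[col]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0)) {
      stop(where, ": column ", col, " must be finite and >= 0 (row ",
           paste(which(!is.finite(boxes[[col]]) | boxes[[col]] < 0),
                 collapse = ", "), ")", call. = FALSE)
    }
  }
  bad <- boxes$xmin >= boxes$xmax | boxes$ymin >= boxes$ymax
  if (any(bad)) {
    stop(where, ": degenerate box (xmin >= xmax or ymin >= ymax) at row ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  bad_lab <- !is_fdi_label(boxes$label)
  if (any(bad_lab)) {
    stop(where, ": invalid FDI label(s) ",
         paste(unique(boxes$label[bad_lab]), collapse = ", "), " at row ",
         paste(which(bad_lab), collapse = ", "), call. = FALSE)
  }
  if (role == "detection") {
    s <- boxes$score
    if (!is.numeric(s) || any(!is.finite(s)) || any(s < 0 | s > 1)) {
      stop(where, ": scores must lie in [0, 1] (row ",
           paste(which(!is.finite(s) | s < 0 | s > 1), collapse = ", "), ")",
           call. = FALSE)
    }
  }
  invisible(boxes)
}

#' Per-image record of detections and ground truth
#'
#' Bundles one film's identifier, pixel dimensions, detected boxes (with
#' FDI label and confidence score) and expert ground-truth boxes. Either
#' box table may be empty.
#'
#' @param image_id opaque image identifier.
#' @param width,height image size in pixels.
#' @param detections data frame of detected boxes
#'   (`xmin, ymin, xmax, ymax, label, score`).
#' @param ground_truth data frame of ground-truth boxes
#'   (`xmin, ymin, xmax, ymax, label`).
#' @return an object of class `image_record`.
#' @export
image_record <- function(image_id, width, height,
                         detections = .empty_boxes("detection"),
                         ground_truth = .empty_boxes("ground_truth")) {
  stopifnot(length(image_id) == 1, length(width) == 1, length(height) == 1,
            is.finite(width), is.finite(height), width > 0, height > 0)
  if (is.null(detections) || !nrow(as.data.frame(detections))) {
    detections <- .empty_boxes("detection")
  }
  if (is.null(ground_truth) || !nrow(as.data.frame(ground_truth))) {
    ground_truth <- .empty_boxes("ground_truth")
  }
  detections <- as.data.frame(detections)[,
    c(.BOX_COLS, "label", "score"), drop = FALSE]
  ground_truth <- as.data.frame(ground_truth)[,
    c(.BOX_COLS, "label"), drop = FALSE]
  validate_boxes(detections, "detection",
                 where = paste0("image ", image_id, " detections"))
  validate_boxes(ground_truth, "ground_truth",
                 where = paste0("image ", image_id, " ground truth"))
  for (df_name in c("detections", "ground_truth")) {
    df <- get(df_name)
    if (nrow(df) && any(df$xmax > width | df$ymax > height)) {
      stop("image ", image_id, ": ", df_name,
           " extend beyond the image bounds", call. = FALSE)
    }
  }
  rownames(detections) <- NULL
  rownames(ground_truth) <- NULL
  structure(list(image_id = as.character(image_id),
                 width = as.numeric(width), height = as.numeric(height),
                 detections = detections, ground_truth = ground_truth),
            class = "image_record")
}

#' @export
print.image_record <- function(x, ...) {
  cat(sprintf("<image_record %s %gx%g px: %d detections, %d ground truth>\n",
              x$image_id, x$width, x$height,
              nrow(x$detections), nrow(x$ground_truth)))
  invisible(x)
}

# Coordinates are stored as integers (pixel distances); fractional
# coordinates produced by the synthetic generator are rounded half-up at
# write time. Scores keep full precision.
.round_half_up <- function(x) floor(x + 0.5)

.records_to_long <- function(records) {
  rows <- lapply(records, function(r) {
    det <- r$detections
    gt <- r$ground_truth
    both <- rbind(
      if (nrow(det)) data.frame(role = "detection", det,
                                stringsAsFactors = FALSE),
      if (nrow(gt)) data.frame(role = "ground_truth", gt, score = NA_real_,
                               stringsAsFactors = FALSE)
    )
    if (is.null(both)) {
      both <- data.frame(role = character(0), .empty_boxes("detection"))
    }
    data.frame(image_id = rep(r$image_id, nrow(both)),
               width = rep(.round_half_up(r$width), nrow(both)),
               height = rep(.round_half_up(r$height), nrow(both)),
               both, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(image_id = character(0), width = numeric(0),
                      height = numeric(0), role = character(0),
                      .empty_boxes("detection"))
  }
  for (col in .BOX_COLS) out[[col]] <- .round_half_up(out[[col]])
  rownames(out) <- NULL
  out
}

#' Read and write detection datasets
#'
#' A dataset is a list of [image_record()] objects. Two plain-text formats
#' are supported: a single JSON document
#' (`{"images": [{image_id, width, height, detections: [...],
#' ground_truth: [...]}]}`) and a long CSV with one box per row and a
#' `role` column (`detection` / `ground_truth`; `score` empty for ground
#' truth). Coordinates are written as integer pixels (rounded half-up);
#' scores keep full precision, so `read_records(write_records(x))`
#' round-trips integer-coordinate records exactly.
#'
#' @param path file path.
#' @param format `"json"` or `"csv"`; inferred from the file extension
#'   when `NULL`.
#' @param records list of [image_record()] objects.
#' @return `read_records()` returns a named list of `image_record`s;
#'   `write_records()` returns `path` invisibly.
#' @export
read_records <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- format %||% tolower(tools::file_ext(path))
  format <- match.arg(format, c("json", "csv"))
  if (format == "json") {
    doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (is.null(doc$images)) {
      stop("JSON dataset must have a top-level 'images' array: ", path,
           call. = FALSE)
    }
    imgs <- doc$images
    n <- if (is.data.frame(imgs)) nrow(imgs) else length(imgs)
    records <- vector("list", n)
    for (i in seq_len(n)) {
      img <- if (is.data.frame(imgs)) lapply(imgs, `[[`, i) else imgs[[i]]
      records[[i]] <- image_record(
        image_id = img$image_id, width = img$width, height = img$height,
        detections = img$detections, ground_truth = img$ground_truth
      )
    }
  } else {
    long <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c(image_id = "character",
                                           label = "character"))
    need <- c("image_id", "width", "height", "role", .BOX_COLS, "label",
              "score")
    missing_cols <- setdiff(need, names(long))
    if (length(missing_cols)) {
      stop("CSV dataset missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    records <- lapply(split(long, factor(long$image_id,
                                         levels = unique(long$image_id))),
                      function(g) {
      det <- g[g$role == "detection", c(.BOX_COLS, "label", "score")]
      gt <- g[g$role == "ground_truth", c(.BOX_COLS, "label")]
      image_record(g$image_id[1], g$width[1], g$height[1], det, gt)
    })
    records <- unname(records)
  }
  stats::setNames(records, vapply(records, `[[`, "", "image_id"))
}

#' @rdname read_records
#' @export
write_records <- function(records, path, format = NULL) {
  if (inherits(records, "image_record")) records <- list(records)
  lapply(records, function(r) {
    if (!inherits(r, "image_record")) {
      stop("write_records() expects image_record objects", call. = FALSE)
    }
  })
  format <- format %||% tolower(tools::file_ext(path))
  format <- match.arg(format, c("json", "csv"))
  if (format == "json") {
    images <- lapply(records, function(r) {
      det <- r$detections
      gt <- r$ground_truth
      for (col in .BOX_COLS) {
        det[[col]] <- as.integer(.round_half_up(det[[col]]))
        gt[[col]] <- as.integer(.round_half_up(gt[[col]]))
      }
      list(image_id = r$image_id,
           width = as.integer(.round_half_up(r$width)),
           height = as.integer(.round_half_up(r$height)),
           detections = det, ground_truth = gt)
    })
    jsonlite::write_json(list(images = images), path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  } else {
    utils::write.csv(.records_to_long(records), path, row.names = FALSE,
                     na = "")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
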