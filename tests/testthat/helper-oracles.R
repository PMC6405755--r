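# Independent reference implementations used as oracles. These are coded
# from the domain definitions directly (plain loops, their own frozen
# category/similarity tables) and share no code with the package
# internals they check.

ORACLE_CATEGORY <- c(
  "18" = "W", "17" = "M", "16" = "M", "15" = "P", "14" = "P", "13" = "Ca",
  "12" = "La", "11" = "Ce", "21" = "Ce", "22" = "La", "23" = "Ca",
  "24" = "P", "25" = "P", "26" = "M", "27" = "M", "28" = "W",
  "48" = "W", "47" = "M", "46" = "M", "45" = "P", "44" = "P", "43" = "Ca",
  "42" = "I", "41" = "I", "31" = "I", "32" = "I", "33" = "Ca",
  "34" = "P", "35" = "P", "36" = "M", "37" = "M", "38" = "W"
)

ORACLE_TEMPLATES <- list(
  upper = c("18", "17", "16", "15", "14", "13", "12", "11",
            "21", "22", "23", "24", "25", "26", "27", "28"),
  lower = c("48", "47", "46", "45", "44", "43", "42", "41",
            "31", "32", "33", "34", "35", "36", "37", "38")
)

ORACLE_SIM <- list(
  upper = matrix(
    c(0.9, 0.8, 0.0, 0.0, 0.0, 0.0,
      0.8, 0.9, 0.0, 0.0, 0.0, 0.0,
      0.0, 0.0, 0.9, 0.6, 0.4, 0.4,
      0.0, 0.0, 0.6, 0.9, 0.6, 0.8,
      0.0, 0.0, 0.4, 0.6, 0.9, 0.8,
      0.0, 0.0, 0.4, 0.8, 0.8, 0.9),
    6, 6, byrow = TRUE,
    dimnames = list(c("W", "M", "P", "Ca", "La", "Ce"),
                    c("W", "M", "P", "Ca", "La", "Ce"))),
  lower = matrix(
    c(0.9, 0.7, 0.0, 0.0, 0.0,
      0.7, 0.9, 0.0, 0.0, 0.0,
      0.0, 0.0, 0.9, 0.5, 0.3,
      0.0, 0.0, 0.5, 0.9, 0.5,
      0.0, 0.0, 0.3, 0.5, 0.9),
    5, 5, byrow = TRUE,
    dimnames = list(c("W", "M", "P", "Ca", "I"),
                    c("W", "M", "P", "Ca", "I")))
)

# IOU by counting unit pixel cells [x, x+1) x [y, y+1); integer boxes only.
oracle_iou_grid <- function(a, b) {
  a <- as.list(a)
  b <- as.list(b)
  cells <- function(box) {
    if (box$xmin >= box$xmax || box$ymin >= box$ymax) return(character(0))
    g <- expand.grid(x = box$xmin:(box$xmax - 1), y = box$ymin:(box$ymax - 1))
    paste(g$x, g$y)
  }
  ca <- cells(a)
  cb <- cells(b)
  length(intersect(ca, cb)) / length(union(ca, cb))
}

# Scalar arithmetic IOU written as interval overlaps, used inside the
# matching/suppression oracles.
oracle_iou <- function(a, b) {
  ox <- min(a$xmax, b$xmax) - max(a$xmin, b$xmin)
  oy <- min(a$ymax, b$ymax) - max(a$ymin, b$ymin)
  if (ox <= 0 || oy <= 0) return(0)
  inter <- ox * oy
  inter / ((a$xmax - a$xmin) * (a$ymax - a$ymin) +
             (b$xmax - b$xmin) * (b$ymax - b$ymin) - inter)
}

# Greedy per-label NMS, loop formulation.
oracle_nms_within <- function(dets, threshold = 0.6) {
  kept <- logical(nrow(dets))
  for (lab in unique(dets$label)) {
    pool <- which(dets$label == lab)
    while (length(pool)) {
      scores <- dets$score[pool]
      top <- pool[which(scores == max(scores))[1]]
      kept[top] <- TRUE
      pool <- setdiff(pool, top)
      drop <- c()
      for (p in pool) {
        if (oracle_iou(dets[top, ], dets[p, ]) > threshold) drop <- c(drop, p)
      }
      pool <- setdiff(pool, drop)
    }
  }
  dets[kept, , drop = FALSE]
}

# Cross-label suppression: repeatedly delete the lower-score member of the
# currently highest-IOU pair above threshold.
oracle_cross <- function(dets, threshold = 0.7) {
  alive <- seq_len(nrow(dets))
  repeat {
    best <- -1
    pair <- NULL
    for (ii in seq_along(alive)) {
      for (jj in seq_len(ii - 1L)) {
        i <- alive[jj]
        j <- alive[ii]
        v <- oracle_iou(dets[i, ], dets[j, ])
        if (v > best + 1e-12) {
          best <- v
          pair <- c(i, j)
        }
      }
    }
    if (is.null(pair) || best <= threshold) break
    i <- pair[1]
    j <- pair[2]
    del <- if (dets$score[i] < dets$score[j]) i
           else if (dets$score[j] < dets$score[i]) j else max(i, j)
    alive <- setdiff(alive, del)
  }
  dets[sort(alive), , drop = FALSE]
}

# Greedy global-max IOU matching of detections to ground truth.
oracle_greedy_match <- function(dets, gts, threshold = 0.7) {
  pairs <- data.frame(det = integer(0), gt = integer(0), iou = numeric(0))
  free_d <- seq_len(nrow(dets))
  free_g <- seq_len(nrow(gts))
  repeat {
    best <- -1
    hit <- NULL
    for (d in free_d) {
      for (g in free_g) {
        v <- oracle_iou(dets[d, ], gts[g, ])
        if (v > best + 1e-12) {
          best <- v
          hit <- c(d, g)
        }
      }
    }
    if (is.null(hit) || best <= threshold) break
    pairs <- rbind(pairs, data.frame(det = hit[1], gt = hit[2], iou = best))
    free_d <- setdiff(free_d, hit[1])
    free_g <- setdiff(free_g, hit[2])
  }
  pairs
}

oracle_similarity <- function(pred, templ, dent) {
  if (pred == "M") return(0)
  pc <- ORACLE_CATEGORY[[pred]]
  if (dent == "lower" && pc %in% c("La", "Ce")) pc <- "I"
  if (dent == "upper" && pc == "I") pc <- "La"
  ORACLE_SIM[[dent]][pc, ORACLE_CATEGORY[[templ]]]
}

# Exhaustive maximization over dentition x direction x offset, elementwise
# scoring in sequence order.
oracle_best_alignment <- function(labels, scores) {
  n <- length(labels)
  best <- NULL
  for (dent in c("upper", "lower")) {
    tmpl <- ORACLE_TEMPLATES[[dent]]
    for (dir in c("forward", "reversed")) {
      lab <- if (dir == "forward") labels else rev(labels)
      sc <- if (dir == "forward") scores else rev(scores)
      for (offset in 0:(16 - n)) {
        total <- 0
        for (i in seq_len(n)) {
          slot <- tmpl[offset + i]
          total <- total +
            if (lab[i] == slot) sc[i]
            else sc[i] * oracle_similarity(lab[i], slot, dent)
        }
        if (is.null(best) || total > best$score + 1e-9) {
          best <- list(dentition = dent, direction = dir, offset = offset,
                       score = total)
        }
      }
    }
  }
  best
}

# Random test-case generators ------------------------------------------

random_boxes <- function(n, max_coord = 120, with_scores = TRUE) {
  xmin <- sample(0:(max_coord - 20), n, replace = TRUE)
  ymin <- sample(0:(max_coord - 20), n, replace = TRUE)
  df <- data.frame(
    xmin = xmin, ymin = ymin,
    xmax = xmin + sample(8:40, n, replace = TRUE),
    ymax = ymin + sample(8:40, n, replace = TRUE),
    label = sample(toothnum::fdi_labels(), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  if (with_scores) df$score <- round(runif(n), 6)
  df
}

# Overlap-rich clusters exercise the suppression logic harder than
# uniformly scattered boxes.
random_cluster <- function(n, centers = 2) {
  base <- random_boxes(centers)
  rows <- lapply(seq_len(n), function(i) {
    b <- base[sample.int(centers, 1), ]
    shift <- sample(-6:6, 2, replace = TRUE)
    b$xmin <- max(0, b$xmin + shift[1])
    b$xmax <- b$xmax + shift[1]
    b$ymin <- max(0, b$ymin + shift[2])
    b$ymax <- b$ymax + shift[2]
    b$label <- sample(toothnum::fdi_labels(), 1)
    b$score <- round(runif(1), 6)
    b
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

random_label_sequence <- function(max_len = 16, placeholder_prob = 0.15) {
  n <- sample.int(max_len, 1)
  labels <- ifelse(runif(n) < placeholder_prob, "M",
                   sample(toothnum::fdi_labels(), n, replace = TRUE))
  list(labels = labels, scores = runif(n, 0.05, 1))
}
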