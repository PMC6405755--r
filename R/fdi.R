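# FDI (ISO-3950) tooth numbering: labels, arrangement templates,
# tooth categories, and category-pair mismatch similarities.

# Category of every permanent tooth. Upper dentition distinguishes lateral
# (La) from central (Ce) incisors; the lower dentition pools all four
# incisors into a single incisor category (I).
.FDI_CATEGORY <- c(
  "18" = "W", "17" = "M", "16" = "M", "15" = "P", "14" = "P", "13" = "Ca",
  "12" = "La", "11" = "Ce", "21" = "Ce", "22" = "La", "23" = "Ca",
  "24" = "P", "25" = "P", "26" = "M", "27" = "M", "28" = "W",
  "48" = "W", "47" = "M", "46" = "M", "45" = "P", "44" = "P", "43" = "Ca",
  "42" = "I", "41" = "I", "31" = "I", "32" = "I", "33" = "Ca",
  "34" = "P", "35" = "P", "36" = "M", "37" = "M", "38" = "W"
)

.FDI_TEMPLATE <- list(
  upper = c("18", "17", "16", "15", "14", "13", "12", "11",
            "21", "22", "23", "24", "25", "26", "27", "28"),
  lower = c("48", "47", "46", "45", "44", "43", "42", "41",
            "31", "32", "33", "34", "35", "36", "37", "38")
)

.UPPER_CATS <- c("W", "M", "P", "Ca", "La", "Ce")
.LOWER_CATS <- c("W", "M", "P", "Ca", "I")

.UPPER_SIM <- matrix(
  c(0.9, 0.8, 0.0, 0.0, 0.0, 0.0,
    0.8, 0.9, 0.0, 0.0, 0.0, 0.0,
    0.0, 0.0, 0.9, 0.6, 0.4, 0.4,
    0.0, 0.0, 0.6, 0.9, 0.6, 0.8,
    0.0, 0.0, 0.4, 0.6, 0.9, 0.8,
    0.0, 0.0, 0.4, 0.8, 0.8, 0.9),
  nrow = 6, byrow = TRUE, dimnames = list(.UPPER_CATS, .UPPER_CATS)
)

.LOWER_SIM <- matrix(
  c(0.9, 0.7, 0.0, 0.0, 0.0,
    0.7, 0.9, 0.0, 0.0, 0.0,
    0.0, 0.0, 0.9, 0.5, 0.3,
    0.0, 0.0, 0.5, 0.9, 0.5,
    0.0, 0.0, 0.3, 0.5, 0.9),
  nrow = 5, byrow = TRUE, dimnames = list(.LOWER_CATS, .LOWER_CATS)
)

#' Placeholder label for a predicted missing tooth
#'
#' A virtual sequence element standing in for a missing tooth. It occupies a
#' template slot during alignment, contributes zero to the comparison score,
#' and yields no output box when relabeling.
#'
#' @export
fdi_placeholder <- "M"

#' All valid FDI tooth labels
#'
#' @return Character vector of the 32 permanent-tooth FDI codes
#'   (`"11"`--`"18"`, `"21"`--`"28"`, `"31"`--`"38"`, `"41"`--`"48"`),
#'   sorted in increasing numeric order.
#' @export
fdi_labels <- function() {
  sort(names(.FDI_CATEGORY))
}

#' Test whether labels are valid FDI codes
#'
#' @param label character (or coercible) vector of candidate labels.
#' @param allow_placeholder also accept the missing-tooth placeholder
#'   [fdi_placeholder] (`"M"`)?
#' @return logical vector.
#' @export
is_fdi_label <- function(label, allow_placeholder = FALSE) {
  label <- as.character(label)
  ok <- label %in% names(.FDI_CATEGORY)
  if (allow_placeholder) ok <- ok | label == fdi_placeholder
  ok
}

.assert_fdi <- function(label, allow_placeholder = FALSE) {
  bad <- !is_fdi_label(label, allow_placeholder = allow_placeholder)
  if (any(bad)) {
    stop("invalid FDI tooth label(s): ",
         paste(unique(as.character(label)[bad]), collapse = ", "),
         call. = FALSE)
  }
  invisible(as.character(label))
}

#' Dentition (arch) of an FDI label
#'
#' Quadrants 1 and 2 form the upper (maxillary) dentition, quadrants 3 and 4
#' the lower (mandibular) dentition.
#'
#' @param label vector of FDI codes.
#' @return character vector, `"upper"` or `"lower"`.
#' @export
fdi_dentition <- function(label) {
  label <- .assert_fdi(label)
  ifelse(substr(label, 1, 1) %in% c("1", "2"), "upper", "lower")
}

#' Tooth category of an FDI label
#'
#' Maps each tooth to its morphological category: `W` wisdom, `M` molar,
#' `P` premolar, `Ca` canine, and for the upper dentition `La` lateral /
#' `Ce` central incisor, for the lower dentition the pooled incisor
#' category `I`.
#'
#' @param label vector of FDI codes.
#' @return character vector of category codes.
#' @examples
#' tooth_category(c("18", "11", "42"))  # "W" "Ce" "I"
#' @export
tooth_category <- function(label) {
  label <- .assert_fdi(label)
  unname(.FDI_CATEGORY[label])
}

#' FDI arrangement template
#'
#' The fixed 16-slot left-to-right arrangement of one dentition:
#' `18,17,...,11,21,...,28` for the upper arch and `48,...,41,31,...,38`
#' for the lower arch. Detected label sequences are slid along this
#' template when correcting tooth numbers.
#'
#' @param dentition `"upper"` or `"lower"`.
#' @return character vector of 16 FDI labels in arch order.
#' @export
fdi_template <- function(dentition = c("upper", "lower")) {
  dentition <- match.arg(dentition)
  .FDI_TEMPLATE[[dentition]]
}

#' Category-pair similarity model for mismatched tooth numbers
#'
#' Per-dentition symmetric matrices giving the similarity weight applied to
#' a detection whose predicted label disagrees with the template label at
#' its aligned slot. Diagonal entries are 0.9 (same-category confusion is
#' cheap); wisdom/molar rows are 0 against premolar and anterior categories
#' (such confusions are implausible and receive no credit).
#'
#' @param upper,lower optional replacement matrices (square, symmetric,
#'   values in `[0, 1]`, category dimnames). Defaults are the built-in
#'   expert matrices.
#' @return An object of class `similarity_model`: a list with elements
#'   `upper` and `lower`.
#' @seealso [tooth_similarity()], [read_similarity_config()]
#' @export
similarity_model <- function(upper = .UPPER_SIM, lower = .LOWER_SIM) {
  model <- structure(list(upper = upper, lower = lower),
                     class = "similarity_model")
  validate_similarity_model(model)
}

#' @rdname similarity_model
#' @param model an object to validate.
#' @export
validate_similarity_model <- function(model) {
  stopifnot(is.list(model), all(c("upper", "lower") %in% names(model)))
  for (dent in c("upper", "lower")) {
    m <- model[[dent]]
    if (!is.matrix(m) || nrow(m) != ncol(m)) {
      stop(dent, " similarity must be a square matrix", call. = FALSE)
    }
    if (is.null(rownames(m)) || !identical(rownames(m), colnames(m))) {
      stop(dent, " similarity must have matching category dimnames",
           call. = FALSE)
    }
    if (any(m < 0) || any(m > 1)) {
      stop(dent, " similarity values must lie in [0, 1]", call. = FALSE)
    }
    if (!isTRUE(all.equal(m, t(m)))) {
      stop(dent, " similarity matrix must be symmetric", call. = FALSE)
    }
  }
  invisible(model)
}

# Translate a category into the target dentition's category set. Needed
# when a noisy detection carries a label from the opposite arch: the upper
# incisor categories La and Ce pool into the lower incisor category I, and
# I widens to La when looked up against an upper template.
.translate_category <- function(category, to_dentition) {
  if (to_dentition == "lower") {
    ifelse(category %in% c("La", "Ce"), "I", category)
  } else {
    ifelse(category == "I", "La", category)
  }
}

#' Similarity between a predicted and a template tooth label
#'
#' Looks up the category-pair similarity used to weight a mismatched
#' prediction score. The placeholder `"M"` always has similarity 0. When
#' the predicted label belongs to the opposite dentition, its category is
#' first translated into the template dentition's category set (La/Ce to I
#' for lower templates, I to La for upper templates) so that the lookup is
#' total.
#'
#' @param pred vector of predicted FDI labels, possibly `"M"`.
#' @param templ vector of template FDI labels (recycled against `pred`).
#' @param model a [similarity_model()].
#' @return numeric vector of similarities in `[0, 1]`.
#' @examples
#' tooth_similarity("13", "11")  # upper canine vs central incisor: 0.8
#' tooth_similarity("17", "16")  # molar diagonal: 0.9
#' tooth_similarity("M", "13")   # placeholder: 0
#' @export
tooth_similarity <- function(pred, templ, model = similarity_model()) {
  n <- max(length(pred), length(templ))
  pred <- rep_len(as.character(pred), n)
  templ <- rep_len(as.character(templ), n)
  .assert_fdi(pred, allow_placeholder = TRUE)
  .assert_fdi(templ)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (pred[i] == fdi_placeholder) {
      out[i] <- 0
      next
    }
    dent <- fdi_dentition(templ[i])
    pc <- .translate_category(tooth_category(pred[i]), dent)
    tc <- tooth_category(templ[i])
    out[i] <- model[[dent]][pc, tc]
  }
  out
}

#' Read and write the arrangement/similarity configuration
#'
#' Serializes the arrangement templates, the tooth-category map and the
#' similarity matrices to a human-readable YAML file, so users can
#' substitute an alternative similarity matrix without touching code.
#'
#' @param model a [similarity_model()].
#' @param path file path of the YAML configuration.
#' @return `write_similarity_config()` returns `path` invisibly;
#'   `read_similarity_config()` returns a validated [similarity_model()].
#' @export
write_similarity_config <- function(model, path) {
  validate_similarity_model(model)
  as_named_rows <- function(m) {
    lapply(stats::setNames(rownames(m), rownames(m)), function(r) {
      as.list(stats::setNames(m[r, ], colnames(m)))
    })
  }
  cfg <- list(
    templates = .FDI_TEMPLATE,
    categories = as.list(.FDI_CATEGORY),
    similarity = list(upper = as_named_rows(model$upper),
                      lower = as_named_rows(model$lower))
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_similarity_config
#' @export
read_similarity_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$similarity)) {
    stop("configuration has no 'similarity' section: ", path, call. = FALSE)
  }
  from_named_rows <- function(rows) {
    cats <- names(rows)
    m <- matrix(NA_real_, length(cats), length(cats),
                dimnames = list(cats, cats))
    for (r in cats) m[r, ] <- unlist(rows[[r]])[cats]
    m
  }
  similarity_model(upper = from_named_rows(cfg$similarity$upper),
                   lower = from_named_rows(cfg$similarity$lower))
}
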