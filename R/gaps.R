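# Stage-4 missing-teeth prediction: per-adjacent-pair gap geometry, a small
# feed-forward classifier for the number of missing teeth (0-3) in each
# gap, and placeholder insertion into the label sequence.

#' Geometric gap features between adjacent detected boxes
#'
#' For each adjacent pair of an image's detections (ordered left to right
#' by horizontal box center) computes the two features used to predict
#' missing teeth: the horizontal margin distance (`xmin` of the right box
#' minus `xmax` of the left box; negative when boxes overlap, e.g. for
#' inclined neighbors leaning into a gap) and the horizontal distance
#' between box centers. Both are also returned normalized by the image's
#' mean detected-box width, which makes the features comparable across
#' films of different scale; the raw pixel values are retained alongside.
#'
#' @param dets data frame of one image's detections; ordered internally
#'   with [order_detections()].
#' @return data frame with one row per adjacent pair (`n - 1` rows for `n`
#'   boxes; zero rows when fewer than 2 boxes) and columns `left_label`,
#'   `right_label`, `margin`, `center_distance`, `normalizer`,
#'   `margin_norm`, `center_norm`.
#' @examples
#' d <- data.frame(xmin = c(0, 150), ymin = 0, xmax = c(100, 250),
#'                 ymax = 200, label = c("16", "13"), score = 1)
#' extract_gap_features(d)[, c("margin", "center_distance")]  # 50, 150
#' @export
extract_gap_features <- function(dets) {
  empty <- data.frame(left_label = character(0), right_label = character(0),
                      margin = numeric(0), center_distance = numeric(0),
                      normalizer = numeric(0), margin_norm = numeric(0),
                      center_norm = numeric(0), stringsAsFactors = FALSE)
  n <- nrow(dets)
  if (is.null(n) || n < 2) return(empty)
  dets <- order_detections(dets)
  cx <- (dets$xmin + dets$xmax) / 2
  widths <- dets$xmax - dets$xmin
  normalizer <- mean(widths)
  left <- seq_len(n - 1)
  right <- left + 1
  margin <- dets$xmin[right] - dets$xmax[left]
  center <- cx[right] - cx[left]
  data.frame(
    left_label = dets$label[left], right_label = dets$label[right],
    margin = margin, center_distance = center, normalizer = normalizer,
    margin_norm = margin / normalizer, center_norm = center / normalizer,
    stringsAsFactors = FALSE
  )
}

.gap_feature_matrix <- function(features) {
  if (is.matrix(features)) {
    stopifnot(ncol(features) == 2)
    return(features)
  }
  need <- c("margin_norm", "center_norm")
  if (!all(need %in% names(features))) {
    stop("gap features need columns margin_norm and center_norm ",
         "(see extract_gap_features())", call. = FALSE)
  }
  as.matrix(features[, need])
}

#' Train the missing-teeth gap classifier
#'
#' Fits a small feed-forward network -- two fully connected hidden layers
#' of 10 rectified-linear units each, softmax output over the four classes
#' 0--3 -- that maps the two normalized gap features to the number of
#' missing teeth in the gap. Training minimizes cross-entropy with Adam on
#' shuffled mini-batches for a fixed number of epochs and is fully
#' reproducible given `seed`.
#'
#' @param features gap-feature data frame from [extract_gap_features()] /
#'   [generate_gap_training_set()] (or an `n x 2` matrix of normalized
#'   margin and center distances).
#' @param labels integer missing-tooth counts in `{0, 1, 2, 3}`, one per
#'   feature row.
#' @param hidden sizes of the hidden layers.
#' @param epochs number of training epochs.
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size.
#' @param seed integer RNG seed for weight initialisation and batch
#'   shuffling; `NULL` uses the current RNG state.
#' @return an object of class `gap_classifier`.
#' @export
train_gap_classifier <- function(features, labels, hidden = c(10, 10),
                                 epochs = 100, learning_rate = 0.01,
                                 batch_size = 32, seed = NULL) {
  x <- .gap_feature_matrix(features)
  labels <- as.integer(labels)
  stopifnot(nrow(x) == length(labels), nrow(x) >= 1)
  if (any(labels < 0 | labels > 3)) {
    stop("gap labels must be missing-tooth counts in 0..3", call. = FALSE)
  }
  if (length(unique(labels)) == 1) {
    warning("all training gaps have the same missing-tooth count (",
            labels[1], "); the classifier will predict that class everywhere",
            call. = FALSE)
  }
  sds <- apply(x, 2, stats::sd)
  if (any(!is.finite(sds)) || any(sds == 0)) {
    warning("zero-variance gap feature(s): ",
            paste(colnames(x)[sds == 0 | !is.finite(sds)], collapse = ", "),
            call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  fit <- .mlp_train(x, labels + 1L, sizes = c(2L, hidden, 4L),
                    epochs = epochs, learning_rate = learning_rate,
                    batch_size = batch_size)
  structure(list(layers = fit$layers, hidden = hidden, classes = 0:3,
                 epochs = epochs, learning_rate = learning_rate,
                 batch_size = batch_size, seed = seed,
                 n_train = nrow(x), final_loss = utils::tail(fit$loss_trace, 1)),
            class = "gap_classifier")
}

#' @export
print.gap_classifier <- function(x, ...) {
  cat(sprintf(paste0("<gap_classifier: 2 -> %s -> 4 classes (0-3 missing),",
                     " %d epochs, n = %d>\n"),
              paste(x$hidden, collapse = " -> "), x$epochs, x$n_train))
  invisible(x)
}

#' Predict from a gap classifier
#'
#' @param object a [train_gap_classifier()] fit.
#' @param newdata gap features (data frame or `n x 2` matrix).
#' @param type `"class"` for hard missing-tooth counts, `"prob"` for the
#'   full class distribution.
#' @param ... unused.
#' @return integer vector of counts, or an `n x 4` probability matrix with
#'   columns `"0"`..`"3"`.
#' @export
predict.gap_classifier <- function(object, newdata,
                                   type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- .gap_feature_matrix(newdata)
  if (nrow(x) == 0) {
    if (type == "class") return(integer(0))
    return(matrix(numeric(0), 0, 4, dimnames = list(NULL, 0:3)))
  }
  probs <- .mlp_forward(object$layers, x)$probs
  colnames(probs) <- as.character(object$classes)
  if (type == "prob") return(probs)
  # argmax; ties resolved toward the smaller count
  as.integer(object$classes[apply(probs, 1, which.max)])
}

#' Predict missing-tooth counts for a sequence of gaps
#'
#' @param model a trained [train_gap_classifier()] object.
#' @param features output of [extract_gap_features()].
#' @return integer vector of per-gap missing-tooth counts (0--3), length
#'   `nrow(features)`.
#' @export
predict_missing <- function(model, features) {
  if (!inherits(model, "gap_classifier")) {
    stop("model must be a trained gap_classifier", call. = FALSE)
  }
  predict(model, features, type = "class")
}

#' Insert missing-tooth placeholders into a label sequence
#'
#' Places `gap_counts[i]` placeholder `"M"` elements between `labels[i]`
#' and `labels[i + 1]`, e.g. labels `17,16,13` with counts `0,2` become
#' `17,16,M,M,13`. The relative order of the real labels is preserved and
#' the output length is `length(labels) + sum(gap_counts)`. Counts above 3
#' are clamped to 3 (the supported label range) with a warning.
#'
#' @param labels character vector of FDI labels, ordered left to right.
#' @param gap_counts integer vector of per-gap missing counts, length
#'   `length(labels) - 1`.
#' @return augmented character label sequence.
#' @export
insert_placeholders <- function(labels, gap_counts) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n == 0) return(character(0))
  gap_counts <- as.integer(gap_counts)
  if (length(gap_counts) != n - 1) {
    stop("gap_counts must have length(labels) - 1 = ", n - 1,
         " elements, got ", length(gap_counts), call. = FALSE)
  }
  if (any(gap_counts < 0)) {
    stop("gap_counts must be non-negative", call. = FALSE)
  }
  if (any(gap_counts > 3)) {
    warning("gap counts above 3 clamped to 3", call. = FALSE)
    gap_counts <- pmin(gap_counts, 3L)
  }
  out <- labels[1]
  for (i in seq_along(gap_counts)) {
    out <- c(out, rep(fdi_placeholder, gap_counts[i]), labels[i + 1])
  }
  out
}

#' Persist and restore a gap classifier
#'
#' Writes the full model -- architecture, weights, class set, training
#' metadata and seed -- to a versioned JSON file at full numeric precision.
#'
#' @param model a [train_gap_classifier()] object.
#' @param path JSON file path.
#' @return `write_gap_model()` returns `path` invisibly;
#'   `read_gap_model()` returns the restored `gap_classifier`.
#' @export
write_gap_model <- function(model, path) {
  stopifnot(inherits(model, "gap_classifier"))
  payload <- list(
    format = "toothnum-gap-model", version = 1L,
    hidden = model$hidden, classes = model$classes,
    epochs = model$epochs, learning_rate = model$learning_rate,
    batch_size = model$batch_size, seed = model$seed,
    n_train = model$n_train, final_loss = model$final_loss,
    feature_normalization = "distances divided by mean detected-box width",
    layers = lapply(model$layers, function(l) {
      list(W = l$W, b = l$b)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gap_model
#' @export
read_gap_model <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (!identical(payload$format, "toothnum-gap-model")) {
    stop("not a toothnum gap-model file: ", path, call. = FALSE)
  }
  layers <- lapply(seq_len(nrow_or_length(payload$layers)), function(i) {
    l <- extract_layer(payload$layers, i)
    list(W = as.matrix(l$W), b = as.numeric(l$b))
  })
  structure(list(layers = layers, hidden = as.integer(payload$hidden),
                 classes = as.integer(payload$classes),
                 epochs = payload$epochs,
                 learning_rate = payload$learning_rate,
                 batch_size = payload$batch_size,
                 seed = payload$seed, n_train = payload$n_train,
                 final_loss = payload$final_loss),
            class = "gap_classifier")
}

# jsonlite may simplify the layer list into a data frame; handle both.
nrow_or_length <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
extract_layer <- function(layers, i) {
  if (is.data.frame(layers)) list(W = layers$W[[i]], b = layers$b[[i]])
  else layers[[i]]
}
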