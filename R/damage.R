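#' Train the binary forest-damage classifier
#'
#' Fits the seeded bagged-tree ensemble on per-pixel delta-composite
#' features at labelled sample locations, and evaluates it on a disjoint
#' validation split. Labels mark forest pixels as damaged (1) or
#' undisturbed (0) over the before/during epoch pair.
#'
#' @param deltas single-epoch `index_stack` of composite differences.
#' @param samples `data.frame` with columns `row`, `col`, `label` (0/1) and
#'   `split` (`"train"` or `"validation"`).
#' @param ntree trees in the ensemble (default 500).
#' @param seed integer seed controlling ensemble growth.
#' @return List of class `damage_classifier`: the fitted `model`, the
#'   `report` (confusion matrix, overall/user's/producer's accuracy on the
#'   validation split), feature names and provenance fields.
#' @export
train_damage_classifier <- function(deltas, samples, ntree = 500,
                                    seed = NULL) {
  stopifnot(all(c("row", "col", "label", "split") %in% names(samples)))
  x <- sample_features(deltas, samples$row, samples$col)
  lab <- factor(samples$label, levels = c(0, 1),
                labels = c("undamaged", "damaged"))
  tr <- samples$split == "train"
  if (length(unique(lab[tr])) < 2L)
    stop("training split contains a single class", call. = FALSE)
  model <- fs_forest_fit(x[tr, , drop = FALSE], lab[tr], ntree = ntree,
                         seed = seed)
  va <- samples$split == "validation"
  report <- if (any(va)) {
    accuracy_report(predict(model, x[va, , drop = FALSE]), lab[va])
  } else NULL
  structure(list(model = model, report = report,
                 features = colnames(x), threshold = 0.5,
                 classifier_id = sprintf("bagged-cart-%d", ntree)),
            class = "damage_classifier")
}

# Per-pixel feature matrix from a single-epoch stack at (row, col) samples.
sample_features <- function(stack, rows, cols) {
  d <- dim(stack$layers[[1]])
  idx <- cbind(rows, cols, 1L)
  x <- vapply(stack$layers, function(a) a[idx], numeric(length(rows)))
  x <- matrix(x, nrow = length(rows),
              dimnames = list(NULL, names(stack$layers)))
  x
}

#' Predict the 2022 damage mask
#'
#' Scores every pixel of the delta stack, keeps positives whose damage vote
#' share exceeds the classifier threshold, intersects with the pre-war
#' forest mask (damage is only defined over forest), and removes
#' single-pixel components as classification noise.
#'
#' @param classifier a fitted `damage_classifier`.
#' @param deltas single-epoch `index_stack`.
#' @param forest_mask binary `fs_grid`; 1 = pre-war forest.
#' @param connectivity connectivity for the noise filter (default 8).
#' @return Binary `fs_grid` damage mask with `provenance` attribute.
#' @export
predict_damage <- function(classifier, deltas, forest_mask,
                           connectivity = 8) {
  if (!inherits(classifier, "damage_classifier") ||
      !inherits(classifier$model, "fs_forest"))
    stop("classifier is not fitted", call. = FALSE)
  d <- dim(deltas$layers[[1]])
  if (!identical(d[1:2], dim(forest_mask$values)))
    stop("geometry mismatch between deltas and forest mask", call. = FALSE)
  forest <- !is.na(forest_mask$values) & forest_mask$values == 1
  out <- matrix(0, d[1], d[2])
  if (any(forest)) {
    idx <- which(forest, arr.ind = TRUE)
    x <- sample_features(deltas, idx[, 1], idx[, 2])
    ok <- stats::complete.cases(x)
    prob <- rep(0, nrow(x))
    if (any(ok))
      prob[ok] <- predict(classifier$model, x[ok, , drop = FALSE],
                          type = "prob")[, "damaged"]
    out[idx] <- as.numeric(prob > classifier$threshold)
  }
  mask <- fs_grid(out, res_m = deltas$res_m, origin = deltas$origin)
  mask <- remove_single_pixels(mask, connectivity = connectivity)
  attr(mask, "provenance") <- list(classifier_id = classifier$classifier_id,
                                   threshold = classifier$threshold)
  mask
}
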