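#' Seeded bagged-tree ensemble classifier
#'
#' A random-forest-style classifier: `ntree` CART trees grown on bootstrap
#' resamples of the training rows, each split chosen from a fresh random
#' subset of `mtry` features, predictions by majority vote. All randomness
#' is drawn from R's RNG, so a `set.seed()` (or the `seed` argument) makes
#' fitting and prediction fully reproducible.
#'
#' This is deliberately plain: no pruning, no class weights, no proximity
#' machinery. It exists so the classification contracts of this package are
#' self-contained and deterministic.
#'
#' @param x numeric matrix or data.frame of features (rows = observations).
#' @param y factor or vector of class labels (>= 2 classes in training).
#' @param ntree number of trees (default 500).
#' @param mtry features tried per split; default `floor(sqrt(p))`.
#' @param max_depth maximum tree depth (default 25).
#' @param min_node minimum node size eligible for splitting (default 2).
#' @param seed optional integer; when given, `set.seed(seed)` is called
#'   before growing.
#' @return An object of class `fs_forest`.
#' @export
fs_forest_fit <- function(x, y, ntree = 500, mtry = NULL, max_depth = 25,
                          min_node = 2, seed = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("features contain missing values", call. = FALSE)
  y <- factor(y)
  if (nlevels(y) < 2L)
    stop("training data must contain at least two classes", call. = FALSE)
  if (nrow(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  yi <- as.integer(y) - 1L
  n <- nrow(x)
  trees <- vector("list", ntree)
  for (t in seq_len(ntree)) {
    boot <- sample.int(n, n, replace = TRUE)
    trees[[t]] <- cpp_grow_tree(x[boot, , drop = FALSE], yi[boot],
                                nlevels(y), as.integer(mtry),
                                as.integer(max_depth), as.integer(min_node))
  }
  structure(
    list(trees = trees, levels = levels(y), mtry = mtry, ntree = ntree,
         features = colnames(x)),
    class = "fs_forest")
}

#' Predict from a bagged-tree ensemble
#'
#' @param object an `fs_forest`.
#' @param newdata matrix or data.frame with the training feature columns.
#' @param type `"class"` for majority-vote labels, `"prob"` for vote shares.
#' @param ... unused.
#' @return Factor of labels, or a numeric matrix of vote shares with one
#'   column per class.
#' @export
predict.fs_forest <- function(object, newdata, type = c("class", "prob"),
                              ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (!is.null(object$features) && !is.null(colnames(newdata)))
    newdata <- newdata[, object$features, drop = FALSE]
  votes <- cpp_forest_votes(object$trees, newdata, length(object$levels))
  colnames(votes) <- object$levels
  if (type == "prob") return(votes / object$ntree)
  factor(object$levels[max.col(votes, ties.method = "first")],
         levels = object$levels)
}

#' @export
print.fs_forest <- function(x, ...) {
  cat(sprintf("<fs_forest> %d trees, mtry %d, classes: %s\n",
              x$ntree, x$mtry, paste(x$levels, collapse = ", ")))
  invisible(x)
}

# Accuracy bookkeeping shared by the damage and agent classifiers:
# confusion matrix plus overall, user's (rows, commission) and producer's
# (cols, omission) accuracies on a labelled set.
accuracy_report <- function(predicted, reference) {
  lev <- union(levels(factor(reference)), levels(factor(predicted)))
  predicted <- factor(predicted, levels = lev)
  reference <- factor(reference, levels = lev)
  cm <- table(predicted = predicted, reference = reference)
  overall <- sum(diag(cm)) / sum(cm)
  users <- diag(cm) / rowSums(cm)      # of mapped as k, share truly k
  producers <- diag(cm) / colSums(cm)  # of truly k, share mapped k
  list(confusion = cm, overall = overall,
       users = users, producers = producers, n = sum(cm))
}
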