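#' Per-patch disturbance features for agent attribution
#'
#' Groups disturbed pixels into patches of connected cells sharing the same
#' disturbance year (8-connectivity by default), then summarises per patch:
#' mean spectral magnitudes (delta NBR/NDVI/Tasseled Cap), mean
#' pre-disturbance NBR, modal duration, rate (delta NBR over duration),
#' patch area (ha) and the fractal shape index. Patches touching nodata in
#' any required layer are flagged incomplete.
#'
#' @param year_grid `fs_grid` of disturbance year (`NA` = undisturbed).
#' @param layers named list of `fs_grid`s with per-pixel attributes; must
#'   include `d_nbr`, `d_ndvi`, `d_tcb`, `d_tcg`, `d_tcw`, `pre_nbr`,
#'   `duration`.
#' @param connectivity patch connectivity (default 8).
#' @param fun summary statistic for spectral features, `"mean"` (default)
#'   or `"median"`.
#' @return `data.frame` with one row per patch: `patch_id`, `year`,
#'   `n_pixels`, the feature columns, `area_ha`, `frac`, `complete`.
#' @export
compute_patch_features <- function(year_grid, layers, connectivity = 8,
                                   fun = c("mean", "median")) {
  fun <- match.arg(fun)
  f <- if (fun == "mean") mean else stats::median
  need <- c("d_nbr", "d_ndvi", "d_tcb", "d_tcg", "d_tcw", "pre_nbr",
            "duration")
  if (!all(need %in% names(layers)))
    stop("missing layers: ", paste(setdiff(need, names(layers)),
                                   collapse = ", "), call. = FALSE)
  yrs <- sort(unique(as.vector(year_grid$values)))
  out <- list()
  pid <- 0L
  for (y in yrs) {
    g <- fs_grid((!is.na(year_grid$values) & year_grid$values == y) * 1,
                 res_m = year_grid$res_m, origin = year_grid$origin)
    patches <- label_patches(g, 1, connectivity = connectivity)
    for (p in patches) {
      pid <- pid + 1L
      px <- p$pixels
      vals <- lapply(layers[need], function(l) l$values[px])
      complete <- !anyNA(unlist(vals))
      feat <- vapply(vals[c("d_nbr", "d_ndvi", "d_tcb", "d_tcg", "d_tcw",
                            "pre_nbr")],
                     function(v) f(v, na.rm = TRUE), 0)
      dur <- vals$duration[!is.na(vals$duration)]
      dur <- if (length(dur)) {
        tb <- table(dur)
        as.numeric(names(tb)[which.max(tb)])
      } else NA_real_
      out[[pid]] <- data.frame(
        patch_id = pid, year = y, n_pixels = nrow(px),
        d_nbr = feat[["d_nbr"]], d_ndvi = feat[["d_ndvi"]],
        d_tcb = feat[["d_tcb"]], d_tcg = feat[["d_tcg"]],
        d_tcw = feat[["d_tcw"]], pre_nbr = feat[["pre_nbr"]],
        duration = dur,
        rate = feat[["d_nbr"]] / dur,
        area_ha = p$area_ha,
        frac = fractal_index(p),
        complete = complete)
    }
  }
  if (!length(out)) {
    cols <- c("patch_id", "year", "n_pixels", "d_nbr", "d_ndvi", "d_tcb",
              "d_tcg", "d_tcw", "pre_nbr", "duration", "rate", "area_ha",
              "frac", "complete")
    return(stats::setNames(
      data.frame(matrix(nrow = 0, ncol = length(cols))), cols))
  }
  do.call(rbind, out)
}

# Feature columns consumed by the agent classifier, in canonical order.
agent_feature_cols <- function() {
  c("d_nbr", "d_ndvi", "d_tcb", "d_tcg", "d_tcw", "pre_nbr", "duration",
    "rate", "area_ha", "frac")
}

#' Train the disturbance-agent classifier
#'
#' Classifies disturbance patches into stand-replacing fire (SRF),
#' stand-replacing harvest (SRH) and non-stand-replacing (NSR) from the
#' patch feature set, using a stratified random holdout of each class for
#' validation (20% by default) and the seeded bagged-tree ensemble for
#' fitting.
#'
#' @param features `data.frame` from [compute_patch_features()] (or any
#'   frame with the columns of `agent_feature_cols()`).
#' @param labels agent labels, same length as `nrow(features)`; levels
#'   SRF/SRH/NSR (all three required, >= 2 exemplars each).
#' @param holdout_fraction fraction of each class held out (default 0.2).
#' @param ntree trees in the ensemble (default 500).
#' @param seed integer seed for the split and the ensemble.
#' @return List of class `agent_classifier`: `model`, `report` (3x3
#'   confusion matrix, overall and per-class accuracies on the holdout),
#'   `holdout` row indices.
#' @export
train_agent_classifier <- function(features, labels, holdout_fraction = 0.2,
                                   ntree = 500, seed = NULL) {
  labels <- factor(labels)
  if (!all(c("SRF", "SRH", "NSR") %in% levels(labels)))
    stop("labels must contain all three classes SRF, SRH, NSR",
         call. = FALSE)
  if (any(table(labels) < 2L))
    stop("every class needs at least 2 exemplars", call. = FALSE)
  x <- as.matrix(features[, agent_feature_cols()])
  if (!is.null(seed)) set.seed(seed)
  hold <- unlist(lapply(levels(labels), function(k) {
    i <- which(labels == k)
    sample(i, max(1L, round(holdout_fraction * length(i))))
  }))
  tr <- setdiff(seq_along(labels), hold)
  model <- fs_forest_fit(x[tr, , drop = FALSE], labels[tr], ntree = ntree)
  report <- accuracy_report(predict(model, x[hold, , drop = FALSE]),
                            labels[hold])
  structure(list(model = model, report = report, holdout = hold),
            class = "agent_classifier")
}

#' Label disturbance patches with causal agents
#'
#' @param classifier a fitted `agent_classifier`.
#' @param features patch feature `data.frame`; rows flagged
#'   `complete = FALSE` (or containing `NA` features) get the label
#'   `"unknown"`.
#' @return Character vector of labels (`SRF`, `SRH`, `NSR`, `unknown`),
#'   one per feature row.
#' @export
classify_agents <- function(classifier, features) {
  if (nrow(features) == 0L) return(character(0))
  x <- as.matrix(features[, agent_feature_cols()])
  ok <- stats::complete.cases(x)
  if ("complete" %in% names(features)) ok <- ok & features$complete
  out <- rep("unknown", nrow(features))
  if (any(ok))
    out[ok] <- as.character(predict(classifier$model, x[ok, , drop = FALSE]))
  out
}

#' Annual disturbed area by causal agent
#'
#' @param labels agent label per patch (from [classify_agents()] or truth).
#' @param features patch features holding `year` and `area_ha`.
#' @return `data.frame` `year` x `agent` x `area_ha`, summed over patches;
#'   `unknown` patches are excluded from the series and returned in the
#'   `unknown_area_ha` attribute.
#' @export
disturbance_time_series <- function(labels, features) {
  stopifnot(length(labels) == nrow(features))
  known <- labels != "unknown"
  unk <- sum(features$area_ha[!known])
  df <- data.frame(year = features$year[known], agent = labels[known],
                   area_ha = features$area_ha[known])
  out <- if (nrow(df)) {
    stats::aggregate(area_ha ~ year + agent, df, sum)
  } else {
    data.frame(year = integer(), agent = character(), area_ha = numeric())
  }
  out <- out[order(out$year, out$agent), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unknown_area_ha") <- unk
  out
}
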