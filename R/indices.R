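#' Normalized Burn Ratio
#'
#' `NBR = (NIR - SWIR2) / (NIR + SWIR2)`, clamped to [-1, 1]. Healthy
#' canopy scores high; char and exposed soil depress it, so its drop
#' (delta-NBR) indexes disturbance severity. Cells where both bands are
#' zero are undefined and return `NA`.
#'
#' @param nir,swir2 reflectance values (vectors, matrices or `fs_grid`
#'   value matrices of equal shape).
#' @return NBR values of the input shape.
#' @examples
#' nbr(0.5, 0.1)  # 0.6667
#' @export
nbr <- function(nir, swir2) {
  denom <- nir + swir2
  out <- (nir - swir2) / denom
  out[denom == 0] <- NA
  pmin(pmax(out, -1), 1)
}

#' Normalized Difference Vegetation Index
#'
#' `NDVI = (NIR - Red) / (NIR + Red)`, clamped to [-1, 1]; `NA` where both
#' bands are zero.
#'
#' @param nir,red reflectance values of equal shape.
#' @return NDVI values of the input shape.
#' @export
ndvi <- function(nir, red) {
  denom <- nir + red
  out <- (nir - red) / denom
  out[denom == 0] <- NA
  pmin(pmax(out, -1), 1)
}

#' Tasseled Cap coefficients (classical reflectance set)
#'
#' Brightness/greenness/wetness loadings for the six optical bands
#' (blue, green, red, NIR, SWIR1, SWIR2). The coefficient set is
#' configurable wherever it is consumed; this is the default.
#'
#' @return 3 x 6 numeric matrix with rows tcb, tcg, tcw.
#' @export
tct_coefficients <- function() {
  m <- rbind(
    tcb = c(0.3037,  0.2793,  0.4743, 0.5585, 0.5082,  0.1863),
    tcg = c(-0.2848, -0.2435, -0.5436, 0.7243, 0.0840, -0.1800),
    tcw = c(0.1509,  0.1973,  0.3279, 0.3406, -0.7112, -0.4572))
  colnames(m) <- c("blue", "green", "red", "nir", "swir1", "swir2")
  m
}

#' Tasseled Cap Transformation of a band stack
#'
#' @param bands numeric matrix with one column per band, named as in
#'   [tct_coefficients()], rows are pixels/observations.
#' @param coefficients 3 x 6 loading matrix (default the classical set).
#' @return Matrix with columns `tcb`, `tcg`, `tcw`.
#' @export
tct <- function(bands, coefficients = tct_coefficients()) {
  bands <- as.matrix(bands)
  bands <- bands[, colnames(coefficients), drop = FALSE]
  out <- bands %*% t(coefficients)
  colnames(out) <- rownames(coefficients)
  out
}

#' Multi-epoch spectral index stack
#'
#' Container for co-registered per-pixel index layers (NBR, NDVI, Tasseled
#' Cap bands, ...) observed over several epochs (years or scenes). Each
#' layer is a 3-D array `[row, col, epoch]`; all layers share one epoch
#' axis, so stacks are never ragged.
#'
#' @param layers named list of 3-D numeric arrays with identical dims.
#' @param epochs vector naming the third dimension (e.g. years).
#' @param res_m,origin geometry as in [fs_grid()].
#' @return An object of class `index_stack`.
#' @export
index_stack <- function(layers, epochs, res_m = 10, origin = c(0, 0)) {
  if (!length(layers) || is.null(names(layers)))
    stop("`layers` must be a non-empty named list", call. = FALSE)
  dims <- lapply(layers, dim)
  if (any(vapply(dims, length, 1L) != 3L) ||
      length(unique(dims)) != 1L)
    stop("all layers must be 3-D arrays of identical dimensions",
         call. = FALSE)
  if (dims[[1]][3] != length(epochs))
    stop("third dimension must match `epochs`", call. = FALSE)
  for (nm in intersect(names(layers), c("nbr", "ndvi"))) {
    v <- layers[[nm]]
    if (any(v < -1 - 1e-9 | v > 1 + 1e-9, na.rm = TRUE))
      stop(nm, " values must lie in [-1, 1]", call. = FALSE)
  }
  structure(list(layers = layers, epochs = epochs, res_m = res_m,
                 origin = as.numeric(origin)),
            class = "index_stack")
}

#' @export
print.index_stack <- function(x, ...) {
  d <- dim(x$layers[[1]])
  cat(sprintf("<index_stack> %d x %d cells, %d epochs, layers: %s\n",
              d[1], d[2], d[3], paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Extract one epoch of a stack as a grid
#'
#' @param stack an `index_stack`.
#' @param layer layer name.
#' @param epoch epoch value (matched against `stack$epochs`).
#' @return An `fs_grid`.
#' @export
stack_grid <- function(stack, layer, epoch) {
  k <- match(epoch, stack$epochs)
  if (is.na(k)) stop("epoch not present in stack", call. = FALSE)
  fs_grid(stack$layers[[layer]][, , k], res_m = stack$res_m,
          origin = stack$origin)
}

#' Median composite over an epoch window
#'
#' Per-pixel, per-layer median over the epochs (scenes) selected by
#' `epochs`; `NA` scenes (clouded/invalid observations) are excluded
#' pixel-wise, and pixels with no valid scene come out as `NA`. The result
#' is a single-epoch stack labelled `label`.
#'
#' @param stack an `index_stack` whose epochs are scenes.
#' @param epochs epochs to composite over (default: all).
#' @param label epoch label of the composite (default `"composite"`).
#' @return Single-epoch `index_stack`.
#' @export
median_composite <- function(stack, epochs = stack$epochs,
                             label = "composite") {
  keep <- stack$epochs %in% epochs
  if (!any(keep)) stop("empty composite window", call. = FALSE)
  d <- dim(stack$layers[[1]])
  layers <- lapply(stack$layers, function(a) {
    sub <- a[, , keep, drop = FALSE]
    med <- apply(sub, c(1, 2), stats::median, na.rm = TRUE)
    med[is.nan(med)] <- NA
    array(med, dim = c(d[1], d[2], 1))
  })
  index_stack(layers, epochs = label, res_m = stack$res_m,
              origin = stack$origin)
}

#' Difference of two single-epoch composites
#'
#' `after - before`, per layer and pixel; `NA` in either input propagates.
#' The before/during pairing of annual composites makes abrupt 2022 canopy
#' loss show up as strongly negative delta-NBR/NDVI.
#'
#' @param before,after single-epoch `index_stack`s with identical geometry
#'   and layer sets.
#' @return Single-epoch `index_stack` of deltas, epoch `"delta"`.
#' @export
delta_composite <- function(before, after) {
  if (!identical(names(before$layers), names(after$layers)))
    stop("layer sets differ", call. = FALSE)
  if (!identical(dim(before$layers[[1]]), dim(after$layers[[1]])) ||
      !isTRUE(all.equal(before$res_m, after$res_m)) ||
      !isTRUE(all.equal(before$origin, after$origin)))
    stop("stack geometry mismatch", call. = FALSE)
  if (dim(before$layers[[1]])[3] != 1L)
    stop("delta_composite expects single-epoch stacks", call. = FALSE)
  layers <- mapply(function(b, a) a - b, before$layers, after$layers,
                   SIMPLIFY = FALSE)
  structure(list(layers = layers, epochs = "delta", res_m = before$res_m,
                 origin = before$origin),
            class = "index_stack")
}
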