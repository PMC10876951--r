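#' Georeferenced raster grid
#'
#' A minimal in-memory raster: a numeric matrix plus square-cell resolution,
#' an upper-left origin and a nodata convention (`NA` internally). Rows run
#' north to south, columns west to east, matching the usual raster layout.
#' All layers of an analysis are assumed co-registered on one such grid;
#' no reprojection is performed anywhere in the package.
#'
#' @param values numeric or integer matrix; use `NA` for nodata cells.
#' @param res_m cell size in meters (> 0). Cells are square.
#' @param origin numeric length-2, x/y map coordinates of the upper-left
#'   corner of the upper-left cell.
#' @param classes optional named integer vector registering categorical
#'   class codes (names are labels). Categorical operations check codes
#'   against this registry when present.
#' @return An object of class `fs_grid`.
#' @examples
#' g <- fs_grid(matrix(0, 4, 4), res_m = 30)
#' dim(g)
#' @export
fs_grid <- function(values, res_m = 10, origin = c(0, 0), classes = NULL) {
  if (!is.matrix(values) || any(dim(values) == 0L))
    stop("`values` must be a non-empty matrix", call. = FALSE)
  if (!is.numeric(res_m) || length(res_m) != 1L || is.na(res_m) || res_m <= 0)
    stop("`res_m` must be a single positive number", call. = FALSE)
  if (length(origin) != 2L || any(is.na(origin)))
    stop("`origin` must be length-2 numeric", call. = FALSE)
  if (!is.null(classes)) {
    codes <- unique(as.vector(values))
    codes <- codes[!is.na(codes)]
    if (length(setdiff(codes, classes)) > 0L)
      stop("grid contains codes not in the class registry: ",
           paste(setdiff(codes, classes), collapse = ", "), call. = FALSE)
  }
  structure(
    list(values = values, res_m = as.numeric(res_m),
         origin = as.numeric(origin), classes = classes),
    class = "fs_grid")
}

#' @export
dim.fs_grid <- function(x) dim(x$values)

#' @export
as.matrix.fs_grid <- function(x, ...) x$values

#' @export
print.fs_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<fs_grid> %d x %d cells, %g m resolution, origin (%g, %g)\n",
              d[1], d[2], x$res_m, x$origin[1], x$origin[2]))
  v <- x$values[!is.na(x$values)]
  if (length(v))
    cat(sprintf("  values: [%g, %g], %d nodata\n", min(v), max(v),
                sum(is.na(x$values))))
  invisible(x)
}

#' Test and enforce shared geometry
#'
#' @param a,b `fs_grid` objects.
#' @return `TRUE` invisibly; errors if the two grids differ in shape,
#'   resolution or origin.
#' @export
stopifnot_same_geometry <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)) ||
      !isTRUE(all.equal(a$res_m, b$res_m)) ||
      !isTRUE(all.equal(a$origin, b$origin)))
    stop("grids do not share geometry", call. = FALSE)
  invisible(TRUE)
}

#' Map coordinates of cell centers
#'
#' @param grid an `fs_grid`.
#' @return List with matrices `x` and `y` of cell-center coordinates.
#' @keywords internal
cell_centers <- function(grid) {
  d <- dim(grid$values)
  xs <- grid$origin[1] + (seq_len(d[2]) - 0.5) * grid$res_m
  ys <- grid$origin[2] - (seq_len(d[1]) - 0.5) * grid$res_m
  list(x = matrix(xs, d[1], d[2], byrow = TRUE),
       y = matrix(ys, d[1], d[2]))
}

#' Read and write grids as ESRI ASCII rasters
#'
#' Plain-text interchange format readable by standard GIS software. Values
#' are written row-major from the north-west corner; `NA` maps to the
#' `NODATA_value` sentinel (-9999).
#'
#' @param grid an `fs_grid`.
#' @param path file path ending in `.asc`.
#' @return `write_asc` returns `path` invisibly; `read_asc` returns an
#'   `fs_grid`.
#' @export
write_asc <- function(grid, path) {
  d <- dim(grid$values)
  hdr <- c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.6f", grid$origin[1]),
    sprintf("yllcorner %.6f", grid$origin[2] - d[1] * grid$res_m),
    sprintf("cellsize %.6f", grid$res_m),
    "NODATA_value -9999")
  v <- grid$values
  v[is.na(v)] <- -9999
  rows <- apply(v, 1L, paste, collapse = " ")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  key <- tolower(vapply(hdr, `[`, "", 1L))
  val <- as.numeric(vapply(hdr, `[`, "", 2L))
  names(val) <- key
  nr <- as.integer(val[["nrows"]]); nc <- as.integer(val[["ncols"]])
  res <- val[["cellsize"]]
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == val[["nodata_value"]]] <- NA
  fs_grid(m, res_m = res,
          origin = c(val[["xllcorner"]], val[["yllcorner"]] + nr * res))
}
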