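#' Connected-component labelling of a logical matrix
#'
#' Iterative flood fill over linear indices; no recursion, so component size
#' is bounded only by memory.
#'
#' @param mask logical matrix (`NA` treated as `FALSE`).
#' @param connectivity 4 (rook) or 8 (queen).
#' @return Integer matrix of component labels (0 = background).
#' @keywords internal
label_components <- function(mask, connectivity = 8) {
  connectivity <- match.arg(as.character(connectivity), c("8", "4"))
  mask[is.na(mask)] <- FALSE
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  dr <- c(-1L, 1L, 0L, 0L)
  dc <- c(0L, 0L, -1L, 1L)
  if (connectivity == "8") {
    dr <- c(dr, -1L, -1L, 1L, 1L)
    dc <- c(dc, -1L, 1L, -1L, 1L)
  }
  queue <- integer(nr * nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    lab[start] <- cur
    queue[1L] <- start
    head <- 1L; tail <- 1L
    while (head <= tail) {
      p <- queue[head]; head <- head + 1L
      r <- ((p - 1L) %% nr) + 1L
      co <- ((p - 1L) %/% nr) + 1L
      for (k in seq_along(dr)) {
        r2 <- r + dr[k]; c2 <- co + dc[k]
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        q <- r2 + (c2 - 1L) * nr
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          tail <- tail + 1L
          queue[tail] <- q
        }
      }
    }
  }
  lab
}

#' Delineate patches of a categorical class
#'
#' A patch is a maximal connected component of cells carrying
#' `target_class`. Patch perimeter is counted as exposed cell edges times
#' the resolution: edges facing another class, nodata, or the grid boundary
#' all count as exposed.
#'
#' @param grid categorical `fs_grid`.
#' @param target_class class code whose patches are delineated.
#' @param connectivity 8 (default, queen) or 4 (rook).
#' @return A list of patches; each has `id`, `class_code`, `pixels`
#'   (two-column matrix of row/col), `area_ha` and `perimeter_m`.
#' @examples
#' g <- fs_grid(matrix(c(1, 0, 0, 1), 2, 2), res_m = 30)
#' length(label_patches(g, 1, connectivity = 8))  # 1: diagonal touch
#' length(label_patches(g, 1, connectivity = 4))  # 2
#' @export
label_patches <- function(grid, target_class, connectivity = 8) {
  if (!is.null(grid$classes) && !(target_class %in% grid$classes))
    stop("unknown class code: ", target_class, call. = FALSE)
  v <- grid$values
  lab <- label_components(!is.na(v) & v == target_class, connectivity)
  n <- max(lab)
  if (n == 0L) return(list())
  res <- grid$res_m
  nr <- nrow(v); nc <- ncol(v)
  out <- vector("list", n)
  idx_by_lab <- split(which(lab > 0L), lab[lab > 0L])
  for (i in seq_len(n)) {
    idx <- idx_by_lab[[as.character(i)]]
    r <- ((idx - 1L) %% nr) + 1L
    co <- ((idx - 1L) %/% nr) + 1L
    # perimeter: 4 edges per cell minus 2 per rook-adjacent pair in the patch
    key <- r + (co - 1L) * nr
    inpatch <- logical(nr * nc)
    inpatch[key] <- TRUE
    adj <- 0L
    right <- key[co < nc] + nr
    down <- key[r < nr] + 1L
    adj <- sum(inpatch[right]) + sum(inpatch[down])
    out[[i]] <- list(
      id = i,
      class_code = target_class,
      pixels = cbind(row = r, col = co),
      area_ha = length(idx) * res^2 / 1e4,
      perimeter_m = (4L * length(idx) - 2L * adj) * res)
  }
  out
}

#' Fractal dimension index of a patch
#'
#' Shape complexity on the scale of the perimeter-area fractal dimension:
#' `FRAC = 2 ln(0.25 P) / ln(A)` with perimeter P in meters and area A in
#' square meters. Square patches score exactly 1; elongated or convoluted
#' patches score higher, approaching 2. Values near 1 flag the simple
#' rectangular footprints typical of clear-cut harvest; wildfire scars are
#' irregular and score higher.
#'
#' @param patch a patch as returned by [label_patches()].
#' @return Dimensionless score >= 1 for raster patches.
#' @export
fractal_index <- function(patch) {
  A <- patch$area_ha * 1e4
  if (!is.finite(A) || A <= 1)
    stop("fractal index undefined for patches of area <= 1 m^2", call. = FALSE)
  2 * log(0.25 * patch$perimeter_m) / log(A)
}

# Felzenszwalb & Huttenlocher 1-D squared-distance transform of a sampled
# function; INF encoded as a large finite number to keep arithmetic exact.
.dt1d <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n)
  v <- integer(n)
  z <- numeric(n + 1L)
  k <- 1L
  v[1L] <- 1L
  z[1L] <- -Inf
  z[2L] <- Inf
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
      if (k > 1L && s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Euclidean distance to the nearest cell of a class
#'
#' Exact center-to-center Euclidean distance (meters) from every cell to the
#' nearest cell carrying `target_class`, via the separable squared-distance
#' transform. Zero on target cells.
#'
#' @param grid categorical `fs_grid`.
#' @param target_class class code of the target set.
#' @return Continuous `fs_grid` of distances in meters.
#' @export
distance_to_class <- function(grid, target_class) {
  v <- grid$values
  on <- !is.na(v) & v == target_class
  if (!any(on)) stop("distance undefined: no cells of the target class",
                     call. = FALSE)
  BIG <- 1e12
  f <- matrix(BIG, nrow(v), ncol(v))
  f[on] <- 0
  # pass 1: along columns; pass 2: along rows
  f <- apply(f, 2L, .dt1d)
  f <- t(apply(f, 1L, .dt1d))
  fs_grid(sqrt(f) * grid$res_m, res_m = grid$res_m, origin = grid$origin)
}

#' Majority (modal) categorical resampling
#'
#' Aggregates a categorical grid by an integer factor; each coarse cell
#' takes the most frequent class of its factor-by-factor block. Grids whose
#' dimensions are not divisible by the factor are padded with nodata on the
#' south/east edges. Nodata cells never win a block that contains data;
#' ties break toward the smallest class code, deterministically.
#'
#' @param grid categorical `fs_grid`.
#' @param factor integer >= 2 aggregation factor.
#' @return Categorical `fs_grid` at `factor` times coarser resolution.
#' @export
resample_majority <- function(grid, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 2L) stop("`factor` must be >= 2", call. = FALSE)
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  nr2 <- ceiling(nr / factor); nc2 <- ceiling(nc / factor)
  pad <- matrix(NA_real_, nr2 * factor, nc2 * factor)
  pad[seq_len(nr), seq_len(nc)] <- v
  out <- matrix(NA_real_, nr2, nc2)
  for (i in seq_len(nr2)) {
    for (j in seq_len(nc2)) {
      block <- pad[((i - 1L) * factor + 1L):(i * factor),
                   ((j - 1L) * factor + 1L):(j * factor)]
      block <- block[!is.na(block)]
      if (length(block)) {
        tab <- table(block)
        best <- names(tab)[tab == max(tab)]
        out[i, j] <- min(as.numeric(best))
      }
    }
  }
  fs_grid(out, res_m = grid$res_m * factor, origin = grid$origin,
          classes = grid$classes)
}

#' Remove single-pixel components from a binary mask
#'
#' Isolated positive pixels are treated as classification noise and
#' cleared; every component of two or more pixels is kept untouched.
#'
#' @param mask binary `fs_grid` (0/1, `NA` allowed).
#' @param connectivity 8 (default) or 4.
#' @return Binary `fs_grid` of the same geometry.
#' @export
remove_single_pixels <- function(mask, connectivity = 8) {
  v <- mask$values
  lab <- label_components(!is.na(v) & v == 1, connectivity)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    drop <- which(lab > 0L)[sizes[lab[lab > 0L]] == 1L]
    v[drop] <- 0
  }
  fs_grid(v, res_m = mask$res_m, origin = mask$origin, classes = mask$classes)
}

# Round fractional flat-top axial hex coordinates to the containing hexagon
# (cube-coordinate rounding), vectorised.
.hex_round <- function(qf, rf) {
  xf <- qf; zf <- rf; yf <- -xf - zf
  rx <- round(xf); ry <- round(yf); rz <- round(zf)
  dx <- abs(rx - xf); dy <- abs(ry - yf); dz <- abs(rz - zf)
  fix_x <- dx > dy & dx > dz
  fix_z <- !fix_x & dz > dy
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  rz[fix_z] <- -rx[fix_z] - ry[fix_z]
  cbind(q = rx, r = rz)
}

#' Summarise a damage mask over a regular hexagonal grid
#'
#' Tessellates the mask's extent with flat-topped regular hexagons of the
#' requested area, anchored at the raster origin, and reports the positive
#' (damaged) area whose cell centers fall inside each hexagon. Every cell
#' center belongs to exactly one hexagon, so hexagon totals partition the
#' mapped area exactly.
#'
#' @param mask binary `fs_grid`.
#' @param hex_area_km2 hexagon area in square kilometers (default 3).
#' @return `data.frame` with `hex_id`, hexagon center coordinates
#'   (`center_x`, `center_y`, map units) and `damaged_ha`.
#' @export
hex_aggregate <- function(mask, hex_area_km2 = 3) {
  if (!is.numeric(hex_area_km2) || hex_area_km2 <= 0)
    stop("`hex_area_km2` must be positive", call. = FALSE)
  side <- sqrt(2 * hex_area_km2 * 1e6 / (3 * sqrt(3)))
  cc <- cell_centers(mask)
  # axial coordinates relative to the raster origin (flat-top layout)
  x <- as.vector(cc$x) - mask$origin[1]
  y <- as.vector(cc$y) - mask$origin[2]
  qf <- (2 / 3) * x / side
  rf <- (-x / 3 + sqrt(3) / 3 * y) / side
  ax <- .hex_round(qf, rf)
  hex_id <- paste(ax[, "q"], ax[, "r"], sep = ":")
  pix_ha <- mask$res_m^2 / 1e4
  pos <- as.vector(mask$values)
  pos[is.na(pos)] <- 0
  agg <- tapply(pos * pix_ha, hex_id, sum)
  ids <- names(agg)
  qr <- do.call(rbind, strsplit(ids, ":", fixed = TRUE))
  q <- as.numeric(qr[, 1]); r <- as.numeric(qr[, 2])
  data.frame(
    hex_id = ids,
    center_x = mask$origin[1] + side * 1.5 * q,
    center_y = mask$origin[2] + side * (sqrt(3) / 2 * q + sqrt(3) * r),
    damaged_ha = as.numeric(agg),
    row.names = NULL)
}
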