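#' Canonical nine-class land-cover registry
#'
#' Integer codes for the nine mapped classes: bare soil, built-up, burned
#' (pre-2022) forest, cropland, forest cover, grassland, water body,
#' wetland, woodland.
#'
#' @return Named integer vector of class codes.
#' @export
landcover_classes <- function() {
  c(bare_soil = 1L, built_up = 2L, burned_forest = 3L, cropland = 4L,
    forest = 5L, grassland = 6L, water = 7L, wetland = 8L, woodland = 9L)
}

#' Configuration of the elevated-fire-hazard analysis
#'
#' Defaults encode the reclassification used throughout: cropland,
#' grassland, woodland and forest burned before 2022 carry fire toward
#' damaged stands (fire-supporting); bare soil, built-up, water, wetland
#' and undamaged forest inhibit it. Only supporting patches of at least
#' 1 ha count as ignition neighbours, and summaries are reported for
#' damaged patches above 0.09 ha (one 30 m cell) and above 1 ha.
#'
#' @param supporting_classes,inhibiting_classes class-name character
#'   vectors partitioning [landcover_classes()] (undamaged forest falls in
#'   the inhibiting set).
#' @param min_supporting_patch_ha minimum supporting-patch area (default 1).
#' @param damaged_patch_thresholds_ha damaged-patch reporting thresholds
#'   (default `c(0.09, 1)`).
#' @param adjacency_distance_m distance (m) at or below which a damaged
#'   patch counts as adjacent to a supporting patch. Default 30: one cell,
#'   center-to-center, i.e. edge-sharing neighbours at 30 m resolution.
#' @return List of class `hazard_config`.
#' @export
hazard_config <- function(
    supporting_classes = c("cropland", "grassland", "woodland",
                           "burned_forest"),
    inhibiting_classes = c("bare_soil", "built_up", "water", "wetland",
                           "forest"),
    min_supporting_patch_ha = 1,
    damaged_patch_thresholds_ha = c(0.09, 1),
    adjacency_distance_m = 30) {
  all9 <- names(landcover_classes())
  if (length(intersect(supporting_classes, inhibiting_classes)))
    stop("supporting and inhibiting sets overlap", call. = FALSE)
  if (!setequal(union(supporting_classes, inhibiting_classes), all9))
    stop("supporting + inhibiting must cover all nine classes",
         call. = FALSE)
  structure(list(
    supporting_classes = supporting_classes,
    inhibiting_classes = inhibiting_classes,
    min_supporting_patch_ha = min_supporting_patch_ha,
    damaged_patch_thresholds_ha = sort(damaged_patch_thresholds_ha),
    adjacency_distance_m = adjacency_distance_m),
    class = "hazard_config")
}

#' Reclassify land cover into fire-supporting vs fire-inhibiting
#'
#' @param landcover categorical `fs_grid` over the nine classes (expected
#'   already at the 30 m analysis resolution).
#' @param damaged_mask binary `fs_grid` of 2022 damage; damaged cells are
#'   the subject of the analysis, not potential neighbours, and come out
#'   `NA`.
#' @param config a [hazard_config()].
#' @return Binary `fs_grid`: 1 = fire-supporting, 0 = fire-inhibiting,
#'   `NA` on damaged or nodata cells.
#' @export
classify_fire_support <- function(landcover, damaged_mask, config) {
  stopifnot_same_geometry(landcover, damaged_mask)
  codes <- landcover_classes()
  sup <- codes[config$supporting_classes]
  inh <- codes[config$inhibiting_classes]
  v <- landcover$values
  present <- unique(v[!is.na(v)])
  bad <- setdiff(present, c(sup, inh))
  if (length(bad))
    stop("class codes in neither set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  out <- matrix(NA_real_, nrow(v), ncol(v))
  out[v %in% sup] <- 1
  out[v %in% inh] <- 0
  out[!is.na(damaged_mask$values) & damaged_mask$values == 1] <- NA
  fs_grid(out, res_m = landcover$res_m, origin = landcover$origin)
}

#' Assess elevated fire hazard of damaged forest patches
#'
#' Labels damaged patches and fire-supporting patches, discards supporting
#' patches below the minimum area, and measures, per damaged patch, the
#' minimum Euclidean distance (cell center to cell center, meters) from
#' any of its cells to the nearest surviving supporting cell. A patch is
#' flagged elevated when that distance does not exceed the adjacency
#' cutoff. Summary proportions of elevated patches are reported at each
#' damaged-patch size threshold, both as a patch-count share and as an
#' area share.
#'
#' @param damaged_mask binary `fs_grid` of damage.
#' @param support binary support `fs_grid` from [classify_fire_support()].
#' @param config a [hazard_config()].
#' @param connectivity patch connectivity (default 8).
#' @return List of class `hazard_assessment` with `patches` (data.frame:
#'   `id`, `area_ha`, `min_edge_distance_m`, `elevated`) and `summary`
#'   (data.frame per threshold: proportions by count and by area; `NA`
#'   when no patch qualifies).
#' @export
assess_hazard <- function(damaged_mask, support, config,
                          connectivity = 8) {
  stopifnot_same_geometry(damaged_mask, support)
  dmg_patches <- label_patches(damaged_mask, 1, connectivity = connectivity)
  sup_patches <- label_patches(support, 1, connectivity = connectivity)
  sup_patches <- Filter(function(p)
    p$area_ha >= config$min_supporting_patch_ha, sup_patches)

  if (!length(dmg_patches)) {
    return(structure(list(
      patches = data.frame(id = integer(), area_ha = numeric(),
                           min_edge_distance_m = numeric(),
                           elevated = logical()),
      summary = data.frame(
        threshold_ha = config$damaged_patch_thresholds_ha,
        n_patches = 0L, prop_count = NA_real_, prop_area = NA_real_)),
      class = "hazard_assessment"))
  }

  dist_m <- if (length(sup_patches)) {
    keep <- matrix(0, nrow(support$values), ncol(support$values))
    for (p in sup_patches) keep[p$pixels] <- 1
    distance_to_class(fs_grid(keep, res_m = support$res_m,
                              origin = support$origin), 1)$values
  } else NULL

  rows <- lapply(dmg_patches, function(p) {
    d <- if (is.null(dist_m)) Inf else min(dist_m[p$pixels])
    data.frame(id = p$id, area_ha = p$area_ha, min_edge_distance_m = d,
               elevated = d <= config$adjacency_distance_m)
  })
  patches <- do.call(rbind, rows)

  summary <- do.call(rbind, lapply(
    config$damaged_patch_thresholds_ha, function(th) {
      sel <- patches[patches$area_ha >= th, , drop = FALSE]
      if (!nrow(sel))
        return(data.frame(threshold_ha = th, n_patches = 0L,
                          prop_count = NA_real_, prop_area = NA_real_))
      data.frame(threshold_ha = th, n_patches = nrow(sel),
                 prop_count = mean(sel$elevated),
                 prop_area = sum(sel$area_ha[sel$elevated]) /
                   sum(sel$area_ha))
    }))
  structure(list(patches = patches, summary = summary),
            class = "hazard_assessment")
}

#' @export
print.hazard_assessment <- function(x, ...) {
  cat(sprintf("<hazard_assessment> %d damaged patches\n", nrow(x$patches)))
  print(x$summary)
  invisible(x)
}

#' Cross-AOI elevated-fire-hazard summary table
#'
#' @param assessments named list of `hazard_assessment`s, one per area of
#'   interest.
#' @return `data.frame`: `aoi`, `threshold_ha`, `n_patches`, `prop_count`,
#'   `prop_area` (proportions in [0, 1], `NA` where undefined).
#' @export
hazard_report <- function(assessments) {
  if (!length(assessments)) stop("no assessments", call. = FALSE)
  if (is.null(names(assessments)))
    names(assessments) <- paste0("AOI", seq_along(assessments))
  out <- do.call(rbind, lapply(names(assessments), function(nm) {
    cbind(aoi = nm, assessments[[nm]]$summary)
  }))
  rownames(out) <- NULL
  out
}
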