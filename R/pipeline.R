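#' Pipeline stage names in dependency order
#' @return Character vector of the canonical stage ordering.
#' @export
pipeline_stages <- function() {
  c("simulate", "classify", "segment", "attribute", "hazard",
    "estimate-area", "anomaly", "report")
}

config_error <- function(...) {
  stop(structure(class = c("firescape_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

data_error <- function(...) {
  stop(structure(class = c("firescape_data_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

# fill defaults and validate the per-stage config sections
normalize_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) config_error("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) config_error("config must be a list or YAML path")
  defaults <- list(
    scenario = list(grid_rows = 96, grid_cols = 96, resolution_m = 10,
                    trajectory_noise_sd = 0.02,
                    weather_anomaly_years = integer(), seed = 1),
    classify = list(ntree = 300, n_train = 600, n_validation = 300,
                    connectivity = 8),
    segment = list(max_segments = 6, rmse_improvement_tol = 0.01),
    attribute = list(ntree = 300, holdout_fraction = 0.2),
    hazard = list(adjacency_distance_m = 30, min_supporting_patch_ha = 1,
                  resample_factor = 3, connectivity = 8),
    area = list(n_reference = 500, aggregation = "linear"),
    anomaly = list(disturbance_threshold = 3, weather_threshold = 2))
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    config_error("unknown config sections: ", paste(unknown, collapse = ", "))
  for (s in names(defaults)) {
    user <- if (s %in% names(config)) config[[s]] else list()
    bad <- setdiff(names(user), names(defaults[[s]]))
    if (length(bad))
      config_error("unknown keys in section '", s, "': ",
                   paste(bad, collapse = ", "))
    defaults[[s]][names(user)] <- user
  }
  if (!defaults$area$aggregation %in% c("linear", "quadrature"))
    config_error("area$aggregation must be 'linear' or 'quadrature'")
  defaults
}

#' Run the analysis pipeline on a synthetic scenario
#'
#' Executes the requested stages in dependency order — simulate the
#' landscape, classify 2022 damage from delta composites, segment the
#' pre-war NBR trajectories, attribute disturbance agents, assess elevated
#' fire hazard, estimate damaged area with uncertainty, flag anomalous
#' years and regress burned area on fire weather, and write a summary
#' report. All outputs are plain text (ASCII grids, CSV, YAML) under
#' `out_dir`; a manifest with per-file checksums makes runs reproducible
#' and comparable.
#'
#' @param config path to a YAML config or an equivalent named list; see
#'   the packaged demo config
#'   (`system.file("extdata", "demo_config.yaml", package = "firescape")`).
#' @param out_dir output directory.
#' @param stages subset of [pipeline_stages()] (default: all). Later
#'   stages require their upstream stages in the same call.
#' @param seed optional integer overriding the scenario seed.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir, stages = pipeline_stages(),
                         seed = NULL) {
  cfg <- normalize_config(config)
  if (!is.null(seed)) cfg$scenario$seed <- as.integer(seed)
  bad <- setdiff(stages, pipeline_stages())
  if (length(bad))
    config_error("unknown stages: ", paste(bad, collapse = ", "))
  stages <- intersect(pipeline_stages(), stages)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- new.env(parent = emptyenv())
  t_all <- list()
  for (stage in stages) {
    t0 <- proc.time()[["elapsed"]]
    switch(stage,
           "simulate" = stage_simulate(cfg, out_dir, st),
           "classify" = stage_classify(cfg, out_dir, st),
           "segment" = stage_segment(cfg, out_dir, st),
           "attribute" = stage_attribute(cfg, out_dir, st),
           "hazard" = stage_hazard(cfg, out_dir, st),
           "estimate-area" = stage_area(cfg, out_dir, st),
           "anomaly" = stage_anomaly(cfg, out_dir, st),
           "report" = stage_report(cfg, out_dir, st))
    t_all[[stage]] <- proc.time()[["elapsed"]] - t0
    message(sprintf("[firescape] stage %-13s %6.1f s", stage,
                    t_all[[stage]]))
  }
  files <- setdiff(list.files(out_dir, recursive = TRUE, full.names = TRUE),
                   file.path(out_dir, "manifest.yaml"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("firescape")),
    seed = cfg$scenario$seed,
    stages = stages,
    config = cfg,
    checksums = as.list(stats::setNames(
      unname(tools::md5sum(files)),
      sub(paste0("^", out_dir, "/?"), "", files))))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  st$manifest <- manifest
  invisible(as.list(st))
}

need_stage <- function(st, what, stage) {
  if (!exists(what, envir = st))
    data_error("stage '", stage, "' requires upstream output '", what,
               "'; run its dependency stages in the same call")
  get(what, envir = st)
}

stage_simulate <- function(cfg, out_dir, st) {
  sc <- cfg$scenario
  st$truth <- generate_scenario(scenario_config(
    grid_rows = sc$grid_rows, grid_cols = sc$grid_cols,
    resolution_m = sc$resolution_m,
    trajectory_noise_sd = sc$trajectory_noise_sd,
    weather_anomaly_years = sc$weather_anomaly_years,
    seed = sc$seed))
  write_scenario(st$truth, file.path(out_dir, "scenario"))
}

stage_classify <- function(cfg, out_dir, st) {
  truth <- need_stage(st, "truth", "classify")
  before <- single_epoch(truth$stack, 2021)
  after <- single_epoch(truth$stack, 2022)
  st$deltas <- delta_composite(before, after)
  # nine-class 2021 land cover from the leaf-on composite, same
  # train/predict contract as the damage model; the mapped forest mask
  # (not the true one) feeds everything downstream, so land-cover error
  # propagates into the damage area estimate as it would with real data
  truth_lc <- truth$landcover_by_year[["2021"]]
  set.seed(cfg$scenario$seed + 7L)
  lc_idx <- unlist(lapply(
    split(seq_along(truth_lc$values), truth_lc$values),
    function(i) sample(i, min(120L, length(i)))))
  nr <- nrow(truth_lc$values)
  lc_x <- sample_features(before, ((lc_idx - 1L) %% nr) + 1L,
                          ((lc_idx - 1L) %/% nr) + 1L)
  lc_model <- fs_forest_fit(lc_x, factor(truth_lc$values[lc_idx]),
                            ntree = cfg$classify$ntree,
                            seed = cfg$scenario$seed + 8L)
  all_idx <- seq_along(truth_lc$values)
  all_x <- sample_features(before, ((all_idx - 1L) %% nr) + 1L,
                           ((all_idx - 1L) %/% nr) + 1L)
  lc_pred <- as.numeric(as.character(predict(lc_model, all_x)))
  st$landcover_map <- fs_grid(matrix(lc_pred, nr), res_m = truth_lc$res_m,
                              origin = truth_lc$origin,
                              classes = landcover_classes())
  write_asc(st$landcover_map, file.path(out_dir, "landcover_map_2021.asc"))
  fmask <- fs_grid((st$landcover_map$values ==
                      landcover_classes()[["forest"]]) * 1,
                   res_m = truth_lc$res_m, origin = truth_lc$origin)
  # calibration/validation points: damaged truth vs undisturbed forest
  set.seed(cfg$scenario$seed + 1L)
  pos <- which(truth$damage_2022$values == 1)
  neg <- which(truth$damage_2022$values == 0 & fmask$values == 1)
  n_each <- min(length(pos), length(neg),
                ceiling((cfg$classify$n_train + cfg$classify$n_validation) / 2))
  if (n_each < 10L) data_error("too few damaged pixels to calibrate")
  pick <- c(sample(pos, n_each), sample(neg, n_each))
  lab <- rep(c(1, 0), each = n_each)
  split <- sample(rep(c("train", "validation"),
                      round(c(0.65, 0.35) * length(pick))))[
                        seq_along(pick)]
  nr <- nrow(fmask$values)
  samples <- data.frame(row = ((pick - 1L) %% nr) + 1L,
                        col = ((pick - 1L) %/% nr) + 1L,
                        label = lab, split = split)
  st$damage_classifier <- train_damage_classifier(
    st$deltas, samples, ntree = cfg$classify$ntree,
    seed = cfg$scenario$seed + 2L)
  st$forest_mask_2021 <- fmask
  st$damage_mask <- predict_damage(st$damage_classifier, st$deltas, fmask,
                                   connectivity = cfg$classify$connectivity)
  write_asc(st$damage_mask, file.path(out_dir, "damage_mask.asc"))
  rep <- st$damage_classifier$report
  utils::write.csv(data.frame(
    metric = c("overall_accuracy",
               paste0("users_", names(rep$users)),
               paste0("producers_", names(rep$producers))),
    value = c(rep$overall, rep$users, rep$producers)),
    file.path(out_dir, "damage_accuracy.csv"), row.names = FALSE)
}

single_epoch <- function(stack, epoch) {
  k <- match(epoch, stack$epochs)
  layers <- lapply(stack$layers, function(a)
    a[, , k, drop = FALSE])
  index_stack(layers, epochs = epoch, res_m = stack$res_m,
              origin = stack$origin)
}

stage_segment <- function(cfg, out_dir, st) {
  truth <- need_stage(st, "truth", "segment")
  # only pixels ever inside a 5-yearly forest mask can carry a disturbance
  ever <- Reduce(`+`, lapply(truth$forest_masks_5yr, function(g) g$values))
  pixels <- which(ever > 0, arr.ind = TRUE)
  st$segments <- segment_stack(
    truth$stack, forest_masks = truth$forest_masks_5yr, pixels = pixels,
    max_segments = cfg$segment$max_segments,
    rmse_improvement_tol = cfg$segment$rmse_improvement_tol)
  utils::write.csv(st$segments, file.path(out_dir, "segments.csv"),
                   row.names = FALSE)
}

stage_attribute <- function(cfg, out_dir, st) {
  truth <- need_stage(st, "truth", "attribute")
  segments <- need_stage(st, "segments", "attribute")
  prim <- segments[segments$rank == "primary", , drop = FALSE]
  if (!nrow(prim)) data_error("no primary segments to attribute")
  d <- dim(truth$stack$layers[[1]])[1:2]
  res <- truth$stack$res_m
  mk <- function() matrix(NA_real_, d[1], d[2])
  year <- mk(); d_nbr <- mk(); dur <- mk(); pre <- mk()
  d_ndvi <- mk(); d_tcb <- mk(); d_tcg <- mk(); d_tcw <- mk()
  ij <- cbind(prim$row, prim$col)
  onset <- prim$end_year - prim$duration + 1L
  year[ij] <- onset
  d_nbr[ij] <- prim$magnitude
  dur[ij] <- prim$duration
  pre[ij] <- prim$pre_nbr
  yrs <- as.integer(truth$stack$epochs)
  i0 <- match(prim$start_year, yrs)
  i1 <- match(prim$end_year, yrs)
  for (l in c("ndvi", "tcb", "tcg", "tcw")) {
    a <- truth$stack$layers[[l]]
    delta <- a[cbind(ij, i0)] - a[cbind(ij, i1)]
    assign(paste0("d_", l), `[<-`(get(paste0("d_", l)), ij, delta))
  }
  g <- function(m) fs_grid(m, res_m = res)
  st$patch_features <- compute_patch_features(
    g(year), list(d_nbr = g(d_nbr), d_ndvi = g(d_ndvi), d_tcb = g(d_tcb),
                  d_tcg = g(d_tcg), d_tcw = g(d_tcw), pre_nbr = g(pre),
                  duration = g(dur)))
  feats <- st$patch_features
  # truth agent per patch: majority of the event-agent raster it overlaps
  agent_map <- matrix(NA_character_, d[1], d[2])
  year_map <- matrix(NA_integer_, d[1], d[2])
  px <- merge(truth$event_pixels, truth$events[, c("event_id", "year",
                                                  "agent")], by = "event_id")
  agent_map[cbind(px$row, px$col)] <- px$agent
  year_map[cbind(px$row, px$col)] <- px$year
  truth_label <- truth_patch_labels(feats, g(year), agent_map)
  ok <- !is.na(truth_label) & feats$complete
  if (length(unique(truth_label[ok])) < 3L)
    data_error("attribution training needs all three agents present")
  st$agent_classifier <- train_agent_classifier(
    feats[ok, ], truth_label[ok],
    holdout_fraction = cfg$attribute$holdout_fraction,
    ntree = cfg$attribute$ntree, seed = cfg$scenario$seed + 3L)
  st$agent_labels <- classify_agents(st$agent_classifier, feats)
  st$agent_series <- disturbance_time_series(st$agent_labels, feats)
  utils::write.csv(cbind(feats, truth_agent = truth_label,
                         predicted_agent = st$agent_labels),
                   file.path(out_dir, "patch_features.csv"),
                   row.names = FALSE)
  utils::write.csv(st$agent_series,
                   file.path(out_dir, "agent_time_series.csv"),
                   row.names = FALSE)
  rep <- st$agent_classifier$report
  yaml::write_yaml(list(
    overall_accuracy = rep$overall,
    users_accuracy = as.list(rep$users),
    producers_accuracy = as.list(rep$producers),
    n_holdout = rep$n),
    file.path(out_dir, "agent_validation.yaml"))
  utils::write.csv(as.data.frame.matrix(rep$confusion),
                   file.path(out_dir, "agent_confusion.csv"))
}

# majority truth agent over each patch footprint (NA if no overlap)
truth_patch_labels <- function(features, year_grid, agent_map) {
  if (!nrow(features)) return(character(0))
  lab <- rep(NA_character_, nrow(features))
  # patches are relabelled the same way compute_patch_features built them,
  # so per-year relabelling recovers the footprint of every feature row
  yrs <- unique(features$year)
  for (y in yrs) {
    g <- fs_grid((!is.na(year_grid$values) & year_grid$values == y) * 1,
                 res_m = year_grid$res_m, origin = year_grid$origin)
    patches <- label_patches(g, 1)
    rows <- which(features$year == y)
    # label_patches order is deterministic, matching compute_patch_features
    for (k in seq_along(patches)) {
      ag <- agent_map[patches[[k]]$pixels]
      ag <- ag[!is.na(ag)]
      lab[rows[k]] <- if (length(ag)) names(which.max(table(ag)))
                      else NA_character_
    }
  }
  lab
}

stage_hazard <- function(cfg, out_dir, st) {
  truth <- need_stage(st, "truth", "hazard")
  damage <- need_stage(st, "damage_mask", "hazard")
  hcfg <- hazard_config(
    min_supporting_patch_ha = cfg$hazard$min_supporting_patch_ha,
    adjacency_distance_m = cfg$hazard$adjacency_distance_m)
  f <- cfg$hazard$resample_factor
  lc_map <- need_stage(st, "landcover_map", "hazard")
  lc30 <- resample_majority(lc_map, f)
  dmg30 <- resample_majority(damage, f)
  dmg30$values[is.na(dmg30$values)] <- 0
  st$support <- classify_fire_support(lc30, dmg30, hcfg)
  st$hazard <- assess_hazard(dmg30, st$support, hcfg,
                             connectivity = cfg$hazard$connectivity)
  utils::write.csv(st$hazard$patches,
                   file.path(out_dir, "hazard_patches.csv"),
                   row.names = FALSE)
  utils::write.csv(hazard_report(list(synthetic = st$hazard)),
                   file.path(out_dir, "hazard_summary.csv"),
                   row.names = FALSE)
}

stage_area <- function(cfg, out_dir, st) {
  truth <- need_stage(st, "truth", "estimate-area")
  damage <- need_stage(st, "damage_mask", "estimate-area")
  fmask <- need_stage(st, "forest_mask_2021", "estimate-area")
  res <- damage$res_m
  pix_ha <- res^2 / 1e4
  region_ha <- length(damage$values) * pix_ha
  n <- cfg$area$n_reference
  # forest share of the region: mapped forest mask is the stratifier, the
  # true land cover provides the reference labels
  truth_lc <- need_stage(st, "truth", "estimate-area")$landcover_by_year[["2021"]]
  truth_forest <- fs_grid(
    (truth_lc$values == landcover_classes()[["forest"]]) * 1, res_m = res)
  map_forest <- fs_grid(fmask$values, res_m = res)
  lc_sample <- generate_reference_sample(
    truth_forest, map_forest, n, seed = cfg$scenario$seed + 4L,
    stratified = TRUE)
  w_f <- table(factor(map_forest$values, levels = c(0, 1))) /
    length(map_forest$values)
  forest_est <- stratified_area_estimate(
    lc_sample, stats::setNames(as.numeric(w_f), c("0", "1")), region_ha)
  forest_est <- forest_est[forest_est$class == 1, ]
  # damaged share of forest, stratified by the mapped damage class
  fidx <- which(fmask$values == 1)
  sub <- function(g) {
    m <- matrix(g$values[fidx], ncol = 1)
    fs_grid(m, res_m = res)
  }
  dm_map <- sub(damage)
  dm_truth <- sub(truth$damage_2022)
  w_d <- table(factor(dm_map$values, levels = c(0, 1))) /
    length(dm_map$values)
  dmg_sample <- generate_reference_sample(
    dm_truth, dm_map, min(n, length(fidx)), seed = cfg$scenario$seed + 5L,
    stratified = TRUE)
  forest_ha_true <- length(fidx) * pix_ha
  damage_est <- stratified_area_estimate(
    dmg_sample, stats::setNames(as.numeric(w_d), c("0", "1")),
    forest_ha_true)
  damage_est <- damage_est[damage_est$class == 1, ]
  st$forest_estimate <- forest_est
  st$damage_estimate <- damage_est
  st$combined_estimate <- combine_uncertainty(forest_est, damage_est,
                                              region_ha)
  st$hex <- hex_aggregate(damage)
  utils::write.csv(rbind(
    cbind(what = "forest_of_region", forest_est[, -1]),
    cbind(what = "damaged_of_forest", damage_est[, -1]),
    cbind(what = "damaged_of_region", st$combined_estimate)),
    file.path(out_dir, "area_estimates.csv"), row.names = FALSE)
  utils::write.csv(st$hex, file.path(out_dir, "hex_summary.csv"),
                   row.names = FALSE)
}

stage_anomaly <- function(cfg, out_dir, st) {
  truth <- need_stage(st, "truth", "anomaly")
  series <- need_stage(st, "agent_series", "anomaly")
  yrs <- truth$config$years
  st$disturbance_flags <- lapply(
    stats::setNames(nm = c("SRF", "SRH", "NSR")), function(ag) {
      a <- series[series$agent == ag, ]
      v <- stats::setNames(rep(0, length(yrs)), yrs)
      v[as.character(a$year)] <- a$area_ha
      zscore_series(as.numeric(v), yrs,
                    threshold = cfg$anomaly$disturbance_threshold)
    })
  st$season <- seasonal_series(truth$weather)
  st$weather_flags <- lapply(
    stats::setNames(nm = c("fwi", "isi", "dc")), function(ix) {
      zscore_series(st$season[[paste0("mean_", ix)]], st$season$year,
                    threshold = cfg$anomaly$weather_threshold)
    })
  # weather-driven expectation of 2022 burned area vs the mapped record
  srf <- st$disturbance_flags$SRF
  area <- data.frame(year = srf$year, area_ha = srf$value)
  train <- area[area$year >= 1987 & area$year <= 2021, ]
  st$regressions <- lapply(
    stats::setNames(nm = c("isi", "dc")), function(ix) {
      tryCatch(regress_burned_area(train, st$season, index = ix,
                                   target_year = 2022),
               error = function(e) NULL)
    })
  flags <- do.call(rbind, c(
    lapply(names(st$disturbance_flags), function(k)
      cbind(series = k, st$disturbance_flags[[k]])),
    lapply(names(st$weather_flags), function(k)
      cbind(series = k, st$weather_flags[[k]]))))
  utils::write.csv(flags, file.path(out_dir, "anomaly_flags.csv"),
                   row.names = FALSE)
  regs <- do.call(rbind, lapply(names(st$regressions), function(k) {
    r <- st$regressions[[k]]
    if (is.null(r)) return(NULL)
    data.frame(index = k, prediction_ha = r$prediction,
               slope = r$slope, intercept = r$intercept,
               r_squared = r$r_squared, n = r$n, floored = r$floored)
  }))
  if (!is.null(regs))
    utils::write.csv(regs, file.path(out_dir, "burned_area_regression.csv"),
                     row.names = FALSE)
}

stage_report <- function(cfg, out_dir, st) {
  req <- c("truth", "damage_mask", "segments", "agent_series", "hazard",
           "combined_estimate", "disturbance_flags")
  for (r in req) need_stage(st, r, "report")
  ce <- st$combined_estimate
  hz <- st$hazard$summary
  lines <- c(
    "firescape pipeline report",
    "=========================",
    "",
    "1. Damaged forest cover (2022, synthetic region)",
    sprintf("   %.1f ha +/- %.1f ha (%.2f%% +/- %.2f%% of the region)",
            ce$area_ha, ce$se_ha, 100 * ce$proportion,
            100 * ce$se_proportion),
    "",
    "2. Elevated fire hazard (share of damaged patches adjacent to",
    "   fire-supporting cover >= 1 ha)",
    vapply(seq_len(nrow(hz)), function(i) {
      if (is.na(hz$prop_count[i]))
        sprintf("   > %.2f ha: undefined (no qualifying patches)",
                hz$threshold_ha[i])
      else
        sprintf("   > %.2f ha: %.0f%% of patches (%.0f%% of area), n = %d",
                hz$threshold_ha[i], 100 * hz$prop_count[i],
                100 * hz$prop_area[i], hz$n_patches[i])
    }, ""),
    "",
    "3. Disturbance agents, mapped area by agent (ha, all years)",
    vapply(split(st$agent_series, st$agent_series$agent), function(a)
      sprintf("   %s: %.1f ha over %d year(s)", a$agent[1],
              sum(a$area_ha), nrow(a)), ""),
    "",
    "4. Abnormal disturbance years (z >= 3)",
    report_flag_lines(st$disturbance_flags),
    "",
    "5. Abnormal fire-weather years (z >= 2)",
    report_flag_lines(st$weather_flags),
    "",
    "6. Weather-predicted vs mapped 2022 fire-attributed area",
    report_regression_lines(st),
    "",
    "7. Hexagonal damage summary",
    sprintf("   %d hexagons, total damaged area %.1f ha",
            nrow(st$hex), sum(st$hex$damaged_ha)))
  writeLines(lines, file.path(out_dir, "report.txt"))
  st$report <- lines
}

report_flag_lines <- function(flags) {
  out <- vapply(names(flags), function(k) {
    ab <- flags[[k]]$year[flags[[k]]$abnormal]
    sprintf("   %s: %s", k,
            if (length(ab)) paste(ab, collapse = ", ") else "none")
  }, "")
  unname(out)
}

report_regression_lines <- function(st) {
  srf <- st$disturbance_flags$SRF
  mapped <- srf$value[srf$year == 2022]
  out <- vapply(names(st$regressions), function(k) {
    r <- st$regressions[[k]]
    if (is.null(r)) return(sprintf("   %s: model unavailable", k))
    sprintf("   %s model: predicted %.1f ha (R^2 = %.2f), mapped %.1f ha",
            k, r$prediction, r$r_squared, mapped)
  }, "")
  unname(out)
}
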