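small_cfg <- function(...) {
  scenario_config(grid_rows = 40, grid_cols = 40, seed = 21, ...)
}

test_that("scenario_config validates its invariants", {
  p <- default_class_proportions()
  p[["forest"]] <- p[["forest"]] + 0.1
  expect_error(scenario_config(class_proportions = p), "sum to 1")

  sched <- default_disturbance_schedule()
  sched$year[1] <- 1901
  expect_error(scenario_config(disturbance_schedule = sched), "outside")

  sched <- default_disturbance_schedule()
  sched$dnbr_max[sched$agent == "NSR"][1] <- 0.4
  expect_error(scenario_config(disturbance_schedule = sched), "< 0.25")

  sched <- default_disturbance_schedule()
  sched$dnbr_min[sched$agent == "SRF"][1] <- 0.1
  expect_error(scenario_config(disturbance_schedule = sched), ">= 0.25")

  expect_error(scenario_config(weather_anomaly_years = 1901), "outside")
})

test_that("a scenario with no events keeps land cover constant", {
  cfg <- small_cfg(disturbance_schedule =
                     default_disturbance_schedule()[0, ],
                   trajectory_noise_sd = 0)
  tr <- generate_scenario(cfg)
  lcs <- tr$landcover_by_year
  expect_true(all(vapply(lcs, function(g)
    identical(g$values, lcs[[1]]$values), TRUE)))
  expect_equal(nrow(tr$events), 0)
  # zero-noise trajectories are constant per pixel
  expect_equal(tr$stack$layers$nbr[, , 1], tr$stack$layers$nbr[, , 37])
})

test_that("a single scheduled harvest yields one rectangular patch", {
  sched <- data.frame(year = 2005, agent = "SRH", count = 1L,
                      npix_min = 12L, npix_max = 12L,
                      dnbr_min = 0.5, dnbr_max = 0.5,
                      duration_min = 1L, duration_max = 1L)
  cfg <- small_cfg(disturbance_schedule = sched, trajectory_noise_sd = 0)
  tr <- generate_scenario(cfg)
  expect_equal(nrow(tr$events), 1)
  expect_equal(tr$events$n_pixels, 12)
  px <- tr$event_pixels
  expect_equal((max(px$row) - min(px$row) + 1) *
                 (max(px$col) - min(px$col) + 1), 12)  # filled bbox
  # NBR drops by 0.5 at the event year on event pixels
  k05 <- match(2005, cfg$years)
  drop <- tr$stack$layers$nbr[cbind(px$row, px$col, k05 - 1)] -
    tr$stack$layers$nbr[cbind(px$row, px$col, k05)]
  expect_equal(drop, rep(0.5, 12), tolerance = 1e-12)
})

test_that("identical seed and config regenerate bit-identical truth", {
  cfg <- small_cfg()
  t1 <- generate_scenario(cfg)
  t2 <- generate_scenario(cfg)
  expect_identical(t1$events, t2$events)
  expect_identical(t1$event_pixels, t2$event_pixels)
  expect_identical(t1$stack$layers, t2$stack$layers)
  expect_identical(t1$weather, t2$weather)
  expect_identical(t1$base_landcover$values, t2$base_landcover$values)
  t3 <- generate_scenario(scenario_config(grid_rows = 40, grid_cols = 40,
                                          seed = 22))
  expect_false(identical(t1$events, t3$events))
})

test_that("events respect agent geometry, severity and forest masks", {
  tr <- generate_scenario(scenario_config(seed = 2))
  ev <- tr$events
  expect_true(all(ev$d_nbr[ev$agent == "NSR"] < 0.25))
  expect_true(all(ev$d_nbr[ev$agent != "NSR"] >= 0.25))
  mask_years <- sort(as.integer(names(tr$forest_masks_5yr)))
  fracs <- c()
  for (i in seq_len(nrow(ev))) {
    px <- tr$event_pixels[tr$event_pixels$event_id == ev$event_id[i], ]
    my <- max(mask_years[mask_years <= ev$year[i]])
    m <- tr$forest_masks_5yr[[as.character(my)]]$values
    expect_true(all(m[cbind(px$row, px$col)] == 1))
    g <- matrix(0, 96, 96)
    g[cbind(px$row, px$col)] <- 1
    p <- label_patches(fs_grid(g, res_m = 10), 1)
    expect_length(p, 1)  # each footprint is one connected patch
    if (ev$agent[i] == "SRH") {
      # rectangles: bounding box exactly filled
      expect_equal((max(px$row) - min(px$row) + 1) *
                     (max(px$col) - min(px$col) + 1), nrow(px))
    } else if (nrow(px) > 4) {
      expect_gte(fractal_index(p[[1]]), 1)
      fracs <- c(fracs, fractal_index(p[[1]]))
    }
  }
  # region-grown fire footprints are predominantly irregular
  expect_gt(mean(fracs > 1.01), 0.8)
})

test_that("disturbed forest fraction tracks the schedule target", {
  sched <- do.call(rbind, lapply(seq(1990, 2015, by = 5), function(y)
    data.frame(year = y, agent = c("SRF", "NSR"), count = 1L,
               npix_min = 30L, npix_max = 30L,
               dnbr_min = c(0.4, 0.15), dnbr_max = c(0.4, 0.15),
               duration_min = 1L, duration_max = 1L)))
  cfg <- scenario_config(grid_rows = 80, grid_cols = 80, seed = 5,
                         disturbance_schedule = sched,
                         trajectory_noise_sd = 0)
  tr <- generate_scenario(cfg)
  forest_px <- sum(tr$base_landcover$values ==
                     landcover_classes()[["forest"]])
  target <- sum(sched$count * sched$npix_min) / forest_px
  got <- nrow(unique(tr$event_pixels[, c("row", "col")])) / forest_px
  expect_lt(abs(got - target), 0.02)
})

test_that("weather generator: seasonality, anomalies, determinism", {
  cfg0 <- small_cfg(weather_noise_sd = 0)
  w0 <- generate_weather(cfg0)
  s0 <- seasonal_series(w0)
  expect_equal(length(unique(round(s0$mean_fwi, 10))), 1)
  expect_equal(length(unique(round(s0$mean_dc, 10))), 1)

  cfga <- small_cfg(weather_anomaly_years = c(2007))
  wa <- generate_weather(cfga)
  sa <- seasonal_series(wa)
  for (ix in c("mean_fwi", "mean_isi", "mean_dc")) {
    z <- zscore_series(sa[[ix]], sa$year, threshold = 2)
    expect_true(z$abnormal[z$year == 2007])
  }
  expect_identical(generate_weather(cfga), generate_weather(cfga))
  empty <- small_cfg()
  empty$years <- integer()
  expect_error(generate_weather(empty), "empty")
})

test_that("reference samples attach labels and honour strata", {
  set.seed(3)
  truth <- fs_grid(matrix(sample(1:3, 100, replace = TRUE), 10, 10),
                   res_m = 10)
  # identity map: full agreement
  s <- generate_reference_sample(truth, truth, 60, seed = 4)
  expect_true(all(s$mapped_class == s$reference_class))

  # census without replacement covers every cell exactly once
  cs <- generate_reference_sample(truth, truth, 100, seed = 4)
  expect_equal(nrow(unique(cs[, c("row", "col")])), 100)
  expect_error(generate_reference_sample(truth, truth, 101, seed = 1),
               "exceeds")

  # a mapped class with zero cells contributes nothing and is reported
  map2 <- truth
  map2$values[map2$values == 3] <- 1
  s2 <- generate_reference_sample(truth, map2, 50, seed = 5,
                                  stratified = TRUE)
  expect_false("3" %in% s2$stratum)
  labels <- truth$values[cbind(s2$row, s2$col)]
  expect_equal(labels, s2$reference_class)
})

test_that("simulated trajectories expose their truth losslessly", {
  sim <- simulate_trajectories(50, seed = 2, noise_sd = 0)
  for (i in c(1, 25, 50)) {
    tr <- sim$truth[i, ]
    k <- match(tr$onset_year, sim$years)
    expect_equal(sim$nbr[i, k - 1], tr$baseline)
    expect_equal(sim$nbr[i, k + tr$duration - 1],
                 tr$baseline - tr$magnitude)
  }
  expect_identical(simulate_trajectories(50, seed = 2)$nbr,
                   simulate_trajectories(50, seed = 2)$nbr)
})

test_that("write_scenario produces a readable plain-text bundle", {
  tr <- generate_scenario(small_cfg())
  dir <- withr::local_tempdir()
  write_scenario(tr, dir)
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_equal(man$kind, "firescape-scenario")
  expect_true(all(file.exists(file.path(dir, man$files))))
  lc <- read_asc(file.path(dir, "landcover_2021.asc"))
  expect_equal(lc$values, tr$landcover_by_year[["2021"]]$values)
  ev <- read.csv(file.path(dir, "events.csv"))
  expect_equal(nrow(ev), nrow(tr$events))
})
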