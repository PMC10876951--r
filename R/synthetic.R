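#' Scenario configuration for the synthetic landscape generator
#'
#' Describes a self-contained test landscape: a nine-class land-cover
#' mosaic, a schedule of disturbance events of three agent types with
#' distinct spectral and geometric signatures, per-pixel annual spectral
#' index trajectories, and a daily fire-weather series. Defaults emulate a
#' fragmented mosaic of croplands and forest patches with a moderate
#' disturbance regime; see [default_disturbance_schedule()].
#'
#' @param grid_rows,grid_cols landscape dimensions in cells.
#' @param resolution_m cell size (default 10 m).
#' @param class_proportions named fractions over [landcover_classes()]
#'   names, summing to 1.
#' @param disturbance_schedule `data.frame` with columns `year`, `agent`
#'   (`SRF`/`SRH`/`NSR`), `count`, `npix_min`, `npix_max`, `dnbr_min`,
#'   `dnbr_max`, `duration_min`, `duration_max`. SRH footprints are
#'   rectangles; SRF/NSR grow irregular patches. NSR severity must stay
#'   below 0.25 delta-NBR, SRF at or above 0.25.
#' @param trajectory_noise_sd Gaussian noise sd added to every index-year
#'   observation (NBR units, default 0.02).
#' @param weather_anomaly_years years receiving an additive March-September
#'   fire-weather shift of `weather_anomaly_scale` within-year standard
#'   deviations (default none).
#' @param weather_noise_sd multiplier on the weather generator's daily and
#'   between-year noise (default 1; 0 gives a purely deterministic cycle).
#' @param weather_anomaly_scale anomaly shift in within-year sd units
#'   (default 2.5, i.e. at least the advertised 2).
#' @param years simulated period (default 1986:2022).
#' @param seed integer RNG seed; identical seed and config give
#'   bit-identical outputs.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(grid_rows = 96, grid_cols = 96,
                            resolution_m = 10,
                            class_proportions = default_class_proportions(),
                            disturbance_schedule =
                              default_disturbance_schedule(),
                            trajectory_noise_sd = 0.02,
                            weather_anomaly_years = integer(),
                            weather_noise_sd = 1,
                            weather_anomaly_scale = 2.5,
                            years = 1986:2022,
                            seed = 1) {
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class proportions must sum to 1", call. = FALSE)
  if (!setequal(names(class_proportions), names(landcover_classes())))
    stop("class_proportions must name all nine classes", call. = FALSE)
  if (nrow(disturbance_schedule)) {
    if (!all(disturbance_schedule$year %in% years))
      stop("scheduled years outside the simulated period", call. = FALSE)
    if (!all(disturbance_schedule$agent %in% c("SRF", "SRH", "NSR")))
      stop("unknown agent in schedule", call. = FALSE)
    nsr <- disturbance_schedule$agent == "NSR"
    if (any(disturbance_schedule$dnbr_max[nsr] >= 0.25))
      stop("NSR severities must be < 0.25 delta-NBR", call. = FALSE)
    if (any(disturbance_schedule$dnbr_min[!nsr] < 0.25))
      stop("SRF/SRH severities must be >= 0.25 delta-NBR", call. = FALSE)
  }
  if (length(weather_anomaly_years) &&
      !all(weather_anomaly_years %in% years))
    stop("anomaly years outside the simulated period", call. = FALSE)
  structure(list(
    grid_rows = grid_rows, grid_cols = grid_cols,
    resolution_m = resolution_m, class_proportions = class_proportions,
    disturbance_schedule = disturbance_schedule,
    trajectory_noise_sd = trajectory_noise_sd,
    weather_anomaly_years = weather_anomaly_years,
    weather_noise_sd = weather_noise_sd,
    weather_anomaly_scale = weather_anomaly_scale,
    years = years, seed = as.integer(seed)),
    class = "scenario_config")
}

#' @rdname scenario_config
#' @export
default_class_proportions <- function() {
  c(bare_soil = 0.04, built_up = 0.04, burned_forest = 0.03,
    cropland = 0.25, forest = 0.35, grassland = 0.12, water = 0.04,
    wetland = 0.05, woodland = 0.08)
}

#' Default disturbance schedule
#'
#' A pre-war background regime (one fire, one harvest and one
#' non-stand-replacing event every fourth year 1988-2020) plus a 2022
#' war-damage pulse of fires and low-severity shelling fires. Severities
#' respect the agent conventions: stand-replacing fire at or above 0.25
#' delta-NBR, non-stand-replacing below 0.25.
#'
#' @return Schedule `data.frame` as required by [scenario_config()].
#' @export
default_disturbance_schedule <- function() {
  prewar <- do.call(rbind, lapply(seq(1988, 2020, by = 4), function(y) {
    data.frame(
      year = y, agent = c("SRF", "SRH", "NSR"), count = 1L,
      npix_min = c(16L, 12L, 6L), npix_max = c(60L, 40L, 24L),
      dnbr_min = c(0.30, 0.40, 0.12), dnbr_max = c(0.70, 0.70, 0.24),
      duration_min = 1L, duration_max = c(3L, 1L, 2L))
  }))
  war <- data.frame(
    year = 2022L, agent = c("SRF", "NSR"), count = c(4L, 4L),
    npix_min = c(20L, 6L), npix_max = c(60L, 20L),
    dnbr_min = c(0.30, 0.12), dnbr_max = c(0.70, 0.24),
    duration_min = 1L, duration_max = 1L)
  rbind(prewar, war)
}

# circular box blur, separable, used to build spatially coherent noise
.boxblur <- function(m, k) {
  w <- rep(1 / k, k)
  m <- apply(m, 2, function(col) stats::filter(col, w, circular = TRUE))
  t(apply(t(m), 2, function(row) stats::filter(row, w, circular = TRUE)))
}

# nine-class mosaic: multi-scale smoothed Gaussian noise thresholded at the
# class-proportion quantiles, giving spatially coherent patches
.make_mosaic <- function(nr, nc, proportions) {
  z1 <- .boxblur(matrix(stats::rnorm(nr * nc), nr, nc), 5)
  z2 <- .boxblur(matrix(stats::rnorm(nr * nc), nr, nc), 17)
  field <- 0.35 * z1 / stats::sd(z1) + z2 / stats::sd(z2)
  codes <- landcover_classes()[names(proportions)]
  breaks <- stats::quantile(field, c(0, cumsum(proportions)), names = FALSE)
  breaks[1] <- -Inf; breaks[length(breaks)] <- Inf
  cls <- as.integer(cut(field, breaks, labels = FALSE,
                        include.lowest = TRUE))
  matrix(codes[cls], nr, nc)
}

# exact-size rectangle dims with bounded aspect ratio
.rect_dims <- function(n) {
  div <- which(n %% seq_len(n) == 0)
  h <- div[which.min(abs(div - sqrt(n)))]
  c(h, n %/% h)
}

# all upper-left corners where an h x w all-eligible block fits, found
# exactly with a summed-area table
.rect_positions <- function(eligible, h, w) {
  nr <- nrow(eligible); nc <- ncol(eligible)
  if (h > nr || w > nc) return(NULL)
  sat <- apply(apply(eligible * 1, 2, cumsum), 1, cumsum)
  sat <- t(sat)  # sat[r, c] = sum of eligible[1:r, 1:c]
  z <- matrix(0, nr + 1L, nc + 1L)
  z[-1, -1] <- sat
  r0 <- seq_len(nr - h + 1L); c0 <- seq_len(nc - w + 1L)
  block <- z[r0 + h, c0 + w, drop = FALSE] - z[r0, c0 + w, drop = FALSE] -
    z[r0 + h, c0, drop = FALSE] + z[r0, c0, drop = FALSE]
  which(block == h * w, arr.ind = TRUE)
}

# place a rectangular patch of exactly npix eligible cells; NULL on failure
.place_rect <- function(eligible, npix) {
  div <- which(npix %% seq_len(npix) == 0)
  div <- div[order(abs(div - sqrt(npix)))]
  dims <- list()
  for (h in div) {
    w <- npix %/% h
    if (max(h, w) / min(h, w) > 8 && length(dims)) break
    dims <- c(dims, list(c(h, w)))
  }
  dims <- unique(dims)
  if (stats::runif(1) < 0.5 && length(dims) > 1L)
    dims <- c(dims[1], rev(dims[-1]))
  for (dd in dims) {
    pos <- .rect_positions(eligible, dd[1], dd[2])
    if (!is.null(pos) && nrow(pos)) {
      k <- pos[sample.int(nrow(pos), 1L), ]
      return(as.matrix(expand.grid(row = k[1]:(k[1] + dd[1] - 1L),
                                   col = k[2]:(k[2] + dd[2] - 1L))))
    }
  }
  NULL
}

# irregular patch by seeded region growing: random accretion from a random
# ignition cell across 4-neighbours
.place_irregular <- function(eligible, npix, tries = 50) {
  nr <- nrow(eligible); nc <- ncol(eligible)
  starts <- which(eligible)
  if (!length(starts)) return(NULL)
  for (t in seq_len(tries)) {
    start <- starts[sample.int(length(starts), 1L)]
    inpatch <- integer(0)
    frontier <- start
    avail <- eligible
    while (length(inpatch) < npix && length(frontier)) {
      pick <- frontier[sample.int(length(frontier), 1L)]
      frontier <- frontier[frontier != pick]
      if (!avail[pick]) next
      avail[pick] <- FALSE
      inpatch <- c(inpatch, pick)
      r <- ((pick - 1L) %% nr) + 1L
      co <- ((pick - 1L) %/% nr) + 1L
      for (dd in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        r2 <- r + dd[1]; c2 <- co + dd[2]
        if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc &&
            avail[r2 + (c2 - 1L) * nr])
          frontier <- c(frontier, r2 + (c2 - 1L) * nr)
      }
    }
    if (length(inpatch) >= npix) {
      idx <- inpatch[seq_len(npix)]
      return(cbind(row = ((idx - 1L) %% nr) + 1L,
                   col = ((idx - 1L) %/% nr) + 1L))
    }
  }
  NULL
}

# per-class baseline index values used by the trajectory synthesiser
.class_baselines <- function() {
  rbind(
    bare_soil     = c(nbr = 0.10, ndvi = 0.12, tcb = 0.45, tcg = 0.05, tcw = -0.15),
    built_up      = c(nbr = 0.05, ndvi = 0.10, tcb = 0.40, tcg = 0.05, tcw = -0.10),
    burned_forest = c(nbr = 0.15, ndvi = 0.20, tcb = 0.30, tcg = 0.10, tcw = -0.05),
    cropland      = c(nbr = 0.30, ndvi = 0.45, tcb = 0.35, tcg = 0.25, tcw = -0.05),
    forest        = c(nbr = 0.68, ndvi = 0.82, tcb = 0.25, tcg = 0.40, tcw = 0.10),
    grassland     = c(nbr = 0.35, ndvi = 0.50, tcb = 0.38, tcg = 0.28, tcw = -0.02),
    water         = c(nbr = -0.20, ndvi = -0.10, tcb = 0.05, tcg = -0.05, tcw = 0.30),
    wetland       = c(nbr = 0.45, ndvi = 0.55, tcb = 0.20, tcg = 0.25, tcw = 0.15),
    woodland      = c(nbr = 0.55, ndvi = 0.68, tcb = 0.30, tcg = 0.35, tcw = 0.05))
}

# Agent-specific multipliers mapping a delta-NBR severity onto the other
# index changes, all in "drop" convention (positive = index decreases by
# mult * d_nbr). Harvest brightens the site, so its tcb multiplier is
# negative; fire chars the canopy and darkens it.
.agent_spectral <- function(agent) {
  switch(agent,
         SRF = c(ndvi = 0.80, tcb = 0.15, tcg = 0.60, tcw = 0.50),
         SRH = c(ndvi = 0.75, tcb = -0.40, tcg = 0.65, tcw = 0.45),
         NSR = c(ndvi = 0.60, tcb = 0.05, tcg = 0.40, tcw = 0.30))
}

#' Generate a synthetic landscape with its full disturbance history
#'
#' Builds the nine-class mosaic, places every scheduled event inside the
#' contemporaneous forest cover (rectangles for harvest, region-grown
#' irregular footprints for fire and non-stand-replacing events), evolves
#' the land cover where events occur, synthesises annual per-pixel
#' NBR/NDVI/Tasseled Cap trajectories with Gaussian observation noise, and
#' attaches 5-yearly forest masks and the daily weather series. The
#' returned truth is lossless: every injected event's year, agent,
#' severity and footprint is recorded.
#'
#' @param config a [scenario_config()].
#' @return List of class `scenario_truth`: `landcover_by_year` (named list
#'   of categorical `fs_grid`s), `base_landcover`, `events` (data.frame),
#'   `event_pixels` (data.frame `event_id`, `row`, `col`),
#'   `forest_masks_5yr` (named list of binary `fs_grid`s at 1986, 1990,
#'   1995, ..., 2020), `stack` (annual `index_stack`), `damage_2022`
#'   (binary `fs_grid` truth mask), `weather`, `config`.
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  nr <- config$grid_rows; nc <- config$grid_cols
  res <- config$resolution_m
  codes <- landcover_classes()
  years <- config$years

  base <- .make_mosaic(nr, nc, config$class_proportions)

  # --- event placement, year by year ------------------------------------
  lc <- base
  mask_years <- seq(1990, max(years) - 2, by = 5)
  mask_years <- c(min(years), mask_years[mask_years > min(years)])
  forest_masks <- list()
  landcover_by_year <- list()
  events <- list()
  event_pixels <- list()
  eid <- 0L
  sched <- config$disturbance_schedule
  # effect bookkeeping for land-cover evolution
  pending <- list()  # each: pixels, agent, year
  last_mask <- (base == codes[["forest"]]) * 1

  for (y in years) {
    # land-cover state for year y from past events
    lc <- base
    for (ev in pending) {
      el <- y - ev$year
      if (el < 0) next
      if (ev$agent == "SRF" && el <= 9) lc[ev$pixels] <- codes[["burned_forest"]]
      if (ev$agent == "SRH") {
        if (el <= 3) lc[ev$pixels] <- codes[["bare_soil"]]
        else if (el <= 7) lc[ev$pixels] <- codes[["grassland"]]
      }
    }
    if (y %in% mask_years) {
      last_mask <- (lc == codes[["forest"]]) * 1
      forest_masks[[as.character(y)]] <-
        fs_grid(last_mask, res_m = res)
    }
    rows <- sched[sched$year == y, , drop = FALSE]
    if (nrow(rows)) {
      used <- matrix(FALSE, nr, nc)
      for (k in seq_len(nrow(rows))) {
        s <- rows[k, ]
        for (i in seq_len(s$count)) {
          eligible <- (lc == codes[["forest"]]) & (last_mask == 1) & !used
          npix <- if (s$npix_max > s$npix_min)
            sample(s$npix_min:s$npix_max, 1L) else s$npix_min
          if (s$agent == "SRH" && s$npix_max > s$npix_min) {
            # prefer harvest sizes factorisable into compact rectangles
            for (draw in 1:20) {
              dd <- .rect_dims(npix)
              if (max(dd) / min(dd) <= 4) break
              npix <- sample(s$npix_min:s$npix_max, 1L)
            }
          }
          px <- if (s$agent == "SRH") .place_rect(eligible, npix)
                else .place_irregular(eligible, npix)
          if (is.null(px)) {
            warning("could not place ", s$agent, " event of ", npix,
                    " pixels in ", y)
            next
          }
          eid <- eid + 1L
          dnbr <- stats::runif(1, s$dnbr_min, s$dnbr_max)
          dur <- if (s$duration_max > s$duration_min)
            sample(s$duration_min:s$duration_max, 1L) else s$duration_min
          events[[eid]] <- data.frame(
            event_id = eid, year = y, agent = s$agent, d_nbr = dnbr,
            duration = dur, n_pixels = nrow(px))
          event_pixels[[eid]] <- data.frame(
            event_id = eid, row = px[, "row"], col = px[, "col"])
          used[px] <- TRUE
          pending[[length(pending) + 1L]] <-
            list(pixels = px, agent = s$agent, year = y)
        }
      }
      # re-derive state after this year's events for bookkeeping next year
    }
    landcover_by_year[[as.character(y)]] <-
      fs_grid(lc, res_m = res, classes = codes)
  }

  events <- if (length(events)) do.call(rbind, events) else
    data.frame(event_id = integer(), year = integer(), agent = character(),
               d_nbr = numeric(), duration = integer(),
               n_pixels = integer())
  event_pixels <- if (length(event_pixels)) do.call(rbind, event_pixels)
    else data.frame(event_id = integer(), row = integer(), col = integer())

  # --- trajectories ------------------------------------------------------
  ny <- length(years)
  bl <- .class_baselines()
  base_name <- names(codes)[match(base, codes)]
  layers <- lapply(c(nbr = "nbr", ndvi = "ndvi", tcb = "tcb", tcg = "tcg",
                     tcw = "tcw"), function(l) {
    array(rep(matrix(bl[base_name, l], nr, nc), ny), dim = c(nr, nc, ny))
  })
  if (nrow(events)) {
    for (e in seq_len(nrow(events))) {
      ev <- events[e, ]
      px <- event_pixels[event_pixels$event_id == ev$event_id,
                         c("row", "col")]
      mult <- c(nbr = 1, .agent_spectral(ev$agent))
      # e-folding recovery times (years): replanted/reseeded stands close
      # canopy over decades, low-severity damage recovers within a few years
      rec_rate <- if (ev$agent == "NSR") 4 else 12
      # the observation of the event year already shows the first step of
      # the drop (leaf-on composites postdate the event season); severity
      # is complete at year + duration - 1, recovery follows
      for (t in seq_len(ny)) {
        el <- years[t] - ev$year
        if (el < 0) next
        deficit <- if (el < ev$duration) ev$d_nbr * (el + 1) / ev$duration
                   else ev$d_nbr * exp(-(el - ev$duration + 1) / rec_rate)
        for (l in names(layers)) {
          idx <- cbind(px$row, px$col, t)
          layers[[l]][idx] <- layers[[l]][idx] - deficit * mult[[l]]
        }
      }
    }
  }
  sd <- config$trajectory_noise_sd
  if (sd > 0) {
    for (l in names(layers)) {
      layers[[l]] <- layers[[l]] + stats::rnorm(nr * nc * ny, 0, sd)
    }
  }
  for (l in c("nbr", "ndvi"))
    layers[[l]] <- pmin(pmax(layers[[l]], -1), 1)
  stack <- index_stack(layers, epochs = years, res_m = res)

  dmg <- matrix(0, nr, nc)
  war <- events$event_id[events$year == 2022]
  if (length(war)) {
    wp <- event_pixels[event_pixels$event_id %in% war, ]
    dmg[cbind(wp$row, wp$col)] <- 1
  }

  structure(list(
    landcover_by_year = landcover_by_year,
    base_landcover = fs_grid(base, res_m = res, classes = codes),
    events = events, event_pixels = event_pixels,
    forest_masks_5yr = forest_masks,
    stack = stack,
    damage_2022 = fs_grid(dmg, res_m = res),
    weather = generate_weather(config),
    config = config), class = "scenario_truth")
}

#' @export
print.scenario_truth <- function(x, ...) {
  cat(sprintf("<scenario_truth> %d x %d cells, %d years, %d events\n",
              x$config$grid_rows, x$config$grid_cols,
              length(x$config$years), nrow(x$events)))
  invisible(x)
}

#' Generate a synthetic daily fire-weather series
#'
#' Daily FWI, ISI and DC over the simulated period on a fixed 365-day
#' calendar, as a summer-peaked seasonal cycle plus a between-year random
#' effect and daily noise (both scaled by `weather_noise_sd`). Years in
#' `weather_anomaly_years` receive an additive March-September shift of
#' `weather_anomaly_scale` times the within-year (seasonal) standard
#' deviation of each index.
#'
#' @param config a [scenario_config()].
#' @return `data.frame`: `year`, `doy`, `fwi`, `isi`, `dc`.
#' @export
generate_weather <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  years <- config$years
  if (!length(years)) stop("empty year range", call. = FALSE)
  set.seed(config$seed + 131071L)
  doy <- 1:365
  shape <- exp(-((doy - 200) / 80)^2)
  base <- list(fwi = 5 + 20 * shape, isi = 2 + 8 * shape,
               dc = 50 + 350 * shape)
  daily_sd <- c(fwi = 2, isi = 0.8, dc = 20) * config$weather_noise_sd
  year_sd <- c(fwi = 0.6, isi = 0.25, dc = 12) * config$weather_noise_sd
  within_sd <- vapply(base, stats::sd, 0)
  season <- doy >= 60 & doy <= 273  # 1 Mar - 30 Sep, non-leap calendar
  out <- lapply(years, function(y) {
    df <- data.frame(year = y, doy = doy)
    for (ix in c("fwi", "isi", "dc")) {
      v <- base[[ix]] + stats::rnorm(1, 0, year_sd[[ix]]) +
        stats::rnorm(365, 0, daily_sd[[ix]])
      if (y %in% config$weather_anomaly_years)
        v[season] <- v[season] +
          config$weather_anomaly_scale * within_sd[[ix]]
      df[[ix]] <- pmax(v, 0)
    }
    df
  })
  do.call(rbind, out)
}

#' Draw a reference sample from a mapped landscape
#'
#' Samples cell locations uniformly at random (or stratified by mapped
#' class, proportionally allocated) and attaches the mapped and true
#' labels, emulating the reference data collection of a map accuracy
#' assessment. Sampling is without replacement by default.
#'
#' @param truth_grid categorical `fs_grid` of true classes.
#' @param map_grid categorical `fs_grid` of mapped classes (same
#'   geometry).
#' @param n sample size (>= 1; at most the cell count when
#'   `replace = FALSE`).
#' @param seed integer seed.
#' @param stratified stratify by mapped class (default `FALSE`)?
#' @param replace sample with replacement (default `FALSE`)?
#' @return `data.frame`: `row`, `col`, `stratum` (mapped class),
#'   `mapped_class`, `reference_class`. Mapped classes with zero cells
#'   contribute no samples and are listed in the `empty_strata` attribute.
#' @export
generate_reference_sample <- function(truth_grid, map_grid, n, seed = 1,
                                      stratified = FALSE, replace = FALSE) {
  stopifnot_same_geometry(truth_grid, map_grid)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  npix <- length(map_grid$values)
  if (!replace && n > npix)
    stop("n exceeds the cell count for sampling without replacement",
         call. = FALSE)
  set.seed(seed)
  if (stratified) {
    classes <- sort(unique(as.vector(map_grid$values)))
    sizes <- vapply(classes, function(k)
      sum(map_grid$values == k, na.rm = TRUE), 0)
    alloc <- floor(n * sizes / sum(sizes))
    rem <- n - sum(alloc)
    if (rem > 0) {
      frac <- n * sizes / sum(sizes) - alloc
      alloc[order(-frac)[seq_len(rem)]] <-
        alloc[order(-frac)[seq_len(rem)]] + 1L
    }
    idx <- unlist(lapply(seq_along(classes), function(j) {
      cells <- which(map_grid$values == classes[j])
      if (!length(cells) || alloc[j] == 0L) return(integer(0))
      cells[sample.int(length(cells), min(alloc[j], length(cells)),
                       replace = replace)]
    }))
    empty <- classes[sizes == 0]
  } else {
    idx <- sample.int(npix, n, replace = replace)
    empty <- numeric(0)
  }
  nr <- nrow(map_grid$values)
  out <- data.frame(
    row = ((idx - 1L) %% nr) + 1L,
    col = ((idx - 1L) %/% nr) + 1L,
    stratum = as.character(map_grid$values[idx]),
    mapped_class = map_grid$values[idx],
    reference_class = truth_grid$values[idx])
  attr(out, "empty_strata") <- empty
  out
}

#' Simulate single-disturbance NBR trajectories
#'
#' Annual trajectories with one injected loss episode each: a flat
#' pre-disturbance canopy baseline, a linear decline of the drawn
#' magnitude over the drawn duration, and a persistent post-disturbance
#' level (stand-replacing losses do not close canopy again within the
#' window). Durations default to 60/30/10% for 1/2/3-year declines —
#' most stand-replacing losses express within a single composite year.
#' Gaussian observation noise is added everywhere.
#'
#' @param n number of trajectories.
#' @param noise_sd observation noise sd in NBR units (default 0.03).
#' @param mag_range magnitude (NBR drop) range, drawn uniformly
#'   (default 0.2-0.7).
#' @param onset_years years eligible as the first declining observation
#'   (default 1990-2018, keeping a baseline and a tail inside the window).
#' @param duration_probs probabilities of 1, 2 and 3-year declines.
#' @param years observation years (default 1986:2022).
#' @param seed integer seed.
#' @return List: `years`, `nbr` (n x length(years) matrix) and `truth`
#'   (`data.frame` with `onset_year`, `duration`, `magnitude`,
#'   `baseline`).
#' @export
simulate_trajectories <- function(n, noise_sd = 0.03,
                                  mag_range = c(0.2, 0.7),
                                  onset_years = 1990:2018,
                                  duration_probs = c(0.6, 0.3, 0.1),
                                  years = 1986:2022, seed = 1) {
  set.seed(seed)
  onset <- sample(onset_years, n, replace = TRUE)
  dur <- sample(1:3, n, replace = TRUE, prob = duration_probs)
  mag <- stats::runif(n, mag_range[1], mag_range[2])
  base <- stats::runif(n, 0.55, 0.75)
  m <- matrix(rep(base, length(years)), n, length(years))
  for (t in seq_along(years)) {
    el <- years[t] - onset
    ramp <- el >= 0 & el < dur
    m[ramp, t] <- base[ramp] - mag[ramp] * (el[ramp] + 1) / dur[ramp]
    done <- el >= dur
    m[done, t] <- base[done] - mag[done]
  }
  m <- m + matrix(stats::rnorm(n * length(years), 0, noise_sd), n)
  list(years = years, nbr = pmin(pmax(m, -1), 1),
       truth = data.frame(onset_year = onset, duration = dur,
                          magnitude = mag, baseline = base))
}

#' Simulate patch features with the designed agent contrasts
#'
#' Draws disturbance-patch feature vectors straight from the agent
#' signatures the landscape generator encodes: harvest patches are
#' rectangular (fractal index about 1) and markedly brighter after the
#' event; fires are large, irregular and severe (delta-NBR at or above
#' 0.25); non-stand-replacing events are low-severity (delta-NBR below
#' 0.25), small and irregular. Used to exercise the agent classifier at a
#' chosen sample size without rasterising thousands of patches.
#'
#' @param n_per_class patches per agent class (default 200).
#' @param seed integer seed.
#' @return List with `features` (data.frame over `agent_feature_cols()`)
#'   and `labels` (factor SRF/SRH/NSR).
#' @export
simulate_agent_features <- function(n_per_class = 200, seed = 1) {
  set.seed(seed)
  n <- n_per_class
  ru <- stats::runif; rn <- stats::rnorm
  mk <- function(agent, d_nbr, area_ha, frac, duration, pre_nbr) {
    sp <- .agent_spectral(agent)
    data.frame(
      d_nbr = d_nbr,
      d_ndvi = sp[["ndvi"]] * d_nbr + rn(n, 0, 0.03),
      d_tcb = sp[["tcb"]] * d_nbr + rn(n, 0, 0.02),
      d_tcg = sp[["tcg"]] * d_nbr + rn(n, 0, 0.03),
      d_tcw = sp[["tcw"]] * d_nbr + rn(n, 0, 0.03),
      pre_nbr = pre_nbr, duration = duration, rate = d_nbr / duration,
      area_ha = area_ha, frac = frac)
  }
  srf <- mk("SRF", d_nbr = ru(n, 0.30, 0.80),
            area_ha = exp(ru(n, log(2), log(100))),
            frac = ru(n, 1.15, 1.60),
            duration = sample(1:3, n, TRUE, prob = c(0.6, 0.3, 0.1)),
            pre_nbr = rn(n, 0.68, 0.04))
  srh <- mk("SRH", d_nbr = ru(n, 0.40, 0.70),
            area_ha = ru(n, 0.5, 5),
            frac = 1 + abs(rn(n, 0, 0.015)),
            duration = rep(1, n), pre_nbr = rn(n, 0.70, 0.03))
  nsr <- mk("NSR", d_nbr = ru(n, 0.10, 0.249),
            area_ha = ru(n, 0.2, 8),
            frac = ru(n, 1.10, 1.50),
            duration = sample(1:2, n, TRUE), pre_nbr = rn(n, 0.60, 0.05))
  list(features = rbind(srf, srh, nsr),
       labels = factor(rep(c("SRF", "SRH", "NSR"), each = n),
                       levels = c("SRF", "SRH", "NSR")))
}

#' Write a scenario to a directory of plain-text files
#'
#' Land cover and masks as ESRI ASCII grids, events/samples/weather as
#' CSV, plus a YAML manifest describing the bundle.
#'
#' @param truth a `scenario_truth`.
#' @param dir output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_scenario <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_asc(truth$landcover_by_year[["2021"]],
            file.path(dir, "landcover_2021.asc"))
  write_asc(truth$landcover_by_year[["2022"]],
            file.path(dir, "landcover_2022.asc"))
  last_mask <- truth$forest_masks_5yr[[length(truth$forest_masks_5yr)]]
  write_asc(last_mask, file.path(dir, "forest_mask.asc"))
  write_asc(truth$damage_2022, file.path(dir, "damage_truth.asc"))
  utils::write.csv(truth$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(truth$event_pixels, file.path(dir, "event_pixels.csv"),
                   row.names = FALSE)
  utils::write.csv(truth$weather, file.path(dir, "weather.csv"),
                   row.names = FALSE)
  manifest <- list(
    kind = "firescape-scenario",
    grid = list(rows = truth$config$grid_rows,
                cols = truth$config$grid_cols,
                resolution_m = truth$config$resolution_m),
    years = range(truth$config$years),
    seed = truth$config$seed,
    n_events = nrow(truth$events),
    files = c("landcover_2021.asc", "landcover_2022.asc",
              "forest_mask.asc", "damage_truth.asc", "events.csv",
              "event_pixels.csv", "weather.csv"))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
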