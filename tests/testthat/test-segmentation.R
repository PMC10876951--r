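yrs37 <- 1986:2022

test_that("fit_vertices: linear series keeps only the endpoints", {
  v <- fit_vertices(yrs37, seq(0.2, 0.7, length.out = 37))
  expect_identical(v, c(1986L, 2022L))
  expect_error(fit_vertices(2000:2002, c(1, 2, 3)), "at least 4")
  expect_error(fit_vertices(c(2000, 2000, 2001, 2002), rep(1, 4)),
               "strictly increasing")
})

test_that("fit_vertices localises a clean step change", {
  vals <- c(rep(0.7, 20), rep(0.2, 17))
  v <- fit_vertices(yrs37, vals)
  expect_true(all(c(2005, 2006) %in% v))  # last high, first low year
  expect_length(v, 4)
})

test_that("fit_vertices equals exhaustive best-subset segmentation", {
  sse_of <- function(yrs, vals, verts) {
    f <- stats::approx(yrs[verts], vals[verts], xout = yrs)$y
    sum((vals - f)^2)
  }
  set.seed(12)
  for (rep in 1:6) {
    n <- 12
    yrs <- 2000 + seq_len(n)
    vals <- c(rep(0.7, 4), 0.35, 0.3, rep(0.31, 3), 0.1, 0.12, 0.13) +
      rnorm(n, 0, 0.015)
    v <- fit_vertices(yrs, vals, max_segments = 4,
                      rmse_improvement_tol = 1e-9)
    k <- length(v) - 1
    combs <- if (k == 1) list(integer(0)) else
      utils::combn(2:(n - 1), k - 1, simplify = FALSE)
    best <- Inf
    for (cc in combs) best <- min(best, sse_of(yrs, vals, c(1, cc, n)))
    expect_equal(sse_of(yrs, vals, match(v, yrs)), best, tolerance = 1e-10)
  }
})

test_that("fit RMSE is non-increasing in max_segments", {
  set.seed(5)
  vals <- 0.6 + cumsum(rnorm(37, 0, 0.05))
  vals <- pmin(pmax(vals, -1), 1)
  rmse <- vapply(1:6, function(k) {
    v <- fit_vertices(yrs37, vals, max_segments = k,
                      rmse_improvement_tol = 1e-9)
    f <- stats::approx(v, vals[match(v, yrs37)], xout = yrs37)$y
    sqrt(mean((vals - f)^2))
  }, 0)
  expect_true(all(diff(rmse) <= 1e-12))
})

test_that("extract_loss_segments applies threshold and duration rules", {
  vals <- rep(0.7, 37)
  vals[yrs37 >= 2000] <- 0.65  # 0.05 drop: below threshold
  segs <- extract_loss_segments(c(1986, 1999, 2000, 2022), yrs37, vals)
  expect_equal(nrow(segs), 0)

  vals <- rep(0.7, 37)
  vals[yrs37 >= 2000] <- 0.2
  segs <- extract_loss_segments(c(1986, 1999, 2000, 2022), yrs37, vals)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$magnitude, 0.5)
  expect_equal(segs$duration, 1)
  expect_equal(segs$rate, 0.5)
  expect_equal(segs$pre_nbr, 0.7)
  expect_equal(segs$rate * segs$duration, segs$magnitude)

  # drop spread over 4 years is rejected by the duration bound
  vals <- rep(0.7, 37)
  ramp <- yrs37 >= 2000 & yrs37 <= 2004
  vals[ramp] <- seq(0.6, 0.3, length.out = sum(ramp))
  vals[yrs37 > 2004] <- 0.3
  segs <- extract_loss_segments(c(1986, 2000, 2004, 2022), yrs37, vals)
  expect_equal(nrow(segs), 0)
  expect_error(extract_loss_segments(c(1986, 1999.5), yrs37, vals),
               "observation years")
})

test_that("rank_disturbances orders by magnitude with tie rules", {
  expect_identical(rank_disturbances(NULL),
                   list(primary = NULL, secondary = NULL))
  s1 <- data.frame(start_year = 2000, end_year = 2001, magnitude = 0.4,
                   duration = 1, rate = 0.4, pre_nbr = 0.7)
  r <- rank_disturbances(s1)
  expect_equal(r$primary$magnitude, 0.4)
  expect_null(r$secondary)

  s3 <- data.frame(start_year = c(1995, 2005, 2010),
                   end_year = c(1996, 2006, 2011),
                   magnitude = c(0.3, 0.5, 0.2), duration = 1,
                   rate = c(0.3, 0.5, 0.2), pre_nbr = 0.7)
  r <- rank_disturbances(s3)
  expect_equal(r$primary$magnitude, 0.5)
  expect_equal(r$secondary$magnitude, 0.3)

  tie <- data.frame(start_year = c(2010, 1995), end_year = c(2011, 1996),
                    magnitude = 0.4, duration = 1, rate = 0.4,
                    pre_nbr = 0.7)
  expect_equal(rank_disturbances(tie)$primary$start_year, 1995)
})

test_that("year_assignment shifts late-season onsets", {
  expect_equal(year_assignment(2010, 166), 2010L)        # mid June
  expect_equal(year_assignment(2010, 263), 2011L)        # late September
  expect_equal(year_assignment(2010, 263,
                               detection_doy_cutoff = 365), 2010L)
  expect_equal(year_assignment(2010, 232), 2010L)        # boundary stays
})

test_that("fit_trajectory recovers injected losses and never violates rules", {
  sim <- simulate_trajectories(250, seed = 99)
  hit <- 0
  for (i in seq_len(nrow(sim$truth))) {
    ft <- fit_trajectory(sim$years, sim$nbr[i, ])
    segs <- extract_loss_segments(ft$vertices, sim$years, ft$fitted)
    expect_true(all(segs$magnitude >= 0.1))
    expect_true(all(segs$duration %in% 1:3))
    # no overlapping segments
    if (nrow(segs) > 1) {
      o <- order(segs$start_year)
      expect_true(all(segs$start_year[o][-1] >=
                        segs$end_year[o][-nrow(segs)]))
    }
    r <- rank_disturbances(segs)$primary
    if (!is.null(r) && r$start_year + 1 == sim$truth$onset_year[i])
      hit <- hit + 1
  }
  expect_gte(hit / nrow(sim$truth), 0.92)
})

test_that("segment_stack applies pre-disturbance forest masking", {
  cfgs <- scenario_config(grid_rows = 40, grid_cols = 40, seed = 13)
  tr <- generate_scenario(cfgs)
  ever <- Reduce(`+`, lapply(tr$forest_masks_5yr, function(g) g$values))
  pixels <- which(ever > 0, arr.ind = TRUE)[1:150, ]
  segs <- segment_stack(tr$stack, forest_masks = tr$forest_masks_5yr,
                        pixels = pixels)
  expect_true(all(segs$rank %in% c("primary", "secondary")))
  expect_true(all(segs$magnitude >= 0.1))
  expect_true(all(segs$duration %in% 1:3))
  # every retained segment starts on a pixel that was forest at the most
  # recent preceding mask year
  mask_years <- sort(as.integer(names(tr$forest_masks_5yr)))
  for (i in seq_len(min(nrow(segs), 50))) {
    my <- max(mask_years[mask_years <= segs$start_year[i]])
    m <- tr$forest_masks_5yr[[as.character(my)]]
    expect_equal(m$values[segs$row[i], segs$col[i]], 1)
  }
})
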