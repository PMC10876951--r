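#' Vertex fitting for an annual NBR trajectory
#'
#' Simplified temporal segmentation in the LandTrendr spirit: the
#' trajectory is approximated by a piecewise-linear curve through vertex
#' years chosen among the observations. For every candidate segment count
#' k up to `max_segments` the sum-of-squares-optimal vertex set is found
#' exactly by dynamic programming over observation knots (series are
#' short, so this is cheap); k is then the largest segment count whose
#' optimal fit still improves RMSE by at least `rmse_improvement_tol`
#' over k - 1 segments. One-at-a-time greedy insertion was rejected: a
#' single added vertex cannot capture a step change, so greedy stalls on
#' exactly the abrupt-disturbance trajectories this fitter exists for.
#'
#' This keeps the loss-segment semantics downstream analyses rely on
#' (magnitude, duration, rate per inter-vertex segment) without the full
#' LandTrendr regression machinery; recovery-rate and p-value filters of
#' the original algorithm are intentionally not applied.
#'
#' @param years strictly increasing integer years (>= 4 observations).
#' @param values NBR observations, same length as `years`.
#' @param max_segments maximum number of linear segments (default 6).
#' @param rmse_improvement_tol minimum RMSE improvement (NBR units, default
#'   0.01) for a vertex to be accepted.
#' @param despike if `TRUE`, damp single-year spikes that fully recover
#'   with a 3-point median filter before fitting (off by default).
#' @return Sorted integer vector of vertex years (always includes both
#'   endpoints).
#' @export
fit_vertices <- function(years, values, max_segments = 6,
                         rmse_improvement_tol = 0.01, despike = FALSE) {
  n <- length(years)
  if (n < 4L) stop("need at least 4 observations", call. = FALSE)
  if (length(values) != n) stop("years/values length mismatch", call. = FALSE)
  if (any(diff(years) <= 0)) stop("years must be strictly increasing",
                                  call. = FALSE)
  if (despike && n >= 3L) {
    sm <- values
    sm[2:(n - 1)] <- vapply(2:(n - 1), function(i)
      stats::median(values[(i - 1):(i + 1)]), 0)
    values <- sm
  }
  kmax <- min(max_segments, n - 1L)
  # cost[i, j]: SSE of the straight line through observations i and j,
  # evaluated over all observations between them
  cost <- matrix(Inf, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      t <- i:j
      line <- values[i] + (values[j] - values[i]) *
        (years[t] - years[i]) / (years[j] - years[i])
      cost[i, j] <- sum((values[t] - line)^2)
    }
  }
  # DP over knots: best[k, j] = min SSE covering 1..j with k segments
  best <- matrix(Inf, kmax, n)
  choice <- matrix(NA_integer_, kmax, n)
  best[1, ] <- cost[1, ]
  if (kmax >= 2L) {
    for (k in 2:kmax) {
      for (j in (k + 1L):n) {
        prev <- k:(j - 1L)
        tot <- best[k - 1L, prev] + cost[prev, j]
        m <- which.min(tot)
        best[k, j] <- tot[m]
        choice[k, j] <- prev[m]
      }
    }
  }
  rmse_k <- sqrt(best[, n] / n)
  gains <- if (kmax >= 2L) rmse_k[-kmax] - rmse_k[-1] else numeric(0)
  k <- max(c(1L, which(gains >= rmse_improvement_tol) + 1L))
  verts <- n
  j <- n
  while (k >= 2L) {
    j <- choice[k, j]
    verts <- c(j, verts)
    k <- k - 1L
  }
  years[sort(unique(c(1L, verts)))]
}

# continuous piecewise-linear least squares with fixed interior knots
# (truncated-line basis); returns SSE and fitted values
.pwl_fit <- function(x, y, knots) {
  X <- cbind(1, x)
  for (k in knots) X <- cbind(X, pmax(x - k, 0))
  f <- .lm.fit(X, y)
  list(sse = sum(f$residuals^2), fitted = y - f$residuals)
}

#' Fit a trajectory: vertices plus regression-smoothed values
#'
#' Full trajectory fit used by [segment_stack()]: vertex years from
#' [fit_vertices()], then two refinements in the spirit of the original
#' algorithm's regression step. First, vertex values are freed from the
#' noisy observations: the trajectory is re-fitted as a continuous
#' piecewise-linear least-squares curve and each interior vertex is moved
#' within one year of its position whenever that lowers the residual sum
#' of squares. Second, any fitted segment that declines by at least
#' `min_delta` but spans more than `max_duration` years receives one
#' additional vertex at its SSE-optimal interior position (duration-aware
#' densification), so real 1-3 year losses are not lost to a spurious
#' extra year absorbed from the flat neighbourhood.
#'
#' @inheritParams fit_vertices
#' @param min_delta,max_duration loss-segment semantics the densification
#'   step serves (defaults 0.1 NBR and 3 years).
#' @return List with `vertices` (years) and `fitted` (smoothed NBR at
#'   every observation year). Pass both to [extract_loss_segments()].
#' @export
fit_trajectory <- function(years, values, max_segments = 6,
                           rmse_improvement_tol = 0.01, despike = FALSE,
                           min_delta = 0.1, max_duration = 3) {
  verts <- fit_vertices(years, values, max_segments = max_segments,
                        rmse_improvement_tol = rmse_improvement_tol,
                        despike = despike)
  interior <- setdiff(years, range(years))
  kn <- setdiff(verts, range(years))
  sweep_knots <- function(kn) {
    for (i in seq_along(kn)) {
      best <- Inf
      bestp <- kn[i]
      for (p in intersect(kn[i] + (-1:1), setdiff(interior, kn[-i]))) {
        s <- .pwl_fit(years, values, sort(unique(c(kn[-i], p))))$sse
        if (s < best) {
          best <- s
          bestp <- p
        }
      }
      kn[i] <- bestp
      kn <- sort(kn)
    }
    kn
  }
  if (length(kn)) {
    for (s in 1:3) {
      old <- kn
      kn <- sweep_knots(kn)
      if (identical(old, kn)) break
    }
  }
  for (pass in 1:2) {
    f <- .pwl_fit(years, values, kn)
    vv <- sort(unique(c(min(years), kn, max(years))))
    ins <- NULL
    for (k in seq_len(length(vv) - 1L)) {
      i0 <- match(vv[k], years)
      i1 <- match(vv[k + 1L], years)
      if (f$fitted[i0] - f$fitted[i1] >= min_delta &&
          (vv[k + 1L] - vv[k]) > max_duration) {
        best <- f$sse
        bestp <- NA
        for (p in setdiff((vv[k] + 1L):(vv[k + 1L] - 1L), kn)) {
          s <- .pwl_fit(years, values, sort(c(kn, p)))$sse
          if (s < best) {
            best <- s
            bestp <- p
          }
        }
        if (!is.na(bestp)) ins <- c(ins, bestp)
      }
    }
    if (is.null(ins)) break
    kn <- sweep_knots(sort(unique(c(kn, ins))))
  }
  f <- .pwl_fit(years, values, kn)
  list(vertices = sort(unique(c(min(years), kn, max(years)))),
       fitted = f$fitted)
}

#' Extract spectral-loss segments between fitted vertices
#'
#' Every inter-vertex interval whose fitted NBR decreases by at least
#' `min_delta` within at most `max_duration` years becomes a loss segment
#' carrying magnitude (the NBR drop), duration, rate (magnitude/duration)
#' and the pre-disturbance NBR. Smaller or slower declines are discarded:
#' a 0.1 NBR drop is the detection floor and loss episodes are bounded at
#' 1-3 years.
#'
#' @param vertices vertex years from [fit_vertices()].
#' @param years,values the trajectory the vertices were fitted on.
#' @param min_delta minimum fitted NBR drop (default 0.1).
#' @param max_duration maximum segment duration in years (default 3).
#' @return `data.frame` with columns `start_year`, `end_year`, `magnitude`,
#'   `duration`, `rate`, `pre_nbr` (possibly zero rows).
#' @export
extract_loss_segments <- function(vertices, years, values, min_delta = 0.1,
                                  max_duration = 3) {
  vi <- match(vertices, years)
  if (anyNA(vi)) stop("vertices must be observation years", call. = FALSE)
  out <- list()
  for (k in seq_len(length(vertices) - 1L)) {
    y0 <- vertices[k]; y1 <- vertices[k + 1L]
    v0 <- values[vi[k]]; v1 <- values[vi[k + 1L]]
    drop <- v0 - v1
    dur <- y1 - y0
    if (drop >= min_delta && dur >= 1 && dur <= max_duration) {
      out[[length(out) + 1L]] <- data.frame(
        start_year = y0, end_year = y1, magnitude = drop,
        duration = dur, rate = drop / dur, pre_nbr = v0)
    }
  }
  if (!length(out))
    return(data.frame(start_year = integer(), end_year = integer(),
                      magnitude = numeric(), duration = integer(),
                      rate = numeric(), pre_nbr = numeric()))
  do.call(rbind, out)
}

#' Rank loss segments into primary and secondary disturbances
#'
#' Primary is the largest-magnitude loss segment of the pixel, secondary
#' the second largest. Ties break toward the earlier start year, then the
#' larger rate.
#'
#' @param segments `data.frame` from [extract_loss_segments()].
#' @return List with elements `primary` and `secondary` (single-row
#'   data.frames or `NULL`).
#' @export
rank_disturbances <- function(segments) {
  if (is.null(segments) || nrow(segments) == 0L)
    return(list(primary = NULL, secondary = NULL))
  o <- order(-segments$magnitude, segments$start_year, -segments$rate)
  segments <- segments[o, , drop = FALSE]
  list(primary = segments[1, , drop = FALSE],
       secondary = if (nrow(segments) >= 2L) segments[2, , drop = FALSE]
                   else NULL)
}

#' Reported year of a disturbance given its onset day
#'
#' Annual change detection built on leaf-on imagery attributes late-season
#' events to the following year: an onset after the day-of-year cutoff is
#' reported as `year + 1`. The default cutoff (day 232, ~20 August)
#' reproduces that known one-year shift; a cutoff of 365 disables it.
#'
#' @param year calendar year of the onset.
#' @param onset_doy day of year of the onset (1-365).
#' @param detection_doy_cutoff last day still attributed to `year`
#'   (default 232).
#' @return Integer reported year.
#' @export
year_assignment <- function(year, onset_doy, detection_doy_cutoff = 232) {
  stopifnot(onset_doy >= 1, onset_doy <= 366)
  ifelse(onset_doy > detection_doy_cutoff, year + 1L, as.integer(year))
}

#' Segment an entire trajectory stack over a forest mask
#'
#' Runs [fit_trajectory()], [extract_loss_segments()] and
#' [rank_disturbances()] per pixel of the NBR layer, keeping only segments
#' whose pre-disturbance state is forest according to the most recent
#' 5-yearly forest mask at or before the segment start (pre-disturbance
#' masking).
#'
#' @param stack annual `index_stack` with an `nbr` layer.
#' @param forest_masks named list of binary `fs_grid`s keyed by mask year
#'   (e.g. "1986", "1990", ... "2020"), or `NULL` to skip masking.
#' @param pixels optional two-column matrix of (row, col) to restrict to.
#' @param ... passed to [fit_vertices()] / [extract_loss_segments()].
#' @return `data.frame`: `row`, `col`, `rank` ("primary"/"secondary"),
#'   `start_year`, `end_year`, `magnitude`, `duration`, `rate`, `pre_nbr`.
#' @export
segment_stack <- function(stack, forest_masks = NULL, pixels = NULL, ...) {
  dots <- list(...)
  fit_args <- dots[names(dots) %in%
                     c("max_segments", "rmse_improvement_tol", "despike")]
  ext_args <- dots[names(dots) %in% c("min_delta", "max_duration")]
  years <- as.integer(stack$epochs)
  a <- stack$layers[["nbr"]]
  d <- dim(a)
  if (is.null(pixels)) {
    pixels <- as.matrix(expand.grid(row = seq_len(d[1]), col = seq_len(d[2])))
  }
  mask_years <- if (!is.null(forest_masks))
    sort(as.integer(names(forest_masks)))
  res <- vector("list", nrow(pixels))
  for (i in seq_len(nrow(pixels))) {
    r <- pixels[i, 1]; co <- pixels[i, 2]
    traj <- a[r, co, ]
    if (anyNA(traj)) next
    ft <- do.call(fit_trajectory, c(list(years, traj), fit_args, ext_args))
    segs <- do.call(extract_loss_segments,
                    c(list(ft$vertices, years, ft$fitted), ext_args))
    if (!nrow(segs)) next
    if (!is.null(forest_masks)) {
      keep <- vapply(segs$start_year, function(y) {
        my <- mask_years[mask_years <= y]
        if (!length(my)) return(FALSE)
        m <- forest_masks[[as.character(max(my))]]
        isTRUE(m$values[r, co] == 1)
      }, logical(1))
      segs <- segs[keep, , drop = FALSE]
      if (!nrow(segs)) next
    }
    rk <- rank_disturbances(segs)
    rows <- rbind(rk$primary, rk$secondary)
    res[[i]] <- data.frame(
      row = r, col = co,
      rank = c("primary", "secondary")[seq_len(nrow(rows))],
      rows, row.names = NULL)
  }
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res))
    return(data.frame(row = integer(), col = integer(), rank = character(),
                      start_year = integer(), end_year = integer(),
                      magnitude = numeric(), duration = integer(),
                      rate = numeric(), pre_nbr = numeric()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
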