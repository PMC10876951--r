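#' Fire-season mean of daily fire-weather indices
#'
#' Averages FWI, ISI and DC over 1 March - 30 September inclusive. The
#' window spans 214 calendar days in any year (a leap year only shifts
#' the day-of-year bounds; February 29 lies outside the window), and the
#' mean is always a simple average of the available in-window days.
#' Missing days are excluded and reflected in the completeness fraction.
#'
#' @param weather `data.frame` with columns `year`, `doy` (day of year)
#'   and one or more of `fwi`, `isi`, `dc`. Dates must be unique.
#' @param year the year to aggregate.
#' @return One-row `data.frame`: `year`, `mean_fwi`, `mean_isi`,
#'   `mean_dc`, `n_days`, `completeness`.
#' @export
seasonal_mean <- function(weather, year) {
  stopifnot(all(c("year", "doy") %in% names(weather)))
  # leap handling is data-driven: synthetic series use a fixed 365-day
  # calendar, so only a year that actually contains day 366 shifts the
  # 1 Mar - 30 Sep day-of-year bounds
  leap <- 366 %in% weather$doy[weather$year == year]
  start <- if (leap) 61L else 60L
  end <- if (leap) 274L else 273L
  w <- weather[weather$year == year & weather$doy >= start &
                 weather$doy <= end, , drop = FALSE]
  if (!nrow(w)) stop("no in-window days for year ", year, call. = FALSE)
  if (anyDuplicated(w$doy)) stop("duplicate dates", call. = FALSE)
  m <- function(col) if (col %in% names(w)) mean(w[[col]], na.rm = TRUE)
                     else NA_real_
  data.frame(year = year, mean_fwi = m("fwi"), mean_isi = m("isi"),
             mean_dc = m("dc"), n_days = nrow(w),
             completeness = nrow(w) / (end - start + 1L))
}

#' Seasonal means for every year of a weather series
#'
#' @param weather as in [seasonal_mean()].
#' @return `data.frame` with one row per year present.
#' @export
seasonal_series <- function(weather) {
  out <- do.call(rbind, lapply(sort(unique(weather$year)),
                               function(y) seasonal_mean(weather, y)))
  rownames(out) <- NULL
  out
}

#' Flag abnormal years by z-score
#'
#' Standardises a yearly series against its own mean and sample standard
#' deviation (the focal year stays in the baseline) and flags years with
#' `z >= threshold`. Disturbed-area series use threshold 3; fire-weather
#' series use threshold 2, reflecting that weather means are far less
#' variable. A constant series (sd = 0) yields all-zero z and no flags.
#'
#' @param values numeric yearly values (>= 3 years).
#' @param years optional year labels.
#' @param threshold flagging threshold (default 3).
#' @return `data.frame`: `year`, `value`, `z`, `abnormal`, `threshold`.
#' @export
zscore_series <- function(values, years = seq_along(values), threshold = 3) {
  if (length(values) < 3L) stop("need at least 3 years", call. = FALSE)
  s <- stats::sd(values)
  z <- if (is.na(s) || s == 0) rep(0, length(values))
       else (values - mean(values)) / s
  data.frame(year = years, value = values, z = z,
             abnormal = z >= threshold, threshold = threshold)
}

#' Regress burned area on a seasonal fire-weather proxy
#'
#' Simple one-predictor ordinary least squares of annual burned
#' (fire-attributed) area on a seasonal fire-weather mean, fitted per
#' index (ISI-based and DC-based models are separate), and used to
#' predict the burned area of a target year from that year's weather. A
#' negative prediction is floored at zero and flagged.
#'
#' @param area `data.frame` with `year` and `area_ha` (the training years,
#'   e.g. 1987-2021).
#' @param season `data.frame` from [seasonal_series()] covering the
#'   training years and the target year.
#' @param index `"isi"`, `"dc"` or `"fwi"`.
#' @param target_year year to predict (default 2022).
#' @return List: `prediction` (ha), `floored` (logical), `slope`,
#'   `intercept`, `r_squared`, `n`, `index`.
#' @export
regress_burned_area <- function(area, season, index = c("isi", "dc", "fwi"),
                                target_year = 2022) {
  index <- match.arg(index)
  col <- paste0("mean_", index)
  df <- merge(area, season[, c("year", col)], by = "year")
  df <- df[df$year != target_year & stats::complete.cases(df), ]
  if (nrow(df) < 10L) stop("need >= 10 paired training years", call. = FALSE)
  if (stats::sd(df[[col]]) == 0)
    stop("predictor has zero variance", call. = FALSE)
  fit <- stats::lm(stats::reformulate(col, "area_ha"), data = df)
  newx <- season[season$year == target_year, , drop = FALSE]
  if (!nrow(newx)) stop("target year missing from season table",
                        call. = FALSE)
  pred <- unname(stats::predict(fit, newdata = newx))
  floored <- pred < 0
  list(prediction = max(0, pred), floored = floored,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = suppressWarnings(summary(fit)$r.squared),
       n = nrow(df), index = index)
}
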