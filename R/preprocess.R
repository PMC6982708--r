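#' Average a timetable to hourly resolution
#'
#' Each clock hour `[h, h+1)` receives the arithmetic mean of the
#' non-missing samples that fall inside it; an hour with no valid sample is
#' missing. Already-hourly input passes through unchanged (idempotent).
#'
#' @param table a [timetable] with spacing at most one hour.
#' @return An hourly [timetable] covering every clock hour from the first to
#'   the last observation.
#' @export
resample_hourly <- function(table) {
  validate_timetable(table)
  if (nrow(table) == 0L) return(table)
  hr <- as.POSIXct(trunc(table$date, "hours"))
  hours <- seq(min(hr), max(hr), by = 3600)
  idx <- match(hr, hours)
  cols <- lapply(tt_vars(table), function(nm) {
    v <- table[[nm]]
    ok <- !is.na(v)
    s <- rep(NA_real_, length(hours))
    if (any(ok)) {
      m <- tapply(v[ok], idx[ok], mean)
      s[as.integer(names(m))] <- as.numeric(m)
    }
    s
  })
  names(cols) <- tt_vars(table)
  do.call(timetable, c(list(date = hours), cols,
                       list(tz_label = attr(table, "tz_label"),
                            meta = attr(table, "meta"))))
}

#' Decompose wind direction into vector components
#'
#' Meteorological wind direction (degrees clockwise from north) is circular
#' and unsuitable for linear regression; it is resolved into a north-south
#' and an east-west component, `wd_n = cos(theta)` and `wd_e = sin(theta)`,
#' so that 0 degrees maps to (1, 0) — purely "north". Missing directions
#' propagate; values outside `[0, 360)` are reduced modulo 360 with a
#' warning.
#'
#' @param direction_deg numeric vector of directions in degrees.
#' @return A list with numeric components `wd_n` and `wd_e`.
#' @export
decompose_wind <- function(direction_deg) {
  d <- as.numeric(direction_deg)
  bad <- !is.na(d) & (d < 0 | d >= 360)
  if (any(bad)) {
    warning(sum(bad), " wind direction value(s) outside [0, 360) reduced modulo 360")
    d[bad] <- d[bad] %% 360
  }
  rad <- d * pi / 180
  list(wd_n = cos(rad), wd_e = sin(rad))
}

#' Apply per-variable transforms
#'
#' Log-transform variables are replaced by their natural logarithm
#' (non-positive values become missing; the count is recorded in the
#' `n_nonpositive` attribute); wind-direction variables are replaced by the
#' two vector components `<name>_n` and `<name>_e`; identity variables are
#' untouched.
#'
#' @param table a [timetable].
#' @param specs a [variable_spec] covering every variable to transform.
#' @return A transformed [timetable]; dropped/added columns per the specs.
#' @export
apply_transforms <- function(table, specs) {
  validate_timetable(table)
  n_nonpos <- 0L
  out <- list(date = table$date)
  for (nm in tt_vars(table)) {
    tr <- specs$transform[match(nm, specs$name)]
    if (is.na(tr)) tr <- "identity"
    v <- table[[nm]]
    if (tr == "log") {
      nonpos <- !is.na(v) & v <= 0
      n_nonpos <- n_nonpos + sum(nonpos)
      v[nonpos] <- NA_real_
      out[[nm]] <- log(v)
    } else if (tr == "wind_direction") {
      comp <- decompose_wind(v)
      out[[paste0(nm, "_n")]] <- comp$wd_n
      out[[paste0(nm, "_e")]] <- comp$wd_e
    } else {
      out[[nm]] <- v
    }
  }
  res <- do.call(timetable, c(out, list(tz_label = attr(table, "tz_label"),
                                        meta = attr(table, "meta"))))
  attr(res, "n_nonpositive") <- n_nonpos
  res
}

#' Candidate names after transformation
#'
#' Maps declared candidate variables to the column names present after
#' [apply_transforms] (wind-direction candidates become their two
#' components).
#' @param specs a [variable_spec].
#' @return character vector of transformed candidate column names.
#' @export
transformed_candidates <- function(specs) {
  unlist(lapply(which(specs$role == "candidate"), function(i) {
    if (specs$transform[i] == "wind_direction")
      paste0(specs$name[i], c("_n", "_e"))
    else specs$name[i]
  }), use.names = FALSE)
}

#' Daily means of an hourly series
#' @param table hourly [timetable].
#' @param var variable name.
#' @return data.frame with `day` (Date) and `value` (mean over non-missing
#'   hours; NA for empty days).
#' @export
daily_means <- function(table, var) {
  day <- as.Date(table$date, tz = "UTC")
  v <- table[[var]]
  days <- seq(min(day), max(day), by = "day")
  m <- tapply(v, factor(as.character(day), levels = as.character(days)),
              function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
  data.frame(day = days, value = as.numeric(m))
}

#' Thermal-season boundaries from daily temperature
#'
#' Fits a smooth curve (local linear `lowess`, default span 60 days) to the
#' daily mean temperature and labels each day by where the smoothed curve
#' sits relative to the thermal thresholds: below 0 C is winter, above 10 C
#' is summer, and the band in between is spring when the curve is rising
#' and autumn when it is falling. Season changes occur where the smoothed
#' curve crosses a threshold, so segments need not follow calendar dates.
#'
#' @param daily_temp data.frame with columns `day` (Date) and `value`
#'   (daily mean temperature, C); gaps allowed.
#' @param span_days smoothing window in days.
#' @return A `season_boundaries` object: data.frame of segments with
#'   `start`, `end` (Dates, inclusive) and `season`, plus attributes
#'   `days`/`season_by_day` giving the per-day labels.
#' @export
fit_thermal_seasons <- function(daily_temp, span_days = 60) {
  ok <- !is.na(daily_temp$value)
  if (sum(ok) < 2L) stop("cannot classify seasons: temperature series is empty")
  days <- daily_temp$day
  x <- as.numeric(days[ok])
  lo <- stats::lowess(x, daily_temp$value[ok],
                      f = min(1, span_days / diff(range(x))))
  sm <- stats::approx(lo$x, lo$y, xout = as.numeric(days), rule = 2)$y
  trend <- c(diff(sm)[1L], diff(sm))  # backward slope, first point forward
  season <- ifelse(sm < 0, "winter",
            ifelse(sm > 10, "summer",
            ifelse(trend >= 0, "spring", "autumn")))
  runs <- rle(season)
  stops <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(stops, -1L) + 1L)
  seg <- data.frame(start = days[starts], end = days[stops],
                    season = runs$values, stringsAsFactors = FALSE)
  structure(seg, class = c("season_boundaries", "data.frame"),
            days = days, season_by_day = season,
            smoothed = sm, span_days = span_days)
}

#' Season of each date under fitted boundaries
#' @param boundaries a `season_boundaries` object from [fit_thermal_seasons].
#' @param dates Date vector (must lie within the fitted span).
#' @return character vector of season labels.
#' @export
season_of <- function(boundaries, dates) {
  days <- attr(boundaries, "days")
  idx <- match(as.Date(dates), days)
  if (anyNA(idx))
    stop("date(s) outside the fitted season coverage: ",
         paste(utils::head(as.Date(dates)[is.na(idx)], 3L), collapse = ", "))
  attr(boundaries, "season_by_day")[idx]
}

#' Workday/weekend classification
#'
#' Saturdays, Sundays and public holidays are weekends; all other days are
#' workdays.
#'
#' @param dates Date vector.
#' @param holidays Date vector of public holidays (see [finnish_holidays]).
#' @return character vector, `"workday"` or `"weekend"`.
#' @export
classify_daytype <- function(dates, holidays = finnish_holidays()) {
  d <- as.Date(dates)
  wday <- as.POSIXlt(d)$wday
  ifelse(wday %in% c(0L, 6L) | d %in% as.Date(holidays),
         "weekend", "workday")
}

#' Assign the eight season-daytype classes
#'
#' Crosses the four thermal seasons with the workday/weekend split, giving
#' each timestamp exactly one of eight class labels like
#' `"winter.workday"`.
#'
#' @param table a [timetable].
#' @param boundaries from [fit_thermal_seasons].
#' @param holidays Date vector of public holidays.
#' @return character vector of class labels, one per row of `table`, with a
#'   `counts` attribute tabulating rows per class.
#' @export
assign_classes <- function(table, boundaries, holidays = finnish_holidays()) {
  d <- as.Date(table$date, tz = "UTC")
  lab <- paste(season_of(boundaries, d), classify_daytype(d, holidays),
               sep = ".")
  structure(lab, counts = base::table(lab))
}
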