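#' Daily sea-ice extent from a thresholded concentration grid
#'
#' Each grid cell is scored present if its ice concentration is strictly
#' greater than the concentration threshold (30% by default); the extent is
#' the summed area of present cells. Cell areas of 12.5 or 25 km^2 are
#' typical for passive-microwave products but any positive area is accepted.
#'
#' @param concentration vector of ice-concentration fractions in \[0, 1\].
#' @param area_km2 cell areas in km^2, recycled against `concentration`.
#' @param threshold concentration cut-off; cells strictly above count.
#' @return total extent in km^2.
#' @examples
#' grid_to_extent(c(0.20, 0.40, 0.31, 0.30), 25)  # 50
#' @export
grid_to_extent <- function(concentration, area_km2, threshold = 0.30) {
  if (length(concentration) == 0L) {
    stop("empty cell list: at least one grid cell is required", call. = FALSE)
  }
  if (any(!is.finite(concentration)) ||
      any(concentration < 0) || any(concentration > 1)) {
    stop("concentrations must be fractions in [0, 1]", call. = FALSE)
  }
  check_positive(area_km2, "area_km2")
  area <- rep_len(area_km2, length(concentration))
  sum(area[concentration > threshold])
}

#' Construct a daily sea-ice extent series
#'
#' @param date `Date` vector, strictly increasing (gaps allowed).
#' @param extent_km2 non-negative extents.
#' @return a `daily_ice` data frame with columns `date`, `extent_km2`.
#' @export
daily_ice_series <- function(date, extent_km2) {
  date <- as.Date(date)
  if (anyNA(date)) stop("unparseable dates in ice series", call. = FALSE)
  if (is.unsorted(date, strictly = TRUE)) {
    stop("dates must be strictly increasing", call. = FALSE)
  }
  if (any(extent_km2 < 0, na.rm = TRUE)) {
    stop("extent_km2 must be non-negative", call. = FALSE)
  }
  structure(data.frame(date = date, extent_km2 = as.numeric(extent_km2)),
            class = c("daily_ice", "data.frame"))
}

# Complete the series to one row per calendar day; interpolate gaps of at
# most `max_gap` missing days linearly, leave longer gaps NA (a long gap
# voids any run it interrupts because NA days never satisfy a run condition).
fill_ice_gaps <- function(series, max_gap = 2) {
  all_days <- seq(min(series$date), max(series$date), by = "day")
  ext <- rep(NA_real_, length(all_days))
  ext[match(series$date, all_days)] <- series$extent_km2
  isna <- is.na(ext)
  if (any(isna)) {
    r <- rle(isna)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    short <- which(r$values & r$lengths <= max_gap)
    fillable <- logical(length(ext))
    for (i in short) fillable[starts[i]:ends[i]] <- TRUE
    if (any(fillable)) {
      interp <- stats::approx(which(!isna), ext[!isna], xout = which(fillable),
                              rule = 1)$y
      ext[fillable] <- interp
    }
  }
  data.frame(date = all_days, extent_km2 = ext)
}

#' Transition threshold between ice-covered and ice-free states
#'
#' The threshold is the midpoint between the climatological September
#' (annual minimum) and March (annual maximum) extents over a reference
#' decade: for each reference year the mean extent over a 30-day September
#' window and a 30-day March window is taken, the window means are averaged
#' over the reference years, and the threshold is halfway between the two
#' climatologies.
#'
#' @param series a `daily_ice` series covering the reference windows.
#' @param reference_years integer years of the reference period
#'   (default 1990--1999).
#' @param min_window,max_window month-day strings `c(start, end)` for the
#'   minimum (September) and maximum (March) windows.
#' @param running if `TRUE`, use the minimum (maximum) running 30-day mean
#'   within the year instead of the fixed calendar windows.
#' @return object of class `ice_threshold`: list with `value_km2`,
#'   `reference_years`, `september_km2`, `march_km2`.
#' @export
transition_threshold <- function(series, reference_years = 1990:1999,
                                 min_window = c("09-01", "09-30"),
                                 max_window = c("03-01", "03-30"),
                                 running = FALSE) {
  filled <- fill_ice_gaps(series)
  win_mean <- function(year, window) {
    lo <- as.Date(sprintf("%d-%s", year, window[1]))
    hi <- as.Date(sprintf("%d-%s", year, window[2]))
    sel <- filled$date >= lo & filled$date <= hi
    v <- filled$extent_km2[sel]
    if (sum(sel) < as.integer(hi - lo) + 1L || anyNA(v)) {
      stop(sprintf("ice series does not cover the %s window of year %d",
                   window[1], year), call. = FALSE)
    }
    mean(v)
  }
  run_extreme <- function(year, which) {
    sel <- format(filled$date, "%Y") == as.character(year)
    v <- filled$extent_km2[sel]
    if (length(v) < 360 || anyNA(v)) {
      stop(sprintf("ice series does not cover year %d", year), call. = FALSE)
    }
    m <- stats::filter(v, rep(1 / 30, 30), sides = 1)
    m <- m[!is.na(m)]
    if (which == "min") min(m) else max(m)
  }
  if (running) {
    sept <- mean(vapply(reference_years, run_extreme, 0, which = "min"))
    mar <- mean(vapply(reference_years, run_extreme, 0, which = "max"))
  } else {
    sept <- mean(vapply(reference_years, win_mean, 0, window = min_window))
    mar <- mean(vapply(reference_years, win_mean, 0, window = max_window))
  }
  structure(list(value_km2 = (sept + mar) / 2,
                 reference_years = reference_years,
                 september_km2 = sept, march_km2 = mar),
            class = "ice_threshold")
}

#' @export
print.ice_threshold <- function(x, ...) {
  cat(sprintf(
    "Sea-ice transition threshold: %.1f km^2\n  (September %.1f, March %.1f; reference %d-%d)\n",
    x$value_km2, x$september_km2, x$march_km2,
    min(x$reference_years), max(x$reference_years)))
  invisible(x)
}

days_in_year <- function(year) {
  ifelse((year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0, 366L, 365L)
}

# Locate the first run of at least `min_run` consecutive TRUEs in `cond`
# (logical, NA treated as FALSE) at or after index `from`; returns the index
# of the run day selected by `convention` ("last" = min_run-th day, the date
# by which the condition has held for min_run consecutive days; "first" =
# first day of the run), or NA if none.
first_run_index <- function(cond, from = 1L, min_run = 5L,
                            convention = c("last", "first")) {
  convention <- match.arg(convention)
  cond[is.na(cond)] <- FALSE
  cond[seq_len(min(from - 1L, length(cond)))] <- FALSE
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= min_run)
  if (length(hit) == 0L) return(NA_integer_)
  s <- starts[hit[1L]]
  if (convention == "last") s + min_run - 1L else s
}

#' Detect the sea-ice break-up date for a year
#'
#' Break-up is the date by which daily extent has been strictly below the
#' transition threshold for `min_run` (default 5) consecutive days, scanning
#' from 1 March (the annual-maximum period) to the end of the calendar year.
#' By default the reported date is the last (5th) day of the first qualifying
#' run; `convention = "first"` reports the run's first day for sensitivity
#' checks. Days equal to the threshold do not count towards a run.
#'
#' @param series a `daily_ice` series.
#' @param threshold an `ice_threshold` or a numeric extent in km^2.
#' @param year calendar year to scan.
#' @param min_run required consecutive days below threshold.
#' @param convention report the `"last"` (default) or `"first"` day of the run.
#' @param max_gap longest data gap (days) bridged by linear interpolation.
#' @return day-of-year (1 = 1 January) of break-up, or `NA` (no-breakup
#'   sentinel) if no qualifying run occurs before year end.
#' @export
detect_breakup <- function(series, threshold, year, min_run = 5L,
                           convention = c("last", "first"), max_gap = 2) {
  convention <- match.arg(convention)
  thr <- threshold_value(threshold)
  filled <- fill_ice_gaps(series, max_gap = max_gap)
  sel <- filled$date >= as.Date(sprintf("%d-03-01", year)) &
    filled$date <= as.Date(sprintf("%d-12-31", year))
  if (!any(sel)) {
    stop(sprintf("ice series does not cover the scan window of year %d", year),
         call. = FALSE)
  }
  sub <- filled[sel, ]
  idx <- first_run_index(sub$extent_km2 < thr, min_run = min_run,
                         convention = convention)
  if (is.na(idx)) return(NA_integer_)
  as.POSIXlt(sub$date[idx])$yday + 1L
}

#' Detect the sea-ice freeze-up date following break-up
#'
#' Freeze-up is the date by which extent has been strictly above the
#' threshold for `min_run` consecutive days, scanning strictly after the
#' break-up date and continuing into the following calendar year; dates in
#' the next year are reported as day-of-year values exceeding 365 (or 366
#' for a leap break-up year). The scan stops `horizon` days after 1 January
#' of the break-up year.
#'
#' @inheritParams detect_breakup
#' @param breakup_doy day-of-year of the detected break-up.
#' @param horizon scan limit, in days after 1 January of `year`.
#' @return day-of-year of freeze-up (may exceed 365), or `NA` (no-freezeup
#'   sentinel).
#' @export
detect_freezeup <- function(series, threshold, year, breakup_doy,
                            min_run = 5L, convention = c("last", "first"),
                            horizon = 550L, max_gap = 2) {
  convention <- match.arg(convention)
  if (is.na(breakup_doy)) return(NA_integer_)
  thr <- threshold_value(threshold)
  filled <- fill_ice_gaps(series, max_gap = max_gap)
  jan1 <- as.Date(sprintf("%d-01-01", year))
  start <- jan1 + breakup_doy            # first day strictly after break-up
  end <- jan1 + (horizon - 1L)
  sel <- filled$date >= start & filled$date <= end
  if (!any(sel)) return(NA_integer_)
  sub <- filled[sel, ]
  idx <- first_run_index(sub$extent_km2 > thr, min_run = min_run,
                         convention = convention)
  if (is.na(idx)) return(NA_integer_)
  as.integer(sub$date[idx] - jan1) + 1L  # doy in the break-up year's calendar
}

threshold_value <- function(threshold) {
  if (inherits(threshold, "ice_threshold")) threshold$value_km2
  else as.numeric(threshold)
}

#' Length of the ice-free season
#'
#' @param breakup_doy,freezeup_doy day-of-year values from
#'   [detect_breakup()] / [detect_freezeup()]; `NA` sentinels propagate.
#' @return `freezeup_doy - breakup_doy` (days), `NA` when either is missing.
#' @export
ice_free_days <- function(breakup_doy, freezeup_doy) {
  out <- freezeup_doy - breakup_doy
  bad <- !is.na(out) & out <= 0
  if (any(bad)) {
    stop("freeze-up must fall strictly after break-up", call. = FALSE)
  }
  out
}

#' Per-year sea-ice phenology table
#'
#' Runs break-up and freeze-up detection for each requested year against a
#' common transition threshold and assembles the annual phenology record,
#' including the one-year-lagged break-up date.
#'
#' @inheritParams detect_breakup
#' @param years integer years to process.
#' @param ... passed to [detect_breakup()] and [detect_freezeup()].
#' @return data frame with columns `year`, `breakup_doy`, `freezeup_doy`,
#'   `ice_free_days`, `breakup_lag1`.
#' @export
ice_phenology <- function(series, threshold, years, ...) {
  rows <- lapply(years, function(y) {
    b <- detect_breakup(series, threshold, y, ...)
    f <- detect_freezeup(series, threshold, y, b, ...)
    data.frame(year = y, breakup_doy = b, freezeup_doy = f,
               ice_free_days = ice_free_days(b, f))
  })
  out <- do.call(rbind, rows)
  lag_covariate(out, "breakup_doy", k = 1, new_name = "breakup_lag1")
}

#' Lag an annual covariate
#'
#' Adds a column holding the value of `name` in year \eqn{t - k}; the first
#' `k` years get `NA`.
#'
#' @param annual data frame keyed by a `year` column (unique years).
#' @param name column to lag.
#' @param k lag in years; `k = 0` copies the column.
#' @param new_name name of the new column (default `<name>_lag<k>`).
#' @return the input with the lagged column appended.
#' @export
lag_covariate <- function(annual, name, k = 1L,
                          new_name = paste0(name, "_lag", k)) {
  stopifnot(is.data.frame(annual), "year" %in% names(annual),
            name %in% names(annual), k >= 0)
  if (anyDuplicated(annual$year)) {
    stop("duplicate year keys in annual table", call. = FALSE)
  }
  annual[[new_name]] <- annual[[name]][match(annual$year - k, annual$year)]
  annual
}

#' Arctic Oscillation window covariates
#'
#' Averages monthly AO index values into the two capture-year covariates:
#' winter AO (October of the year before capture through January of the
#' capture year) and spring AO (April--June of the capture year), plus the
#' previous year's spring AO.
#'
#' @param monthly data frame with integer `year`, `month` and numeric `ao`.
#' @param years capture years for which to compute the covariates.
#' @return data frame `year`, `winter_ao`, `spring_ao`, `spring_ao_lag1`.
#' @export
ao_covariates <- function(monthly, years) {
  stopifnot(all(c("year", "month", "ao") %in% names(monthly)))
  if (anyDuplicated(monthly[c("year", "month")])) {
    stop("duplicate (year, month) rows in AO table", call. = FALSE)
  }
  pick <- function(y, m) {
    v <- monthly$ao[monthly$year == y & monthly$month %in% m]
    if (length(v) != length(m)) {
      stop(sprintf("AO table missing months for year %d", y), call. = FALSE)
    }
    v
  }
  spring <- function(y) mean(pick(y, 4:6))
  out <- data.frame(year = years)
  out$winter_ao <- vapply(years, function(y) {
    mean(c(pick(y - 1L, 10:12), pick(y, 1L)))
  }, 0)
  out$spring_ao <- vapply(years, spring, 0)
  out$spring_ao_lag1 <- vapply(years - 1L, spring, 0)
  out
}
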