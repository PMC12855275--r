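#' Spring day index of a capture date
#'
#' Converts a spring capture date into the day index used as the `day`
#' covariate, counted so that 1 March = day 1 (hence 1 April = day 32 and
#' 8 May = day 69). Counting starts on 1 March, so February's length -- and
#' therefore leap years -- never enters the index.
#'
#' @param date a `Date` vector (or something coercible); must fall in
#'   March--May.
#' @return integer day index.
#' @examples
#' day_of_spring(as.Date("2001-04-01"))  # 32
#' @export
day_of_spring <- function(date) {
  date <- as.Date(date)
  lt <- as.POSIXlt(date)
  mon <- lt$mon + 1L                     # 1..12
  if (any(mon < 3L | mon > 5L)) {
    stop("capture dates must fall between 1 March and 31 May", call. = FALSE)
  }
  offset <- c(`3` = 0L, `4` = 31L, `5` = 61L)
  unname(offset[as.character(mon)] + lt$mday)
}

#' Canonical reproductive-state coding for adult females
#'
#' Maps raw field labels to the three-level reproductive-state factor:
#' `Fc` (with cubs-of-the-year), `Fy` (with one-year-olds), and `F` (alone
#' or with two-year-olds, which wean in spring). `Fc` is the baseline
#' (first) level, matching the intercept parameterisation used in the
#' condition models.
#'
#' @param raw_label character vector of field labels; recognised synonyms
#'   include `"coy"`, `"with cubs"`, `"cubs-of-the-year"` (Fc);
#'   `"yearling(s)"`, `"with 1-yr-olds"` (Fy); `"lone"`, `"alone"`,
#'   `"with 2-yr-olds"`, `"two-year-olds"` (F).
#' @return factor with levels `c("Fc", "Fy", "F")`.
#' @export
encode_reproductive_state <- function(raw_label) {
  key <- tolower(trimws(as.character(raw_label)))
  key <- gsub("[_-]", " ", key)
  synonyms <- c(
    "fc" = "Fc", "coy" = "Fc", "cub" = "Fc", "cubs" = "Fc",
    "with cubs" = "Fc", "cubs of the year" = "Fc", "with coy" = "Fc",
    "fy" = "Fy", "yearling" = "Fy", "yearlings" = "Fy",
    "with yearlings" = "Fy", "with 1 yr olds" = "Fy",
    "with one year olds" = "Fy",
    "f" = "F", "lone" = "F", "alone" = "F", "solitary" = "F",
    "with 2 yr olds" = "F", "with two year olds" = "F",
    "two year olds" = "F")
  out <- synonyms[key]
  if (anyNA(out)) {
    bad <- unique(raw_label[is.na(out)])
    stop(sprintf("unknown reproductive-state label(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  factor(unname(out), levels = c("Fc", "Fy", "F"))
}

#' A-priori exclusion filters for capture records
#'
#' Applies the study-design exclusions to a validated capture table:
#' captures before `min_year` (default 1995; early years were few and
#' spatially restricted), captures outside the longitude window
#' \[`lon_range`\] (default 0--35 degrees E, for spatial homogeneity of
#' coverage over time), ages outside \[`age_range`\] (adults 5--28), and
#' duplicate (bear, year) records beyond the first by date. The filter is
#' idempotent: already-filtered data pass unchanged.
#'
#' @param records capture data frame with columns `bear_id`, `year`, `date`,
#'   `lon`, `age` (others carried through).
#' @param min_year first retained capture year.
#' @param lon_range numeric length-2 retained longitude window, degrees E.
#' @param age_range integer length-2 retained age window, years.
#' @return list with `records` (the retained rows) and `report`, a
#'   `filter_report` tallying drops per rule
#'   (`n_input = n_output + sum(drops)`).
#' @export
apply_exclusions <- function(records, min_year = 1995,
                             lon_range = c(0, 35), age_range = c(5, 28)) {
  stopifnot(is.data.frame(records))
  needed <- c("bear_id", "year", "lon", "age")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("capture table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n_input <- nrow(records)
  drops <- c(year = 0L, lon = 0L, age = 0L, dup = 0L)

  keep <- records$year >= min_year
  drops["year"] <- sum(!keep)
  records <- records[keep, , drop = FALSE]

  keep <- records$lon >= lon_range[1] & records$lon <= lon_range[2]
  drops["lon"] <- sum(!keep)
  records <- records[keep, , drop = FALSE]

  keep <- records$age >= age_range[1] & records$age <= age_range[2]
  drops["age"] <- sum(!keep)
  records <- records[keep, , drop = FALSE]

  if (nrow(records)) {
    ord <- if ("date" %in% names(records)) {
      order(records$bear_id, records$year, records$date)
    } else {
      order(records$bear_id, records$year)
    }
    records <- records[ord, , drop = FALSE]
    dup <- duplicated(records[c("bear_id", "year")])
    drops["dup"] <- sum(dup)
    records <- records[!dup, , drop = FALSE]
    records <- records[order(records$year, records$bear_id), , drop = FALSE]
  }
  rownames(records) <- NULL
  report <- structure(list(n_input = n_input,
                           n_dropped_by_rule = as.list(drops),
                           n_output = nrow(records)),
                      class = "filter_report")
  list(records = records, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Capture filter: %d in, %d out\n", x$n_input, x$n_output))
  for (rule in names(x$n_dropped_by_rule)) {
    cat(sprintf("  dropped by %-4s: %d\n", rule, x$n_dropped_by_rule[[rule]]))
  }
  invisible(x)
}

#' Attach year-level covariates to capture records
#'
#' Joins an annual covariate table (phenology and climate indices, keyed by
#' `year`) onto the capture table. Ice-free days and lagged covariates must
#' already refer to the season relevant for the capture year (for ice-free
#' days, the season preceding capture). Missing capture years in the annual
#' table are a hard error naming the year.
#'
#' @param records capture data frame with a `year` column.
#' @param annual annual covariate data frame keyed by unique `year`.
#' @return `records` with the annual columns appended.
#' @export
attach_annual_covariates <- function(records, annual) {
  stopifnot(is.data.frame(records), is.data.frame(annual),
            "year" %in% names(records), "year" %in% names(annual))
  if (anyDuplicated(annual$year)) {
    stop("duplicate year keys in annual covariate table", call. = FALSE)
  }
  idx <- match(records$year, annual$year)
  if (anyNA(idx)) {
    missing_years <- sort(unique(records$year[is.na(idx)]))
    stop(sprintf("annual covariate table lacks year(s): %s",
                 paste(missing_years, collapse = ", ")), call. = FALSE)
  }
  cols <- setdiff(names(annual), "year")
  clash <- intersect(cols, names(records))
  if (length(clash)) {
    stop("covariate column(s) already present: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  cbind(records, annual[idx, cols, drop = FALSE], row.names = NULL)
}

#' Project capture coordinates to kilometres
#'
#' Azimuthal equidistant projection centred on the centroid of the capture
#' locations. At ~78 degrees N a degree of longitude is barely a fifth of a
#' degree of latitude in metric terms, so spatial models must never operate
#' on raw lon/lat; this projection preserves distances from the centre,
#' adequate over the few-hundred-km extent of an archipelago-scale study
#' area.
#'
#' @param lon,lat coordinates in decimal degrees.
#' @param center optional `c(lon, lat)` projection centre; defaults to the
#'   data centroid.
#' @return data frame with `x_km`, `y_km` and the centre as an attribute.
#' @export
project_locations <- function(lon, lat, center = NULL) {
  if (is.null(center)) center <- c(mean(lon), mean(lat))
  R <- 6371.0088
  rad <- pi / 180
  lam <- lon * rad; phi <- lat * rad
  lam0 <- center[1] * rad; phi0 <- center[2] * rad
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  cosc <- pmin(1, pmax(-1, cosc))
  c_ang <- acos(cosc)
  k <- ifelse(c_ang < 1e-12, 1, c_ang / sin(c_ang))
  x <- R * k * cos(phi) * sin(lam - lam0)
  y <- R * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0))
  structure(data.frame(x_km = x, y_km = y), center = center)
}

#' Collinearity screen for model covariates
#'
#' Pairwise Pearson correlations and variance-inflation factors for a set of
#' candidate covariates. The VIF of covariate j is \eqn{1/(1-R_j^2)} from the
#' linear regression of covariate j on the others.
#'
#' @param data data frame holding the covariates.
#' @param covariates character vector of numeric column names.
#' @return list with `correlations` (matrix) and `vif` (named vector).
#' @export
collinearity_screen <- function(data, covariates) {
  x <- data[covariates]
  stopifnot(all(vapply(x, is.numeric, TRUE)))
  x <- x[stats::complete.cases(x), , drop = FALSE]
  vif <- vapply(covariates, function(v) {
    fit <- stats::lm(stats::reformulate(setdiff(covariates, v), response = v),
                     data = x)
    1 / (1 - summary(fit)$r.squared)
  }, 0)
  list(correlations = stats::cor(x), vif = vif)
}

#' Split a capture table by sex
#'
#' Condition models are fitted separately for adult males and adult females;
#' this returns the two sex-specific tables and checks that each bear has a
#' single recorded sex.
#'
#' @param records capture data frame with `bear_id` and `sex` (`"M"`/`"F"`).
#' @return named list with elements `M` and `F`.
#' @export
split_by_sex <- function(records) {
  stopifnot(all(c("bear_id", "sex") %in% names(records)))
  if (!all(records$sex %in% c("M", "F"))) {
    stop("sex must be coded 'M' or 'F'", call. = FALSE)
  }
  n_sex <- tapply(records$sex, records$bear_id,
                  function(s) length(unique(s)))
  if (any(n_sex > 1)) {
    stop("bear(s) recorded with more than one sex: ",
         paste(names(n_sex)[n_sex > 1], collapse = ", "), call. = FALSE)
  }
  list(M = records[records$sex == "M", , drop = FALSE],
       F = records[records$sex == "F", , drop = FALSE])
}
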