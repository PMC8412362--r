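#' Daily forcing tables
#'
#' The model is driven by a daily forcing table with columns `date`
#' (class `Date`), `tmin`, `tmax` (degrees C) and `prcp` (mm), plus an
#' optional `cell` column identifying grid cells. `wb_forcing()` validates
#' such a table: equal column lengths, a gap-free strictly increasing
#' daily calendar per cell, non-negative precipitation, and
#' `tmax >= tmin` wherever both are present. Missing values must be `NA`
#' (the explicit nodata sentinel); any `NA` in a cell-day's forcing makes
#' that cell-day's model outputs `NA`.
#'
#' Two calendars are supported: `"gregorian"` (real dates, Feb 29 in leap
#' years) and `"noleap"` (the 365-day calendar of Daymet-style products,
#' Feb 29 absent every year). `calendar = "auto"` accepts a series as
#' noleap when every Feb 29 is absent but the index is otherwise gap-free.
#'
#' @param x A data frame with columns `date`, `tmin`, `tmax`, `prcp` and
#'   optionally `cell`.
#' @param calendar `"auto"`, `"gregorian"` or `"noleap"`.
#' @return A tibble of class `wb_forcing` with a `calendar` attribute.
#' @examples
#' f <- wb_forcing(data.frame(
#'   date = as.Date("2001-01-01") + 0:2,
#'   tmin = c(-5, -4, -3), tmax = c(2, 3, 4), prcp = c(0, 5, 0)
#' ))
#' attr(f, "calendar")
#' @export
wb_forcing <- function(x, calendar = c("auto", "gregorian", "noleap")) {
  calendar <- match.arg(calendar)
  required <- c("date", "tmin", "tmax", "prcp")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Forcing table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- tibble::as_tibble(x)
  if (!inherits(x$date, "Date")) x$date <- as.Date(x$date)
  if (!("cell" %in% names(x))) x$cell <- 1L

  ok <- !is.na(x$tmax) & !is.na(x$tmin)
  if (any(x$tmax[ok] < x$tmin[ok])) {
    bad <- x$date[ok][which(x$tmax[ok] < x$tmin[ok])[1]]
    abort(paste0("tmax < tmin on ", format(bad)))
  }
  if (any(x$prcp < 0, na.rm = TRUE)) {
    abort("Negative precipitation in forcing")
  }

  cal <- calendar
  for (cl in unique(x$cell)) {
    d <- sort(x$date[x$cell == cl])
    if (anyDuplicated(d)) {
      abort(paste0("Duplicated dates in forcing for cell ", cl))
    }
    cal <- check_daily_index(d, cal)
  }
  if (cal == "auto") cal <- "gregorian"

  x <- dplyr::arrange(x, .data$cell, .data$date)
  structure(x, class = c("wb_forcing", class(tibble::tibble())),
            calendar = cal)
}

# Validate a sorted daily date vector against a calendar; returns the
# resolved calendar (resolving "auto"). Errors name the first missing day.
check_daily_index <- function(d, calendar) {
  if (length(d) < 2) {
    return(if (calendar == "auto") "gregorian" else calendar)
  }
  full <- seq(d[1], d[length(d)], by = "day")
  gaps <- full[!(full %in% d)]
  if (length(gaps) == 0) {
    if (calendar == "noleap" && any(is_feb29(d))) {
      abort("Calendar declared noleap but Feb 29 present")
    }
    return(if (calendar == "auto") "gregorian" else calendar)
  }
  feb29 <- is_feb29(gaps)
  if (all(feb29) && calendar %in% c("auto", "noleap")) {
    return("noleap")
  }
  abort(paste0("Daily index has gap(s); first missing day: ",
               format(gaps[!feb29][1] %||% gaps[1])))
}

is_feb29 <- function(d) {
  format(d, "%m-%d") == "02-29"
}

#' Build a daily date sequence under a model calendar
#'
#' @param start,end First and last day (`Date` or coercible).
#' @param calendar `"gregorian"` keeps every real day; `"noleap"` drops
#'   Feb 29, giving 365 days per year.
#' @return A `Date` vector.
#' @examples
#' length(wb_dates("2000-01-01", "2000-12-31", "noleap"))
#' @export
wb_dates <- function(start, end, calendar = c("gregorian", "noleap")) {
  calendar <- match.arg(calendar)
  d <- seq(as.Date(start), as.Date(end), by = "day")
  if (calendar == "noleap") d <- d[!is_feb29(d)]
  d
}

#' Read and write daily site forcing as CSV
#'
#' Reads a `date,tmin,tmax,prcp` CSV (optional `cell` column) into a
#' validated [wb_forcing] table. Units are mandatory metadata: the
#' defaults assert degrees C and mm, and any other declared unit is
#' converted on read. Unknown units are an error, never guessed.
#'
#' @param path File path.
#' @param temp_units `"degC"` or `"K"`.
#' @param prcp_units `"mm"`, `"cm"` or `"in"`.
#' @inheritParams wb_forcing
#' @return A `wb_forcing` tibble.
#' @export
read_wb_forcing <- function(path, temp_units = "degC", prcp_units = "mm",
                            calendar = "auto") {
  x <- readr::read_csv(path, show_col_types = FALSE)
  tf <- switch(temp_units,
    degC = identity,
    K = function(v) v - 273.15,
    abort(paste0("Unknown temperature unit '", temp_units,
                 "' and no conversion declared"))
  )
  pf <- switch(prcp_units,
    mm = identity,
    cm = function(v) v * 10,
    `in` = function(v) v * 25.4,
    abort(paste0("Unknown precipitation unit '", prcp_units,
                 "' and no conversion declared"))
  )
  x$tmin <- tf(x$tmin)
  x$tmax <- tf(x$tmax)
  x$prcp <- pf(x$prcp)
  wb_forcing(x, calendar = calendar)
}

#' @rdname read_wb_forcing
#' @param x A `wb_forcing` table (or any data frame passing [wb_forcing]).
#' @export
write_wb_forcing <- function(x, path) {
  x <- wb_forcing(x)
  readr::write_csv(tibble::as_tibble(unclass_tbl(x)), path)
  invisible(path)
}

unclass_tbl <- function(x) {
  class(x) <- class(tibble::tibble())
  attr(x, "calendar") <- NULL
  x
}

#' Water-year labels and day-of-water-year
#'
#' The hydrological water year runs 1 October to 30 September and is
#' labeled by its ending calendar year: 2000-10-01 is day 1 of water year
#' 2001 and 2001-09-30 its last day.
#'
#' @param dates A `Date` vector.
#' @param calendar `"gregorian"` or `"noleap"`; under `"noleap"` day
#'   counts skip Feb 29.
#' @return `water_year()`: integer labels. `water_year_day()`: integer day
#'   within the water year, counted from 1 at Oct 1.
#' @examples
#' water_year(as.Date(c("2000-10-01", "2001-09-30", "2001-10-01")))
#' water_year_day(as.Date("2000-10-01"))
#' @export
water_year <- function(dates) {
  y <- as.integer(format(dates, "%Y"))
  m <- as.integer(format(dates, "%m"))
  ifelse(m >= 10L, y + 1L, y)
}

#' @rdname water_year
#' @export
water_year_day <- function(dates, calendar = c("gregorian", "noleap")) {
  calendar <- match.arg(calendar)
  wy <- water_year(dates)
  start <- as.Date(paste0(wy - 1L, "-10-01"))
  day <- as.integer(dates - start) + 1L
  if (calendar == "noleap") {
    feb29 <- as.Date(paste0(wy, "-02-29"), optional = TRUE)
    has_leap <- !is.na(feb29) & dates >= feb29
    day <- day - as.integer(has_leap)
  }
  day
}

# Day-of-year index into a length-365 climatology: Feb 29 maps to the
# Feb 28 entry so leap years never index past 365.
ndvi_day_index <- function(dates) {
  j <- as.integer(format(dates, "%j"))
  leap <- as.integer(format(dates, "%Y")) %% 4 == 0 &
    (as.integer(format(dates, "%Y")) %% 100 != 0 |
       as.integer(format(dates, "%Y")) %% 400 == 0)
  after_feb28 <- leap & j >= 60L
  j - as.integer(after_feb28)
}

#' Cell attribute tables
#'
#' Static per-cell attributes of the model grid: `cell` id, `latitude`
#' (decimal degrees), `slope` (degrees), `aspect` (degrees clockwise from
#' north), `whc` (mm of plant-available water in the top meter of soil)
#' and optionally `snow_t50` (degrees C, per-cell rain--snow partition
#' midpoint) and `ndvi` (a list-column of length-365 daily NDVI
#' climatology values in `[-1, 1]`; absent means no vegetation adjustment,
#' i.e. an AET scalar of 1). Optional `x`, `y` columns carry projected or
#' geographic cell-center coordinates for point extraction.
#'
#' @param x A data frame with at least `cell`, `latitude`, `whc`;
#'   `slope` and `aspect` default to 0 (flat).
#' @return A validated tibble of class `wb_attributes`.
#' @export
wb_attributes <- function(x) {
  x <- tibble::as_tibble(x)
  if (!("cell" %in% names(x))) x$cell <- seq_len(nrow(x))
  for (col in c("latitude", "whc")) {
    if (!(col %in% names(x))) abort(paste0("Attributes missing column ", col))
  }
  if (!("slope" %in% names(x))) x$slope <- 0
  if (!("aspect" %in% names(x))) x$aspect <- 0
  stopifnot(
    all(x$latitude >= -90 & x$latitude <= 90),
    all(x$slope >= 0 & x$slope <= 90),
    all(x$aspect >= 0 & x$aspect < 360),
    all(x$whc > 0)
  )
  if ("ndvi" %in% names(x)) {
    lens <- lengths(x$ndvi)
    if (any(lens != 365)) {
      abort("Each ndvi climatology must have length 365")
    }
    rng <- range(unlist(x$ndvi))
    if (rng[1] < -1 || rng[2] > 1) abort("NDVI values must lie in [-1, 1]")
  }
  if (anyDuplicated(x$cell)) abort("Duplicated cell ids in attributes")
  structure(x, class = c("wb_attributes", class(tibble::tibble())))
}
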