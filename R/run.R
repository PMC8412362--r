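#' Run the daily water balance over cells and time
#'
#' Advances every cell through the forcing period one day at a time,
#' carrying snowpack and soil water as prognostic state. Cells are fully
#' independent (no lateral coupling), so results are invariant to how
#' the grid is split into chunks and identical between the long-table
#' and matrix forcing representations. The daily mean temperature
#' driving snow and PET is `(tmin + tmax) / 2`. Accumulation is in
#' double precision.
#'
#' With `output = "daily"` the full day-by-cell flux table is returned;
#' with `output = "annual"` fluxes are accumulated into calendar-year or
#' water-year totals on the fly (constant memory in the number of days),
#' together with start/end storage so mass balance can be audited per
#' cell-year with [wb_mass_balance()]. Partial years at either end are
#' dropped from annual output with a warning.
#'
#' @param forcing A [wb_forcing] table or [wb_grid_forcing] object.
#' @param attributes A [wb_attributes] table covering every forcing cell.
#' @param params A [wb_params].
#' @param output `"daily"` or `"annual"`.
#' @param water_year Label annual totals by water year (Oct 1--Sep 30,
#'   labeled by ending year) instead of calendar year.
#' @param init Optional initial state: list with `swe` and `soil` vectors
#'   (mm, recycled over cells). Default: `swe = 0`, `soil = whc` (full
#'   bucket). See [wb_spin_up()] for a principled alternative.
#' @return A tibble. Daily: one row per cell-day with states (`swe`,
#'   `soil_water`) and fluxes (`pet`, `aet`, `cwd`, `rain`, `snowfall`,
#'   `melt`, `runoff`, `interception_loss`), class `wb_daily`. Annual:
#'   one row per cell-year with flux totals, `precip`, and storage
#'   bookkeeping columns (`swe_start`, `soil_start`, `swe_end`,
#'   `soil_end`), class `wb_annual`.
#' @examples
#' f <- make_forcing(fixture_spec(nrow = 1, ncol = 1, years = 2001:2002))
#' a <- make_attributes(fixture_spec(nrow = 1, ncol = 1))
#' ann <- wb_run(f, a, output = "annual")
#' ann[, c("cell", "year", "aet", "cwd")]
#' @export
wb_run <- function(forcing, attributes, params = wb_params(),
                   output = c("daily", "annual"), water_year = FALSE,
                   init = NULL) {
  output <- match.arg(output)
  gf <- as_grid_forcing(forcing)
  attributes <- wb_attributes(attributes)
  eng <- wb_engine(gf, attributes, params, init)

  dates <- gf$dates
  cells <- gf$cells
  if (output == "daily") {
    res <- eng$run_daily()
    nd <- length(dates)
    out <- tibble::tibble(
      cell = rep(cells, each = nd),
      date = rep(dates, times = length(cells)),
      swe = as.vector(res$swe),
      soil_water = as.vector(res$soil),
      pet = as.vector(res$pet),
      aet = as.vector(res$aet),
      cwd = as.vector(res$cwd),
      rain = as.vector(res$rain),
      snowfall = as.vector(res$snowfall),
      melt = as.vector(res$melt),
      runoff = as.vector(res$runoff),
      interception_loss = as.vector(res$interception_loss)
    )
    return(structure(out, class = c("wb_daily", class(out)),
                     calendar = gf$calendar, params = params))
  }

  labels <- if (water_year) water_year(dates) else
    as.integer(format(dates, "%Y"))
  res <- eng$run_annual(labels)
  keep <- complete_year_labels(dates, labels, water_year, gf$calendar)
  if (length(keep) < length(unique(labels))) {
    warn(paste0("Dropping partial year(s): ",
                paste(setdiff(unique(labels), keep), collapse = ", ")))
  }
  ki <- match(keep, res$years)
  ncell <- length(cells)
  grab <- function(m) as.vector(m[ki, , drop = FALSE])
  out <- tibble::tibble(
    cell = rep(cells, each = length(keep)),
    year = rep(keep, times = ncell),
    precip = grab(res$precip), pet = grab(res$pet), aet = grab(res$aet),
    cwd = grab(res$cwd), rain = grab(res$rain),
    snowfall = grab(res$snowfall), melt = grab(res$melt),
    runoff = grab(res$runoff),
    interception_loss = grab(res$interception_loss),
    swe_start = grab(res$swe_start), soil_start = grab(res$soil_start),
    swe_end = grab(res$swe_end), soil_end = grab(res$soil_end)
  )
  structure(out, class = c("wb_annual", class(out)),
            calendar = gf$calendar, params = params,
            year_type = if (water_year) "water" else "calendar")
}

# Core engine: closures over precomputed per-cell terrain and radiation.
wb_engine <- function(gf, attributes, params, init = NULL) {
  cells <- gf$cells
  at <- attributes[match(cells, attributes$cell), ]
  if (any(is.na(at$cell))) {
    abort(paste0("Attributes missing for cell(s): ",
                 paste(utils::head(cells[is.na(at$cell)], 5), collapse = ", ")))
  }
  ncell <- length(cells)
  nd <- length(gf$dates)
  doy <- as.integer(format(gf$dates, "%j"))
  # noleap series reindex post-Feb-28 days so J stays 1..365
  if (gf$calendar == "noleap") doy <- ndvi_day_index(gf$dates)

  hli <- heat_load_index(at$latitude, at$slope, at$aspect)
  udoy <- sort(unique(doy))
  ra_by_doy <- matrix(0, 366, ncell)
  for (j in udoy) {
    ra_by_doy[j, ] <- extraterrestrial_radiation(at$latitude, j, params)
  }
  ndvi_idx <- ndvi_day_index(gf$dates)
  scal_by_day <- NULL
  if ("ndvi" %in% names(at)) {
    ndvi_mat <- vapply(at$ndvi, identity, numeric(365))  # 365 x ncell
    scal_by_day <- ndvi_aet_scalar(ndvi_mat, params)
  }
  t50 <- if ("snow_t50" %in% names(at)) at$snow_t50 else params$snow_t50
  whc <- at$whc

  init_state <- function() {
    if (is.null(init)) {
      list(swe = rep(0, ncell), soil = whc)
    } else {
      list(swe = rep_len(init$swe, ncell), soil = rep_len(init$soil, ncell))
    }
  }

  day_step <- function(state, d) {
    tmean <- (gf$tmin[d, ] + gf$tmax[d, ]) / 2
    precip <- gf$prcp[d, ]
    ic <- intercept_precip(precip, params)
    sn <- step_snow(state$swe, ic$throughfall, tmean, params, t50)
    pet <- oudin_pet(ra_by_doy[doy[d], ], tmean, params) * hli
    scalar <- if (is.null(scal_by_day)) 1 else scal_by_day[ndvi_idx[d], ]
    sb <- step_soil(state$soil, sn$rain + sn$melt, pet * scalar, whc)
    fx <- list(
      swe = sn$swe, soil = sb$soil, pet = pet,
      aet = sb$aet + ic$interception_loss,
      cwd = pmax(0, pet - (sb$aet + ic$interception_loss)),
      rain = sn$rain, snowfall = sn$snowfall, melt = sn$melt,
      runoff = sb$runoff, interception_loss = ic$interception_loss,
      precip = precip
    )
    bad <- is.na(tmean) | is.na(precip)
    if (any(bad)) {
      for (nm in setdiff(names(fx), c("swe", "soil"))) fx[[nm]][bad] <- NA_real_
      fx$swe[bad] <- state$swe[bad]
      fx$soil[bad] <- state$soil[bad]
    }
    fx
  }

  flux_names <- c("pet", "aet", "cwd", "rain", "snowfall", "melt",
                  "runoff", "interception_loss", "precip")

  run_daily <- function() {
    state <- init_state()
    keep <- c("swe", "soil", flux_names[flux_names != "precip"])
    out <- lapply(setNames(keep, keep),
                  function(nm) matrix(NA_real_, nd, ncell))
    for (d in seq_len(nd)) {
      fx <- day_step(state, d)
      state <- list(swe = fx$swe, soil = fx$soil)
      for (nm in keep) out[[nm]][d, ] <- fx[[nm]]
    }
    out
  }

  run_annual <- function(labels) {
    state <- init_state()
    years <- unique(labels)
    ny <- length(years)
    acc <- lapply(setNames(flux_names, flux_names),
                  function(nm) matrix(0, ny, ncell))
    swe_start <- soil_start <- swe_end <- soil_end <-
      matrix(NA_real_, ny, ncell)
    yi <- match(labels, years)
    prev <- 0L
    for (d in seq_len(nd)) {
      y <- yi[d]
      if (y != prev) {
        swe_start[y, ] <- state$swe
        soil_start[y, ] <- state$soil
        prev <- y
      }
      fx <- day_step(state, d)
      state <- list(swe = fx$swe, soil = fx$soil)
      for (nm in flux_names) acc[[nm]][y, ] <- acc[[nm]][y, ] + fx[[nm]]
      swe_end[y, ] <- state$swe
      soil_end[y, ] <- state$soil
    }
    c(acc, list(years = years, swe_start = swe_start,
                soil_start = soil_start, swe_end = swe_end,
                soil_end = soil_end))
  }

  run_cycle <- function(n_cycles) {
    state <- init_state()
    prev_state <- state
    for (k in seq_len(n_cycles)) {
      prev_state <- state
      for (d in seq_len(nd)) {
        fx <- day_step(state, d)
        state <- list(swe = fx$swe, soil = fx$soil)
      }
    }
    delta <- max(abs(state$swe - prev_state$swe),
                 abs(state$soil - prev_state$soil))
    list(state = state, delta = delta)
  }

  list(run_daily = run_daily, run_annual = run_annual,
       run_cycle = run_cycle, cells = cells)
}

# Year labels whose full span is present in the daily index.
complete_year_labels <- function(dates, labels, water_year, calendar) {
  ulab <- unique(labels)
  starts <- if (water_year) as.Date(paste0(ulab - 1L, "-10-01")) else
    as.Date(paste0(ulab, "-01-01"))
  ends <- if (water_year) as.Date(paste0(ulab, "-09-30")) else
    as.Date(paste0(ulab, "-12-31"))
  n_expected <- as.integer(ends - starts) + 1L
  if (calendar == "noleap") {
    for (k in seq_along(ulab)) {
      span <- seq(starts[k], ends[k], by = "day")
      n_expected[k] <- n_expected[k] - sum(is_feb29(span))
    }
  }
  counts <- tabulate(match(labels, ulab))
  ulab[counts == n_expected]
}

#' Spin up the model to a quasi-equilibrium initial state
#'
#' Repeats the first forcing year `n_cycles` times, carrying state
#' between cycles, and returns the end state together with the maximum
#' absolute state change between the final two cycles as a convergence
#' diagnostic. Initial storages are not observable quantities, so
#' first-year totals of any run are burn-in sensitive; spin-up bounds
#' that sensitivity.
#'
#' @inheritParams wb_run
#' @param n_cycles Number of one-year cycles, >= 1.
#' @return List with `state` (list of `swe`, `soil` vectors, one value
#'   per cell in forcing order), `delta` (mm, max state change over the
#'   last cycle) and `cells`.
#' @export
wb_spin_up <- function(forcing, attributes, params = wb_params(),
                       n_cycles = 1) {
  stopifnot(n_cycles >= 1)
  gf <- as_grid_forcing(forcing)
  first_year_end <- min(max(gf$dates),
                        seq(gf$dates[1], by = "1 year", length.out = 2)[2] - 1)
  keep <- gf$dates <= first_year_end
  gf1 <- wb_grid_forcing(gf$dates[keep],
                         gf$tmin[keep, , drop = FALSE],
                         gf$tmax[keep, , drop = FALSE],
                         gf$prcp[keep, , drop = FALSE],
                         gf$cells, calendar = gf$calendar)
  eng <- wb_engine(gf1, wb_attributes(attributes), params)
  res <- eng$run_cycle(n_cycles)
  list(state = res$state, delta = res$delta, cells = gf1$cells)
}

#' Aggregate daily fluxes to annual or water-year totals
#'
#' Sums each flux column of a daily table over calendar years or water
#' years, per cell. Only complete years are kept; partial years at the
#' ends of the record are dropped with a warning. State columns (`swe`,
#' `soil_water`) are reported at the year's last day rather than summed.
#'
#' @param daily A `wb_daily` table from [wb_run()], or any data frame
#'   with `cell`, `date` and numeric flux columns.
#' @param water_year Use Oct--Sep water years (labeled by ending year).
#' @param calendar `"gregorian"` or `"noleap"`; defaults to the table's
#'   calendar attribute.
#' @return A tibble with `cell`, `year` and one total per flux column,
#'   class `wb_annual`.
#' @export
annual_totals <- function(daily, water_year = FALSE, calendar = NULL) {
  calendar <- calendar %||% attr(daily, "calendar") %||% "gregorian"
  stopifnot(all(c("cell", "date") %in% names(daily)))
  labels <- if (water_year) water_year(daily$date) else
    as.integer(format(daily$date, "%Y"))
  d1 <- daily[daily$cell == daily$cell[1], ]
  keep <- complete_year_labels(
    d1$date, if (water_year) water_year(d1$date) else
      as.integer(format(d1$date, "%Y")),
    water_year, calendar)
  if (length(keep) == 0) abort("No complete years in selection")
  if (length(keep) < length(unique(labels))) {
    warn(paste0("Dropping partial year(s): ",
                paste(setdiff(unique(labels), keep), collapse = ", ")))
  }
  x <- tibble::as_tibble(as.data.frame(daily))
  x$year <- labels
  x <- x[x$year %in% keep, ]
  state_cols <- intersect(c("swe", "soil_water"), names(x))
  flux_cols <- setdiff(names(x)[vapply(x, is.numeric, logical(1))],
                       c("cell", "year", state_cols))
  out <- x |>
    dplyr::group_by(.data$cell, .data$year) |>
    dplyr::arrange(.data$date, .by_group = TRUE) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(flux_cols), sum),
      dplyr::across(dplyr::all_of(state_cols), dplyr::last),
      .groups = "drop"
    )
  structure(out, class = c("wb_annual", class(out)),
            year_type = if (water_year) "water" else "calendar")
}

#' Per-cell, per-year mass-balance residual
#'
#' Water conservation audit of an annual run table:
#' `residual = precip - aet - runoff - (storage_end - storage_start)`
#' where storage is SWE + soil water. Residuals should be at floating
#' round-off (well below 1e-6 mm per year) for any valid run.
#'
#' @param annual A `wb_annual` table from `wb_run(output = "annual")`
#'   (must carry the storage bookkeeping columns).
#' @return Tibble with `cell`, `year`, `residual` (mm/year).
#' @export
wb_mass_balance <- function(annual) {
  need <- c("precip", "aet", "runoff", "swe_start", "soil_start",
            "swe_end", "soil_end")
  stopifnot(all(need %in% names(annual)))
  tibble::tibble(
    cell = annual$cell, year = annual$year,
    residual = annual$precip - annual$aet - annual$runoff -
      (annual$swe_end + annual$soil_end -
         annual$swe_start - annual$soil_start)
  )
}

#' Snow-phenology metrics per water year
#'
#' Summarizes a daily SWE series into the standard snow-season metrics,
#' per cell and water year (Oct 1--Sep 30, labeled by ending year):
#' first day of the water year with snow cover (SWE > 0), last such day
#' plus one, peak SWE, and the count of days with snow cover. Incomplete
#' water years are dropped. Snow-free years report `snow_days = 0`,
#' `peak_swe = 0` and `NA` for the day metrics.
#'
#' @param daily A table with `cell`, `date` and `swe` columns (e.g. from
#'   `wb_run(output = "daily")`).
#' @param calendar `"gregorian"` or `"noleap"` (defaults to the table's
#'   attribute); controls day-of-water-year counting.
#' @return Tibble with `cell`, `water_year`, `first_snow_day`,
#'   `last_snow_day_plus1`, `peak_swe`, `snow_days`.
#' @export
snow_phenology <- function(daily, calendar = NULL) {
  calendar <- calendar %||% attr(daily, "calendar") %||% "gregorian"
  stopifnot(all(c("cell", "date", "swe") %in% names(daily)))
  x <- tibble::as_tibble(as.data.frame(daily))
  x$water_year <- water_year(x$date)
  x$wyday <- water_year_day(x$date, calendar)
  d1 <- x[x$cell == x$cell[1], ]
  keep <- complete_year_labels(d1$date, d1$water_year, TRUE, calendar)
  x <- x[x$water_year %in% keep, ]
  if (nrow(x) == 0) abort("No complete water years in selection")
  x |>
    dplyr::group_by(.data$cell, .data$water_year) |>
    dplyr::summarise(
      first_snow_day = if (any(.data$swe > 0))
        min(.data$wyday[.data$swe > 0]) else NA_integer_,
      last_snow_day_plus1 = if (any(.data$swe > 0))
        max(.data$wyday[.data$swe > 0]) + 1L else NA_integer_,
      peak_swe = max(.data$swe),
      snow_days = sum(.data$swe > 0),
      .groups = "drop"
    )
}
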