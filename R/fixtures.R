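#' Specification of a synthetic forcing/attribute fixture
#'
#' Describes a reproducible synthetic study region: grid shape, daily
#' calendar span, a sinusoidal temperature climate with elevational
#' lapse, optional linear trends (including elevation-dependent
#' warming), a Bernoulli-gamma precipitation generator with optional
#' seasonality, orographic enhancement and trend, and static attribute
#' fields (elevation ramp, slope/aspect, water holding capacity, NDVI
#' seasonal curve). A fixed seed makes every derived fixture
#' byte-identical. Synthetic elevation exists only here, to drive lapse
#' rates and attribute gradients; the model itself never consumes it.
#'
#' @param nrow,ncol Grid shape; row 1 is the northernmost row.
#' @param years Calendar years of daily forcing.
#' @param seed Integer RNG seed.
#' @param calendar `"noleap"` (365-day, Daymet-like; default) or
#'   `"gregorian"`.
#' @param cellsize Cell size in map units (m).
#' @param lat_range Latitudes of the north and south grid edges
#'   (decimal degrees).
#' @param tmean_base Sea-level annual-mean temperature (degrees C).
#' @param seasonal_amplitude Half-range of the annual temperature cycle
#'   (degrees C), peaking July 21.
#' @param diurnal_range `tmax - tmin` (degrees C).
#' @param lapse_rate Temperature lapse with elevation (degrees C per km;
#'   negative).
#' @param trend_temp Imposed warming trend (degrees C per decade).
#' @param edw Elevation-dependent warming: extra warming (degrees C per
#'   decade) at the top of the elevation ramp, scaling linearly from 0
#'   at its base.
#' @param temp_noise_sd Daily temperature noise (degrees C, i.i.d.).
#' @param p_wet Daily precipitation occurrence probability.
#' @param wet_day_mean Mean wet-day amount (mm).
#' @param gamma_shape Gamma shape of wet-day amounts.
#' @param seasonal_precip_amplitude Fractional seasonal modulation of
#'   occurrence probability (winter-peaking when positive).
#' @param trend_precip Fractional precipitation trend per decade
#'   (e.g. 0.06 = +6% per decade).
#' @param orographic Fractional precipitation enhancement at the top of
#'   the elevation ramp.
#' @param elev_range Elevation at the two ends of the west--east ramp (m).
#' @param whc_range Range of soil water holding capacity (mm); deeper
#'   soils at lower elevation.
#' @param slope_range Range of terrain slope (degrees).
#' @param ndvi_mean,ndvi_amplitude Mean and seasonal half-range of the
#'   NDVI climatology (summer-peaking, clamped to `[-1, 1]`).
#' @param snow_t50 Rain--snow partition midpoint for all cells (degrees C).
#' @return A list of class `wb_fixture_spec`.
#' @export
fixture_spec <- function(nrow = 12, ncol = 12, years = 1980:2019,
                         seed = 1, calendar = c("noleap", "gregorian"),
                         cellsize = 1000,
                         lat_range = c(42, 38),
                         tmean_base = 12, seasonal_amplitude = 10,
                         diurnal_range = 10, lapse_rate = -6.5,
                         trend_temp = 0, edw = 0, temp_noise_sd = 2,
                         p_wet = 0.25, wet_day_mean = 8,
                         gamma_shape = 0.7,
                         seasonal_precip_amplitude = 0,
                         trend_precip = 0, orographic = 0,
                         elev_range = c(300, 2300),
                         whc_range = c(80, 250),
                         slope_range = c(0, 25),
                         ndvi_mean = 0.45, ndvi_amplitude = 0.25,
                         snow_t50 = 1.0) {
  calendar <- match.arg(calendar)
  spec <- as.list(environment())
  stopifnot(nrow >= 1, ncol >= 1, length(years) >= 1,
            p_wet >= 0, p_wet <= 1, wet_day_mean > 0, gamma_shape > 0,
            all(whc_range > 0))
  structure(spec, class = "wb_fixture_spec")
}

# Deterministic elevation ramp along columns (west low unless reversed
# via elev_range), no RNG.
elevation_field <- function(spec) {
  frac <- if (spec$ncol > 1) (seq_len(spec$ncol) - 1) / (spec$ncol - 1)
  else 0
  elev_col <- spec$elev_range[1] +
    frac * (spec$elev_range[2] - spec$elev_range[1])
  grid <- tidyr::expand_grid(row = seq_len(spec$nrow),
                             col = seq_len(spec$ncol))
  grid$cell <- seq_len(nrow(grid))
  grid$elevation <- elev_col[grid$col]
  grid
}

elev_fraction <- function(spec, elevation) {
  span <- diff(range(spec$elev_range))
  if (span == 0) rep(0, length(elevation))
  else (elevation - min(spec$elev_range)) / span
}

#' Generate synthetic daily forcing
#'
#' Draws a seeded realization of the fixture's climate: daily mean
#' temperature as annual sinusoid + lapse + trend + Gaussian noise,
#' split symmetrically into `tmin`/`tmax`; precipitation as
#' Bernoulli-gamma with seasonal occurrence, orographic enhancement and
#' a multiplicative linear trend (floored at zero). Same seed, same
#' bytes.
#'
#' @param spec A [fixture_spec()].
#' @return A [wb_grid_forcing] object.
#' @export
make_forcing <- function(spec) {
  stopifnot(inherits(spec, "wb_fixture_spec"))
  set.seed(spec$seed)
  dates <- wb_dates(paste0(min(spec$years), "-01-01"),
                    paste0(max(spec$years), "-12-31"), spec$calendar)
  nd <- length(dates)
  doy <- ndvi_day_index(dates)  # 1..365 in both calendars
  grid <- elevation_field(spec)
  ncell <- nrow(grid)
  efrac <- elev_fraction(spec, grid$elevation)
  t_years <- as.numeric(dates - dates[1]) / 365.25

  season <- spec$tmean_base + spec$seasonal_amplitude *
    cos(2 * pi * (doy - 202) / 365)
  lapse <- spec$lapse_rate * grid$elevation / 1000
  warm_rate <- spec$trend_temp + spec$edw * efrac  # degC per decade
  tmean <- outer(season, rep(1, ncell)) +
    outer(rep(1, nd), lapse) +
    outer(t_years / 10, warm_rate) +
    matrix(stats::rnorm(nd * ncell, sd = spec$temp_noise_sd), nd, ncell)
  half <- spec$diurnal_range / 2

  p_doy <- spec$p_wet * (1 + spec$seasonal_precip_amplitude *
                           cos(2 * pi * (doy - 15) / 365))
  p_doy <- pmin(1, pmax(0, p_doy))
  wet <- matrix(stats::runif(nd * ncell), nd, ncell) <
    outer(p_doy, rep(1, ncell))
  amount <- matrix(
    stats::rgamma(nd * ncell, shape = spec$gamma_shape,
                  scale = spec$wet_day_mean / spec$gamma_shape),
    nd, ncell)
  trend_mult <- pmax(0, 1 + spec$trend_precip * t_years / 10)
  oro_mult <- 1 + spec$orographic * efrac
  prcp <- wet * amount * outer(trend_mult, oro_mult)

  wb_grid_forcing(dates, tmin = tmean - half, tmax = tmean + half,
                  prcp = prcp, cells = grid$cell,
                  calendar = spec$calendar)
}

#' Generate synthetic static attributes
#'
#' Elevation ramps along columns; latitude spans `lat_range` from the
#' north row down; water holding capacity decreases linearly with
#' elevation across `whc_range`; slope and aspect are seeded uniform
#' draws; the NDVI climatology is a summer-peaking sinusoid shared by
#' all cells. Also carries `x`, `y` cell-center coordinates and the
#' synthetic `elevation` (for analysis stratification only; the model
#' never reads it).
#'
#' @param spec A [fixture_spec()].
#' @return A [wb_attributes] tibble.
#' @export
make_attributes <- function(spec) {
  stopifnot(inherits(spec, "wb_fixture_spec"))
  set.seed(spec$seed + 1000L)
  grid <- elevation_field(spec)
  efrac <- elev_fraction(spec, grid$elevation)
  lat_row <- if (spec$nrow > 1) {
    seq(spec$lat_range[1], spec$lat_range[2], length.out = spec$nrow)
  } else {
    mean(spec$lat_range)
  }
  ndvi_curve <- pmin(1, pmax(-1, spec$ndvi_mean + spec$ndvi_amplitude *
                               cos(2 * pi * (1:365 - 202) / 365)))
  at <- tibble::tibble(
    cell = grid$cell,
    row = grid$row,
    col = grid$col,
    x = (grid$col - 0.5) * spec$cellsize,
    y = (spec$nrow - grid$row + 0.5) * spec$cellsize,
    latitude = lat_row[grid$row],
    elevation = grid$elevation,
    slope = stats::runif(nrow(grid), spec$slope_range[1],
                         spec$slope_range[2]),
    aspect = stats::runif(nrow(grid), 0, 360) %% 360,
    whc = spec$whc_range[2] -
      efrac * (spec$whc_range[2] - spec$whc_range[1]),
    snow_t50 = spec$snow_t50,
    ndvi = rep(list(ndvi_curve), nrow(grid))
  )
  wb_attributes(at)
}

#' Named end-to-end scenarios
#'
#' Three seeded study conditions exercising the qualitative contrasts
#' the model is built to resolve:
#'
#' * `"drying_west"`: semi-arid, sparse vegetation, +0.5 degC/decade
#'   warming with slightly declining precipitation; evaporative demand
#'   outgrows supply, so CWD trends upward.
#' * `"wetting_east"`: temperate, denser vegetation, +6%/decade
#'   precipitation with mild warming; supply catches up with demand, so
#'   AET rises and CWD falls.
#' * `"alpine_gradient"`: a 500--3000 m elevation ramp with orographic
#'   precipitation and elevation-dependent warming (0.2 degC/decade at
#'   the base to 1.2 at the top); the combined AET:CWD change is
#'   largest at high elevation.
#'
#' @param name One of `"drying_west"`, `"wetting_east"`,
#'   `"alpine_gradient"`.
#' @param seed Integer seed.
#' @param nrow,ncol Grid shape (default 12 x 12).
#' @param years Forcing years (default 1980:2019).
#' @return A list of class `wb_scenario` with elements `name`, `spec`,
#'   `forcing` ([wb_grid_forcing]) and `attributes` ([wb_attributes]).
#' @examples
#' sc <- make_scenario("drying_west", seed = 7, nrow = 2, ncol = 2,
#'                     years = 2000:2002)
#' sc$forcing
#' @export
make_scenario <- function(name, seed = 1, nrow = 12, ncol = 12,
                          years = 1980:2019) {
  scenarios <- c("drying_west", "wetting_east", "alpine_gradient")
  if (!name %in% scenarios) {
    abort(paste0("Unknown scenario '", name, "'. Available: ",
                 paste(scenarios, collapse = ", ")))
  }
  base <- list(nrow = nrow, ncol = ncol, years = years, seed = seed)
  spec <- switch(name,
    drying_west = do.call(fixture_spec, c(base, list(
      trend_temp = 0.5, trend_precip = -0.03,
      p_wet = 0.18, wet_day_mean = 6,
      whc_range = c(50, 150), elev_range = c(300, 1500),
      ndvi_mean = 0.35, ndvi_amplitude = 0.15
    ))),
    wetting_east = do.call(fixture_spec, c(base, list(
      trend_temp = 0.1, trend_precip = 0.06,
      p_wet = 0.3, wet_day_mean = 5,
      whc_range = c(100, 200), elev_range = c(100, 500),
      ndvi_mean = 0.7, ndvi_amplitude = 0.15
    ))),
    alpine_gradient = do.call(fixture_spec, c(base, list(
      trend_temp = 0.2, edw = 1.0, orographic = 0.8,
      p_wet = 0.3, wet_day_mean = 7,
      whc_range = c(80, 150), elev_range = c(500, 3000),
      ndvi_mean = 0.5, ndvi_amplitude = 0.2
    )))
  )
  structure(
    list(name = name, spec = spec, forcing = make_forcing(spec),
         attributes = make_attributes(spec)),
    class = "wb_scenario"
  )
}
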