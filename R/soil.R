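#' Canopy interception
#'
#' A fixed fraction of incoming precipitation is intercepted by the
#' canopy and evaporated the same day; the rest is throughfall. Default
#' fraction is 0 (feature off).
#'
#' @param precip Incoming precipitation (mm, >= 0); vectorized.
#' @param params A [wb_params].
#' @return List with `throughfall` and `interception_loss` (mm).
#' @export
intercept_precip <- function(precip, params = wb_params()) {
  if (any(precip < 0, na.rm = TRUE)) abort("Negative precipitation")
  loss <- params$interception_fraction * precip
  list(throughfall = precip - loss, interception_loss = loss)
}

#' NDVI-based evapotranspiration scalar
#'
#' Vegetation structure and cover scale evaporative demand: the daily
#' NDVI climatology value maps linearly to a multiplier between
#' `aet_scalar_min` (at NDVI <= 0) and `aet_scalar_max` (at NDVI = 1).
#' The multiplier is applied to the PET demand presented to the soil;
#' reported PET itself is unscaled, keeping CWD = PET - AET literal.
#'
#' @param ndvi NDVI in `[-1, 1]`; vectorized.
#' @param params A [wb_params] with the scalar bounds.
#' @return Multiplier in `[aet_scalar_min, aet_scalar_max]`.
#' @examples
#' ndvi_aet_scalar(c(-0.2, 0.5, 1))   # 0, 0.5, 1 with default bounds
#' @export
ndvi_aet_scalar <- function(ndvi, params = wb_params()) {
  stopifnot(all(ndvi >= -1 & ndvi <= 1, na.rm = TRUE))
  lo <- params$aet_scalar_min
  hi <- params$aet_scalar_max
  lo + (hi - lo) * pmin(pmax(ndvi, 0), 1)
}

#' One day of the Thornthwaite--Mather soil bucket
#'
#' Routes the day's liquid water input (rain + melt + any throughfall
#' already net of interception) against the evaporative demand. When
#' supply meets demand, AET equals demand and the surplus recharges the
#' bucket, spilling as same-day runoff once the water holding capacity is
#' full. When demand exceeds supply, the deficit draws soil water down
#' the exponential Thornthwaite--Mather drying curve:
#' `extraction = soil * (1 - exp(-(demand - supply) / whc))`,
#' so a dry bucket yields water ever more reluctantly and soil water can
#' never go negative.
#'
#' @param soil Soil water at start of day (mm, `0 <= soil <= whc`).
#' @param water_in Liquid water input (mm/day, >= 0).
#' @param demand Evaporative demand presented to the soil (mm/day, >= 0).
#' @param whc Water holding capacity (mm, > 0).
#' @return List with `soil` (end-of-day storage), `aet` (mm/day) and
#'   `runoff` (mm/day).
#' @examples
#' step_soil(soil = 100, water_in = 0, demand = 10, whc = 100)
#' @export
step_soil <- function(soil, water_in, demand, whc) {
  if (any(soil < 0 | water_in < 0 | demand < 0, na.rm = TRUE)) {
    abort("step_soil inputs must be non-negative")
  }
  if (any(soil > whc, na.rm = TRUE)) abort("soil exceeds whc")
  wet <- !is.na(water_in) & !is.na(demand) & water_in >= demand
  recharge <- ifelse(wet, water_in - demand, 0)
  soil_wet <- pmin(whc, soil + recharge)
  runoff <- pmax(0, soil + recharge - whc)
  unmet <- ifelse(wet, 0, demand - water_in)
  extraction <- soil * (1 - exp(-unmet / whc))
  list(
    soil = ifelse(wet, soil_wet, soil - extraction),
    aet = ifelse(wet, demand, water_in + extraction),
    runoff = ifelse(wet, runoff, 0)
  )
}

#' One daily step of the full water balance for a cell
#'
#' Composes the compartments in the model's fixed intra-day order:
#' canopy interception of total precipitation, rain--snow partition and
#' snowpack update, Oudin PET with terrain heat load, NDVI scaling of
#' the demand, and the soil bucket. Reported AET is soil-derived AET plus
#' the same-day interception loss; CWD is `max(PET - AET, 0)`.
#'
#' Every argument is vectorized over cells, so one call advances a whole
#' grid by one day.
#'
#' @param swe,soil Start-of-day states (mm).
#' @param tmean Daily mean temperature (degrees C).
#' @param precip Daily precipitation (mm).
#' @param latitude,slope,aspect,whc Cell attributes.
#' @param ndvi Day's NDVI climatology value (or `NA` to skip vegetation
#'   scaling, i.e. scalar 1).
#' @param day_of_year 1..366.
#' @param params A [wb_params].
#' @param t50 Optional per-cell partition midpoint override.
#' @return List of end-of-day states and daily fluxes: `swe`, `soil`,
#'   `pet`, `aet`, `cwd`, `rain`, `snowfall`, `melt`, `runoff`,
#'   `interception_loss` (all mm or mm/day).
#' @export
step_cell <- function(swe, soil, tmean, precip,
                      latitude, whc, day_of_year,
                      slope = 0, aspect = 0, ndvi = NA_real_,
                      params = wb_params(), t50 = NULL) {
  ic <- intercept_precip(precip, params)
  sn <- step_snow(swe, ic$throughfall, tmean, params, t50)
  pet <- daily_pet(tmean, latitude, day_of_year, slope, aspect, params)
  scalar <- ifelse(is.na(ndvi), 1, ndvi_aet_scalar(ndvi, params))
  sb <- step_soil(soil, sn$rain + sn$melt, pet * scalar, whc)
  aet <- sb$aet + ic$interception_loss
  bad <- is.na(tmean) | is.na(precip)
  out <- list(
    swe = sn$swe, soil = sb$soil, pet = pet, aet = aet,
    cwd = pmax(0, pet - aet), rain = sn$rain, snowfall = sn$snowfall,
    melt = sn$melt, runoff = sb$runoff,
    interception_loss = ic$interception_loss
  )
  if (any(bad)) {
    # nodata forcing poisons the day's fluxes but must not corrupt the
    # carried state; states hold their previous value
    for (nm in c("pet", "aet", "cwd", "rain", "snowfall", "melt",
                 "runoff", "interception_loss")) {
      out[[nm]][bad] <- NA_real_
    }
    out$swe[bad] <- swe[bad]
    out$soil[bad] <- soil[bad]
  }
  out
}
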