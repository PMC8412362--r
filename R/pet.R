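#' Solar geometry and extraterrestrial radiation
#'
#' Potential evapotranspiration needs the day's top-of-atmosphere solar
#' radiation. `solar_declination()` recomputes the solar declination for
#' every day of the year with the standard approximation
#' `0.409 sin(2*pi*J/365 - 1.39)` (radians). `extraterrestrial_radiation()`
#' is the FAO-56 closed form: solar constant, inverse relative Earth--Sun
#' distance `1 + 0.033 cos(2*pi*J/365)`, declination and sunset hour
#' angle; the hour-angle argument is clamped so polar night returns
#' exactly 0.
#'
#' @param day_of_year Integer day of year, 1..366; vectorized.
#' @param latitude Latitude in decimal degrees, `[-90, 90]`; vectorized.
#' @param params A [wb_params] (supplies the solar constant).
#' @return Declination in radians; radiation in MJ m^-2 day^-1.
#' @examples
#' solar_declination(172)                     # near the June maximum
#' extraterrestrial_radiation(0, 81)          # equator, near equinox
#' extraterrestrial_radiation(90, 355)        # polar night: 0
#' @export
solar_declination <- function(day_of_year) {
  if (any(day_of_year < 1 | day_of_year > 366)) {
    abort("day_of_year must be in 1..366")
  }
  0.409 * sin(2 * pi * day_of_year / 365 - 1.39)
}

#' @rdname solar_declination
#' @export
extraterrestrial_radiation <- function(latitude, day_of_year,
                                       params = wb_params()) {
  stopifnot(all(abs(latitude) <= 90))
  phi <- latitude * pi / 180
  delta <- solar_declination(day_of_year)
  dr <- 1 + 0.033 * cos(2 * pi * day_of_year / 365)
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(delta))))
  ra <- (24 * 60 / pi) * params$solar_constant * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
  pmax(0, ra)
}

#' Oudin potential evapotranspiration
#'
#' The Oudin formulation estimates daily PET from temperature and
#' extraterrestrial radiation alone:
#' `PET = Ra / (lambda * rho) * (tmean + 5) / 100` (mm/day) when
#' `tmean + 5 > 0`, else 0, with `lambda = 2.45` MJ/kg and water density
#' 1 Mg/m^3 so `Ra / lambda` is an evaporative depth in mm/day. The
#' offset (5 degrees C) and scale (100) are configurable for sensitivity
#' analysis via [wb_params].
#'
#' @param ra Extraterrestrial radiation (MJ m^-2 day^-1, >= 0).
#' @param tmean Daily mean temperature (degrees C).
#' @param params A [wb_params].
#' @return PET in mm/day, >= 0.
#' @examples
#' oudin_pet(24.5, 15)   # 2 mm/day
#' oudin_pet(30, -5)     # 0: below the Oudin threshold
#' @export
oudin_pet <- function(ra, tmean, params = wb_params()) {
  if (any(ra < 0, na.rm = TRUE)) abort("Negative radiation")
  drive <- pmax(tmean + params$oudin_offset, 0)
  ra / params$lambda * drive / params$oudin_scale
}

#' Terrain heat-load index
#'
#' McCune--Keon style heat-load index from latitude, slope and aspect
#' folded about the southwest axis (`180 - |aspect - 225|` in absolute
#' value), so that at equal slope a SW-facing cell loads more heat than a
#' NE-facing one. The published regression is valid for latitudes
#' 30--60 N; latitudes outside that range are clamped with a warning.
#' The index is normalized by its flat-ground value at the same latitude,
#' so slope 0 gives exactly 1 and the index multiplies PET as a unitless
#' terrain adjustment.
#'
#' @param latitude Decimal degrees.
#' @param slope Degrees, `[0, 90]`.
#' @param aspect Degrees clockwise from north, `[0, 360)`.
#' @return Unitless positive multiplier; 1 for flat cells.
#' @examples
#' heat_load_index(40, 30, 225) > heat_load_index(40, 30, 45)  # SW > NE
#' heat_load_index(40, 0, 0)                                   # flat: 1
#' @export
heat_load_index <- function(latitude, slope, aspect) {
  stopifnot(all(slope >= 0 & slope <= 90),
            all(aspect >= 0 & aspect < 360))
  lat <- abs(latitude)
  if (any(lat < 30 | lat > 60)) {
    warn("heat_load_index: latitude outside the published 30-60 degree validity range; clamped")
    lat <- pmin(60, pmax(30, lat))
  }
  folded <- abs(180 - abs(aspect - 225)) * pi / 180
  l <- lat * pi / 180
  s <- slope * pi / 180
  hl <- function(s_) {
    0.339 + 0.808 * cos(l) * cos(s_) -
      0.196 * sin(l) * sin(s_) -
      0.482 * cos(folded) * sin(s_)
  }
  hl(s) / hl(0)
}

#' Daily potential evapotranspiration for a cell
#'
#' Composes the radiation, Oudin and terrain components:
#' `daily_pet = oudin_pet(Ra(latitude, J), tmean) * heat_load_index`.
#' The heat load multiplies the final PET, so the Oudin temperature
#' cutoff (PET = 0 at `tmean <= -5`) is terrain-independent.
#'
#' @param tmean Daily mean temperature (degrees C).
#' @param latitude,slope,aspect Cell terrain attributes (degrees).
#' @param day_of_year 1..366.
#' @param params A [wb_params].
#' @return PET in mm/day, >= 0.
#' @export
daily_pet <- function(tmean, latitude, day_of_year,
                      slope = 0, aspect = 0, params = wb_params()) {
  ra <- extraterrestrial_radiation(latitude, day_of_year, params)
  oudin_pet(ra, tmean, params) * heat_load_index(latitude, slope, aspect)
}
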