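#' Water-balance model parameters
#'
#' Bundles every tunable constant of the daily model: the rain--snow
#' partition, degree-day melt, canopy interception, the NDVI-to-AET
#' scalar, and the physical constants of the Oudin
#' potential-evapotranspiration equation. Defaults are the package's
#' reference configuration; any subset can be overridden.
#'
#' @param snow_t50 Temperature (degrees C) at which precipitation falls as
#'   50% snow. May be overridden per cell through the `snow_t50` column of
#'   the attribute table (spatially varying partition coefficients).
#' @param snow_partition_width Half-width (degrees C) of the rain--snow
#'   transition: precipitation is all snow at or below
#'   `snow_t50 - snow_partition_width` and all rain at or above
#'   `snow_t50 + snow_partition_width`.
#' @param snow_partition_shape `"linear"` for a clamped linear ramp between
#'   the two endpoints (default) or `"logistic"` for a logistic curve with
#'   the same midpoint, clamped to 0/1 outside the transition band.
#' @param melt_factor Degree-day melt rate (mm per degree C per day).
#' @param melt_threshold Temperature (degrees C) above which snow melts.
#' @param interception_fraction Fraction of incoming precipitation
#'   intercepted by the canopy and evaporated the same day, in `[0, 1)`.
#'   Default 0 (interception off).
#' @param aet_scalar_min,aet_scalar_max Bounds of the linear NDVI-to-AET
#'   demand multiplier: NDVI <= 0 maps to `aet_scalar_min`, NDVI = 1 to
#'   `aet_scalar_max`, linearly in between.
#' @param oudin_offset Temperature offset (degrees C) of the Oudin
#'   equation; PET is zero when mean temperature + offset <= 0.
#' @param oudin_scale Denominator of the Oudin equation (default 100).
#' @param lambda Latent heat of vaporization (MJ per kg), used to convert
#'   extraterrestrial radiation to an evaporative water equivalent.
#' @param solar_constant Solar constant (MJ m^-2 min^-1), FAO-56 value.
#'
#' @return An object of class `wb_params`: a named list of validated
#'   parameters.
#' @examples
#' p <- wb_params(snow_t50 = 0.5, melt_factor = 3)
#' p$melt_factor
#' @export
wb_params <- function(snow_t50 = 1.0,
                      snow_partition_width = 3.0,
                      snow_partition_shape = c("linear", "logistic"),
                      melt_factor = 4.0,
                      melt_threshold = 0.0,
                      interception_fraction = 0.0,
                      aet_scalar_min = 0.0,
                      aet_scalar_max = 1.0,
                      oudin_offset = 5.0,
                      oudin_scale = 100.0,
                      lambda = 2.45,
                      solar_constant = 0.0820) {
  snow_partition_shape <- match.arg(snow_partition_shape)
  p <- list(
    snow_t50 = snow_t50,
    snow_partition_width = snow_partition_width,
    snow_partition_shape = snow_partition_shape,
    melt_factor = melt_factor,
    melt_threshold = melt_threshold,
    interception_fraction = interception_fraction,
    aet_scalar_min = aet_scalar_min,
    aet_scalar_max = aet_scalar_max,
    oudin_offset = oudin_offset,
    oudin_scale = oudin_scale,
    lambda = lambda,
    solar_constant = solar_constant
  )
  validate_wb_params(p)
  structure(p, class = "wb_params")
}

validate_wb_params <- function(p) {
  stopifnot(
    is.numeric(p$snow_partition_width), p$snow_partition_width > 0,
    is.numeric(p$melt_factor), p$melt_factor >= 0,
    is.numeric(p$interception_fraction),
    p$interception_fraction >= 0, p$interception_fraction < 1,
    p$aet_scalar_max >= p$aet_scalar_min,
    p$lambda > 0, p$oudin_scale > 0, p$solar_constant > 0
  )
  invisible(p)
}

#' @export
print.wb_params <- function(x, ...) {
  cat("<wb_params>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}

# Coerce a plain list (e.g. from a YAML config) into wb_params,
# rejecting unknown keys with a nearest-match hint.
as_wb_params <- function(x) {
  if (inherits(x, "wb_params")) return(x)
  stopifnot(is.list(x))
  known <- names(formals(wb_params))
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0) {
    hints <- vapply(unknown, function(k) {
      d <- utils::adist(k, known)
      known[which.min(d)]
    }, character(1))
    abort(sprintf(
      "Unknown parameter key(s): %s. Did you mean: %s?",
      paste(unknown, collapse = ", "), paste(hints, collapse = ", ")
    ))
  }
  do.call(wb_params, x)
}
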