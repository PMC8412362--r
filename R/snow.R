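#' Rain--snow partition and degree-day snowmelt
#'
#' Daily precipitation is split into rain and snowfall from the daily
#' mean temperature. `snow_fraction()` is the snow fraction of
#' precipitation: 1 at or below `t50 - width`, 0 at or above
#' `t50 + width`, exactly 0.5 at `t50`, and monotone non-increasing in
#' temperature. The default shape is a clamped linear ramp across the
#' transition band; a logistic curve with the same midpoint is available
#' via `wb_params(snow_partition_shape = "logistic")` (clamped to 0/1
#' outside the band so the endpoint contract still holds). `t50` varies
#' by cell when the attribute table carries a `snow_t50` column, which is
#' how spatially varying partition coefficients (e.g. humidity-dependent
#' thresholds) enter the model.
#'
#' Melt is temperature-index: `melt_factor * (tmean - melt_threshold)`
#' mm/day above the threshold, capped at the available snowpack, zero at
#' or below it. Within a day, snowfall is added to the pack before melt
#' is taken.
#'
#' @param tmean Daily mean temperature (degrees C); vectorized.
#' @param params A [wb_params] object.
#' @param t50 Optional per-cell override of the partition midpoint
#'   (degrees C); defaults to `params$snow_t50`.
#' @return `snow_fraction()`: snow fraction in `[0, 1]`.
#' @examples
#' p <- wb_params()
#' snow_fraction(c(-10, 1, 10), p)          # 1, 0.5, 0
#' partition_precip(8, 1, p)                # 4 mm rain, 4 mm snow
#' snow_melt(swe = 100, tmean = 5, params = p)  # 20 mm
#' @export
snow_fraction <- function(tmean, params = wb_params(), t50 = NULL) {
  t50 <- t50 %||% params$snow_t50
  w <- params$snow_partition_width
  if (params$snow_partition_shape == "logistic") {
    # slope matched to the linear ramp at the midpoint: f'(t50) = -1/(2w)
    f <- 1 / (1 + exp(2 * (tmean - t50) / w))
    f[!is.na(tmean) & tmean <= t50 - w] <- 1
    f[!is.na(tmean) & tmean >= t50 + w] <- 0
  } else {
    f <- (t50 + w - tmean) / (2 * w)
    f <- pmin(1, pmax(0, f))
  }
  f
}

#' @rdname snow_fraction
#' @param precip Daily precipitation (mm, >= 0).
#' @return `partition_precip()`: a list with `rain` and `snowfall` (mm);
#'   they sum to `precip` exactly.
#' @export
partition_precip <- function(precip, tmean, params = wb_params(),
                             t50 = NULL) {
  if (any(precip < 0, na.rm = TRUE)) abort("Negative precipitation")
  fs <- snow_fraction(tmean, params, t50)
  snowfall <- precip * fs
  list(rain = precip - snowfall, snowfall = snowfall)
}

#' @rdname snow_fraction
#' @param swe Snow water equivalent available to melt (mm, >= 0).
#' @return `snow_melt()`: melt (mm), in `[0, swe]`.
#' @export
snow_melt <- function(swe, tmean, params = wb_params()) {
  potential <- params$melt_factor * pmax(0, tmean - params$melt_threshold)
  pmin(swe, potential)
}

#' @rdname snow_fraction
#' @return `step_snow()`: a list with `swe` (end-of-day pack, mm),
#'   `rain`, `snowfall`, `melt` (mm/day). Liquid water released to the
#'   soil for the day is `rain + melt`.
#' @export
step_snow <- function(swe, precip, tmean, params = wb_params(),
                      t50 = NULL) {
  if (any(swe < 0, na.rm = TRUE)) abort("Negative SWE state")
  pp <- partition_precip(precip, tmean, params, t50)
  pack <- swe + pp$snowfall
  melt <- snow_melt(pack, tmean, params)
  list(swe = pack - melt, rain = pp$rain, snowfall = pp$snowfall,
       melt = melt)
}
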