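# Independent oracles: deliberately naive, scalar, and coded without
# calling the package's own implementations.

# Daily extraterrestrial radiation by minute-wise numerical integration
# of the instantaneous irradiance Gsc * dr * cos(zenith), clamped at 0.
oracle_ra_integral <- function(lat_deg, doy, gsc = 0.0820) {
  phi <- lat_deg * pi / 180
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  minutes <- seq(0.5, 24 * 60 - 0.5, by = 1)
  omega <- (minutes / (24 * 60) - 0.5) * 2 * pi  # hour angle, rad
  cosz <- sin(phi) * sin(delta) + cos(phi) * cos(delta) * cos(omega)
  sum(pmax(0, cosz)) * gsc * dr
}

# Spencer (1971) Fourier-series declination, radians.
oracle_declination_spencer <- function(doy) {
  g <- 2 * pi * (doy - 1) / 365
  0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
}

# McCune-Keon heat-load regression evaluated directly (unnormalized).
oracle_heat_load_raw <- function(lat_deg, slope_deg, aspect_deg) {
  l <- lat_deg * pi / 180
  s <- slope_deg * pi / 180
  fa <- abs(180 - abs(aspect_deg - 225)) * pi / 180
  0.339 + 0.808 * cos(l) * cos(s) - 0.196 * sin(l) * sin(s) -
    0.482 * cos(fa) * sin(s)
}

# Scalar day-by-day Thornthwaite-Mather bucket reference: Oudin PET
# (flat terrain), no snow, no interception, no vegetation scaling.
# Formulas recoded inline; nothing shared with the package internals.
oracle_tm_bucket <- function(dates, tmean, precip, lat_deg, whc,
                             soil0 = whc) {
  doy <- as.integer(strftime(dates, "%j"))
  soil <- soil0
  out <- data.frame(soil = numeric(length(dates)),
                    aet = numeric(length(dates)),
                    pet = numeric(length(dates)),
                    runoff = numeric(length(dates)))
  phi <- lat_deg * pi / 180
  for (i in seq_along(dates)) {
    delta <- 0.409 * sin(2 * pi * doy[i] / 365 - 1.39)
    dr <- 1 + 0.033 * cos(2 * pi * doy[i] / 365)
    x <- -tan(phi) * tan(delta)
    ws <- acos(min(1, max(-1, x)))
    ra <- (1440 / pi) * 0.0820 * dr *
      (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
    ra <- max(0, ra)
    pet <- if (tmean[i] + 5 > 0) ra / 2.45 * (tmean[i] + 5) / 100 else 0
    w <- precip[i]
    if (w >= pet) {
      aet <- pet
      soil <- soil + (w - pet)
      runoff <- max(0, soil - whc)
      soil <- min(soil, whc)
    } else {
      extraction <- soil * (1 - exp(-(pet - w) / whc))
      aet <- w + extraction
      soil <- soil - extraction
      runoff <- 0
    }
    out$soil[i] <- soil
    out$aet[i] <- aet
    out$pet[i] <- pet
    out$runoff[i] <- runoff
  }
  out
}

# Normal-equations slope via explicit design-matrix solve.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# Forcing tibble for a single cell from explicit series.
site_forcing <- function(dates, tmean, prcp, drange = 0) {
  tibble::tibble(date = dates, tmin = tmean - drange / 2,
                 tmax = tmean + drange / 2, prcp = prcp)
}

flat_attributes <- function(whc = 100, latitude = 40, n = 1) {
  tibble::tibble(cell = seq_len(n), latitude = latitude, slope = 0,
                 aspect = 0, whc = whc)
}
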