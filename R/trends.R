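#' Per-cell least-squares trends in annual totals
#'
#' Fits ordinary least squares of an annual total against calendar year,
#' independently for every cell, and reports the slope (mm/year), the
#' intercept (at year 0, since years enter uncentered), the period mean
#' (mm) and the normalized change index (fraction of the mean per
#' decade). Significance is deliberately not computed by default; broad
#' spatial patterns of change, not inference, are the use case. Cells
#' with fewer than 3 non-missing years get `NA` results.
#'
#' The trend period and the mean period are independent explicit
#' arguments (e.g. slopes over 1980--2019 against a 1981--2019 mean);
#' both default to all years present.
#'
#' @param annual A `wb_annual` table (or any data frame with `cell`,
#'   `year` and the variable columns).
#' @param vars Character vector of columns to analyse, e.g.
#'   `c("aet", "cwd")`.
#' @param years Years used for the regression (default: all).
#' @param mean_years Years used for the normalizing mean (default:
#'   `years`).
#' @param se Also report the slope's standard error and p-value
#'   (default `FALSE`).
#' @return A tibble of class `wb_trends`: one row per cell and variable
#'   with `n`, `slope`, `intercept`, `mean`, `normalized_index` (and
#'   optionally `slope_se`, `p_value`).
#' @examples
#' ann <- tibble::tibble(cell = 1, year = 2000:2009,
#'                       aet = 2 * (2000:2009) + 7)
#' wb_trends(ann, "aet")$slope   # exactly 2
#' @export
wb_trends <- function(annual, vars = c("aet", "cwd"), years = NULL,
                      mean_years = NULL, se = FALSE) {
  stopifnot(all(c("cell", "year") %in% names(annual)))
  missing_vars <- setdiff(vars, names(annual))
  if (length(missing_vars) > 0) {
    abort(paste0("Variable(s) not in table: ",
                 paste(missing_vars, collapse = ", ")))
  }
  x <- tibble::as_tibble(as.data.frame(annual))
  years <- years %||% sort(unique(x$year))
  mean_years <- mean_years %||% years
  long <- tidyr::pivot_longer(x[c("cell", "year", vars)],
                              dplyr::all_of(vars),
                              names_to = "variable", values_to = "value")
  fit <- long |>
    dplyr::filter(.data$year %in% years, !is.na(.data$value)) |>
    dplyr::group_by(.data$cell, .data$variable) |>
    dplyr::summarise(
      n = dplyr::n(),
      slope = ols_slope(.data$year, .data$value),
      intercept = mean(.data$value) - slope * mean(.data$year),
      rss = sum((.data$value - intercept - slope * .data$year)^2),
      sxx = sum((.data$year - mean(.data$year))^2),
      .groups = "drop"
    )
  means <- long |>
    dplyr::filter(.data$year %in% mean_years, !is.na(.data$value)) |>
    dplyr::group_by(.data$cell, .data$variable) |>
    dplyr::summarise(mean = mean(.data$value), .groups = "drop")
  out <- dplyr::left_join(fit, means, by = c("cell", "variable"))
  out$normalized_index <- normalized_index(out$slope, out$mean)
  if (se) {
    out$slope_se <- sqrt(out$rss / pmax(out$n - 2, 1)) / sqrt(out$sxx)
    out$p_value <- 2 * stats::pt(abs(out$slope / out$slope_se),
                                 df = out$n - 2, lower.tail = FALSE)
  }
  out$rss <- NULL
  out$sxx <- NULL
  structure(out, class = c("wb_trends", class(out)),
            years = years, mean_years = mean_years)
}

# Closed-form OLS slope (normal equations); NA with < 3 points or
# degenerate x.
ols_slope <- function(x, y) {
  if (length(x) < 3) return(NA_real_)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) return(NA_real_)
  sum((x - mean(x)) * (y - mean(y))) / sxx
}

#' Trend on a single annual series
#'
#' Convenience single-series version of [wb_trends()].
#'
#' @param years Numeric vector of calendar years.
#' @param values Annual totals (mm); `NA`s dropped pairwise.
#' @return One-row tibble with `n`, `slope`, `intercept`, `mean`,
#'   `normalized_index`.
#' @export
pixel_trend <- function(years, values) {
  stopifnot(length(years) == length(values))
  ok <- !is.na(years) & !is.na(values)
  x <- years[ok]
  y <- values[ok]
  slope <- ols_slope(x, y)
  m <- if (length(y) > 0) mean(y) else NA_real_
  tibble::tibble(
    n = length(y),
    slope = slope,
    intercept = if (is.na(slope)) NA_real_ else m - slope * mean(x),
    mean = m,
    normalized_index = normalized_index(slope, m)
  )
}

#' Normalized change index (fraction of the mean per decade)
#'
#' `(slope / mean) * 10`: the regression slope in mm/year expressed as a
#' fraction of the period mean per decade, so areas with small baseline
#' values register proportionally. Stored as a fraction; multiply by 100
#' to display as percent per decade. `NA` where the mean is 0.
#'
#' @param slope Trend slope (mm/year).
#' @param mean Period mean (mm).
#' @return Fraction of the mean per decade; sign follows the slope.
#' @examples
#' normalized_index(5, 250)    # 0.2 per decade (20% per decade)
#' @export
normalized_index <- function(slope, mean) {
  ifelse(!is.na(mean) & mean != 0, slope / mean * 10, NA_real_)
}

#' Two-period means per cell
#'
#' Arithmetic means of annual totals over two year ranges, the start and
#' end points of change vectors.
#'
#' @inheritParams wb_trends
#' @param period1,period2 Year vectors, e.g. `1980:1999` and
#'   `2000:2019`; must be non-empty subsets of the available years.
#' @return Tibble with `cell`, `variable`, `mean1`, `mean2`.
#' @export
wb_period_means <- function(annual, vars = c("aet", "cwd"),
                            period1, period2) {
  stopifnot(all(c("cell", "year") %in% names(annual)))
  x <- tibble::as_tibble(as.data.frame(annual))
  for (p in list(period1, period2)) {
    if (!any(x$year %in% p)) abort("Empty period: no matching years")
  }
  long <- tidyr::pivot_longer(x[c("cell", "year", vars)],
                              dplyr::all_of(vars),
                              names_to = "variable", values_to = "value")
  long |>
    dplyr::group_by(.data$cell, .data$variable) |>
    dplyr::summarise(
      mean1 = mean(.data$value[.data$year %in% period1], na.rm = TRUE),
      mean2 = mean(.data$value[.data$year %in% period2], na.rm = TRUE),
      .groups = "drop"
    )
}

#' Bivariate AET:CWD change vectors
#'
#' Each location's two-period mean position in the plane with CWD on the
#' horizontal axis and AET on the vertical axis defines a vector from
#' the first-period point to the second. Its Euclidean length is the
#' intensity of combined change (mm); its direction class records the
#' sign of change of each variable: `"+CWD+AET"`, `"+CWD-AET"`,
#' `"-CWD+AET"`, `"-CWD-AET"`, or `"no change"` for a zero vector.
#' Tie-break: a component that is exactly unchanged is classed as
#' increasing (`+`), documented here and stable.
#'
#' @param cwd1,aet1 First-period means (mm); vectorized.
#' @param cwd2,aet2 Second-period means (mm).
#' @return Tibble with the endpoint coordinates, displacement (`d_cwd`,
#'   `d_aet`), `intensity` (mm) and `direction_class`.
#' @examples
#' change_vector(300, 400, 303, 404)$intensity   # 5 (3-4-5 triangle)
#' @export
change_vector <- function(cwd1, aet1, cwd2, aet2) {
  d_cwd <- cwd2 - cwd1
  d_aet <- aet2 - aet1
  intensity <- sqrt(d_cwd^2 + d_aet^2)
  cls <- paste0(ifelse(d_cwd >= 0, "+", "-"), "CWD",
                ifelse(d_aet >= 0, "+", "-"), "AET")
  cls[!is.na(intensity) & intensity == 0] <- "no change"
  cls[is.na(intensity)] <- NA_character_
  tibble::tibble(cwd1 = cwd1, aet1 = aet1, cwd2 = cwd2, aet2 = aet2,
                 d_cwd = d_cwd, d_aet = d_aet, intensity = intensity,
                 direction_class = cls)
}

#' @rdname change_vector
#' @inheritParams wb_period_means
#' @param annual A `wb_annual` table with `aet` and `cwd` columns.
#' @return `wb_change_vectors()`: one row per cell, class
#'   `wb_change_vectors`.
#' @export
wb_change_vectors <- function(annual, period1 = 1980:1999,
                              period2 = 2000:2019) {
  pm <- wb_period_means(annual, c("aet", "cwd"), period1, period2)
  wide <- tidyr::pivot_wider(pm, names_from = "variable",
                             values_from = c("mean1", "mean2"))
  cv <- change_vector(wide$mean1_cwd, wide$mean1_aet,
                      wide$mean2_cwd, wide$mean2_aet)
  out <- dplyr::bind_cols(wide["cell"], cv)
  structure(out, class = c("wb_change_vectors", class(out)),
            period1 = period1, period2 = period2)
}

#' Equal-count bivariate AET:CWD zones
#'
#' Classifies cells into a k-by-k grid of zones by marginal equal-count
#' bins of AET and CWD: each variable is split into k bins holding (up
#' to ties) the same number of valid cells, and a cell's zone is the
#' pair (AET bin, CWD bin). Binning is by ranks, so zone labels are
#' exactly invariant to any monotone transform of either variable;
#' values tied on a bin boundary go to the lower bin.
#'
#' @param x A data frame with one row per cell.
#' @param aet,cwd Column names (character) of the two variables.
#' @param n_zones Total number of zones; must be a perfect square k^2.
#' @return `x` with integer `aet_bin`, `cwd_bin` (1 = lowest) and a
#'   `zone` label `"A<i>C<j>"`; class `wb_zones`.
#' @export
bivariate_zones <- function(x, aet = "aet", cwd = "cwd", n_zones = 9) {
  k <- sqrt(n_zones)
  if (k != floor(k)) abort("n_zones must be a perfect square")
  k <- as.integer(k)
  stopifnot(all(c(aet, cwd) %in% names(x)))
  va <- x[[aet]]
  vc <- x[[cwd]]
  if (all(is.na(va) | is.na(vc))) abort("All cells are nodata")
  bin_of <- function(v) {
    ok <- !is.na(v)
    r <- rank(v[ok], ties.method = "average")
    b <- pmin(k, pmax(1L, ceiling(r / length(r) * k)))
    out <- rep(NA_integer_, length(v))
    out[ok] <- as.integer(b)
    out
  }
  x <- tibble::as_tibble(x)
  x$aet_bin <- bin_of(va)
  x$cwd_bin <- bin_of(vc)
  x$zone <- ifelse(is.na(x$aet_bin) | is.na(x$cwd_bin), NA_character_,
                   paste0("A", x$aet_bin, "C", x$cwd_bin))
  structure(x, class = c("wb_zones", class(x)), k = k)
}

#' Per-category distribution summaries
#'
#' Summaries of one or more per-cell values within the categories of an
#' aligned categorical mask (e.g. ecoregion labels): count, mean, sd,
#' and the 5/25/50/75/95 percent quantiles, per category and variable.
#'
#' @param x Data frame with one row per cell.
#' @param vars Character vector of value columns.
#' @param category Name of the category column.
#' @return Tibble with one row per (category, variable).
#' @export
category_summary <- function(x, vars, category = "category") {
  stopifnot(all(c(vars, category) %in% names(x)))
  long <- tidyr::pivot_longer(
    tibble::as_tibble(x)[c(category, vars)],
    dplyr::all_of(vars), names_to = "variable", values_to = "value")
  long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(category)),
                    .data$variable) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      sd = stats::sd(.data$value, na.rm = TRUE),
      q05 = quantile(.data$value, 0.05, na.rm = TRUE, names = FALSE),
      q25 = quantile(.data$value, 0.25, na.rm = TRUE, names = FALSE),
      median = quantile(.data$value, 0.50, na.rm = TRUE, names = FALSE),
      q75 = quantile(.data$value, 0.75, na.rm = TRUE, names = FALSE),
      q95 = quantile(.data$value, 0.95, na.rm = TRUE, names = FALSE),
      .groups = "drop"
    )
}

#' Change vectors at point locations
#'
#' Extracts the change vector of the grid cell nearest to each query
#' point (e.g. park centroids). Points falling outside the grid's bounds
#' are skipped with a warning and reported in the `n_skipped` attribute.
#'
#' @param vectors A `wb_change_vectors` table.
#' @param cells Data frame with `cell`, `x`, `y` giving cell-center
#'   coordinates for every cell in `vectors`.
#' @param points Data frame with `x`, `y` and optionally `name`.
#' @return The matched rows of `vectors` with `name`, `x`, `y` and the
#'   matched `cell`; attribute `n_skipped` counts out-of-bounds points.
#' @export
centroid_vectors <- function(vectors, cells, points) {
  stopifnot(all(c("cell", "x", "y") %in% names(cells)),
            all(c("x", "y") %in% names(points)))
  points <- tibble::as_tibble(points)
  if (!("name" %in% names(points))) {
    points$name <- paste0("point_", seq_len(nrow(points)))
  }
  half <- function(v) {
    u <- sort(unique(v))
    if (length(u) > 1) stats::median(diff(u)) / 2 else 0.5
  }
  hx <- half(cells$x)
  hy <- half(cells$y)
  inb <- points$x >= min(cells$x) - hx & points$x <= max(cells$x) + hx &
    points$y >= min(cells$y) - hy & points$y <= max(cells$y) + hy
  if (any(!inb)) {
    warn(sprintf("Skipping %d out-of-bounds point(s): %s",
                 sum(!inb), paste(points$name[!inb], collapse = ", ")))
  }
  kept <- points[inb, ]
  nearest <- vapply(seq_len(nrow(kept)), function(i) {
    which.min((cells$x - kept$x[i])^2 + (cells$y - kept$y[i])^2)
  }, integer(1))
  out <- dplyr::bind_cols(
    kept[c("name", "x", "y")],
    tibble::tibble(cell = cells$cell[nearest])
  )
  out <- dplyr::left_join(out, tibble::as_tibble(as.data.frame(vectors)),
                          by = "cell")
  attr(out, "n_skipped") <- sum(!inb)
  out
}

#' @method tidy wb_trends
#' @export
tidy.wb_trends <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' @method glance wb_trends
#' @export
glance.wb_trends <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x)) |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      n_fitted = sum(!is.na(.data$slope)),
      median_slope = stats::median(.data$slope, na.rm = TRUE),
      median_normalized_index =
        stats::median(.data$normalized_index, na.rm = TRUE),
      frac_positive = mean(.data$slope > 0, na.rm = TRUE),
      .groups = "drop"
    )
}

#' @method tidy wb_change_vectors
#' @export
tidy.wb_change_vectors <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' @method glance wb_change_vectors
#' @export
glance.wb_change_vectors <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    mean_intensity = mean(x$intensity, na.rm = TRUE),
    median_intensity = stats::median(x$intensity, na.rm = TRUE),
    frac_drying = mean(x$direction_class == "+CWD-AET", na.rm = TRUE),
    frac_wetting = mean(x$direction_class == "-CWD+AET", na.rm = TRUE)
  )
}
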