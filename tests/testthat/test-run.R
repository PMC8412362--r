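make_small_run <- function(years = 2001:2002, nrow = 2, ncol = 2,
                           seed = 3) {
  spec <- fixture_spec(nrow = nrow, ncol = ncol, years = years,
                       seed = seed)
  list(spec = spec, forcing = make_forcing(spec),
       attributes = make_attributes(spec))
}

test_that("a 1x1 grid run reproduces the scalar step_cell trajectory", {
  s <- make_small_run(nrow = 1, ncol = 1, years = 2001:2001)
  daily <- wb_run(s$forcing, s$attributes, output = "daily")
  at <- s$attributes
  p <- wb_params()
  swe <- 0; soil <- at$whc
  doy <- waterbal:::ndvi_day_index(s$forcing$dates)
  for (i in seq_along(s$forcing$dates)) {
    tm <- (s$forcing$tmin[i, 1] + s$forcing$tmax[i, 1]) / 2
    st <- step_cell(swe, soil, tm, s$forcing$prcp[i, 1],
                    latitude = at$latitude, whc = at$whc,
                    day_of_year = doy[i], slope = at$slope,
                    aspect = at$aspect, ndvi = at$ndvi[[1]][doy[i]],
                    params = p, t50 = at$snow_t50)
    expect_identical(daily$swe[i], st$swe)
    expect_identical(daily$aet[i], st$aet)
    expect_identical(daily$cwd[i], st$cwd)
    expect_identical(daily$runoff[i], st$runoff)
    swe <- st$swe; soil <- st$soil
  }
})

test_that("runs are deterministic and invariant to spatial chunking", {
  s <- make_small_run(nrow = 2, ncol = 3)
  full1 <- wb_run(s$forcing, s$attributes, output = "daily")
  full2 <- wb_run(s$forcing, s$attributes, output = "daily")
  expect_identical(full1, full2)
  # run the cells in two chunks, then in reversed order
  chunk <- function(cols) {
    gf <- s$forcing
    sub <- wb_grid_forcing(gf$dates, gf$tmin[, cols, drop = FALSE],
                           gf$tmax[, cols, drop = FALSE],
                           gf$prcp[, cols, drop = FALSE],
                           gf$cells[cols], calendar = gf$calendar)
    wb_run(sub, s$attributes, output = "daily")
  }
  split_run <- dplyr::bind_rows(chunk(1:2), chunk(3:6))
  expect_identical(
    dplyr::arrange(as.data.frame(split_run), cell, date),
    dplyr::arrange(as.data.frame(full1), cell, date))
  rev_run <- chunk(6:1)
  expect_identical(
    dplyr::arrange(as.data.frame(rev_run), cell, date),
    dplyr::arrange(as.data.frame(full1), cell, date))
})

test_that("annual accumulation agrees with summing the daily output", {
  s <- make_small_run()
  daily <- wb_run(s$forcing, s$attributes, output = "daily")
  ann <- wb_run(s$forcing, s$attributes, output = "annual")
  agg <- annual_totals(daily)
  for (v in c("pet", "aet", "cwd", "runoff", "rain", "snowfall")) {
    expect_equal(ann[[v]], agg[[v]], tolerance = 1e-10, info = v)
  }
  # aggregation linearity: totals of a doubled stack are doubled
  daily2 <- daily
  daily2$aet <- 2 * daily2$aet
  expect_equal(annual_totals(daily2)$aet, 2 * agg$aet)
})

test_that("annual totals sum complete years and assign water years", {
  dates <- wb_dates("2000-01-01", "2001-12-31", "noleap")
  daily <- tibble::tibble(cell = 1L, date = dates, aet = 1)
  ann <- annual_totals(daily, calendar = "noleap")
  expect_equal(ann$aet, c(365, 365))
  expect_equal(ann$year, c(2000L, 2001L))
  # a flux occurring only in November lands in the next water year
  nov <- tibble::tibble(
    cell = 1L, date = wb_dates("2000-10-01", "2001-09-30", "noleap"))
  nov$aet <- ifelse(format(nov$date, "%m") == "11", 1, 0)
  wy <- annual_totals(nov, water_year = TRUE, calendar = "noleap")
  expect_equal(wy$year, 2001L)
  expect_equal(wy$aet, 30)
  # partial years are dropped with a warning
  part <- tibble::tibble(cell = 1L,
                         date = wb_dates("2000-01-01", "2001-03-31",
                                         "noleap"),
                         aet = 1)
  expect_warning(out <- annual_totals(part, calendar = "noleap"),
                 "2001")
  expect_equal(out$year, 2000L)
})

test_that("every cell of a multi-year run closes the water balance", {
  s <- make_small_run(years = 2001:2004, nrow = 3, ncol = 3)
  ann <- wb_run(s$forcing, s$attributes, output = "annual")
  mb <- wb_mass_balance(ann)
  expect_lt(max(abs(mb$residual)), 1e-6)
  # and the run-level identities hold
  expect_true(all(ann$aet <= ann$pet + 1e-9))
  expect_true(all(ann$cwd >= -1e-9))
})

test_that("nodata forcing days yield nodata outputs for that cell", {
  s <- make_small_run(nrow = 1, ncol = 2, years = 2001:2001)
  s$forcing$tmin[50, 1] <- NA
  s$forcing$tmax[50, 1] <- NA
  daily <- wb_run(s$forcing, s$attributes, output = "daily")
  bad <- daily[daily$cell == 1 & daily$date == s$forcing$dates[50], ]
  expect_true(is.na(bad$aet) && is.na(bad$pet) && is.na(bad$runoff))
  good <- daily[daily$cell == 2 & daily$date == s$forcing$dates[50], ]
  expect_false(anyNA(good))
})

test_that("spin-up converges and matches a plain run at one cycle", {
  s <- make_small_run(years = 2001:2002)
  one <- wb_spin_up(s$forcing, s$attributes, n_cycles = 1)
  daily <- wb_run(s$forcing, s$attributes, output = "daily")
  last <- daily[daily$date == max(s$forcing$dates[
    s$forcing$dates <= s$forcing$dates[1] + 364]), ]
  expect_equal(one$state$swe, last$swe)
  expect_equal(one$state$soil, last$soil_water)
  many <- wb_spin_up(s$forcing, s$attributes, n_cycles = 8)
  expect_lt(many$delta, 0.01)
})

test_that("a desert cell spins down to an empty store", {
  dates <- wb_dates("2001-01-01", "2001-12-31", "noleap")
  gf <- wb_grid_forcing(dates,
                        tmin = matrix(10, 365, 1),
                        tmax = matrix(20, 365, 1),
                        prcp = matrix(0, 365, 1),
                        cells = 1L, calendar = "noleap")
  su <- wb_spin_up(gf, flat_attributes(whc = 100), n_cycles = 2)
  expect_equal(su$state$swe, 0)
  expect_lt(su$state$soil, 0.01)
})

test_that("snow phenology metrics count water-year snow cover", {
  dates <- wb_dates("2000-10-01", "2001-09-30", "noleap")
  wyd <- water_year_day(dates, "noleap")
  swe <- ifelse(wyd >= 50 & wyd <= 100, 5 + wyd / 10, 0)
  daily <- tibble::tibble(cell = 1L, date = dates, swe = swe)
  m <- snow_phenology(daily, calendar = "noleap")
  expect_equal(m$first_snow_day, 50L)
  expect_equal(m$last_snow_day_plus1, 101L)
  expect_equal(m$snow_days, 51L)
  expect_equal(m$peak_swe, 15)
  # two disjoint spells
  swe2 <- ifelse((wyd >= 10 & wyd <= 20) | (wyd >= 40 & wyd <= 45),
                 1, 0)
  m2 <- snow_phenology(tibble::tibble(cell = 1L, date = dates,
                                      swe = swe2),
                       calendar = "noleap")
  expect_equal(m2$first_snow_day, 10L)
  expect_equal(m2$last_snow_day_plus1, 46L)
  expect_equal(m2$snow_days, 17L)
  # snow-free year: sentinel day metrics
  m3 <- snow_phenology(tibble::tibble(cell = 1L, date = dates, swe = 0),
                       calendar = "noleap")
  expect_true(is.na(m3$first_snow_day) && is.na(m3$last_snow_day_plus1))
  expect_equal(m3$snow_days, 0L)
  expect_equal(m3$peak_swe, 0)
})

test_that("misaligned attribute tables are rejected with cell ids", {
  s <- make_small_run(nrow = 1, ncol = 2, years = 2001:2001)
  expect_error(wb_run(s$forcing, s$attributes[1, ], output = "annual"),
               "Attributes missing for cell")
})
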