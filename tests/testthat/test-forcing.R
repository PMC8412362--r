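test_that("site CSV round-trips and validates identity reads", {
  f <- tibble::tibble(
    date = as.Date("2001-01-01") + 0:2,
    tmin = c(-5, -4, -3), tmax = c(2, 3, 4), prcp = c(0, 5, 0)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_wb_forcing(f, path)
  got <- read_wb_forcing(path)
  expect_s3_class(got, "wb_forcing")
  expect_equal(nrow(got), 3)
  expect_equal(got$tmin, f$tmin)
  expect_equal(got$prcp, f$prcp)
  expect_equal(attr(got, "calendar"), "gregorian")
})

test_that("calendar gaps are rejected and the missing day is named", {
  f <- tibble::tibble(
    date = as.Date(c("2001-01-01", "2001-01-03")),
    tmin = 0, tmax = 1, prcp = 0
  )
  expect_error(wb_forcing(f), "2001-01-02")
})

test_that("declared units are converted; unknown units refuse to guess", {
  f <- tibble::tibble(date = as.Date("2001-01-01") + 0:1,
                      tmin = c(268.15, 270.15), tmax = c(278.15, 280.15),
                      prcp = c(1, 0.5))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(f, path)
  got <- read_wb_forcing(path, temp_units = "K", prcp_units = "cm")
  expect_equal(got$tmin, c(-5, -3))
  expect_equal(got$tmax, c(5, 7))
  expect_equal(got$prcp, c(10, 5))
  expect_error(read_wb_forcing(path, temp_units = "degF"), "degF")
})

test_that("noleap calendars keep 365 steps with Dec 31 and no Feb 29", {
  dates <- wb_dates("2000-01-01", "2000-12-31", "noleap")
  expect_length(dates, 365)
  expect_true(as.Date("2000-12-31") %in% dates)
  expect_false(as.Date("2000-02-29") %in% dates)
  f <- tibble::tibble(date = dates, tmin = 0, tmax = 10, prcp = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_wb_forcing(wb_forcing(f), path)
  got <- read_wb_forcing(path)
  expect_equal(attr(got, "calendar"), "noleap")
  expect_equal(nrow(got), 365)
  # a real gap in a noleap series is still a gap
  expect_error(
    wb_forcing(tibble::tibble(date = dates[-100], tmin = 0, tmax = 1,
                              prcp = 0)),
    format(dates[100]))
})

test_that("physical invariants are enforced on construction", {
  base <- tibble::tibble(date = as.Date("2001-01-01") + 0:1,
                         tmin = c(5, 5), tmax = c(10, 4), prcp = c(0, 0))
  expect_error(wb_forcing(base), "tmax < tmin")
  base$tmax <- c(10, 10)
  base$prcp <- c(-1, 0)
  expect_error(wb_forcing(base), "precipitation")
  dup <- tibble::tibble(date = as.Date(c("2001-01-01", "2001-01-01")),
                        tmin = 0, tmax = 1, prcp = 0)
  expect_error(wb_forcing(dup), "Duplicated")
})

test_that("water years run Oct 1 - Sep 30, labeled by the ending year", {
  expect_equal(water_year(as.Date("2000-10-01")), 2001L)
  expect_equal(water_year_day(as.Date("2000-10-01")), 1L)
  expect_equal(water_year(as.Date("2001-09-30")), 2001L)
  expect_equal(water_year_day(as.Date("2001-09-30")), 365L)
  expect_equal(water_year(as.Date("2001-10-01")), 2002L)
  expect_equal(water_year_day(as.Date("2001-10-01")), 1L)
})

test_that("water-year assignment partitions any daily index", {
  d <- seq(as.Date("1999-03-15"), as.Date("2003-07-04"), by = "day")
  wy <- water_year(d)
  # every day gets exactly one label and labels are contiguous blocks
  expect_length(wy, length(d))
  expect_false(anyNA(wy))
  expect_true(all(diff(wy) %in% c(0L, 1L)))
  # within one full water year the day counter covers 1..n once
  block <- d[wy == 2001]
  expect_equal(sort(water_year_day(block)),
               seq_len(length(block)))
})

test_that("day-of-year indexing maps Feb 29 onto the Feb 28 entry", {
  expect_equal(
    waterbal:::ndvi_day_index(as.Date(c("2004-02-28", "2004-02-29",
                                        "2004-03-01", "2004-12-31"))),
    c(59L, 59L, 60L, 365L))
  expect_equal(
    waterbal:::ndvi_day_index(as.Date(c("2003-02-28", "2003-03-01",
                                        "2003-12-31"))),
    c(59L, 60L, 365L))
})

test_that("attribute tables validate ranges and NDVI climatologies", {
  a <- flat_attributes(n = 2)
  expect_s3_class(wb_attributes(a), "wb_attributes")
  bad <- a; bad$aspect <- c(0, 360)
  expect_error(wb_attributes(bad))
  bad <- a; bad$whc <- c(100, 0)
  expect_error(wb_attributes(bad))
  withndvi <- a
  withndvi$ndvi <- list(rep(0.5, 365), rep(0.5, 364))
  expect_error(wb_attributes(withndvi), "365")
})
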