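test_that("pixel trends recover exact and degenerate slopes", {
  yrs <- 2000:2009
  tr <- pixel_trend(yrs, 2 * yrs + 7)
  expect_equal(tr$slope, 2)
  expect_equal(tr$intercept, 7)
  expect_equal(pixel_trend(yrs, rep(5, 10))$slope, 0)
  few <- pixel_trend(2000:2001, c(1, 2))
  expect_true(is.na(few$slope))
  expect_equal(few$n, 2)
})

test_that("per-cell slopes match the normal equations and lm", {
  set.seed(77)
  yrs <- 1980:2019
  ann <- purrr::map_dfr(1:20, function(cl) {
    tibble::tibble(cell = cl, year = yrs,
                   aet = 300 + 1.5 * (yrs - 1980) + rnorm(40, sd = 25))
  })
  tr <- wb_trends(ann, "aet")
  for (cl in c(1, 7, 20)) {
    y <- ann$aet[ann$cell == cl]
    expect_equal(tr$slope[tr$cell == cl],
                 unname(oracle_ols(yrs, y)["slope"]),
                 tolerance = 1e-10)
    fit <- stats::lm(y ~ yrs)
    expect_equal(tr$slope[tr$cell == cl], unname(coef(fit)[2]),
                 tolerance = 1e-10)
  }
  # standard errors, when requested, also match lm
  tr_se <- wb_trends(ann, "aet", se = TRUE)
  fit <- stats::lm(ann$aet[ann$cell == 1] ~ yrs)
  expect_equal(tr_se$slope_se[tr_se$cell == 1],
               unname(summary(fit)$coefficients[2, 2]),
               tolerance = 1e-8)
})

test_that("slope estimation is unbiased on noisy synthetic series", {
  set.seed(123)
  b <- 2; sigma <- 10; yrs <- 1980:2019
  slopes <- replicate(500, {
    pixel_trend(yrs, 100 + b * (yrs - 1980) + rnorm(40, sd = sigma))$slope
  })
  se <- sigma / sqrt(sum((yrs - mean(yrs))^2))
  expect_lt(abs(mean(slopes) - b), 2 * se)
})

test_that("trend properties: scale consistency and year-shift invariance", {
  set.seed(9)
  yrs <- 1990:2019
  vals <- 200 + 3 * (yrs - 1990) + rnorm(30, sd = 15)
  base <- pixel_trend(yrs, vals)
  scaled <- pixel_trend(yrs, 2.5 * vals)
  expect_equal(scaled$slope, 2.5 * base$slope)
  expect_equal(scaled$normalized_index, base$normalized_index)
  shifted <- pixel_trend(yrs - 1000, vals)
  expect_equal(shifted$slope, base$slope, tolerance = 1e-10)
})

test_that("the normalized index is Eq-style slope over mean per decade", {
  expect_identical(normalized_index(5, 250), 0.2)
  expect_identical(normalized_index(-3, 300), -0.1)
  expect_identical(normalized_index(0, 77), 0)
  expect_true(is.na(normalized_index(1, 0)))
})

test_that("independent trend and mean periods are honoured", {
  yrs <- 1980:2019
  ann <- tibble::tibble(cell = 1L, year = yrs, aet = yrs - 1979)
  tr <- wb_trends(ann, "aet", years = 1980:2019,
                  mean_years = 1981:2019)
  expect_equal(tr$slope, 1)
  expect_equal(tr$mean, mean(2:40))
})

test_that("two-period means behave on constructed series", {
  yrs <- 1980:2019
  ann <- tibble::tibble(cell = 1L, year = yrs,
                        aet = ifelse(yrs >= 2000, 110, 100))
  pm <- wb_period_means(ann, "aet", 1980:1999, 2000:2019)
  expect_equal(pm$mean2 - pm$mean1, 10)
  same <- wb_period_means(ann, "aet", 1980:1999, 1980:1999)
  expect_equal(same$mean1, same$mean2)
  ramp <- tibble::tibble(cell = 1L, year = yrs, aet = yrs)
  pm2 <- wb_period_means(ramp, "aet", 1980:1999, 2000:2019)
  expect_equal(pm2$mean1, mean(1980:1999))
  expect_error(wb_period_means(ann, "aet", 1950:1960, 2000:2019),
               "Empty period")
})

test_that("change vectors have Euclidean intensity and sign classes", {
  cv <- change_vector(300, 400, 303, 404)
  expect_identical(cv$intensity, 5)
  expect_equal(cv$direction_class, "+CWD+AET")
  cv0 <- change_vector(10, 20, 10, 20)
  expect_identical(cv0$intensity, 0)
  expect_equal(cv0$direction_class, "no change")
  # exhaustive sign grid against a brute-force classification
  deltas <- tidyr::expand_grid(dc = c(-5, 0, 5), da = c(-5, 0, 5))
  cv9 <- change_vector(100, 200, 100 + deltas$dc, 200 + deltas$da)
  oracle <- mapply(function(dc, da) {
    if (dc == 0 && da == 0) return("no change")
    paste0(if (dc >= 0) "+" else "-", "CWD",
           if (da >= 0) "+" else "-", "AET")
  }, deltas$dc, deltas$da)
  expect_equal(cv9$direction_class, unname(oracle))
  expect_equal(cv9$intensity, sqrt(deltas$dc^2 + deltas$da^2))
  # swapping periods negates displacement, preserves intensity
  fwd <- change_vector(300, 400, 310, 390)
  bwd <- change_vector(310, 390, 300, 400)
  expect_equal(bwd$intensity, fwd$intensity)
  expect_equal(bwd$d_cwd, -fwd$d_cwd)
  expect_equal(bwd$d_aet, -fwd$d_aet)
})

test_that("grouped change vectors equal direct period-mean arithmetic", {
  set.seed(5)
  yrs <- 1980:2019
  ann <- purrr::map_dfr(1:4, function(cl) {
    tibble::tibble(cell = cl, year = yrs,
                   aet = rnorm(40, 400), cwd = rnorm(40, 300))
  })
  cv <- wb_change_vectors(ann, 1980:1999, 2000:2019)
  one <- ann[ann$cell == 2, ]
  expect_equal(cv$cwd1[cv$cell == 2],
               mean(one$cwd[one$year <= 1999]))
  expect_equal(cv$aet2[cv$cell == 2],
               mean(one$aet[one$year >= 2000]))
})

test_that("bivariate zones are equal-count and rank-invariant", {
  set.seed(31)
  x <- tibble::tibble(cell = 1:10000, aet = runif(10000),
                      cwd = runif(10000))
  z <- bivariate_zones(x, n_zones = 9)
  counts <- table(z$zone)
  expect_length(counts, 9)
  expect_true(all(abs(counts / 10000 - 1 / 9) < 0.02))
  # monotone transforms leave labels unchanged
  x2 <- x
  x2$aet <- exp(3 * x2$aet)
  z2 <- bivariate_zones(x2, n_zones = 9)
  expect_equal(z$zone, z2$zone)
  # single zone holds everything; non-square counts are rejected
  z1 <- bivariate_zones(x, n_zones = 1)
  expect_equal(unique(z1$zone), "A1C1")
  expect_error(bivariate_zones(x, n_zones = 8), "perfect square")
  expect_error(bivariate_zones(tibble::tibble(aet = NA_real_,
                                              cwd = NA_real_)),
               "nodata")
})

test_that("category summaries recover per-category statistics", {
  x <- tibble::tibble(category = rep(c("a", "b"), each = 50),
                      aet = c(rep(1, 50), rep(3, 50)),
                      cwd = c(rep(10, 50), rep(20, 50)))
  s <- category_summary(x, c("aet", "cwd"))
  expect_equal(sum(s$n), 200)
  expect_equal(s$mean[s$category == "a" & s$variable == "aet"], 1)
  expect_equal(s$median[s$category == "b" & s$variable == "cwd"], 20)
  # one category equals the whole-grid summary
  x1 <- x
  x1$category <- "all"
  s1 <- category_summary(x1, "aet")
  expect_equal(s1$mean, mean(x$aet))
  expect_equal(s1$n, 100)
})

test_that("point extraction picks nearest cells and skips out-of-bounds", {
  cells <- tidyr::expand_grid(row = 1:3, col = 1:3)
  cells$cell <- 1:9
  cells$x <- (cells$col - 0.5) * 100
  cells$y <- (3 - cells$row + 0.5) * 100
  yrs <- 1980:2019
  ann <- purrr::map_dfr(1:9, function(cl) {
    tibble::tibble(cell = cl, year = yrs, aet = 100 + cl, cwd = 50 + cl)
  })
  cv <- wb_change_vectors(ann)
  pts <- tibble::tibble(x = c(150, 150, 9999), y = c(150, 150, 50),
                        name = c("p1", "p1b", "far"))
  expect_warning(got <- centroid_vectors(cv, cells, pts), "far")
  expect_equal(nrow(got), 2)
  expect_equal(attr(got, "n_skipped"), 1)
  # exact cell center maps to that cell; coincident points agree
  expect_equal(got$cell, c(5L, 5L))
  expect_equal(got$intensity[1], got$intensity[2])
})

test_that("tidy and glance methods summarise fitted objects", {
  set.seed(2)
  yrs <- 1980:2019
  ann <- purrr::map_dfr(1:6, function(cl) {
    tibble::tibble(cell = cl, year = yrs,
                   aet = 300 + 2 * (yrs - 1980) + rnorm(40, sd = 10),
                   cwd = 200 - (yrs - 1980) + rnorm(40, sd = 10))
  })
  tr <- wb_trends(ann)
  td <- tidy(tr)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 12)
  gl <- glance(tr)
  expect_equal(gl$n_cells, c(6L, 6L))
  expect_gt(gl$median_slope[gl$variable == "aet"], 0)
  cv <- wb_change_vectors(ann)
  expect_equal(nrow(glance(cv)), 1)
})
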