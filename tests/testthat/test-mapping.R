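test_that("the per-pixel R0 map equals the pointwise climate R0", {
  p <- baseline_params(); lh <- lh_working()
  one <- r0_map(tiny_raster(matrix(25, 1, 1), 1),
                tiny_raster(matrix(25, 1, 1), 1), p, lh)
  expect_equal(one$values[1, 1], 1.8740571, tolerance = 1e-6)

  # nodata propagation from either input
  temp <- tiny_raster(matrix(c(25, 25, NA, 25), 2), 2)
  rain <- tiny_raster(matrix(c(25, NA, 25, 25), 2), 2)
  out <- r0_map(temp, rain, p, lh)
  expect_true(is.na(out$values[2, 1]) && is.na(out$values[1, 2]))
  expect_false(is.na(out$values[1, 1]))

  all_na <- tiny_raster(matrix(NA_real_, 2, 2), 2)
  expect_true(all(is.na(r0_map(temp, all_na, p, lh)$values)))

  # grid mismatch errors name the attribute
  shifted <- tiny_raster(matrix(25, 2, 2), 2, xll = 5)
  expect_error(r0_map(temp, shifted, p, lh), "xllcorner")
  bigger <- tiny_raster(matrix(25, 3, 2), 3)
  expect_error(r0_map(temp, bigger, p, lh), "rows")
})

test_that("R0 mapping commutes with pixel permutations", {
  set.seed(51)
  p <- baseline_params(); lh <- lh_working()
  tv <- matrix(runif(20, 15, 35), 4)
  rv <- matrix(runif(20, 0, 60), 4)
  perm <- sample(20)
  m1 <- r0_map(tiny_raster(tv, 4), tiny_raster(rv, 4), p, lh)
  m2 <- r0_map(tiny_raster(matrix(tv[perm], 4), 4),
               tiny_raster(matrix(rv[perm], 4), 4), p, lh)
  expect_equal(as.vector(m2$values), as.vector(m1$values)[perm])
  c1 <- classify_map(m1); c2 <- classify_map(m2)
  expect_equal(as.vector(c2$values), as.vector(c1$values)[perm])
})

test_that("classification maps thresholds to codes with nodata pass-through", {
  r0map <- tiny_raster(matrix(c(0.5, 1.05, 1.2, NA), 2), 2)
  cls <- classify_map(r0map)
  expect_equal(cls$values[1, 1], 1)   # 0.5 -> low
  expect_equal(cls$values[2, 1], 2)   # 1.05 -> moderate
  expect_equal(cls$values[1, 2], 3)   # 1.2 -> high
  expect_true(is.na(cls$values[2, 2]))
  all_na <- classify_map(tiny_raster(matrix(NA_real_, 2, 2), 2))
  expect_true(all(is.na(all_na$values)))
})

test_that("annual aggregation averages valid months per pixel", {
  months <- constant_months(rep(2, 12))
  same <- annual_aggregate(months)
  expect_equal(same$values, months[[1]]$values)

  halfhalf <- constant_months(c(rep(1, 6), rep(2, 6)))
  expect_equal(annual_aggregate(halfhalf)$values[1, 1], 1.5)
  expect_equal(annual_aggregate(halfhalf, method = "median")$values[1, 1],
               1.5)

  # one nodata month at a pixel: mean of the remaining 11
  months[[3]]$values[1, 1] <- NA
  months[[5]]$values[1, 1] <- 13
  agg <- annual_aggregate(months)
  expect_equal(agg$values[1, 1], (10 * 2 + 13) / 11)
  expect_identical(attr(agg, "aggregation"), "mean")

  expect_error(annual_aggregate(months[1:11]), "12")
})

test_that("confidence-interval layers implement mean +/- 1.96 sd with n-1 divisor", {
  # constant pixel: zero-width interval
  const <- ci_rasters(constant_months(rep(3, 12)))
  expect_equal(const$lower$values[1, 1], 3)
  expect_equal(const$upper$values[1, 1], 3)
  expect_equal(const$sd$values[1, 1], 0)

  # six months at 1, six at 2: sd = sqrt(3/11)
  ci <- ci_rasters(constant_months(c(rep(1, 6), rep(2, 6))))
  expect_equal(ci$mean$values[1, 1], 1.5)
  expect_equal(ci$sd$values[1, 1], sqrt(3 / 11), tolerance = 1e-12)
  expect_equal(ci$lower$values[1, 1], 1.5 - 1.0235766, tolerance = 1e-6)
  expect_equal(ci$upper$values[1, 1], 1.5 + 1.0235766, tolerance = 1e-6)

  # raster-wide: width == 2 * 1.96 * sd, and width is shift-invariant
  set.seed(52)
  vals <- lapply(1:12, function(i) matrix(runif(16, 0, 3), 4))
  months <- lapply(vals, tiny_raster, nrow = 4)
  ci <- ci_rasters(months)
  expect_equal(ci$upper$values - ci$lower$values, 2 * 1.96 * ci$sd$values,
               tolerance = 1e-12)
  shifted <- lapply(vals, function(v) tiny_raster(v + 7, nrow = 4))
  ci_s <- ci_rasters(shifted)
  expect_equal(ci_s$upper$values - ci_s$lower$values,
               ci$upper$values - ci$lower$values, tolerance = 1e-12)
  expect_gt(glance(ci)$n_valid, 0)
})

test_that("overlay accuracy counts resistant points per class", {
  cls <- tiny_raster(matrix(c(3, 3, 1, 2), 2, byrow = TRUE), 2,
                     xll = 0, yll = 0, cellsize = 1)
  # top row (lat in [1,2)) is high; bottom row low/moderate
  pts <- tibble::tibble(
    lon = c(0.5, 1.5, 0.5, 1.5),
    lat = c(1.5, 1.5, 0.5, 0.5),
    year = 2022L,
    status = c("resistant", "resistant", "resistant", "resistant"))
  res <- overlay_accuracy(pts, cls)
  expect_equal(res$accuracy, 0.5)
  expect_equal(res$n_high, 2); expect_equal(res$n_low, 1)
  expect_equal(res$n_moderate, 1)

  # 3 of 4 in target class
  pts2 <- pts; pts2$lat <- c(1.5, 1.5, 1.5, 0.5)
  expect_equal(overlay_accuracy(pts2, cls)$accuracy, 0.75)

  # susceptible points are not scored; off-grid points are dropped
  pts3 <- dplyr::bind_rows(pts2,
    tibble::tibble(lon = 0.5, lat = 0.5, year = 2022L,
                   status = "susceptible"),
    tibble::tibble(lon = 50, lat = 50, year = 2022L, status = "resistant"))
  res3 <- overlay_accuracy(pts3, cls)
  expect_equal(res3$n_scored, 4)
  expect_equal(res3$n_dropped, 1)
  expect_equal(res3$accuracy, 0.75)

  # all points in target class
  expect_equal(overlay_accuracy(pts[1:2, ], cls)$accuracy, 1)
  expect_error(overlay_accuracy(pts3[5, ], cls), "no resistant")
  off <- pts[1, ]; off$lon <- 99
  expect_error(overlay_accuracy(off, cls), "off-grid")
  expect_equal(overlay_accuracy(pts, cls, target_class = "low")$accuracy,
               0.25)
})

test_that("uniformly scattered points recover the high-class area fraction", {
  set.seed(53)
  vals <- matrix(runif(400, 0.8, 1.3), 20)
  cls <- classify_map(tiny_raster(vals, 20))
  f_high <- mean(cls$values == 3)
  accs <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 2000
    lon <- runif(n, cls$xllcorner, cls$xllcorner + 20 * cls$cellsize)
    lat <- runif(n, cls$yllcorner, cls$yllcorner + 20 * cls$cellsize)
    pts <- tibble::tibble(lon = lon, lat = lat, year = 2022L,
                          status = "resistant")
    overlay_accuracy(pts, cls)$accuracy
  }, numeric(1))
  expect_true(all(abs(accs - f_high) < 0.03))
})

test_that("points CSV round-trips with validation", {
  pts <- tibble::tibble(lon = c(1.2, -3), lat = c(0.5, 10), year = 2022L,
                        status = c("resistant", "susceptible"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_points_csv(pts, f)
  back <- read_points_csv(f)
  expect_equal(back$lon, pts$lon)
  expect_equal(back$status, pts$status)

  writeLines("lon,lat,year,status\n1,2,2022,weird", f)
  expect_error(read_points_csv(f), "status")
  writeLines("lon,lat\n1,2", f)
  expect_error(read_points_csv(f), "year")
  writeLines("lon,lat,year,status\n500,2,2022,resistant", f)
  expect_error(read_points_csv(f), "coordinates")
})
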