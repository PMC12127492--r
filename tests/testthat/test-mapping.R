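test_that("classification uses left-closed four-level intervals", {
  v <- matrix(c(0, 0.29999, 0.30, 0.499, 0.50, 0.65, 0.699, 0.70, 1, NA,
                0.2, 0.8), 3, 4)
  cm <- classify(grid_layer(v, 0, 0, 1))
  got <- cm$layer$values
  expect_equal(got[1:9], c(0, 0, 1, 1, 2, 2, 2, 3, 3))
  expect_true(is.na(got[10]))  # nodata propagates
  expect_equal(cm$labels[got[6] + 1], "moderate")  # 0.65 is moderate

  expect_error(classify(grid_layer(matrix(1.2), 0, 0, 1)), "outside")
  # monotone: raising any cell's suitability never lowers its class
  set.seed(5)
  x <- matrix(stats::runif(100), 10)
  up <- pmin(x + stats::runif(100, 0, 0.2), 1)
  c1 <- classify(grid_layer(x, 0, 0, 1))$layer$values
  c2 <- classify(grid_layer(up, 0, 0, 1))$layer$values
  expect_true(all(c2 >= c1))
})

test_that("areas use cos-latitude weighting and partition the valid cells", {
  # 2x2 one-degree cells astride the equator: ~4 * 111.32^2 km2
  eq <- classify(grid_layer(matrix(0.9, 2, 2), 0, -1, 1))
  a_eq <- area_summary(eq)
  expect_equal(a_eq$areas[["high"]], 4 * 111.32^2 * cos(0.5 * pi / 180),
               tolerance = 1e-12)
  expect_lt(abs(a_eq$areas[["high"]] / (4 * 111.32^2) - 1), 0.001)

  # the same grid centered at 60 N has about half that area
  hi <- classify(grid_layer(matrix(0.9, 2, 2), 0, 59, 1))
  a_hi <- area_summary(hi)
  expect_lt(abs(a_hi$areas[["high"]] / a_eq$areas[["high"]] - 0.5), 0.005)

  # partition: class areas sum to the total valid area
  set.seed(6)
  v <- matrix(stats::runif(400), 20)
  v[sample(400, 30)] <- NA
  cm <- classify(grid_layer(v, 100, 20, 0.1))
  a <- area_summary(cm)
  total_valid <- sum(nichemax:::cell_area_km2(cm$layer)[!is.na(v)])
  expect_equal(sum(a$areas), total_valid, tolerance = 1e-6)
  expect_equal(a$total_suitable,
               sum(a$areas[c("low", "moderate", "high")]), tolerance = 1e-9)

  none <- classify(grid_layer(matrix(NA_real_, 2, 2), 0, 0, 1))
  expect_equal(sum(area_summary(none)$areas), 0)

  # optional share of a reference land area
  expect_equal(area_summary(eq, reference_area_km2 = a_eq$areas[["high"]] * 4)$share,
               25)
})

test_that("scenario comparison reproduces published-style percent changes", {
  mk <- function(low, moderate, high) structure(
    list(areas = c(unsuitable = 0, low = low, moderate = moderate,
                   high = high),
         total_suitable = low + moderate + high), class = "area_summary")
  cur <- mk(72.77, 65.13, 15.05)                   # total 152.95
  fut <- mk(101.22, 64.37, 20.47)                  # total 186.06
  cmp <- compare_scenarios(cur, fut, "s1")
  expect_equal(cmp$pct_change[cmp$class == "total"], 21.65)
  expect_equal(cmp$pct_change[cmp$class == "high"], 36.01)

  # identity comparison is exactly zero everywhere
  expect_true(all(compare_scenarios(cur, cur)$pct_change == 0))
  # zero baseline flags NA
  z <- mk(0, 1, 1)
  expect_true(is.na(compare_scenarios(z, mk(1, 1, 1))$pct_change[1]))
})

test_that("round_half_up breaks ties away from zero at 2 decimals", {
  expect_equal(round_half_up(2.005, 2), 2.01)
  expect_equal(round_half_up(-2.005, 2), -2.01)
  expect_equal(round_half_up(1.004, 2), 1.00)
  expect_equal(round_half_up(109.3687, 2), 109.37)
})

test_that("centroids are (area-weighted) means of suitable cell centers", {
  # two suitable cells at the same latitude: midpoint
  v <- matrix(NA_real_, 1, 3)
  v[1, 1] <- 0.8; v[1, 3] <- 0.8
  cm <- classify(grid_layer(v, 99.5, 19.5, 1))  # centers 100, 102 at 20 N
  ct <- centroid(cm)
  expect_equal(ct$lon, 101)
  expect_equal(ct$lat, 20)
  expect_equal(ct$n_cells, 2)

  # single cell: its own center
  v1 <- matrix(0.9, 1, 1)
  c1 <- centroid(classify(grid_layer(v1, 10, 10, 1)))
  expect_equal(c(c1$lon, c1$lat), c(10.5, 10.5))

  # 10x10 block: unweighted centroid at block center, area-weighted
  # centroid pulled toward the equator; translation-equivariant in lon
  blk <- classify(grid_layer(matrix(0.6, 10, 10), 100, 40, 1))
  cu <- centroid(blk, area_weighted = FALSE)
  cw <- centroid(blk, area_weighted = TRUE)
  expect_equal(c(cu$lon, cu$lat), c(105, 45))
  expect_lt(cw$lat, cu$lat)
  # closed-form weighted mean over rows
  lats <- 40.5:49.5
  expect_equal(cw$lat, sum(lats * cos(lats * pi / 180)) /
                 sum(cos(lats * pi / 180)))
  blk2 <- classify(grid_layer(matrix(0.6, 10, 10), 130, 40, 1))
  expect_equal(centroid(blk2)$lon - centroid(blk)$lon, 30)

  expect_error(centroid(classify(grid_layer(matrix(0.1), 0, 0, 1))),
               "no cells")
})

test_that("centroid shifts match an independent haversine oracle", {
  s0 <- centroid_shift(list(lon = 5, lat = 5), list(lon = 5, lat = 5))
  expect_equal(s0$distance_km, 0)
  expect_true(s0$degenerate)

  # one degree due north along any meridian: ~111.19 km, bearing 0
  s1 <- centroid_shift(list(lon = 77, lat = 10), list(lon = 77, lat = 11))
  expect_equal(s1$distance_km, pi * 6371 / 180, tolerance = 1e-6)
  expect_equal(s1$bearing_deg, 0)

  # plain-formula haversine oracle on the reference coordinate pair
  hav <- function(lon1, lat1, lon2, lat2) {
    to <- pi / 180
    dlat <- (lat2 - lat1) * to; dlon <- (lon2 - lon1) * to
    a <- sin(dlat / 2)^2 +
      cos(lat1 * to) * cos(lat2 * to) * sin(dlon / 2)^2
    2 * 6371 * asin(sqrt(a))
  }
  s2 <- centroid_shift(list(lon = 108.21, lat = 27.23),
                       list(lon = 109.40, lat = 28.11))
  expect_equal(s2$distance_km, hav(108.21, 27.23, 109.40, 28.11),
               tolerance = 0.1)
  expect_gt(s2$bearing_deg, 0); expect_lt(s2$bearing_deg, 90)  # northeast
})
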