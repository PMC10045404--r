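test_that("cell areas follow the spherical-zone formula", {
  expect_lt(cell_area(60, 1), cell_area(0, 1))
  expect_equal(cell_area(45, 1), cell_area(-45, 1))
  # whole-sphere tiling reproduces the Earth's surface area
  lats <- seq(-89.5, 89.5, 1)
  total <- sum(cell_area(lats, 1)) * 360
  expect_equal(total, 4 * pi * 6371^2, tolerance = 1e-3)
})

test_that("suitable area integrates thresholded cells with latitude weights", {
  lats <- seq(40, 50, 1); lons <- seq(0, 9, 1)
  zero <- ecoclim:::new_suitability_grid(lats, lons,
                                         matrix(0, 11, 10), "EI")
  expect_equal(suitable_area(zero, 10), 0)
  ones <- ecoclim:::new_suitability_grid(lats, lons,
                                         matrix(50, 11, 10), "EI")
  expect_equal(suitable_area(ones, 0), sum(cell_area(rep(lats, 10), 1)))
  # checkerboard on one latitude band: half the band area up to cell rounding
  vals <- matrix(0, 11, 10)
  vals[6, seq(1, 10, 2)] <- 50
  cb <- ecoclim:::new_suitability_grid(lats, lons, vals, "EI")
  expect_equal(suitable_area(cb, 10), 5 * cell_area(45, 1))
  # monotone non-increasing in the threshold
  withr::with_seed(60, {
    rnd <- ecoclim:::new_suitability_grid(lats, lons,
                                          matrix(runif(110, 0, 100), 11, 10),
                                          "EI")
  })
  areas <- vapply(c(0, 10, 30, 60, 90), function(th)
    suitable_area(rnd, th), numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("percent change reproduces the reference arithmetic", {
  expect_equal(area_change(4.80e7, 6.54e7), 36.25)
  expect_equal(area_change(1, 1), 0)
  expect_equal(area_change(2, 4), 100)
  expect_error(area_change(0, 1), "zero")
})

test_that("occurrence coverage snaps points to nearest cells", {
  lats <- seq(0, 4, 1); lons <- seq(0, 4, 1)
  vals <- matrix(100, 5, 5); vals[1, 1] <- 0
  g <- ecoclim:::new_suitability_grid(lats, lons, vals, "EI")
  occ <- data.frame(lon = c(0.1, 2.2, 3.9), lat = c(0.2, 2.4, 1.6))
  cov <- occurrence_coverage(g, occ, 10)
  expect_equal(cov$inside, 2L)   # first point snaps to the unsuitable corner
  expect_equal(cov$percent, 66.67)
  all_in <- occurrence_coverage(g, data.frame(lon = 2, lat = 2), 10)
  expect_equal(all_in$percent, 100)
  expect_error(occurrence_coverage(g, data.frame(lon = numeric(0),
                                                 lat = numeric(0)), 10),
               "empty")
  # invariant to occurrence ordering
  withr::with_seed(61, {
    occ2 <- data.frame(lon = runif(30, 0, 4), lat = runif(30, 0, 4))
    cov_a <- occurrence_coverage(g, occ2, 10)
    cov_b <- occurrence_coverage(g, occ2[sample(30), ], 10)
  })
  expect_equal(cov_a, cov_b)
})

test_that("ensemble means average cell-wise across model grids", {
  lats <- seq(0, 4, 1); lons <- seq(0, 4, 1)
  g1 <- ecoclim:::new_suitability_grid(lats, lons, matrix(20, 5, 5), "EI")
  expect_equal(ensemble_mean(list(g1))$values, g1$values)
  g2 <- g1; g2$values <- matrix(60, 5, 5)
  expect_equal(ensemble_mean(list(g1, g2))$values, matrix(40, 5, 5))
  # 23-member ensemble against a per-cell loop oracle
  withr::with_seed(62, {
    gs <- lapply(1:23, function(i) {
      g <- g1; g$values <- matrix(runif(25, 0, 100), 5, 5); g
    })
  })
  em <- ensemble_mean(gs)$values
  oracle <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5)
    oracle[i, j] <- mean(vapply(gs, function(g) g$values[i, j], numeric(1)))
  expect_equal(em, oracle, tolerance = 1e-12)
  # mismatched lattices refuse to average
  g3 <- ecoclim:::new_suitability_grid(lats + 1, lons, matrix(1, 5, 5), "EI")
  expect_error(ensemble_mean(list(g1, g3)), "lattice")
  # climate grids average field-wise
  ga <- small_grid(noise_sd = 1, seed = 1, resolution = 20)
  gb <- small_grid(noise_sd = 1, seed = 2, resolution = 20)
  gm <- ensemble_mean(list(ga, gb))
  expect_equal(gm$tmin, (ga$tmin + gb$tmin) / 2)
})

test_that("area reports combine totals, classes and percent change", {
  lats <- seq(30, 40, 1); lons <- seq(0, 9, 1)
  cur <- ecoclim:::new_suitability_grid(lats, lons, matrix(20, 11, 10), "EI")
  fut <- cur; fut$values <- matrix(c(rep(20, 55), rep(0, 55)), 11, 10)
  rep_ <- area_report(fut, cur, threshold = 10)
  expect_lt(rep_$percent_change, 0)
  expect_equal(rep_$suitable_km2, suitable_area(fut, 10))
  expect_equal(rep_$percent_change,
               area_change(suitable_area(cur, 10), suitable_area(fut, 10)))
})
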