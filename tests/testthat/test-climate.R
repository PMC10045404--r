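test_that("generated grids follow the prescribed latitudinal lapse", {
  g <- small_grid(noise_sd = 0)  # lapse 0.6, equator mean 27
  i30 <- which(g$lats == 30)
  ann <- mean((g$tmin[i30, 1, ] + g$tmax[i30, 1, ]) / 2)
  expect_equal(ann, 27 - 0.6 * 30, tolerance = 0.01)
  # seasonal phase opposite across hemispheres: July warm in N, cool in S
  iN <- which(g$lats == 40); iS <- which(g$lats == -40)
  expect_gt(g$tmax[iN, 1, 7], g$tmax[iN, 1, 1])
  expect_lt(g$tmax[iS, 1, 7], g$tmax[iS, 1, 1])
})

test_that("degenerate seasonality and zero noise give identical months", {
  g <- small_grid(noise_sd = 0, seasonal_amplitude = 0,
                  rain_regime = "uniform")
  expect_equal(apply(g$tmin, c(1, 2), function(x) diff(range(x))),
               matrix(0, length(g$lats), length(g$lons)))
})

test_that("same spec and seed reproduce bit-identical grids", {
  s <- climate_spec(resolution = 10, noise_sd = 0.5, seed = 99)
  expect_identical(generate_climate_grid(s), generate_climate_grid(s))
  s2 <- climate_spec(resolution = 10, noise_sd = 0.5, seed = 100)
  expect_false(identical(generate_climate_grid(s), generate_climate_grid(s2)))
})

test_that("generated grids always satisfy the monthly invariants", {
  for (seed in 1:3) {
    g <- small_grid(noise_sd = 2, resolution = 15, seed = seed,
                    rain_regime = "summer-wet")
    expect_true(all(g$tmin <= g$tmax))
    expect_true(all(g$rain >= 0))
    expect_true(all(g$rh09 >= 0 & g$rh09 <= 100))
    expect_true(all(g$rh15 >= 0 & g$rh15 <= 100))
  }
})

test_that("constant monthly input interpolates to constant weeks", {
  wc <- monthly_to_weekly(rep(15, 12), rep(25, 12), rep(30, 12),
                          rep(70, 12), rep(50, 12))
  expect_equal(wc$tmean, rep(20, 52))
  expect_equal(wc$rh, rep(60, 52))
  expect_equal(length(wc$rain), 52L)
})

test_that("weekly rain redistribution is day-weighted and conservative", {
  # uniform 520 mm/yr: weekly shares follow day counts (~10 mm/week)
  rain <- 520 * c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31) / 365
  wc <- monthly_to_weekly(rep(10, 12), rep(20, 12), rain,
                          rep(70, 12), rep(50, 12))
  daily <- rep(rain / c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31),
               times = c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31))
  oracle <- colSums(matrix(daily[1:364], nrow = 7))
  oracle[52] <- oracle[52] + daily[365]     # week 52 absorbs the odd day
  expect_equal(wc$rain, oracle)
  expect_true(all(abs(wc$rain - 10) < 1.5))
  expect_true(all(abs(wc$rain[1:51] - 10) < 0.05))
  # conservation (well within the 0.5% contract) for arbitrary totals
  withr::with_seed(4, {
    for (i in 1:20) {
      r <- runif(12, 0, 300)
      wc <- monthly_to_weekly(rep(0, 12), rep(10, 12), r,
                              rep(60, 12), rep(60, 12))
      expect_lt(abs(sum(wc$rain) - sum(r)) / max(sum(r), 1e-9), 0.005)
    }
  })
})

test_that("invalid monthly records are rejected", {
  ok <- rep(10, 12)
  expect_error(monthly_to_weekly(rep(21, 12), rep(20, 12), ok, ok, ok),
               "tmin > tmax")
  expect_error(monthly_to_weekly(ok[1:11], ok[1:11], ok[1:11], ok[1:11],
                                 ok[1:11]), "12-month")
  expect_error(monthly_to_weekly(ok, ok, -ok, ok, ok), "negative")
})

test_that("scenario transforms shift, scale and preserve invariants", {
  g <- small_grid(noise_sd = 0.5, seed = 3)
  expect_equal(apply_scenario(g, 0, 1), g)
  g5 <- apply_scenario(g, deltaT = 5)
  expect_equal((g5$tmin + g5$tmax) / 2, (g$tmin + g$tmax) / 2 + 5)
  expect_equal(g5$rh09, g$rh09)
  g0 <- apply_scenario(g, rain_factor = 0)
  expect_true(all(g0$rain == 0))
  expect_error(apply_scenario(g, rain_factor = -1), "non-negative")
  # warming strictly increases every weekly tmean downstream
  wc0 <- do.call(monthly_to_weekly, grid_cell(g, 2, 1))
  wc5 <- do.call(monthly_to_weekly, grid_cell(g5, 2, 1))
  expect_true(all(wc5$tmean > wc0$tmean))
})

test_that("climate CSV round-trips within float tolerance", {
  g <- generate_climate_grid(climate_spec(lat_min = 0, lat_max = 20,
                                          lon_min = 0, lon_max = 20,
                                          resolution = 10, noise_sd = 0.7,
                                          seed = 5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_climate(g, f)
  g2 <- read_climate(f)
  expect_equal(g2$lats, g$lats)
  for (v in c("tmin", "tmax", "rain", "rh09", "rh15"))
    expect_equal(g2[[v]], g[[v]], tolerance = 1e-6)
})

test_that("malformed climate CSVs fail with informative errors", {
  g <- small_grid(resolution = 20)
  f <- withr::local_tempfile(fileext = ".csv")
  write_climate(g, f)
  d <- read.csv(f)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(d[d$var != "rh15", ], f2, row.names = FALSE)
  expect_error(read_climate(f2), "rh15")
  f3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(d[d$month != 12, ], f3, row.names = FALSE)
  expect_error(read_climate(f3), "months 1\\.\\.12")
})
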