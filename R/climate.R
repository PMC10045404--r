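#' Specification for a synthetic monthly climate grid
#'
#' Describes a latitudinally structured synthetic world: mean annual
#' temperature declines linearly away from the equator, a sinusoidal seasonal
#' cycle has opposite phase in the two hemispheres, and rainfall follows one
#' of three regimes. Used by [generate_climate_grid()] to produce test worlds
#' with known structure in place of observational archives.
#'
#' @param lat_min,lat_max latitude range, degrees (cell centers).
#' @param lon_min,lon_max longitude range, degrees in [-180, 180).
#' @param resolution grid spacing, degrees (> 0).
#' @param equator_tmean mean annual temperature at the equator, deg C.
#' @param lapse cooling per degree of |latitude|, deg C / degree.
#' @param seasonal_amplitude half-range of the seasonal tmean cycle, deg C;
#'   the sign of the cycle flips across the equator (July-peaked in the
#'   northern hemisphere, January-peaked in the southern).
#' @param diurnal_range tmax - tmin, deg C.
#' @param rain_regime one of \code{"uniform"}, \code{"winter-wet"},
#'   \code{"summer-wet"}; "winter" means the local cold season.
#' @param annual_rain total annual rainfall, mm.
#' @param rh_base baseline relative humidity, percent (applies to both the
#'   09:00 and 15:00 observations, 09:00 running 10 points moister).
#' @param noise_sd standard deviation of cell-level Gaussian noise added to
#'   monthly temperatures, deg C (also scales rain noise).
#' @param seed integer seed; identical spec (including seed) gives a
#'   bit-identical grid.
#' @return an object of class \code{"climate_spec"}.
#' @export
climate_spec <- function(lat_min = -60, lat_max = 60,
                         lon_min = 0, lon_max = 20,
                         resolution = 2,
                         equator_tmean = 27, lapse = 0.6,
                         seasonal_amplitude = 8, diurnal_range = 10,
                         rain_regime = c("winter-wet", "uniform", "summer-wet"),
                         annual_rain = 800, rh_base = 70,
                         noise_sd = 0.3, seed = 1L) {
  rain_regime <- match.arg(rain_regime)
  if (resolution <= 0) stop("resolution must be positive")
  if (lat_max < lat_min) stop("empty latitude range")
  if (annual_rain < 0) stop("annual_rain must be non-negative")
  if (rh_base < 0 || rh_base > 100) stop("rh_base must be in [0, 100]")
  structure(list(lat_min = lat_min, lat_max = lat_max,
                 lon_min = lon_min, lon_max = lon_max,
                 resolution = resolution,
                 equator_tmean = equator_tmean, lapse = lapse,
                 seasonal_amplitude = seasonal_amplitude,
                 diurnal_range = diurnal_range,
                 rain_regime = rain_regime, annual_rain = annual_rain,
                 rh_base = rh_base, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "climate_spec")
}

# Month lengths of the 365-day climatological year; used for day-weighted
# rain splitting. The engine itself runs on a 52-week (364-day) calendar.
MONTH_DAYS <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

new_climate_grid <- function(lats, lons, vars, mask = NULL) {
  nlat <- length(lats); nlon <- length(lons)
  for (v in c("tmin", "tmax", "rain", "rh09", "rh15")) {
    a <- vars[[v]]
    if (is.null(a) || !identical(dim(a), c(nlat, nlon, 12L)))
      stop("variable '", v, "' missing or mis-shaped")
  }
  if (is.null(mask)) mask <- matrix(TRUE, nlat, nlon)
  structure(list(lats = lats, lons = lons,
                 tmin = vars$tmin, tmax = vars$tmax, rain = vars$rain,
                 rh09 = vars$rh09, rh15 = vars$rh15, mask = mask,
                 resolution = if (nlat > 1) diff(lats)[1] else NA_real_),
            class = "climate_grid")
}

#' Generate a synthetic monthly climate grid
#'
#' Realises the world described by a [climate_spec()]: for every grid cell,
#' twelve months of tmin/tmax, rainfall, and 09:00/15:00 relative humidity.
#' The construction guarantees tmin <= tmax, rain >= 0 and rh in [0, 100],
#' and is deterministic for a fixed spec.
#'
#' @param spec a \code{"climate_spec"}.
#' @return an object of class \code{"climate_grid"}: fields \code{lats},
#'   \code{lons} (cell-center degrees, latitude ascending), five
#'   \code{nlat x nlon x 12} arrays (\code{tmin}, \code{tmax}, \code{rain},
#'   \code{rh09}, \code{rh15}), a logical \code{mask}, and \code{resolution}.
#' @export
generate_climate_grid <- function(spec) {
  stopifnot(inherits(spec, "climate_spec"))
  lats <- seq(spec$lat_min, spec$lat_max, by = spec$resolution)
  lons <- seq(spec$lon_min, spec$lon_max, by = spec$resolution)
  nlat <- length(lats); nlon <- length(lons)
  if (nlat < 1L) stop("empty latitude range")

  # month-midpoint phase: seasonal peak at mid-July in the north
  mid <- (cumsum(MONTH_DAYS) - MONTH_DAYS / 2) / 365
  season <- cos(2 * pi * (mid - 196.5 / 365))       # +1 mid-July, -1 mid-Jan

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  tmean <- array(0, c(nlat, nlon, 12L))
  for (m in 1:12) {
    base <- spec$equator_tmean - spec$lapse * abs(lats)
    hemi <- ifelse(lats >= 0, 1, -1)
    tmean[, , m] <- outer(base + hemi * spec$seasonal_amplitude * season[m],
                          rep(1, nlon))
  }
  if (spec$noise_sd > 0)
    tmean <- tmean + array(stats::rnorm(length(tmean), 0, spec$noise_sd),
                           dim(tmean))

  half <- spec$diurnal_range / 2
  tmin <- tmean - half
  tmax <- tmean + half

  # rainfall: day-weighted split of the annual total, modulated by regime
  wt <- matrix(MONTH_DAYS / 365, nlat, 12, byrow = TRUE)
  if (spec$rain_regime != "uniform") {
    sgn <- if (spec$rain_regime == "summer-wet") 1 else -1
    hemi <- ifelse(lats >= 0, 1, -1)
    mod <- 1 + 0.8 * sgn * outer(hemi, season)      # nlat x 12
    wt <- wt * mod
    wt <- wt / rowSums(wt)
  }
  rain <- array(0, c(nlat, nlon, 12L))
  for (m in 1:12) rain[, , m] <- spec$annual_rain * wt[, m]
  if (spec$noise_sd > 0) {
    rain <- rain * (1 + array(stats::rnorm(length(rain), 0, 0.02 * spec$noise_sd),
                              dim(rain)))
  }
  rain <- pmax(rain, 0)

  rh09 <- array(pmin(100, pmax(0, spec$rh_base + 10)), c(nlat, nlon, 12L))
  rh15 <- array(pmin(100, pmax(0, spec$rh_base - 10)), c(nlat, nlon, 12L))

  new_climate_grid(lats, lons,
                   list(tmin = tmin, tmax = tmax, rain = rain,
                        rh09 = rh09, rh15 = rh15))
}

# save/restore the RNG state so generators don't perturb the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Apply a climate-change scenario transform to a grid
#'
#' Additive warming plus multiplicative precipitation scaling, the standard
#' delta-change surrogate for projected climate fields (roughly +2 deg C for a
#' low-emission pathway, +5 deg C for a high-emission pathway by end of
#' century). Humidity is left unchanged.
#'
#' @param grid a \code{"climate_grid"}.
#' @param deltaT additive shift applied to tmin and tmax, deg C.
#' @param rain_factor multiplicative rainfall factor (>= 0).
#' @return a transformed \code{"climate_grid"}.
#' @export
apply_scenario <- function(grid, deltaT = 0, rain_factor = 1) {
  stopifnot(inherits(grid, "climate_grid"))
  if (rain_factor < 0) stop("rain_factor must be non-negative")
  grid$tmin <- grid$tmin + deltaT
  grid$tmax <- grid$tmax + deltaT
  grid$rain <- grid$rain * rain_factor
  grid
}

#' Interpolate one cell's monthly record to the 52-week engine series
#'
#' The mechanistic engine runs on a 52-week, 364-day year (weekly stress and
#' growth rates are then exact). Temperatures and humidity are linearly
#' interpolated from month midpoints to week midpoints (periodic in the year);
#' each month's rainfall is divided among the days of a 365-day calendar and
#' summed into weeks, with the 365th day folded into week 52, so the annual
#' total is preserved exactly. The two humidity observations are averaged into the single
#' weekly series the engine uses, clamped to [0, 100].
#'
#' @param tmin,tmax,rain,rh09,rh15 numeric[12] monthly records for one cell.
#' @return a \code{"weekly_climate"} list: \code{tmin}, \code{tmax},
#'   \code{tmean} (midpoint), \code{rain} (mm/week), \code{rh}, each length 52.
#' @export
monthly_to_weekly <- function(tmin, tmax, rain, rh09, rh15) {
  for (v in list(tmin, tmax, rain, rh09, rh15))
    if (length(v) != 12L || anyNA(v)) stop("complete 12-month records required")
  if (any(tmin > tmax)) stop("tmin > tmax in at least one month")
  if (any(rain < 0)) stop("negative rainfall")
  if (any(rh09 < 0 | rh09 > 100 | rh15 < 0 | rh15 > 100))
    stop("relative humidity outside [0, 100]")

  month_mid <- cumsum(MONTH_DAYS) - MONTH_DAYS / 2     # day-of-year, 365-d cal
  week_mid <- (seq_len(52) - 0.5) * 7                  # day-of-year, 364-d cal

  interp_periodic <- function(y) {
    # periodic linear interpolation across the year boundary
    xs <- c(month_mid[12] - 365, month_mid, month_mid[1] + 365)
    ys <- c(y[12], y, y[1])
    stats::approx(xs, ys, xout = week_mid)$y
  }

  w_tmin <- interp_periodic(tmin)
  w_tmax <- interp_periodic(tmax)
  w_rh <- pmin(100, pmax(0, interp_periodic((rh09 + rh15) / 2)))

  # day-weighted rain: spread each month evenly over its days, sum weeks;
  # day 365 folds into week 52 so the annual total is conserved exactly
  daily <- rep(rain / MONTH_DAYS, times = MONTH_DAYS)  # 365 values
  w_rain <- colSums(matrix(daily[1:364], nrow = 7))
  w_rain[52] <- w_rain[52] + daily[365]

  structure(list(tmin = w_tmin, tmax = w_tmax,
                 tmean = (w_tmin + w_tmax) / 2,
                 rain = w_rain, rh = w_rh),
            class = "weekly_climate")
}

#' Extract one cell's monthly record from a grid
#'
#' @param grid a \code{"climate_grid"}.
#' @param i,j latitude and longitude indices.
#' @return list of the five numeric[12] monthly series.
#' @export
grid_cell <- function(grid, i, j) {
  list(tmin = grid$tmin[i, j, ], tmax = grid$tmax[i, j, ],
       rain = grid$rain[i, j, ], rh09 = grid$rh09[i, j, ],
       rh15 = grid$rh15[i, j, ])
}

#' Read / write gridded monthly climate as long-format CSV
#'
#' Columns \code{lat, lon, month, var, value} with \code{var} one of
#' \code{tmin, tmax, rain, rh09, rh15}. Values are written as float32-precision
#' decimals; \code{read_climate(write_climate(g))} reproduces \code{g} within
#' 1e-6. The grid must be regular and every cell must carry all 12 months of
#' all five variables.
#'
#' @param path CSV file path.
#' @param grid a \code{"climate_grid"} (for \code{write_climate}).
#' @return \code{read_climate}: a \code{"climate_grid"}.
#' @export
read_climate <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lat", "lon", "month", "var", "value")
  if (!all(need %in% names(d)))
    stop("climate CSV must have columns: ", paste(need, collapse = ", "))
  vars <- c("tmin", "tmax", "rain", "rh09", "rh15")
  missing <- setdiff(vars, unique(d$var))
  if (length(missing))
    stop("climate CSV missing variable(s): ", paste(missing, collapse = ", "))
  if (!setequal(unique(d$month), 1:12))
    stop("climate CSV must contain exactly months 1..12")
  lats <- sort(unique(d$lat)); lons <- sort(unique(d$lon))
  check_regular <- function(x, what) {
    if (length(x) > 2 && max(abs(diff(diff(x)))) > 1e-6)
      stop("irregular ", what, " spacing")
  }
  check_regular(lats, "latitude"); check_regular(lons, "longitude")
  arr <- function(v) {
    a <- array(NA_real_, c(length(lats), length(lons), 12L))
    sub <- d[d$var == v, ]
    a[cbind(match(sub$lat, lats), match(sub$lon, lons), sub$month)] <- sub$value
    if (anyNA(a)) stop("incomplete records for variable '", v, "'")
    a
  }
  new_climate_grid(lats, lons,
                   list(tmin = arr("tmin"), tmax = arr("tmax"),
                        rain = arr("rain"), rh09 = arr("rh09"),
                        rh15 = arr("rh15")))
}

#' @rdname read_climate
#' @export
write_climate <- function(grid, path) {
  stopifnot(inherits(grid, "climate_grid"))
  vars <- c("tmin", "tmax", "rain", "rh09", "rh15")
  rows <- lapply(vars, function(v) {
    a <- grid[[v]]
    idx <- which(!is.na(a), arr.ind = TRUE)
    data.frame(lat = grid$lats[idx[, 1]], lon = grid$lons[idx[, 2]],
               month = idx[, 3], var = v,
               # round-trip through float32 precision
               value = signif(a[idx], 8))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("Monthly climate grid: %d x %d cells (%.3g deg), lat [%g, %g], lon [%g, %g]\n",
              length(x$lats), length(x$lons), x$resolution,
              min(x$lats), max(x$lats), min(x$lons), max(x$lons)))
  cat(sprintf("  annual tmean range: %.1f to %.1f deg C; annual rain range: %.0f to %.0f mm\n",
              min((x$tmin + x$tmax) / 2), max((x$tmin + x$tmax) / 2),
              min(apply(x$rain, c(1, 2), sum)), max(apply(x$rain, c(1, 2), sum))))
  invisible(x)
}
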