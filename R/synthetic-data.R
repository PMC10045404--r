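# Synthetic fixture generators: smooth predictor rasters with bioclim-style
# magnitudes, a known truth surface, seeded presence samplers, and irrigation
# masks. Everything is pure given (arguments, seed), so tests regenerate
# fixtures instead of storing them.

#' Generate synthetic predictor rasters
#'
#' Spatially autocorrelated fields built by Gaussian smoothing of white noise
#' on the lat/lon lattice, rescaled to plausible bioclim-style magnitudes
#' (temperature seasonality, quarter temperatures and precipitation, an
#' elevation field), plus an exact latitude raster and slope/aspect derived
#' from the elevation field via [derive_topography()].
#'
#' @param lats,lons cell-center coordinate vectors (regular spacing).
#' @param seed integer seed; fixed seed gives identical rasters.
#' @param smooth smoothing radius in cells (0 = white noise).
#' @param vars named list mapping raster names to \code{c(min, max)} target
#'   ranges; defaults cover bio4, bio8, bio15, bio17, bio19 and elev.
#' @return named list of matrices (rows = lats, cols = lons), including
#'   \code{latitude}, \code{slope} and \code{aspect}.
#' @export
make_predictor_rasters <- function(lats, lons, seed = 1L, smooth = 2,
                                   vars = list(bio4 = c(100, 9000),
                                               bio8 = c(-5, 25),
                                               bio15 = c(10, 120),
                                               bio17 = c(0, 400),
                                               bio19 = c(0, 900),
                                               elev = c(0, 2500))) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  nr <- length(lats); nc <- length(lons)
  out <- lapply(vars, function(r) {
    f <- smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), smooth)
    lo <- min(f); hi <- max(f)
    if (hi > lo) r[1] + (f - lo) / (hi - lo) * (r[2] - r[1]) else f * 0 + r[1]
  })
  out$latitude <- matrix(lats, nr, nc)
  if (!is.null(out$elev) && nr > 1 && nc > 1) {
    res <- if (nr > 1) diff(lats)[1] else diff(lons)[1]
    topo <- derive_topography(out$elev, lats, res)
    out$slope <- topo$slope
    out$aspect <- topo$aspect
  }
  out
}

# moving-average Gaussian-kernel smoother with edge renormalisation
smooth_field <- function(m, radius) {
  if (radius <= 0) return(m)
  k <- stats::dnorm(seq(-radius, radius), sd = radius / 1.5)
  sm1 <- function(x) {  # smooth along columns of a matrix
    n <- nrow(x)
    out <- x * 0
    wsum <- numeric(n)
    for (o in seq(-radius, radius)) {
      i <- seq_len(n) + o
      ok <- i >= 1 & i <= n
      out[ok, ] <- out[ok, ] + k[o + radius + 1] * x[i[ok], ]
      wsum[ok] <- wsum[ok] + k[o + radius + 1]
    }
    out / wsum
  }
  t(sm1(t(sm1(m))))
}

#' Known logistic truth surface over predictor rasters
#'
#' Builds the presence-probability surface
#' \eqn{p = logit^{-1}(b_0 + \sum_j b_j z_j)} with \eqn{z_j} the named rasters
#' standardized over the lattice. The intercept is chosen to hit a target
#' mean prevalence. The generating coefficients are recorded so parameter-
#' recovery tests know the truth.
#'
#' @param rasters named list of matrices (from [make_predictor_rasters()]).
#' @param coefs named numeric vector of generating coefficients (on the
#'   standardized scale).
#' @param prevalence target mean probability (default 0.2).
#' @return a \code{"truth_surface"} list: \code{prob} matrix, \code{coefs},
#'   \code{prevalence}.
#' @export
truth_surface <- function(rasters, coefs, prevalence = 0.2) {
  stopifnot(all(names(coefs) %in% names(rasters)))
  lin <- 0
  for (v in names(coefs)) {
    z <- rasters[[v]]
    z <- (z - mean(z)) / max(stats::sd(z), 1e-12)
    lin <- lin + coefs[[v]] * z
  }
  b0 <- stats::uniroot(function(b) mean(stats::plogis(b + lin)) - prevalence,
                       c(-30, 30))$root
  structure(list(prob = stats::plogis(b0 + lin), coefs = coefs,
                 intercept = b0, prevalence = prevalence),
            class = "truth_surface")
}

#' Sample presence points from a truth surface
#'
#' Draws \code{n} distinct cells without replacement with probability
#' proportional to the truth surface, and returns their cell-center
#' coordinates — one record per location, as after distance thinning.
#'
#' @param truth a [truth_surface()].
#' @param lats,lons lattice coordinates.
#' @param n number of presence points.
#' @param seed integer seed.
#' @return data.frame: \code{lon}, \code{lat}, \code{cell} (lattice index).
#' @export
sample_presences <- function(truth, lats, lons, n, seed = 1L) {
  p <- as.numeric(truth$prob)
  if (n > sum(p > 0)) stop("not enough cells with positive probability")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cells <- sample.int(length(p), n, replace = FALSE, prob = p)
  idx <- arrayInd(cells, dim(truth$prob))
  data.frame(lon = lons[idx[, 2]], lat = lats[idx[, 1]], cell = cells)
}

#' Seeded random irrigation mask
#'
#' Marks exactly \code{round(fraction * n_cells)} cells TRUE, chosen uniformly
#' at random — a synthetic surrogate for a global irrigated-areas map.
#'
#' @param lats,lons lattice coordinates.
#' @param fraction target irrigated fraction in [0, 1].
#' @param seed integer seed.
#' @return logical matrix (rows = lats, cols = lons).
#' @export
make_irrigation_mask <- function(lats, lons, fraction, seed = 1L) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  n <- length(lats) * length(lons)
  mask <- matrix(FALSE, length(lats), length(lons))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mask[sample.int(n, round(fraction * n))] <- TRUE
  mask
}

#' Build an environment table from rasters
#'
#' Flattens a raster stack into the rows x predictors table consumed by
#' [maxent()], stacking presence cells above a seeded uniform background
#' sample of the lattice.
#'
#' @param rasters named list of matrices.
#' @param presences data.frame from [sample_presences()] (needs \code{cell}).
#' @param n_background number of background cells (uniform, seeded; default
#'   10000, capped at the lattice size).
#' @param seed integer seed for the background draw.
#' @return list: \code{env} (data.frame), \code{presence} (logical),
#'   \code{bg_cells} (lattice indices of the background rows).
#' @export
env_table <- function(rasters, presences, n_background = 10000, seed = 1L) {
  ncell <- length(rasters[[1]])
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  bg <- sample.int(ncell, min(n_background, ncell), replace = FALSE)
  cells <- c(presences$cell, bg)
  env <- as.data.frame(lapply(rasters, function(r) as.numeric(r)[cells]))
  list(env = env,
       presence = c(rep(TRUE, nrow(presences)), rep(FALSE, length(bg))),
       bg_cells = bg)
}

#' Read / write a raster as long-format CSV
#'
#' Columns \code{lat, lon, value}; the grid must be regular and complete.
#'
#' @param path CSV path.
#' @param raster matrix (rows = lats ascending).
#' @param lats,lons lattice coordinates (for writing).
#' @return \code{read_raster_csv}: list \code{lats}, \code{lons},
#'   \code{values} (matrix).
#' @export
read_raster_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("lat", "lon", "value") %in% names(d)))
    stop("raster CSV must have columns lat, lon, value")
  lats <- sort(unique(d$lat)); lons <- sort(unique(d$lon))
  m <- matrix(NA_real_, length(lats), length(lons))
  m[cbind(match(d$lat, lats), match(d$lon, lons))] <- d$value
  if (anyNA(m)) stop("incomplete raster")
  list(lats = lats, lons = lons, values = m)
}

#' @rdname read_raster_csv
#' @export
write_raster_csv <- function(raster, lats, lons, path) {
  idx <- which(!is.na(raster), arr.ind = TRUE)
  utils::write.csv(data.frame(lat = lats[idx[, 1]], lon = lons[idx[, 2]],
                              value = signif(raster[idx], 8)),
                   path, row.names = FALSE)
  invisible(path)
}
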