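# Scenario accounting over suitability grids: latitude-corrected areas,
# percent change, ensemble means and occurrence coverage.

EARTH_RADIUS_KM <- 6371

#' Area of one grid cell
#'
#' Spherical-zone formula for a cell of the given angular resolution centered
#' at \code{lat_center}:
#' \code{R^2 * dlon_rad * (sin(lat + d/2) - sin(lat - d/2))}, R = 6371 km.
#'
#' @param lat_center cell-center latitude, degrees (vectorised).
#' @param resolution cell size, degrees.
#' @return cell area, km^2.
#' @export
cell_area <- function(lat_center, resolution) {
  half <- resolution / 2
  EARTH_RADIUS_KM^2 * (resolution * pi / 180) *
    (sin(pmin(90, lat_center + half) * pi / 180) -
       sin(pmax(-90, lat_center - half) * pi / 180))
}

#' Total suitable area of a suitability grid
#'
#' Sums [cell_area()] over unmasked (non-NA) cells whose value meets the
#' threshold. For an EI grid the conventional cut is EI >= 10; every area
#' total is conditional on the chosen threshold.
#'
#' @param grid a \code{"suitability_grid"}.
#' @param threshold suitability cut (value >= threshold counts).
#' @return km^2.
#' @export
suitable_area <- function(grid, threshold = 10) {
  stopifnot(inherits(grid, "suitability_grid"))
  res <- if (length(grid$lats) > 1) diff(grid$lats)[1] else
    stop("cannot infer resolution from a single-row grid")
  ok <- !is.na(grid$values) & grid$values >= threshold
  sum(cell_area(grid$lats[row(grid$values)[ok]], res))
}

#' Percent change in suitable area between scenarios
#'
#' \code{100 * (future - current) / current}.
#'
#' @param current_km2,future_km2 areas, km^2.
#' @return percent change.
#' @export
area_change <- function(current_km2, future_km2) {
  if (current_km2 == 0) stop("current area is zero; percent change undefined")
  100 * (future_km2 - current_km2) / current_km2
}

#' Occurrence coverage of a suitability grid
#'
#' Looks each occurrence up in its nearest grid cell (ties snap toward the
#' lower index) and reports the share of occurrences falling in suitable
#' cells — the standard check that a mechanistic model captures the known
#' distribution.
#'
#' @param grid a \code{"suitability_grid"}.
#' @param occurrences data.frame with columns \code{lon}, \code{lat}.
#' @param threshold suitability cut.
#' @return list: \code{percent} (2 decimals), \code{inside}, \code{total}.
#' @export
occurrence_coverage <- function(grid, occurrences, threshold = 10) {
  stopifnot(inherits(grid, "suitability_grid"))
  n <- nrow(occurrences)
  if (is.null(n) || n == 0) stop("empty occurrence set")
  snap <- function(x, centers) {
    vapply(x, function(xi) {
      d <- abs(centers - xi)
      which(d == min(d))[1]          # ties toward the lower index
    }, integer(1))
  }
  i <- snap(occurrences$lat, grid$lats)
  j <- snap(occurrences$lon, grid$lons)
  v <- grid$values[cbind(i, j)]
  inside <- sum(!is.na(v) & v >= threshold)
  list(percent = round(100 * inside / n, 2), inside = inside, total = n)
}

#' Cell-wise ensemble mean of grids
#'
#' Arithmetic mean across a list of suitability or climate grids on identical
#' lattices — the multi-model ensemble average used to summarise projections
#' across global climate models. NA (masked) cells propagate.
#'
#' @param grids list of \code{"suitability_grid"}s or \code{"climate_grid"}s,
#'   all on the same lattice and of the same kind.
#' @return a grid of the same class.
#' @export
ensemble_mean <- function(grids) {
  if (!length(grids)) stop("empty grid list")
  g1 <- grids[[1]]
  same_lattice <- function(g) identical(g$lats, g1$lats) &&
    identical(g$lons, g1$lons)
  if (!all(vapply(grids, same_lattice, logical(1))))
    stop("grids are not on identical lattices")
  if (inherits(g1, "suitability_grid")) {
    if (!all(vapply(grids, function(g) identical(g$kind, g1$kind), logical(1))))
      stop("grids are of mixed kinds")
    vals <- Reduce(`+`, lapply(grids, `[[`, "values")) / length(grids)
    out <- g1; out$values <- vals
    out$scenario$label <- sprintf("ensemble mean (n=%d)", length(grids))
    out
  } else if (inherits(g1, "climate_grid")) {
    out <- g1
    for (v in c("tmin", "tmax", "rain", "rh09", "rh15"))
      out[[v]] <- Reduce(`+`, lapply(grids, `[[`, v)) / length(grids)
    out
  } else stop("unsupported grid class")
}

#' Scenario area report
#'
#' Suitable-area accounting for one scenario grid against a reference:
#' per-class areas, total suitable area and percent change. Percentages are
#' computed from unrounded areas.
#'
#' @param grid scenario \code{"suitability_grid"}.
#' @param reference reference (current-climate) grid, or NULL.
#' @param threshold binary suitability cut.
#' @param ei_mid optimal-band cut for the 3-class breakdown.
#' @return an \code{"area_report"} list.
#' @export
area_report <- function(grid, reference = NULL, threshold = 10, ei_mid = 30) {
  a <- suitable_area(grid, threshold)
  rep <- list(scenario = grid$scenario$label,
              threshold = threshold,
              suitable_km2 = a,
              optimal_km2 = suitable_area(grid, ei_mid),
              percent_change = if (!is.null(reference))
                area_change(suitable_area(reference, threshold), a)
              else NA_real_)
  structure(rep, class = "area_report")
}

#' @export
print.area_report <- function(x, ...) {
  cat(sprintf("Area report [%s], threshold %g\n", x$scenario, x$threshold))
  cat(sprintf("  suitable: %.4g km^2 (optimal band: %.4g km^2)\n",
              x$suitable_km2, x$optimal_km2))
  if (!is.na(x$percent_change))
    cat(sprintf("  change vs reference: %+.2f%%\n", x$percent_change))
  invisible(x)
}
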