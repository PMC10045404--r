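#' Ecoclimatic Index from growth and stress components
#'
#' The Ecoclimatic Index (EI, 0-100) discounts the annual growth index by each
#' accumulated stress multiplicatively:
#' \deqn{EI = GI_A (1 - CS/100)(1 - HS/100)(1 - DS/100)(1 - WS/100)(1 - HW/100)}
#' with every factor floored at 0, and EI forced to 0 when the annual
#' degree-days fall short of the PDD generation requirement. EI = 0 marks a
#' climate in which the species cannot persist; EI = 100 a climate optimal in
#' every respect year-round.
#'
#' @param GI_A annual growth index in [0, 100].
#' @param CS,HS,DS,WS,HW cold, heat, dry, wet and hot-wet stress totals in
#'   [0, 100].
#' @param annual_dd annual degree-days above the development threshold.
#' @param p a [species_params()] object (supplies PDD).
#' @return EI in [0, 100].
#' @export
ecoclimatic_index <- function(GI_A, CS, HS, DS, WS, HW, annual_dd, p) {
  ei <- GI_A *
    max(0, 1 - CS / 100) * max(0, 1 - HS / 100) *
    max(0, 1 - DS / 100) * max(0, 1 - WS / 100) * max(0, 1 - HW / 100)
  if (annual_dd < p$PDD) ei <- 0
  min(100, max(0, ei))
}

#' Run the mechanistic engine for a single location
#'
#' Chains the weekly pipeline for one cell: soil-moisture spin-up, weekly
#' temperature/moisture indices, annual growth index, the four single
#' stresses, hot-wet interaction stress, degree-days and the Ecoclimatic
#' Index.
#'
#' @param wc a \code{"weekly_climate"} for the location.
#' @param p a [species_params()] object.
#' @param irrigated logical; apply the irrigation top-up to the water balance.
#' @param rule an [irrigation_rule()].
#' @param ... further arguments to [soil_moisture_series()] (capacity,
#'   \code{c_et}, caps, tolerances).
#' @return a \code{"location_result"} list: \code{GI_A}, \code{CS}, \code{HS},
#'   \code{DS}, \code{WS}, \code{HW}, \code{annual_dd}, \code{EI}, plus the
#'   weekly \code{sm} cycle.
#' @export
location_result <- function(wc, p, irrigated = FALSE,
                            rule = irrigation_rule(), ...) {
  sms <- soil_moisture_series(wc, irrigated = irrigated, rule = rule, ...)
  TI <- temperature_index(wc$tmean, p)
  MI <- moisture_index(sms$sm, p)
  GI_A <- annual_growth_index(weekly_growth_index(TI, MI))
  CS <- accumulate_stress(wc$tmean, p$TTCS, p$THCS, "below")
  HS <- accumulate_stress(wc$tmean, p$TTHS, p$THHS, "above")
  DS <- accumulate_stress(sms$sm, p$SMDS, p$HDS, "below")
  WS <- accumulate_stress(sms$sm, p$SMWS, p$HWS, "above")
  HW <- hot_wet_stress(wc$tmean, sms$sm, p)
  dd <- annual_degree_days(wc$tmean, p$DV0)
  structure(list(GI_A = GI_A, CS = CS, HS = HS, DS = DS, WS = WS, HW = HW,
                 annual_dd = dd,
                 EI = ecoclimatic_index(GI_A, CS, HS, DS, WS, HW, dd, p),
                 sm = sms$sm),
            class = "location_result")
}

new_suitability_grid <- function(lats, lons, values, kind = c("EI", "probability"),
                                 scenario = list(label = "current",
                                                 deltaT = 0, rain_factor = 1)) {
  kind <- match.arg(kind)
  stopifnot(identical(dim(values), c(length(lats), length(lons))))
  structure(list(lats = lats, lons = lons, values = values, kind = kind,
                 scenario = scenario),
            class = "suitability_grid")
}

#' Compare-locations run: EI across a climate grid
#'
#' Runs the mechanistic engine over every unmasked cell of a monthly climate
#' grid, under both water regimes, and composes the agricultural map: where
#' the irrigation mask is TRUE the irrigated EI is used, elsewhere the
#' rainfed EI.
#'
#' @param grid a \code{"climate_grid"}.
#' @param p a [species_params()] object.
#' @param irrigation_mask logical nlat x nlon matrix (default all FALSE).
#' @param rule an [irrigation_rule()].
#' @param scenario_label character tag stored in the output grids.
#' @param ... further arguments to [soil_moisture_series()].
#' @return a \code{"climex_grid"} object: \code{rainfed}, \code{irrigated} and
#'   \code{composite} suitability grids (EI kind), per-stress grid means, and
#'   the run configuration.
#' @export
climex_run <- function(grid, p, irrigation_mask = NULL,
                       rule = irrigation_rule(), scenario_label = "current",
                       ...) {
  stopifnot(inherits(grid, "climate_grid"), inherits(p, "species_params"))
  nlat <- length(grid$lats); nlon <- length(grid$lons)
  if (is.null(irrigation_mask)) irrigation_mask <- matrix(FALSE, nlat, nlon)
  if (!identical(dim(irrigation_mask), c(nlat, nlon)))
    stop("irrigation mask shape does not match the climate grid")

  ei_rf <- ei_ir <- matrix(NA_real_, nlat, nlon)
  comp <- c(GI_A = 0, CS = 0, HS = 0, DS = 0, WS = 0, HW = 0)
  n_run <- 0L
  for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
    if (!grid$mask[i, j]) next
    wc <- do.call(monthly_to_weekly, grid_cell(grid, i, j))
    rf <- location_result(wc, p, irrigated = FALSE, rule = rule, ...)
    ir <- location_result(wc, p, irrigated = TRUE, rule = rule, ...)
    ei_rf[i, j] <- rf$EI
    ei_ir[i, j] <- ir$EI
    comp <- comp + unlist(rf[c("GI_A", "CS", "HS", "DS", "WS", "HW")])
    n_run <- n_run + 1L
  }
  ei_comp <- ifelse(irrigation_mask, ei_ir, ei_rf)

  scen <- list(label = scenario_label, deltaT = 0, rain_factor = 1)
  structure(list(
    rainfed = new_suitability_grid(grid$lats, grid$lons, ei_rf, "EI", scen),
    irrigated = new_suitability_grid(grid$lats, grid$lons, ei_ir, "EI", scen),
    composite = new_suitability_grid(grid$lats, grid$lons, ei_comp, "EI", scen),
    stress_means = comp / max(1L, n_run),
    irrigation_mask = irrigation_mask,
    params = p, n_cells = n_run),
    class = "climex_grid")
}

#' Classify Ecoclimatic Index values into suitability classes
#'
#' The published maps show a continuous EI ramp; any "suitable area" figure
#' needs a cut. The default binary rule calls a cell suitable when
#' \code{EI >= ei_min} (closed lower bound), with \code{ei_min = 10}. The
#' three-class banding used for maps is \code{[ei_min, ei_mid)} marginal and
#' \code{>= ei_mid} optimal. Both cuts are configuration, not biology: every
#' area total in this package is conditional on them.
#'
#' @param EI numeric EI values (vectorised; NA passes through).
#' @param ei_min suitability cut (default 10).
#' @param ei_mid optimal-band cut for 3-class maps (default 30).
#' @param classes \code{"binary"} or \code{"bands"}.
#' @return factor of class labels.
#' @export
classify_suitability <- function(EI, ei_min = 10, ei_mid = 30,
                                 classes = c("binary", "bands")) {
  classes <- match.arg(classes)
  if (classes == "binary") {
    factor(ifelse(EI >= ei_min, "suitable", "unsuitable"),
           levels = c("unsuitable", "suitable"))
  } else {
    factor(ifelse(EI >= ei_mid, "optimal",
                  ifelse(EI >= ei_min, "marginal", "unsuitable")),
           levels = c("unsuitable", "marginal", "optimal"))
  }
}

#' @export
print.climex_grid <- function(x, ...) {
  v <- x$composite$values
  cat(sprintf("Mechanistic suitability run (%s): %d cells\n",
              x$composite$scenario$label, x$n_cells))
  cat(sprintf("  composite EI: min %.1f, median %.1f, max %.1f; %d cells with EI > 0\n",
              min(v, na.rm = TRUE), stats::median(v, na.rm = TRUE),
              max(v, na.rm = TRUE), sum(v > 0, na.rm = TRUE)))
  cat("  grid-mean components: ",
      paste(sprintf("%s=%.2f", names(x$stress_means), x$stress_means),
            collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.climex_grid <- function(object, ei_min = 10, ...) {
  v <- object$composite$values
  cls <- classify_suitability(v, ei_min = ei_min)
  out <- list(ei_summary = summary(v[!is.na(v)]),
              class_counts = table(cls),
              suitable_area_km2 = suitable_area(object$composite,
                                                threshold = ei_min),
              stress_means = object$stress_means)
  class(out) <- "summary.climex_grid"
  out
}

#' @export
print.summary.climex_grid <- function(x, ...) {
  cat("Ecoclimatic Index summary\n")
  print(x$ei_summary)
  print(x$class_counts)
  cat(sprintf("Suitable area: %.4g km^2\n", x$suitable_area_km2))
  invisible(x)
}

#' Plot a suitability grid
#'
#' Filled image of EI (0-100) or SDM probability (0-1) over the lat/lon
#' lattice, white for unsuitable through dark red for optimal.
#'
#' @param x a \code{"suitability_grid"}.
#' @param ... passed to [graphics::image()].
#' @export
plot.suitability_grid <- function(x, ...) {
  zmax <- if (x$kind == "EI") 100 else 1
  pal <- grDevices::colorRampPalette(c("white", "gold", "orangered", "darkred"))(64)
  graphics::image(x$lons, x$lats, t(x$values), col = pal,
                  zlim = c(0, zmax), xlab = "longitude", ylab = "latitude",
                  main = sprintf("%s (%s)", x$kind, x$scenario$label), ...)
  invisible(x)
}
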