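# Weekly growth indices, annual stress accumulation and degree-days: the
# mechanistic core. All operations are vectorised over weeks; an independent
# per-week loop implementation lives in the test suite as an oracle.

trapezoid <- function(x, a, b, c, d) {
  # piecewise-linear suitability: 0 outside (a,d), 1 on [b,c]
  out <- numeric(length(x))
  up <- x > a & x < b
  out[up] <- (x[up] - a) / (b - a)
  out[x >= b & x <= c] <- 1
  down <- x > c & x < d
  out[down] <- (d - x[down]) / (d - c)
  out
}

#' Weekly temperature suitability index
#'
#' Piecewise-linear trapezoid over the development thresholds: 0 at or below
#' DV0 and at or above DV3, rising linearly to 1 at DV1, flat at 1 over the
#' optimal range [DV1, DV2], falling linearly to 0 at DV3.
#'
#' @param tmean weekly mean temperature, deg C (vectorised).
#' @param p a [species_params()] object.
#' @return suitability in [0, 1].
#' @export
temperature_index <- function(tmean, p) {
  trapezoid(tmean, p$DV0, p$DV1, p$DV2, p$DV3)
}

#' Weekly moisture suitability index
#'
#' Same trapezoid over the soil-moisture thresholds SM0..SM3.
#'
#' @param sm weekly soil-moisture fraction (vectorised, >= 0).
#' @param p a [species_params()] object.
#' @return suitability in [0, 1].
#' @export
moisture_index <- function(sm, p) {
  if (any(sm < 0)) stop("soil moisture must be non-negative")
  trapezoid(sm, p$SM0, p$SM1, p$SM2, p$SM3)
}

#' Weekly and annual growth index
#'
#' The weekly growth index is the product of the temperature and moisture
#' indices; the annual growth index is 100 times the mean over the 52 weeks.
#'
#' @param TI,MI weekly temperature and moisture indices in [0, 1].
#' @return \code{weekly_growth_index}: numeric in [0, 1].
#' @export
weekly_growth_index <- function(TI, MI) TI * MI

#' @rdname weekly_growth_index
#' @param GI numeric[52] weekly growth indices.
#' @return \code{annual_growth_index}: scalar in [0, 100].
#' @export
annual_growth_index <- function(GI) {
  if (length(GI) != 52L) stop("expected 52 weekly values")
  100 * mean(GI)
}

#' Annual accumulation of a single climatic stress
#'
#' Stress accrues linearly in the weekly exceedance of a threshold, at a
#' species-specific weekly rate, and is capped at 100 (total exclusion).
#' Cold and heat stress drive on weekly mean temperature (side \code{"below"}
#' and \code{"above"} respectively); dry and wet stress on the weekly
#' soil-moisture fraction. Rates are taken by absolute value since published
#' tables mix signs. The x100 factor converts the dimensionless weekly
#' accumulation to percentage points.
#'
#' @param driver numeric[52] weekly driver series (deg C or sm fraction).
#' @param threshold stress threshold in driver units.
#' @param rate weekly accumulation rate (sign ignored).
#' @param side \code{"below"} (stress when driver < threshold) or
#'   \code{"above"}.
#' @return stress total in [0, 100]:
#'   \code{min(100, sum(100 * |rate| * max(0, exceedance)))}.
#' @export
accumulate_stress <- function(driver, threshold, rate,
                              side = c("below", "above")) {
  side <- match.arg(side)
  if (!all(is.finite(driver))) stop("non-finite driver series")
  exc <- if (side == "below") threshold - driver else driver - threshold
  min(100, sum(100 * abs(rate) * pmax(0, exc)))
}

#' Annual hot-wet interaction stress
#'
#' Accrues only in weeks where temperature and soil moisture simultaneously
#' exceed their thresholds (TTHW, MTHW), proportionally to the product of the
#' two exceedances at rate PHW; capped at 100.
#'
#' @param tmean numeric[52] weekly mean temperature, deg C.
#' @param sm numeric[52] weekly soil-moisture fraction.
#' @param p a [species_params()] object.
#' @return stress total in [0, 100].
#' @export
hot_wet_stress <- function(tmean, sm, p) {
  min(100, sum(100 * abs(p$PHW) *
                 pmax(0, tmean - p$TTHW) * pmax(0, sm - p$MTHW)))
}

#' Annual degree-days above the development threshold
#'
#' \code{sum(7 * max(0, tmean_w - DV0))} over the 52-week year. Compared to
#' the PDD requirement to decide whether one generation can complete.
#'
#' @param tmean numeric[52] weekly mean temperature, deg C.
#' @param DV0 lower development threshold, deg C.
#' @return annual degree-days (>= 0).
#' @export
annual_degree_days <- function(tmean, DV0) {
  sum(7 * pmax(0, tmean - DV0))
}
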