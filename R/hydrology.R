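#' Irrigation top-up rule
#'
#' The agricultural scenario tops rainfall up to a weekly threshold, capped by
#' a maximum daily application. The published configuration applies up to
#' 1.5 mm/day year-round: a week with more than 10.5 mm of rain receives no
#' irrigation; a drier week is topped up to the 10.5 mm weekly threshold.
#'
#' @param threshold_mm weekly rainfall threshold, mm (default 10.5).
#' @param daily_cap_mm maximum irrigation per day, mm (default 1.5).
#' @return an \code{"irrigation_rule"} list.
#' @export
irrigation_rule <- function(threshold_mm = 10.5, daily_cap_mm = 1.5) {
  if (threshold_mm < 0 || daily_cap_mm < 0) stop("rule values must be >= 0")
  structure(list(threshold_mm = threshold_mm, daily_cap_mm = daily_cap_mm),
            class = "irrigation_rule")
}

#' Weekly irrigation top-up
#'
#' @param rain_week weekly rainfall, mm (vectorised; >= 0).
#' @param rule an [irrigation_rule()].
#' @return mm of irrigation added per week:
#'   \code{min(max(0, threshold - rain), 7 * daily_cap)}.
#' @export
irrigation_topup <- function(rain_week, rule = irrigation_rule()) {
  if (any(rain_week < 0)) stop("negative rainfall")
  pmin(pmax(0, rule$threshold_mm - rain_week), 7 * rule$daily_cap_mm)
}

#' Weekly evapotranspiration
#'
#' A linear temperature-driven evaporative demand moderated by atmospheric
#' saturation: \code{E = max(0, c_et * tmean) * (1 - rh/100) * 7} mm per week.
#' This is a deliberately simple bulk formulation (no radiation or wind terms);
#' \code{c_et} is a calibration knob.
#'
#' @param tmean weekly mean temperature, deg C (vectorised).
#' @param rh weekly relative humidity, percent in [0, 100].
#' @param c_et evaporation coefficient, mm per deg C per day (default 0.8).
#' @return mm/week, non-negative; zero at saturation (rh = 100).
#' @export
weekly_evapotranspiration <- function(tmean, rh, c_et = 0.8) {
  if (any(rh < 0 | rh > 100)) stop("rh outside [0, 100]")
  pmax(0, c_et * tmean) * (1 - rh / 100) * 7
}

#' Converged weekly soil-moisture cycle for one location
#'
#' A single-bucket weekly water balance expressed as a fraction of
#' soil-moisture-holding capacity:
#' \code{sm_w = clamp(sm_{w-1} + (rain_w + irrigation_w - E_w)/capacity, 0, sm_cap)}.
#' Fractions above 1 represent waterlogging (the wet-stress threshold of the
#' packaged species sits at 2.5). The annual cycle is iterated to a periodic
#' steady state: starting from \code{sm = init}, whole years are repeated
#' until the largest week-wise change between successive years falls below
#' \code{tol}. The cap makes the map a contraction, so the converged cycle is
#' independent of the start value.
#'
#' @param wc a \code{"weekly_climate"} (see [monthly_to_weekly()]).
#' @param irrigated logical; apply the top-up rule to each week's rainfall.
#' @param rule an [irrigation_rule()].
#' @param capacity_mm soil-moisture-holding capacity, mm (default 100).
#' @param sm_cap hard upper cap on the soil-moisture fraction (default 3).
#' @param c_et evaporation coefficient passed to
#'   [weekly_evapotranspiration()].
#' @param init starting fraction for spin-up (default 0.5).
#' @param tol convergence tolerance on the year-over-year change (default 1e-6).
#' @param spinup_max maximum spin-up years (default 500).
#' @return a \code{"soil_moisture"} list: \code{sm} (numeric[52] converged
#'   cycle), \code{irrigation} (mm/week added), \code{years} used.
#' @export
soil_moisture_series <- function(wc, irrigated = FALSE,
                                 rule = irrigation_rule(),
                                 capacity_mm = 100, sm_cap = 3,
                                 c_et = 0.8, init = 0.5,
                                 tol = 1e-6, spinup_max = 500) {
  stopifnot(inherits(wc, "weekly_climate"))
  irr <- if (irrigated) irrigation_topup(wc$rain, rule) else rep(0, 52)
  water <- wc$rain + irr
  et <- weekly_evapotranspiration(wc$tmean, wc$rh, c_et)
  delta <- (water - et) / capacity_mm

  sm <- numeric(52)
  prev <- rep(NA_real_, 52)
  s <- init
  for (yr in seq_len(spinup_max)) {
    for (w in 1:52) {
      s <- min(max(s + delta[w], 0), sm_cap)
      sm[w] <- s
    }
    if (!anyNA(prev) && max(abs(sm - prev)) < tol) {
      return(structure(list(sm = sm, irrigation = irr, years = yr),
                       class = "soil_moisture"))
    }
    prev <- sm
  }
  stop("soil-moisture spin-up did not converge within ", spinup_max, " years")
}
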