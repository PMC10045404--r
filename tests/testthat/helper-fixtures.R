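# Shared fixtures and independent oracle implementations. Oracles are written
# as plain per-week loops / brute-force enumerations, deliberately ignorant of
# the package's vectorised code paths.

table_params <- function() cfigulilella_params()

small_grid <- function(noise_sd = 0, resolution = 10, seed = 1,
                       lat_min = -60, lat_max = 60, ...) {
  generate_climate_grid(climate_spec(
    lat_min = lat_min, lat_max = lat_max, lon_min = 0, lon_max = 10,
    resolution = resolution, noise_sd = noise_sd, seed = seed, ...))
}

random_weekly_climate <- function() {
  # one random but valid weekly series (caller controls the RNG seed)
  tmean <- runif(52, -10, 40)
  half <- runif(1, 2, 8)
  structure(list(tmin = tmean - half, tmax = tmean + half, tmean = tmean,
                 rain = runif(52, 0, 40), rh = runif(52, 20, 95)),
            class = "weekly_climate")
}

# --- naive per-week loop engine (oracle for the vectorised core) -----------

naive_trapezoid <- function(x, a, b, c_, d) {
  if (x <= a || x >= d) return(0)
  if (x >= b && x <= c_) return(1)
  if (x < b) (x - a) / (b - a) else (d - x) / (d - c_)
}

naive_stress <- function(driver, threshold, rate, side) {
  s <- 0
  for (w in 1:52) {
    exc <- if (side == "below") threshold - driver[w] else driver[w] - threshold
    if (exc > 0) s <- s + 100 * abs(rate) * exc
  }
  min(100, s)
}

naive_hot_wet <- function(tmean, sm, p) {
  s <- 0
  for (w in 1:52) {
    a <- tmean[w] - p$TTHW
    b <- sm[w] - p$MTHW
    if (a > 0 && b > 0) s <- s + 100 * abs(p$PHW) * a * b
  }
  min(100, s)
}

naive_location <- function(tmean, sm, p) {
  gi <- 0
  dd <- 0
  for (w in 1:52) {
    ti <- naive_trapezoid(tmean[w], p$DV0, p$DV1, p$DV2, p$DV3)
    mi <- naive_trapezoid(sm[w], p$SM0, p$SM1, p$SM2, p$SM3)
    gi <- gi + ti * mi
    if (tmean[w] > p$DV0) dd <- dd + 7 * (tmean[w] - p$DV0)
  }
  GI_A <- 100 * gi / 52
  CS <- naive_stress(tmean, p$TTCS, p$THCS, "below")
  HS <- naive_stress(tmean, p$TTHS, p$THHS, "above")
  DS <- naive_stress(sm, p$SMDS, p$HDS, "below")
  WS <- naive_stress(sm, p$SMWS, p$HWS, "above")
  HW <- naive_hot_wet(tmean, sm, p)
  ei <- GI_A
  for (s in c(CS, HS, DS, WS, HW)) ei <- ei * max(0, 1 - s / 100)
  if (dd < p$PDD) ei <- 0
  list(GI_A = GI_A, CS = CS, HS = HS, DS = DS, WS = WS, HW = HW,
       annual_dd = dd, EI = min(100, max(0, ei)))
}

vectorized_location <- function(tmean, sm, p) {
  GI_A <- annual_growth_index(
    weekly_growth_index(temperature_index(tmean, p), moisture_index(sm, p)))
  CS <- accumulate_stress(tmean, p$TTCS, p$THCS, "below")
  HS <- accumulate_stress(tmean, p$TTHS, p$THHS, "above")
  DS <- accumulate_stress(sm, p$SMDS, p$HDS, "below")
  WS <- accumulate_stress(sm, p$SMWS, p$HWS, "above")
  HW <- hot_wet_stress(tmean, sm, p)
  dd <- annual_degree_days(tmean, p$DV0)
  list(GI_A = GI_A, CS = CS, HS = HS, DS = DS, WS = WS, HW = HW,
       annual_dd = dd,
       EI = ecoclimatic_index(GI_A, CS, HS, DS, WS, HW, dd, p))
}

# brute-force AUC over all (pos, neg) pairs
pairwise_auc <- function(pos, neg) {
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# two-variable SDM recovery world shared by tests and checks
recovery_world <- function(seed, n_presence = 200, n_background = 2500,
                           nlat = 40, nlon = 40) {
  lats <- seq(-39, 39, length.out = nlat)
  lons <- seq(-39, 39, length.out = nlon)
  r <- make_predictor_rasters(lats, lons, seed = seed, smooth = 3,
                              vars = list(x1 = c(0, 10), x2 = c(-3, 3)))
  r <- r[c("x1", "x2")]
  tr <- truth_surface(r, c(x1 = 2, x2 = -1.5), prevalence = 0.15)
  occ <- sample_presences(tr, lats, lons, n_presence, seed = seed + 7)
  et <- env_table(r, occ, n_background = n_background, seed = seed + 13)
  list(rasters = r, truth = tr, occ = occ, env = et$env,
       presence = et$presence, lats = lats, lons = lons)
}
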