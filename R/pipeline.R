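# End-to-end pipeline: synthetic world -> mechanistic EI scenarios ->
# SDM tuning/fit/prediction -> scenario area report. Configuration is a
# plain named list (or YAML file); one global seed fans out to fixed
# per-stage seeds so each stage is individually reproducible.

#' Default pipeline configuration
#'
#' Returns the full configuration list with every tunable of the pipeline:
#' the synthetic-world lattice, the scenario list (additive warming and rain
#' scaling), the irrigated fraction, the SDM tuning grid, sample sizes, and
#' the suitability threshold. Any subset can be overridden via
#' \code{modifyList()} or a YAML file with the same keys.
#'
#' @param seed global seed.
#' @return named list.
#' @export
default_pipeline_config <- function(seed = 42L) {
  list(
    seed = as.integer(seed),
    climate = list(lat_min = -60, lat_max = 60, lon_min = 0, lon_max = 16,
                   resolution = 4, equator_tmean = 27, lapse = 0.6,
                   seasonal_amplitude = 8, diurnal_range = 10,
                   rain_regime = "winter-wet", annual_rain = 800,
                   rh_base = 70, noise_sd = 0.3),
    params_file = NULL,                  # default: packaged raisin-moth set
    irrigated_fraction = 0.3,
    scenarios = list(
      list(label = "ssp126-like", deltaT = 2, rain_factor = 1),
      list(label = "ssp585-like", deltaT = 5, rain_factor = 1)),
    sdm = list(enabled = TRUE, n_presence = 80, n_background = 1500,
               rm_values = seq(0.5, 4, by = 0.5),
               fc_values = c("L", "LQ", "H", "LQH", "LQHP", "LQHPT"),
               n_hinge_knots = 6, n_threshold_knots = 4,
               truth_coefs = c(bio8 = -1.5, bio19 = -1, latitude = 0)),
    ei_min = 10)
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror [default_pipeline_config()]; missing keys take defaults.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- merge_config(default_pipeline_config(), user)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

# name-wise merge over the defaults; the scenario list is replaced wholesale
# (modifyList cannot express "no scenarios" and must not merge scenario
# entries element-wise)
merge_config <- function(default, user) {
  cfg <- utils::modifyList(default, user)
  if (!is.null(user$scenarios) || ("scenarios" %in% names(user)))
    cfg$scenarios <- user$scenarios
  cfg
}

# fixed per-stage seed fan-out (kept < 2^31)
stage_seed <- function(seed, stage) {
  offs <- c(climate = 101L, rasters = 211L, presences = 307L, mask = 401L,
            background = 503L, tuning = 601L)
  (as.integer(seed) * 1009L + offs[[stage]]) %% .Machine$integer.max
}

#' Run the full synthetic-world pipeline
#'
#' Chains every stage of the analysis on a synthetic world: (1) generate the
#' monthly climate grid, predictor rasters, truth surface, presence sample
#' and irrigation mask; (2) run the mechanistic engine under the current
#' climate and every configured scenario, composing rainfed/irrigated maps;
#' (3) tune, fit and project the maxent SDM; (4) produce the scenario area
#' report (suitable areas, percent changes, occurrence coverage). All outputs
#' are returned in-memory; when \code{out_dir} is given, grids are written as
#' long CSV and the report (with the resolved config and seed) as JSON.
#'
#' @param config configuration list (see [default_pipeline_config()]) or a
#'   YAML path.
#' @param out_dir optional output directory.
#' @return an \code{"ecoclim_pipeline"} list: \code{climate}, \code{rasters},
#'   \code{occurrences}, \code{mask}, \code{mechanistic} (per scenario
#'   \code{"climex_grid"}s), \code{tuning}, \code{sdm_fit}, \code{sdm_grid},
#'   \code{report}, \code{config}.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- merge_config(default_pipeline_config(), config)
  seed <- cfg$seed

  # --- stage 1: synthetic world -------------------------------------------
  spec <- do.call(climate_spec,
                  c(cfg$climate, list(seed = stage_seed(seed, "climate"))))
  grid <- generate_climate_grid(spec)
  rasters <- make_predictor_rasters(grid$lats, grid$lons,
                                    seed = stage_seed(seed, "rasters"))
  mask <- make_irrigation_mask(grid$lats, grid$lons, cfg$irrigated_fraction,
                               seed = stage_seed(seed, "mask"))
  p <- if (is.null(cfg$params_file)) cfigulilella_params() else
    read_species_params(cfg$params_file)

  tc <- cfg$sdm$truth_coefs
  truth <- truth_surface(rasters, tc[names(tc) %in% names(rasters)])
  occ <- sample_presences(truth, grid$lats, grid$lons, cfg$sdm$n_presence,
                          seed = stage_seed(seed, "presences"))

  # --- stage 2: mechanistic engine ----------------------------------------
  mech <- list(current = climex_run(grid, p, irrigation_mask = mask))
  for (sc in cfg$scenarios) {
    g2 <- apply_scenario(grid, deltaT = sc$deltaT,
                         rain_factor = sc$rain_factor)
    mech[[sc$label]] <- climex_run(g2, p, irrigation_mask = mask,
                                   scenario_label = sc$label)
  }

  # --- stage 3: SDM --------------------------------------------------------
  tuning <- sdm_fit <- sdm_grid <- NULL
  if (isTRUE(cfg$sdm$enabled)) {
    et <- env_table(rasters, occ, n_background = cfg$sdm$n_background,
                    seed = stage_seed(seed, "background"))
    tuning <- tune_maxent(et$env, et$presence, occ[c("lon", "lat")],
                          rm_values = cfg$sdm$rm_values,
                          fc_values = cfg$sdm$fc_values,
                          n_hinge_knots = cfg$sdm$n_hinge_knots,
                          n_threshold_knots = cfg$sdm$n_threshold_knots)
    sdm_fit <- maxent(et$env, et$presence, rm = tuning$rm,
                      classes = tuning$fc,
                      n_hinge_knots = cfg$sdm$n_hinge_knots,
                      n_threshold_knots = cfg$sdm$n_threshold_knots)
    all_env <- as.data.frame(lapply(rasters, as.numeric))
    pred <- matrix(predict(sdm_fit, all_env),
                   length(grid$lats), length(grid$lons))
    sdm_grid <- new_suitability_grid(grid$lats, grid$lons, pred,
                                     "probability")
  }

  # --- stage 4: report -----------------------------------------------------
  cur <- mech$current$composite
  scen_reports <- lapply(mech[-1], function(m)
    unclass(area_report(m$composite, cur, threshold = cfg$ei_min)))
  cov <- occurrence_coverage(cur, occ, threshold = cfg$ei_min)
  report <- list(seed = seed,
                 config_hash = config_hash(cfg),
                 threshold = cfg$ei_min,
                 current_suitable_km2 = suitable_area(cur, cfg$ei_min),
                 scenarios = scen_reports,
                 occurrence_coverage = cov)

  out <- structure(list(climate = grid, rasters = rasters, truth = truth,
                        occurrences = occ, mask = mask, params = p,
                        mechanistic = mech, tuning = tuning,
                        sdm_fit = sdm_fit, sdm_grid = sdm_grid,
                        report = report, config = cfg),
                   class = "ecoclim_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE)
  # small stable rolling hash of the resolved config, for provenance
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

write_pipeline_outputs <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_climate(x$climate, file.path(out_dir, "climate.csv"))
  for (nm in names(x$mechanistic))
    write_raster_csv(x$mechanistic[[nm]]$composite$values,
                     x$climate$lats, x$climate$lons,
                     file.path(out_dir, paste0("ei_", nm, ".csv")))
  if (!is.null(x$sdm_grid))
    write_raster_csv(x$sdm_grid$values, x$climate$lats, x$climate$lons,
                     file.path(out_dir, "sdm_probability.csv"))
  utils::write.csv(x$occurrences, file.path(out_dir, "occurrences.csv"),
                   row.names = FALSE)
  if (!is.null(x$tuning))
    utils::write.csv(x$tuning$results, file.path(out_dir, "tuning.csv"),
                     row.names = FALSE)
  jsonlite::write_json(x$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.ecoclim_pipeline <- function(x, ...) {
  cat("Synthetic-world suitability pipeline\n")
  cat(sprintf("  seed %d, config %s\n", x$report$seed, x$report$config_hash))
  cat(sprintf("  scenarios: %s\n",
              paste(names(x$mechanistic), collapse = ", ")))
  cat(sprintf("  current suitable area (EI >= %g): %.4g km^2\n",
              x$report$threshold, x$report$current_suitable_km2))
  if (!is.null(x$tuning))
    cat(sprintf("  SDM: RM = %g, FC = %s selected from %d combinations\n",
                x$tuning$rm, x$tuning$fc, nrow(x$tuning$results)))
  cat(sprintf("  occurrence coverage: %.2f%% (%d/%d)\n",
              x$report$occurrence_coverage$percent,
              x$report$occurrence_coverage$inside,
              x$report$occurrence_coverage$total))
  invisible(x)
}
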