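#' Species parameter set for the mechanistic suitability engine
#'
#' Constructs and validates the full parameter set consumed by the
#' Ecoclimatic Index engine: the temperature and soil-moisture suitability
#' trapezoids, the four single-stress threshold/rate pairs, the hot-wet
#' interaction stress triple, and the degree-day requirement for one
#' generation.
#'
#' Parameter names follow the standard CLIMEX vocabulary so parameter files
#' from the mechanistic-modelling literature map one-to-one:
#' \describe{
#'   \item{DV0..DV3}{temperature thresholds (deg C): development is possible on
#'     (DV0, DV3) and optimal on [DV1, DV2].}
#'   \item{SM0..SM3}{soil-moisture thresholds (fraction of holding capacity;
#'     values above 1 represent waterlogging).}
#'   \item{TTCS, THCS}{cold-stress temperature threshold (deg C) and weekly
#'     accumulation rate.}
#'   \item{TTHS, THHS}{heat-stress threshold and rate.}
#'   \item{SMDS, HDS}{dry-stress soil-moisture threshold and rate.}
#'   \item{SMWS, HWS}{wet-stress soil-moisture threshold and rate.}
#'   \item{TTHW, MTHW, PHW}{hot-wet interaction stress: temperature threshold,
#'     moisture threshold, and rate.}
#'   \item{PDD}{degree-days above DV0 needed to complete one generation;
#'     locations accumulating less are unsuitable regardless of growth.}
#' }
#'
#' Stress rates are interpreted by absolute value: published parameter tables
#' mix signs (a cold-stress rate of -0.001 and a wet-stress rate of +0.0015
#' both accumulate stress).
#'
#' @param DV0,DV1,DV2,DV3 temperature thresholds, deg C.
#' @param SM0,SM1,SM2,SM3 soil-moisture thresholds, fractions.
#' @param TTCS,THCS cold stress threshold (deg C) and rate (week^-1).
#' @param TTHS,THHS heat stress threshold (deg C) and rate (week^-1).
#' @param SMDS,HDS dry stress threshold (fraction) and rate (week^-1).
#' @param SMWS,HWS wet stress threshold (fraction) and rate (week^-1).
#' @param TTHW,MTHW,PHW hot-wet stress temperature threshold (deg C),
#'   moisture threshold (fraction) and rate (week^-1).
#' @param PDD degree-days required per generation.
#' @return an object of class \code{"species_params"} (named list).
#' @seealso [cfigulilella_params()] for the packaged raisin-moth values,
#'   [read_species_params()] to load a parameter file.
#' @export
species_params <- function(DV0, DV1, DV2, DV3,
                           SM0, SM1, SM2, SM3,
                           TTCS, THCS, TTHS, THHS,
                           SMDS, HDS, SMWS, HWS,
                           TTHW, MTHW, PHW, PDD) {
  p <- list(DV0 = DV0, DV1 = DV1, DV2 = DV2, DV3 = DV3,
            SM0 = SM0, SM1 = SM1, SM2 = SM2, SM3 = SM3,
            TTCS = TTCS, THCS = THCS, TTHS = TTHS, THHS = THHS,
            SMDS = SMDS, HDS = HDS, SMWS = SMWS, HWS = HWS,
            TTHW = TTHW, MTHW = MTHW, PHW = PHW, PDD = PDD)
  p <- lapply(p, as.numeric)
  bad <- names(p)[!vapply(p, function(x) length(x) == 1L && is.finite(x), logical(1))]
  if (length(bad))
    stop("non-finite or non-scalar parameter(s): ", paste(bad, collapse = ", "))
  if (!(p$DV0 < p$DV1 && p$DV1 <= p$DV2 && p$DV2 < p$DV3))
    stop("temperature thresholds must satisfy DV0 < DV1 <= DV2 < DV3")
  if (!(p$SM0 < p$SM1 && p$SM1 <= p$SM2 && p$SM2 < p$SM3))
    stop("soil-moisture thresholds must satisfy SM0 < SM1 <= SM2 < SM3")
  if (p$PDD < 0) stop("PDD must be non-negative")
  structure(p, class = "species_params")
}

#' Raisin moth (*Cadra figulilella*) parameter set
#'
#' The packaged parameter values for the raisin moth, read from the parameter
#' file shipped in \code{inst/extdata/cfigulilella.params}. Development occurs
#' between 13 and 36 deg C (optimum 15-30), soil-moisture suitability spans
#' 0.25-2.5 of holding capacity (optimum 0.8-1.5), and 292 degree-days above
#' the lower threshold are required per generation.
#'
#' Note: the source literature is internally inconsistent about the lower
#' temperature threshold (narrative text mentions 11 deg C; the parameter
#' table lists 13). The packaged file follows the parameter table (DV0 = 13).
#'
#' @return a \code{"species_params"} object.
#' @export
cfigulilella_params <- function() {
  read_species_params(system.file("extdata", "cfigulilella.params",
                                  package = "ecoclim", mustWork = TRUE))
}

#' Published variable-importance table for the raisin-moth SDM
#'
#' The reference percent-contribution and permutation-importance values of
#' the twelve predictors retained in the raisin-moth maximum-entropy model,
#' as reported in the source study. Useful as an input for importance
#' summaries (e.g. [cumulative_importance()]) and for comparing a refit
#' against the reference ranking.
#'
#' @return data.frame: \code{variable}, \code{description},
#'   \code{percent_contribution}, \code{permutation_importance}.
#' @export
cfigulilella_importance <- function() {
  utils::read.csv(system.file("extdata", "cfigulilella_maxent_importance.csv",
                              package = "ecoclim", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Read / write a species parameter file
#'
#' Flat key-value text format, one \code{NAME = value} pair per line,
#' \code{#} comments allowed. Keys mirror the standard parameter names
#' (\code{DV0} ... \code{PDD}); all 20 are required.
#'
#' @param path file path.
#' @return \code{read_species_params}: a \code{"species_params"} object.
#' @export
read_species_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L)) stop("malformed parameter line in ", path)
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, character(1), 2L))))
  if (anyNA(vals)) stop("non-numeric parameter value in ", path)
  need <- c("DV0", "DV1", "DV2", "DV3", "SM0", "SM1", "SM2", "SM3",
            "TTCS", "THCS", "TTHS", "THHS", "SMDS", "HDS", "SMWS", "HWS",
            "TTHW", "MTHW", "PHW", "PDD")
  missing <- setdiff(need, keys)
  if (length(missing))
    stop("parameter file missing: ", paste(missing, collapse = ", "))
  do.call(species_params, as.list(stats::setNames(vals, keys)[need]))
}

#' @rdname read_species_params
#' @param p a \code{"species_params"} object.
#' @export
write_species_params <- function(p, path) {
  stopifnot(inherits(p, "species_params"))
  writeLines(sprintf("%s = %.10g", names(p), unlist(p)), path)
  invisible(path)
}

#' @export
print.species_params <- function(x, ...) {
  cat("Species parameter set (mechanistic suitability engine)\n")
  cat(sprintf("  Temperature (deg C): DV0=%g DV1=%g DV2=%g DV3=%g\n",
              x$DV0, x$DV1, x$DV2, x$DV3))
  cat(sprintf("  Soil moisture:       SM0=%g SM1=%g SM2=%g SM3=%g\n",
              x$SM0, x$SM1, x$SM2, x$SM3))
  cat(sprintf("  Cold stress: TTCS=%g THCS=%g   Heat stress: TTHS=%g THHS=%g\n",
              x$TTCS, x$THCS, x$TTHS, x$THHS))
  cat(sprintf("  Dry stress:  SMDS=%g HDS=%g    Wet stress:  SMWS=%g HWS=%g\n",
              x$SMDS, x$HDS, x$SMWS, x$HWS))
  cat(sprintf("  Hot-wet:     TTHW=%g MTHW=%g PHW=%g\n", x$TTHW, x$MTHW, x$PHW))
  cat(sprintf("  Degree-days per generation (PDD): %g\n", x$PDD))
  invisible(x)
}
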