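# Maxent feature construction. Feature definitions are frozen against the
# background sample (ranges, quantile knots) so the same transform can be
# re-applied to new locations at prediction time.

#' Build a maxent feature matrix
#'
#' Expands raw predictor columns into the classical maxent feature classes:
#' \describe{
#'   \item{L}{linear: each column rescaled to [0, 1] over the reference rows.}
#'   \item{Q}{quadratic: squares, rescaled likewise.}
#'   \item{P}{product: pairwise products of rescaled linear features.}
#'   \item{T}{threshold: step indicators \code{x > knot} at reference
#'     quantile knots.}
#'   \item{H}{hinge: forward \code{max(0, (x-k)/(max-k))} and reverse
#'     \code{max(0, (k-x)/(k-min))} pieces at reference quantile knots.}
#' }
#' All features lie in [0, 1] over the reference rows. Rescaling makes the
#' model invariant to (orientation-preserving) affine changes of the raw
#' predictor units.
#'
#' @param env data.frame or matrix of raw predictor columns (numeric).
#' @param classes character string or vector of feature-class letters, e.g.
#'   \code{"LQH"} or \code{c("L","Q","H")}.
#' @param n_hinge_knots interior knots per variable for hinge features
#'   (default 20).
#' @param n_threshold_knots interior knots for threshold features (default 10).
#' @param reference rows used to freeze ranges and knots (default: all rows;
#'   pass the background index when presences are appended).
#' @param defs frozen definitions from a previous call; when supplied, the
#'   same transform is re-applied (for prediction).
#' @return list with the numeric feature matrix \code{X} (named columns) and
#'   the definition list \code{defs}.
#' @export
build_features <- function(env, classes = "LQH",
                           n_hinge_knots = 20, n_threshold_knots = 10,
                           reference = NULL, defs = NULL) {
  env <- as.data.frame(env)
  if (!all(vapply(env, is.numeric, logical(1))))
    stop("all predictor columns must be numeric")
  if (is.null(defs)) {
    classes <- sort(unique(strsplit(paste(classes, collapse = ""), "")[[1]]))
    if (!all(classes %in% c("L", "Q", "H", "P", "T")))
      stop("unknown feature class; use letters from L, Q, H, P, T")
    ref <- if (is.null(reference)) seq_len(nrow(env)) else reference
    defs <- make_feature_defs(env[ref, , drop = FALSE], classes,
                              n_hinge_knots, n_threshold_knots)
  }
  X <- eval_features(env, defs)
  list(X = X, defs = defs)
}

make_feature_defs <- function(ref, classes, n_hinge, n_thresh) {
  vars <- names(ref)
  rng <- lapply(ref, range)
  defs <- list()
  add <- function(d) defs[[length(defs) + 1L]] <<- d
  if ("L" %in% classes)
    for (v in vars) add(list(type = "L", var = v,
                             lo = rng[[v]][1], hi = rng[[v]][2]))
  if ("Q" %in% classes)
    for (v in vars) {
      r2 <- range(ref[[v]]^2)
      add(list(type = "Q", var = v, lo = r2[1], hi = r2[2]))
    }
  if ("P" %in% classes && length(vars) > 1)
    for (a in seq_len(length(vars) - 1)) for (b in (a + 1):length(vars)) {
      va <- vars[a]; vb <- vars[b]
      pr <- scale01(ref[[va]], rng[[va]]) * scale01(ref[[vb]], rng[[vb]])
      add(list(type = "P", var = c(va, vb),
               lo1 = rng[[va]][1], hi1 = rng[[va]][2],
               lo2 = rng[[vb]][1], hi2 = rng[[vb]][2],
               plo = min(pr), phi = max(pr)))
    }
  if ("T" %in% classes)
    for (v in vars) {
      ks <- unique(stats::quantile(ref[[v]], probs = seq_len(n_thresh) /
                                     (n_thresh + 1), names = FALSE))
      for (k in ks) add(list(type = "T", var = v, knot = k))
    }
  if ("H" %in% classes)
    for (v in vars) {
      ks <- unique(stats::quantile(ref[[v]],
                                   probs = seq_len(n_hinge) / (n_hinge + 1),
                                   names = FALSE))
      for (k in ks) {
        if (rng[[v]][2] > k)
          add(list(type = "Hf", var = v, knot = k, hi = rng[[v]][2]))
        if (k > rng[[v]][1])
          add(list(type = "Hr", var = v, knot = k, lo = rng[[v]][1]))
      }
    }
  defs
}

scale01 <- function(x, r) {
  if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else x * 0
}

eval_features <- function(env, defs) {
  n <- nrow(env)
  X <- matrix(0, n, length(defs))
  nm <- character(length(defs))
  for (j in seq_along(defs)) {
    d <- defs[[j]]
    X[, j] <- switch(d$type,
      L = scale01(env[[d$var]], c(d$lo, d$hi)),
      Q = scale01(env[[d$var]]^2, c(d$lo, d$hi)),
      P = scale01(scale01(env[[d$var[1]]], c(d$lo1, d$hi1)) *
                    scale01(env[[d$var[2]]], c(d$lo2, d$hi2)),
                  c(d$plo, d$phi)),
      T = as.numeric(env[[d$var]] > d$knot),
      Hf = pmax(0, (env[[d$var]] - d$knot) / (d$hi - d$knot)),
      Hr = pmax(0, (d$knot - env[[d$var]]) / (d$knot - d$lo)),
      stop("unknown feature type"))
    nm[j] <- switch(d$type,
      L = d$var,
      Q = paste0("I(", d$var, "^2)"),
      P = paste(d$var, collapse = ":"),
      T = sprintf("(%s>%.4g)", d$var, d$knot),
      Hf = sprintf("hinge(%s,%.4g)", d$var, d$knot),
      Hr = sprintf("hinge(%.4g,%s)", d$knot, d$var))
  }
  colnames(X) <- nm
  X
}

# source variable(s) of each feature, for attribution and jackknifes
feature_vars <- function(defs) lapply(defs, function(d) d$var)
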