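# Model evaluation and tuning: AUC, omission rates, AICc, spatial-block
# folds, the RM x FC tuning grid, jackknife importance and contributions.

#' Area under the ROC curve
#'
#' Rank-based AUC: the probability that a randomly chosen positive scores
#' above a randomly chosen negative, with ties counting one half.
#'
#' @param pos,neg numeric score vectors for positives (presences) and
#'   negatives (background).
#' @return AUC in [0, 1].
#' @export
auc <- function(pos, neg) {
  if (!length(pos) || !length(neg)) stop("empty score vector")
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' 10% training omission rate
#'
#' The threshold is the training-presence score sitting just above the lowest
#' 10% of training scores (ceiling rule on the count); OR10 is the fraction
#' of test presences scoring strictly below that threshold. Values well above
#' the expected 0.10 indicate overfitting to the training presences.
#'
#' @param train training-presence scores.
#' @param test test-presence scores.
#' @param q omission quantile (default 0.10).
#' @return omission rate in [0, 1].
#' @export
or10 <- function(train, test, q = 0.10) {
  if (!length(train) || !length(test)) stop("empty score vector")
  n_low <- ceiling(q * length(train))
  thr <- sort(train)[min(n_low + 1L, length(train))]
  mean(test < thr)
}

#' Small-sample-corrected AIC for a maxent model
#'
#' \code{AICc = 2k - 2 lnL + 2k(k+1)/(n-k-1)} with k the count of nonzero
#' coefficients, n the number of presences, and lnL the presence
#' log-likelihood under the background-normalized model density. Undefined
#' (NA) when \code{n <= k + 1}; such combinations are excluded from model
#' selection.
#'
#' @param model a \code{"maxent"} fit.
#' @return AICc, or NA when undefined.
#' @export
aicc <- function(model) {
  k <- sum(model$beta != 0)
  n <- model$n_presence
  if (n <= k + 1) return(NA_real_)
  2 * k - 2 * model$lnL + 2 * k * (k + 1) / (n - k - 1)
}

#' Spatial-block fold assignment
#'
#' Splits occurrence points into four geographic blocks: first at the median
#' latitude, then at the median longitude within each latitude half. The
#' hierarchical split keeps the four groups equal to within one point while
#' remaining purely geographic, so cross-validation tests spatial
#' transferability rather than random interpolation.
#'
#' @param points data.frame with columns \code{lon}, \code{lat}.
#' @param k number of folds; only the 2x2 block design (k = 4) is supported.
#' @return integer fold id (1-4) per point.
#' @export
spatial_block_folds <- function(points, k = 4) {
  if (k != 4) stop("only the 2x2 block design (k = 4) is supported")
  lon <- points$lon; lat <- points$lat
  if (length(unique(lon)) < 2 && length(unique(lat)) < 2)
    stop("degenerate blocks: all points at one location")
  split_half <- function(x) {
    # TRUE for the upper half; rank-based so equal-sized up to ties
    rank(x, ties.method = "first") > length(x) / 2
  }
  top <- split_half(lat)
  fold <- integer(length(lat))
  fold[!top] <- 1L + split_half(lon[!top])
  fold[top] <- 3L + split_half(lon[top])
  fold
}

#' Tune the regularization multiplier and feature classes
#'
#' Evaluates every (RM, FC) combination on the published tuning protocol:
#' for each combination a full-data fit gives AICc, and k-fold
#' cross-validation over spatial-block folds gives the mean train-test AUC
#' difference (AUC.DIFF, an overfitting gap) and the mean 10% training
#' omission rate (OR10). The default grid is RM in 0.5-4 by 0.5 crossed with
#' FC in \{L, LQ, H, LQH, LQHP, LQHPT\} — 48 combinations — and the selected
#' combination minimises AICc (delta.AICc = 0).
#'
#' @param env data.frame of raw predictors, presence rows first then
#'   background (see \code{presence}).
#' @param presence logical flag per row of \code{env}.
#' @param coords data.frame (\code{lon}, \code{lat}) for the presence rows,
#'   used for spatial-block folds.
#' @param rm_values RM grid (default \code{seq(0.5, 4, 0.5)}).
#' @param fc_values feature-combination grid (default the six published sets).
#' @param folds optional fold ids per presence; default
#'   [spatial_block_folds()] on \code{coords}.
#' @param ... passed to [maxent()] (knot counts etc.).
#' @return a \code{"maxent_tuning"} object: \code{results} data.frame (one
#'   row per combination: \code{rm}, \code{fc}, \code{AICc},
#'   \code{delta.AICc}, \code{avg.AUC.DIFF}, \code{avg.OR10},
#'   \code{n_nonzero}), and \code{best} = the selected row.
#' @export
tune_maxent <- function(env, presence, coords,
                        rm_values = seq(0.5, 4, by = 0.5),
                        fc_values = c("L", "LQ", "H", "LQH", "LQHP", "LQHPT"),
                        folds = NULL, ...) {
  presence <- as.logical(presence)
  if (is.null(folds)) folds <- spatial_block_folds(coords)
  stopifnot(length(folds) == sum(presence))
  grid <- expand.grid(rm = rm_values, fc = fc_values,
                      stringsAsFactors = FALSE)
  pres_idx <- which(presence)
  bg_idx <- which(!presence)

  res <- lapply(seq_len(nrow(grid)), function(g) {
    rm <- grid$rm[g]; fc <- grid$fc[g]
    full <- maxent(env, presence, rm = rm, classes = fc, ...)
    a <- aicc(full)
    diffs <- ors <- numeric(0)
    for (f in sort(unique(folds))) {
      test_rows <- pres_idx[folds == f]
      train_rows <- c(pres_idx[folds != f], bg_idx)
      if (sum(folds != f) < 2) next
      fit <- maxent(env[train_rows, , drop = FALSE],
                    presence[train_rows], rm = rm, classes = fc, ...)
      s_train <- predict(fit, env[pres_idx[folds != f], , drop = FALSE])
      s_test <- predict(fit, env[test_rows, , drop = FALSE])
      s_bg <- predict(fit, env[bg_idx, , drop = FALSE])
      diffs <- c(diffs, auc(s_train, s_bg) - auc(s_test, s_bg))
      ors <- c(ors, or10(s_train, s_test))
    }
    data.frame(rm = rm, fc = fc, AICc = a,
               avg.AUC.DIFF = mean(diffs), avg.OR10 = mean(ors),
               n_nonzero = sum(full$beta != 0))
  })
  res <- do.call(rbind, res)
  res$delta.AICc <- res$AICc - min(res$AICc, na.rm = TRUE)
  ok <- which(!is.na(res$AICc))
  best <- ok[which.min(res$AICc[ok])]
  structure(list(results = res, best = res[best, ],
                 rm = res$rm[best], fc = res$fc[best]),
            class = "maxent_tuning")
}

#' @export
print.maxent_tuning <- function(x, ...) {
  cat(sprintf("Maxent tuning: %d RM x FC combinations evaluated\n",
              nrow(x$results)))
  cat(sprintf("Selected: RM = %g, FC = %s (delta.AICc = %g, avg.OR10 = %.4f)\n",
              x$rm, x$fc, x$best$delta.AICc, x$best$avg.OR10))
  invisible(x)
}

#' Jackknife variable importance
#'
#' Refits the model with (a) each predictor alone and (b) all predictors but
#' that one, reporting the regularized training gain of each fit next to the
#' full-model gain — the classical jackknife bar chart. A variable whose
#' with-only gain is near zero carries no signal on its own; a variable whose
#' without gain equals the full gain is redundant given the others.
#'
#' @param env,presence training data as for [maxent()].
#' @param rm,classes model configuration.
#' @param ... passed to [maxent()].
#' @return data.frame: \code{variable}, \code{gain_with_only},
#'   \code{gain_without}, plus attribute \code{full_gain}.
#' @export
jackknife_importance <- function(env, presence, rm = 1, classes = "LQH", ...) {
  env <- as.data.frame(env)
  full <- maxent(env, presence, rm = rm, classes = classes, ...)
  rows <- lapply(names(env), function(v) {
    with_only <- maxent(env[v], presence, rm = rm, classes = classes, ...)
    without <- if (ncol(env) > 1)
      maxent(env[setdiff(names(env), v)], presence, rm = rm,
             classes = classes, ...)
    data.frame(variable = v,
               gain_with_only = with_only$gain,
               gain_without = if (ncol(env) > 1) without$gain else 0)
  })
  out <- do.call(rbind, rows)
  attr(out, "full_gain") <- full$gain
  out
}

#' Percent contribution and permutation importance
#'
#' Percent contribution shares out the cumulative objective improvements of
#' the coordinate-descent fit across the source variable of each updated
#' feature, normalized to sum to 100. Permutation importance permutes one raw
#' predictor column at a time (seeded), measures the drop in training AUC
#' (presences vs background), and normalizes the drops to 100.
#'
#' @param model a \code{"maxent"} fit.
#' @param permutation also compute permutation importance (default TRUE).
#' @param seed seed for the permutations.
#' @return data.frame: \code{variable}, \code{percent_contribution} and (if
#'   requested) \code{permutation_importance}.
#' @export
variable_contributions <- function(model, permutation = TRUE, seed = 1L) {
  fv <- feature_vars(model$defs)
  contrib <- stats::setNames(numeric(length(model$vars)), model$vars)
  for (j in seq_along(fv)) {
    share <- model$gain_trace[j] / length(fv[[j]])
    for (v in fv[[j]]) contrib[v] <- contrib[v] + share
  }
  pc <- if (sum(contrib) > 0) 100 * contrib / sum(contrib) else contrib
  out <- data.frame(variable = model$vars,
                    percent_contribution = as.numeric(pc))
  if (permutation) {
    env <- model$training$env
    pres <- model$training$presence
    base_scores <- predict(model, env)
    base_auc <- auc(base_scores[pres], base_scores[!pres])
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    drops <- vapply(model$vars, function(v) {
      pe <- env
      pe[[v]] <- sample(pe[[v]])
      s <- predict(model, pe)
      max(0, base_auc - auc(s[pres], s[!pres]))
    }, numeric(1))
    out$permutation_importance <-
      if (sum(drops) > 0) as.numeric(100 * drops / sum(drops)) else drops
  }
  out
}

#' Cumulative importance of the leading variables
#'
#' Sum of the importance values of the n leading variables — the "the top six
#' variables jointly account for X%" summary used when reporting variable
#' importance tables. By default variables are ranked by the summed column
#' itself; pass \code{order_by} to rank by a different measure (e.g. sum
#' permutation importance over the variables ranked by percent contribution,
#' so both cumulative figures describe the same variable set).
#'
#' @param importance numeric vector of percentages (summing to ~100).
#' @param n how many leading variables to sum (default 6).
#' @param order_by numeric vector used for the ranking (default
#'   \code{importance}).
#' @return the cumulative percentage.
#' @export
cumulative_importance <- function(importance, n = 6, order_by = importance) {
  stopifnot(length(order_by) == length(importance))
  keep <- order(order_by, decreasing = TRUE)[seq_len(min(n, length(importance)))]
  sum(importance[keep])
}

#' Greedy collinearity filter
#'
#' Among every pair of predictors with |Pearson r| above the threshold, the
#' lower-contribution variable is dropped. Implemented greedily in
#' deterministic order: variables are considered by descending contribution
#' (ties broken alphabetically) and kept only if they correlate at or below
#' the threshold with every already-kept variable.
#'
#' @param env data.frame of predictor columns.
#' @param contributions named numeric vector, one value per column of
#'   \code{env}.
#' @param r_thresh correlation threshold (default 0.8).
#' @return character vector of retained variable names.
#' @export
collinearity_filter <- function(env, contributions, r_thresh = 0.8) {
  env <- as.data.frame(env)
  if (!all(names(env) %in% names(contributions)))
    stop("contributions required for every predictor")
  ord <- names(env)[order(-contributions[names(env)], names(env))]
  r <- abs(stats::cor(env))
  kept <- character(0)
  for (v in ord) {
    if (!length(kept) || all(r[v, kept] <= r_thresh)) kept <- c(kept, v)
  }
  kept
}

#' Distance thinning of occurrence records
#'
#' Greedy spatial thinning: while any retained pair lies closer than
#' \code{min_km} (great-circle), remove the point with the most neighbours
#' inside the radius, breaking ties by a seeded random draw. Emulates the
#' standard occurrence-thinning step used to reduce sampling bias.
#'
#' @param points data.frame with columns \code{lon}, \code{lat} (degrees).
#' @param min_km minimum allowed pairwise distance, km.
#' @param seed seed for tie-breaking.
#' @return the thinned data.frame (original row subset).
#' @export
thin_occurrences <- function(points, min_km, seed = 1L) {
  stopifnot(all(c("lon", "lat") %in% names(points)))
  if (any(points$lat < -90 | points$lat > 90))
    stop("latitude outside [-90, 90]")
  points <- unique(points[c("lon", "lat")])
  n <- nrow(points)
  if (n <= 1) return(points)
  d <- geosphere::distm(as.matrix(points[c("lon", "lat")])) / 1000
  close <- d < min_km
  diag(close) <- FALSE
  keep <- rep(TRUE, n)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  repeat {
    deg <- rowSums(close[, keep, drop = FALSE]) * keep
    if (all(deg == 0)) break
    worst <- which(deg == max(deg))
    drop <- if (length(worst) > 1) sample(worst, 1) else worst
    keep[drop] <- FALSE
    close[drop, ] <- FALSE
    close[, drop] <- FALSE
  }
  points[keep, , drop = FALSE]
}

#' Slope and aspect from an elevation grid
#'
#' Horn's third-order finite-difference method on the 3x3 neighbourhood,
#' with metric cell sizes derived from the geographic resolution (meridional
#' arc for north-south, parallel arc scaled by cos(latitude) for east-west).
#' Border cells use their nearest interior neighbourhood (edge replication).
#'
#' @param elev matrix of elevations (rows = latitudes ascending, cols =
#'   longitudes), metres.
#' @param lats latitude of each row, degrees.
#' @param resolution grid spacing, degrees.
#' @return list of two matrices: \code{slope} (degrees, >= 0) and
#'   \code{aspect} (degrees clockwise from north in [0, 360); flat cells 0).
#' @export
derive_topography <- function(elev, lats, resolution) {
  nr <- nrow(elev); nc <- ncol(elev)
  if (nr < 2 || nc < 2) stop("elevation grid too small for a 3x3 neighbourhood")
  pad <- function(m) m[c(1, 1:nr, nr), c(1, 1:nc, nc)]   # edge replication
  e <- pad(elev)
  # 3x3 shifted views; rows ascend with latitude so "north" = row + 1
  sh <- function(dr, dc) e[(2:(nr + 1)) + dr, (2:(nc + 1)) + dc]
  nw <- sh(1, -1); n_ <- sh(1, 0); ne <- sh(1, 1)
  w_ <- sh(0, -1);                  e_ <- sh(0, 1)
  sw <- sh(-1, -1); s_ <- sh(-1, 0); se <- sh(-1, 1)

  m_per_deg <- 111320
  dx <- matrix(m_per_deg * cos(lats * pi / 180) * resolution, nr, nc)
  dy <- m_per_deg * resolution
  dzdx <- ((ne + 2 * e_ + se) - (nw + 2 * w_ + sw)) / (8 * dx)
  dzdy <- ((ne + 2 * n_ + nw) - (se + 2 * s_ + sw)) / (8 * dy)

  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  # compass direction the slope faces = steepest downhill bearing
  aspect <- (atan2(-dzdx, -dzdy) * 180 / pi + 360) %% 360
  aspect[slope == 0] <- 0
  list(slope = slope, aspect = aspect)
}
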