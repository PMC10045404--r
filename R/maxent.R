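#' Fit a presence-only maximum-entropy distribution model
#'
#' Fits the maxent model of species presence against a background sample: the
#' model density over the background is the Gibbs distribution
#' \eqn{q(x) \propto \exp(\eta(x))} with \eqn{\eta} a linear combination of
#' features built from the raw predictors ([build_features()]). Coefficients
#' minimise the L1-regularized negative presence log-likelihood
#' \deqn{-\frac{1}{m}\sum_{presence} \eta(x_i) + \log \bar Z +
#'       \sum_j \lambda_j |\beta_j|}
#' where \eqn{\bar Z} is the mean of \eqn{e^{\eta}} over the background and
#' \eqn{\lambda_j = RM \cdot \beta_{class} \, s_j / \sqrt{m}} (\eqn{s_j} the
#' presence-sample s.d. of feature j, m the presence count). The
#' regularization multiplier RM scales all penalties; larger RM gives sparser,
#' smoother models. Optimisation is cyclic coordinate descent with Newton
#' steps and soft-thresholding; the per-update gain increments are retained so
#' percent contributions can be attributed to source variables
#' ([variable_contributions()]).
#'
#' This is the penalized presence/background conditional-likelihood
#' formulation (equivalent to an infinitely weighted logistic regression),
#' not the original sequential-update algorithm; attribution from
#' coordinate-descent gain increments approximates the original tool's trace.
#'
#' @param env data.frame of raw predictor values, presences and background
#'   stacked rowwise.
#' @param presence logical or 0/1 vector flagging presence rows.
#' @param rm regularization multiplier (> 0, default 1).
#' @param classes feature classes, e.g. \code{"LQ"} (see [build_features()]).
#' @param n_hinge_knots,n_threshold_knots knot counts per variable.
#' @param beta_class named base penalties per feature class letter.
#' @param tol convergence tolerance on the objective change per cycle
#'   (default 1e-7).
#' @param max_iter maximum coordinate-descent cycles (default 10000 single
#'   coordinate updates, i.e. cycles = max_iter / n_features, at least 50).
#' @return an object of class \code{"maxent"}: coefficients \code{beta},
#'   feature \code{defs}, \code{rm}, \code{classes}, entropy of the fitted
#'   background distribution, presence log-likelihood, regularized training
#'   \code{gain}, per-variable gain attribution, convergence info.
#' @seealso [predict.maxent()], [tune_maxent()], [response_curve()].
#' @export
maxent <- function(env, presence, rm = 1, classes = "LQH",
                   n_hinge_knots = 20, n_threshold_knots = 10,
                   beta_class = c(L = 1, Q = 1, P = 1, T = 1, H = 0.5),
                   tol = 1e-7, max_iter = 10000) {
  env <- as.data.frame(env)
  presence <- as.logical(presence)
  m <- sum(presence)
  nbg <- sum(!presence)
  if (m < 2) stop("at least 2 presence rows required")
  if (nbg < 10) stop("at least 10 background rows required")
  if (rm <= 0) stop("rm must be positive")

  fb <- build_features(env, classes, n_hinge_knots, n_threshold_knots,
                       reference = which(!presence))
  X <- fb$X
  k <- ncol(X)
  Xp <- X[presence, , drop = FALSE]
  Xb <- X[!presence, , drop = FALSE]
  pbar <- colMeans(Xp)                      # presence feature means

  # per-feature penalty: class base penalty x presence s.d. / sqrt(m)
  cls1 <- substr(vapply(fb$defs, function(d) d$type, character(1)), 1, 1)
  lam <- rm * beta_class[cls1] * pmax(apply(Xp, 2, stats::sd), 1e-4) / sqrt(m)

  beta <- numeric(k)
  eta_b <- numeric(nbg)
  eta_p_mean <- 0

  objective <- function(eta_p_mean, w) {
    # w: unnormalized background weights exp(eta - mx); returns f and logZbar
    NULL
  }

  # state: background Gibbs weights
  upd_w <- function(eta_b) {
    mx <- max(eta_b)
    w <- exp(eta_b - mx)
    list(w = w / sum(w), logZbar = mx + log(mean(exp(eta_b - mx))))
  }
  st <- upd_w(eta_b)
  f_cur <- -eta_p_mean + st$logZbar + sum(lam * abs(beta))

  var_gain <- stats::setNames(numeric(k), colnames(X))
  n_updates <- 0L
  cycles <- max(200L, ceiling(max_iter / max(1L, k)))
  converged <- FALSE

  for (cy in seq_len(cycles)) {
    f_start <- f_cur
    for (j in seq_len(k)) {
      xj <- Xb[, j]
      qj <- sum(st$w * xj)
      g <- -pbar[j] + qj                     # unpenalized gradient
      h <- max(sum(st$w * xj^2) - qj^2, 1e-10)
      z <- beta[j] - g / h
      bnew <- sign(z) * max(0, abs(z) - lam[j] / h)
      dstep <- bnew - beta[j]
      if (dstep == 0) next
      # backtracking to guarantee descent (Newton step can overshoot)
      repeat {
        bj <- beta[j] + dstep
        eta_try <- eta_b + dstep * xj
        st_try <- upd_w(eta_try)
        ep_try <- eta_p_mean + dstep * pbar[j]
        f_try <- -ep_try + st_try$logZbar +
          sum(lam * abs(replace(beta, j, bj)))
        if (f_try <= f_cur + 1e-12 || abs(dstep) < 1e-12) break
        dstep <- dstep / 2
      }
      if (f_try < f_cur) {
        var_gain[j] <- var_gain[j] + (f_cur - f_try)
        beta[j] <- beta[j] + dstep
        eta_b <- eta_try
        eta_p_mean <- ep_try
        st <- st_try
        f_cur <- f_try
        n_updates <- n_updates + 1L
      }
    }
    if (f_start - f_cur < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    # KKT violation: active coords need g = -lam*sign(b); zero coords |g| <= lam
    grad <- -pbar + as.numeric(crossprod(Xb, st$w))
    viol <- ifelse(beta == 0, pmax(0, abs(grad) - lam),
                   abs(grad + lam * sign(beta)))
    if (max(viol) > 1e-3)
      warning(sprintf(
        "coordinate descent stopped at max cycles; max KKT violation = %.3g",
        max(viol)))
    else converged <- TRUE
  }

  # fitted background distribution and its entropy (for cloglog output)
  q <- st$w
  H <- -sum(q * log(pmax(q, 1e-300)))
  # presence log-likelihood under the background-normalized density
  eta_p <- as.numeric(Xp %*% beta)
  lnL <- sum(eta_p - st$logZbar - log(nbg))

  structure(list(
    beta = stats::setNames(beta, colnames(X)),
    defs = fb$defs, rm = rm,
    classes = sort(unique(cls1)),
    lambda = stats::setNames(as.numeric(lam), colnames(X)),
    entropy = H, logZbar = st$logZbar, n_background = nbg, n_presence = m,
    lnL = unname(lnL), gain = unname(-f_cur),
    gain_trace = var_gain,
    vars = names(env),
    env_means = colMeans(env[!presence, , drop = FALSE]),
    env_ranges = lapply(env[!presence, , drop = FALSE], range),
    training = list(env = env, presence = presence),
    converged = converged, updates = n_updates),
    class = "maxent")
}

#' Predict suitability from a fitted maxent model
#'
#' @param object a \code{"maxent"} fit.
#' @param newdata data.frame with the model's raw predictor columns.
#' @param type \code{"cloglog"} (default; suitability in [0, 1], the standard
#'   map output), \code{"exponential"} (relative occurrence rate, mean 1 over
#'   the training background), or \code{"link"} (the linear predictor).
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.maxent <- function(object, newdata, type = c("cloglog", "exponential",
                                                     "link"), ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  miss <- setdiff(unique(unlist(feature_vars(object$defs))), names(newdata))
  if (length(miss))
    stop("newdata missing predictor(s): ", paste(miss, collapse = ", "))
  X <- eval_features(newdata, object$defs)
  eta <- as.numeric(X %*% object$beta)
  switch(type,
         link = eta,
         exponential = exp(eta - object$logZbar),
         cloglog = 1 - exp(-exp(object$entropy) *
                             exp(eta - object$logZbar) / object$n_background))
}

#' @export
print.maxent <- function(x, ...) {
  nz <- sum(x$beta != 0)
  cat(sprintf("Maxent model: RM = %g, classes = %s\n", x$rm,
              paste(x$classes, collapse = "")))
  cat(sprintf("  %d presences vs %d background; %d/%d nonzero features\n",
              x$n_presence, x$n_background, nz, length(x$beta)))
  cat(sprintf("  regularized training gain %.4f; lnL %.2f%s\n", x$gain, x$lnL,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
coef.maxent <- function(object, ...) object$beta

#' @export
summary.maxent <- function(object, ...) {
  vc <- variable_contributions(object)
  out <- list(fit = object, contributions = vc)
  class(out) <- "summary.maxent"
  out
}

#' @export
print.summary.maxent <- function(x, ...) {
  print(x$fit)
  cat("\nVariable contributions (%):\n")
  df <- x$contributions
  df[-1] <- lapply(df[-1], round, 1)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Response curve of one predictor
#'
#' Sweeps one predictor over its background range with every other predictor
#' held at its background mean, and returns the predicted suitability — the
#' standard marginal response curve.
#'
#' @param model a \code{"maxent"} fit.
#' @param variable predictor name.
#' @param n_points number of evaluation points (default 100).
#' @param type prediction scale (see [predict.maxent()]).
#' @return data.frame with columns \code{x} and \code{suitability}.
#' @export
response_curve <- function(model, variable, n_points = 100,
                           type = "cloglog") {
  if (!variable %in% model$vars) stop("unknown predictor: ", variable)
  xs <- seq(model$env_ranges[[variable]][1], model$env_ranges[[variable]][2],
            length.out = n_points)
  nd <- as.data.frame(lapply(model$env_means, rep, n_points))
  nd[[variable]] <- xs
  data.frame(x = xs, suitability = predict(model, nd, type = type))
}

#' Plot maxent response curves
#'
#' @param x a \code{"maxent"} fit.
#' @param variables predictors to plot (default: all, up to 6 by
#'   contribution).
#' @param ... passed to [graphics::plot()].
#' @export
plot.maxent <- function(x, variables = NULL, ...) {
  if (is.null(variables)) {
    vc <- variable_contributions(x, permutation = FALSE)
    variables <- utils::head(
      vc$variable[order(vc$percent_contribution, decreasing = TRUE)], 6)
  }
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(variables)))
  on.exit(graphics::par(old))
  for (v in variables) {
    rc <- response_curve(x, v)
    graphics::plot(rc$x, rc$suitability, type = "l", xlab = v,
                   ylab = "suitability", ylim = c(0, 1), ...)
  }
  invisible(x)
}
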