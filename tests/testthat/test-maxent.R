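test_that("feature expansion has the documented shape", {
  withr::with_seed(30, {
    env <- data.frame(a = runif(50), b = rnorm(50), c = runif(50, 5, 9))
  })
  expect_equal(ncol(build_features(env, "L")$X), 3L)
  expect_equal(ncol(build_features(env, "LQ")$X), 6L)
  expect_equal(ncol(build_features(env, "LQP")$X), 9L)      # + 3 products
  fb <- build_features(env, "T", n_threshold_knots = 4)
  expect_equal(ncol(fb$X), 12L)
  # all features in [0, 1] over the reference rows
  for (cl in c("L", "LQHPT"))
    expect_true(all(build_features(env, cl)$X >= 0 &
                      build_features(env, cl)$X <= 1))
})

test_that("hinge features reproduce the closed-form pieces", {
  env <- data.frame(x = seq(0, 10, length.out = 21))
  fb <- build_features(env, "H", n_hinge_knots = 3)
  defs <- fb$defs
  fwd <- which(vapply(defs, function(d) d$type, "") == "Hf")[1]
  k <- defs[[fwd]]$knot
  expect_equal(fb$X[, fwd], pmax(0, (env$x - k) / (max(env$x) - k)))
  rev <- which(vapply(defs, function(d) d$type, "") == "Hr")[1]
  k2 <- defs[[rev]]$knot
  expect_equal(fb$X[, rev], pmax(0, (k2 - env$x) / (k2 - min(env$x))))
})

make_toy <- function(n_p = 120, n_bg = 1500, seed = 31) {
  withr::with_seed(seed, {
    bg <- data.frame(x1 = runif(n_bg, 0, 10), x2 = rnorm(n_bg))
    pr <- data.frame(x1 = 10 * rbeta(n_p, 5, 1.5), x2 = rnorm(n_p))
  })
  list(env = rbind(pr, bg),
       presence = c(rep(TRUE, n_p), rep(FALSE, n_bg)))
}

test_that("an extreme penalty shrinks every coefficient to zero", {
  d <- make_toy()
  m <- maxent(d$env, d$presence, rm = 1e6, classes = "LQ")
  expect_true(all(coef(m) == 0))
  expect_equal(sd(predict(m, d$env)), 0)   # uniform prediction
})

test_that("presences at the high end earn a positive linear coefficient", {
  d <- make_toy()
  m <- maxent(d$env, d$presence, rm = 1, classes = "L")
  expect_gt(coef(m)[["x1"]], 0)
  s <- predict(m, d$env)
  expect_true(all(s >= 0 & s <= 1))
})

test_that("null presences give held-out AUC near one half", {
  withr::with_seed(32, {
    env <- data.frame(x1 = runif(2500), x2 = rnorm(2500))
  })
  pres <- c(rep(TRUE, 300), rep(FALSE, 2200))  # presences == background dist
  train <- c(rep(TRUE, 200), rep(FALSE, 100), rep(TRUE, 2200))
  m <- maxent(env[train, ], pres[train], rm = 1, classes = "LQ")
  s <- predict(m, env)
  held_auc <- auc(s[!train], s[!pres])
  expect_lt(abs(held_auc - 0.5), 0.05)
})

test_that("coordinate descent agrees with an independent optimizer", {
  d <- make_toy(n_p = 100, n_bg = 800)
  m <- maxent(d$env, d$presence, rm = 0.05, classes = "L")
  # same objective, smooth |.| surrogate, generic BFGS
  fb <- build_features(d$env, "L", reference = which(!d$presence))
  Xp <- fb$X[d$presence, , drop = FALSE]
  Xb <- fb$X[!d$presence, , drop = FALSE]
  lam <- m$lambda
  f <- function(b) {
    eta_b <- Xb %*% b
    mx <- max(eta_b)
    -mean(Xp %*% b) + mx + log(mean(exp(eta_b - mx))) +
      sum(lam * sqrt(b^2 + 1e-14))
  }
  o <- optim(rep(0, ncol(fb$X)), f, method = "BFGS",
             control = list(maxit = 1000, reltol = 1e-12))
  expect_equal(unname(coef(m)), o$par, tolerance = 1e-3)
  expect_equal(m$gain, -o$value, tolerance = 1e-5)
})

test_that("predictions follow the cloglog transform of the Gibbs density", {
  d <- make_toy(n_p = 60, n_bg = 400)
  m <- maxent(d$env, d$presence, rm = 1, classes = "LQ")
  nd <- d$env[1:3, ]
  X <- ecoclim:::eval_features(nd, m$defs)
  eta <- as.numeric(X %*% coef(m))
  raw <- exp(eta - m$logZbar) / m$n_background
  expect_equal(predict(m, nd, type = "cloglog"),
               1 - exp(-exp(m$entropy) * raw))
  # exponential output averages one over the training background
  expect_equal(mean(predict(m, d$env[!d$presence, ], type = "exponential")),
               1, tolerance = 1e-9)
})

test_that("predictions are invariant to affine predictor rescaling", {
  d <- make_toy(n_p = 80, n_bg = 600)
  m1 <- maxent(d$env, d$presence, rm = 1, classes = "LQH", n_hinge_knots = 5,
               tol = 1e-12)
  env2 <- data.frame(x1 = 3.7 * d$env$x1 - 120, x2 = 0.01 * d$env$x2 + 5)
  m2 <- maxent(env2, d$presence, rm = 1, classes = "LQH", n_hinge_knots = 5,
               tol = 1e-12)
  expect_equal(predict(m1, d$env), predict(m2, env2), tolerance = 1e-6)
})

test_that("raising RM never adds nonzero coefficients", {
  d <- make_toy(n_p = 80, n_bg = 600, seed = 33)
  nz <- vapply(seq(0.5, 4, 0.5), function(rm)
    sum(coef(maxent(d$env, d$presence, rm = rm, classes = "LQ")) != 0),
    numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("response curves reflect the fitted feature shapes", {
  d <- make_toy()
  m <- maxent(d$env, d$presence, rm = 1, classes = "L")
  rc1 <- response_curve(m, "x1")
  expect_true(all(diff(rc1$suitability) >= -1e-12))   # positive linear
  if (coef(m)[["x2"]] == 0) {
    rc2 <- response_curve(m, "x2")
    expect_equal(diff(range(rc2$suitability)), 0)      # flat when zeroed
  }
  # unimodal under L + Q with a negative quadratic: vertex inside the range
  withr::with_seed(34, {
    bg <- data.frame(x = runif(2000, -3, 3))
    pr <- data.frame(x = rnorm(250, 0.5, 0.5))
  })
  mq <- maxent(rbind(pr, bg), c(rep(TRUE, 250), rep(FALSE, 2000)),
               rm = 1, classes = "LQ")
  rcq <- response_curve(mq, "x", n_points = 201)
  peak <- rcq$x[which.max(rcq$suitability)]
  expect_lt(abs(peak - 0.5), 0.5)
  ds <- diff(rcq$suitability)
  flip <- which(sign(ds[-1]) != sign(ds[-length(ds)]))
  expect_lte(length(unique(sign(ds[abs(ds) > 1e-12]))), 2)
  expect_gt(rcq$suitability[which.max(rcq$suitability)],
            rcq$suitability[1])
})
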