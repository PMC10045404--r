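test_that("AUC is the pairwise ordering probability with half ties", {
  expect_equal(auc(c(0.8, 0.9), c(0.1, 0.2)), 1)
  expect_equal(auc(c(0.5, 0.5), c(0.5, 0.5)), 0.5)
  expect_equal(auc(c(0.9, 0.8), c(0.7, 0.85)), 0.75)  # brute force: 3/4
  withr::with_seed(40, {
    for (i in 1:10) {
      pos <- round(runif(7), 2)   # rounded so ties occur
      neg <- round(runif(9), 2)
      expect_equal(auc(pos, neg), pairwise_auc(pos, neg))
      expect_equal(auc(pos, neg) + auc(neg, pos), 1)
    }
  })
})

test_that("AUC matches an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(41, {
    pos <- runif(40); neg <- runif(60, 0, 0.8)
  })
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 40), rep(0, 60)), predictor = c(pos, neg),
    quiet = TRUE, direction = "<")))
  expect_equal(auc(pos, neg), ref)
})

test_that("OR10 applies the ceiling rule on the training quantile", {
  expect_equal(or10(1:10 / 10, 1:10 / 10), 0.1)   # 1 of 10 omitted
  expect_equal(or10(1:10 / 10, rep(1, 5)), 0)     # all test above threshold
  expect_equal(or10(1:10 / 10, rep(0, 5)), 1)     # all below
  expect_equal(or10(1:15 / 15, 1:15 / 15), 2 / 15)  # ceiling(1.5) = 2
})

test_that("AICc follows the small-sample-corrected formula", {
  fake <- structure(list(beta = c(a = 1), n_presence = 5, lnL = 0),
                    class = "maxent")
  expect_equal(aicc(fake), 10 / 3)
  fake0 <- structure(list(beta = c(a = 0), n_presence = 5, lnL = -7),
                     class = "maxent")
  expect_equal(aicc(fake0), 14)                  # k = 0: plain -2 lnL
  fake_bad <- structure(list(beta = c(a = 1, b = 2, c = 3, d = 4),
                             n_presence = 5, lnL = 0), class = "maxent")
  expect_true(is.na(aicc(fake_bad)))             # n <= k + 1 undefined
})

test_that("spatial blocks form four balanced geographic groups", {
  pts <- data.frame(lon = c(-10, 10, -10, 10), lat = c(-5, -5, 5, 5))
  expect_setequal(spatial_block_folds(pts), 1:4)
  expect_error(spatial_block_folds(data.frame(lon = rep(1, 5),
                                              lat = rep(2, 5))),
               "degenerate")
  withr::with_seed(42, {
    for (i in 1:5) {
      n <- sample(c(40, 69, 100), 1)
      pts <- data.frame(lon = runif(n, -180, 180), lat = runif(n, -60, 60))
      f <- spatial_block_folds(pts)
      expect_true(all(abs(tabulate(f, 4) - n / 4) <= 1))
    }
  })
})

test_that("the tuning grid covers 48 combinations and selects min AICc", {
  w <- recovery_world(seed = 50, n_presence = 50, n_background = 600,
                      nlat = 25, nlon = 25)
  tn <- tune_maxent(w$env, w$presence, w$occ[c("lon", "lat")],
                    n_hinge_knots = 4, n_threshold_knots = 3)
  expect_equal(nrow(tn$results), 48L)
  expect_equal(nrow(unique(tn$results[c("rm", "fc")])), 48L)
  expect_true(all(tn$results$delta.AICc >= 0, na.rm = TRUE))
  expect_equal(tn$best$delta.AICc, 0)
  expect_equal(tn$best$AICc, min(tn$results$AICc, na.rm = TRUE))
  # single-combination grid degenerates gracefully
  tn1 <- tune_maxent(w$env, w$presence, w$occ[c("lon", "lat")],
                     rm_values = 1, fc_values = "L")
  expect_equal(nrow(tn1$results), 1L)
  expect_equal(tn1$fc, "L")
})

test_that("jackknife gains isolate informative variables", {
  w <- recovery_world(seed = 51, n_presence = 120, n_background = 1200,
                      nlat = 30, nlon = 30)
  env <- w$env
  withr::with_seed(52, env$noise <- runif(nrow(env)))
  jk <- jackknife_importance(env, w$presence, rm = 1, classes = "LQ")
  expect_true(all(jk$gain_with_only >= 0))
  expect_true(all(jk$gain_without >= 0))
  full <- attr(jk, "full_gain")
  expect_gte(full + 1e-9, max(jk$gain_with_only))  # nesting on training set
  expect_lt(jk$gain_with_only[jk$variable == "noise"], 0.05)
  expect_gt(jk$gain_with_only[jk$variable == "x1"], 0.2)
  # a duplicated informative variable is redundant: dropping it costs ~nothing
  env2 <- w$env
  env2$x1_copy <- env2$x1
  jk2 <- jackknife_importance(env2, w$presence, rm = 1, classes = "LQ")
  full2 <- attr(jk2, "full_gain")
  expect_lt(abs(jk2$gain_without[jk2$variable == "x1_copy"] - full2) /
              full2, 0.05)
})

test_that("contributions normalise to 100 and track the signal", {
  w <- recovery_world(seed = 53, n_presence = 150, n_background = 1500,
                      nlat = 30, nlon = 30)
  env <- w$env
  withr::with_seed(54, env$noise <- runif(nrow(env)))
  m <- maxent(env, w$presence, rm = 1, classes = "LQ")
  vc <- variable_contributions(m, seed = 9)
  expect_equal(sum(vc$percent_contribution), 100, tolerance = 0.1)
  expect_equal(sum(vc$permutation_importance), 100, tolerance = 0.1)
  expect_gt(vc$percent_contribution[vc$variable == "x1"],
            vc$percent_contribution[vc$variable == "noise"])
  # single informative variable takes everything
  m1 <- maxent(env["x1"], w$presence, rm = 1, classes = "LQ")
  vc1 <- variable_contributions(m1, seed = 9)
  expect_equal(vc1$percent_contribution, 100)
  expect_equal(vc1$permutation_importance, 100)
})

test_that("collinearity filter keeps the higher-contribution twin", {
  withr::with_seed(55, {
    env <- data.frame(a = rnorm(300), b = rnorm(300), c = rnorm(300))
  })
  env$a_dup <- env$a
  kept <- collinearity_filter(env, c(a = 30, b = 20, c = 10, a_dup = 5))
  expect_setequal(kept, c("a", "b", "c"))
  # independent noise columns all survive
  kept2 <- collinearity_filter(env[c("a", "b", "c")],
                               c(a = 1, b = 2, c = 3))
  expect_setequal(kept2, c("a", "b", "c"))
})

test_that("distance thinning enforces the minimum great-circle spacing", {
  two <- data.frame(lon = c(0, 0.009), lat = c(0, 0))   # ~1 km apart
  expect_equal(nrow(thin_occurrences(two, 10)), 1L)
  far <- data.frame(lon = c(0, 5, 10), lat = c(0, 5, 10))
  expect_equal(nrow(thin_occurrences(far, 10)), 3L)
  withr::with_seed(56, {
    for (i in 1:10) {
      pts <- data.frame(lon = runif(8, 0, 2), lat = runif(8, 0, 2))
      kept <- thin_occurrences(pts, 60, seed = i)
      d <- geosphere::distm(as.matrix(kept)) / 1000
      expect_true(all(d[upper.tri(d)] >= 60))
      # maximality: no dropped point can be added back
      dropped <- pts[!do.call(paste, pts) %in% do.call(paste, kept), ]
      if (nrow(dropped)) {
        dd <- geosphere::distm(as.matrix(dropped), as.matrix(kept)) / 1000
        expect_true(all(apply(dd, 1, min) < 60))
      }
    }
  })
})

test_that("topography derivation recovers analytic planes", {
  flat <- matrix(500, 6, 6)
  topo <- derive_topography(flat, seq(0, 5, 1), 1)
  expect_equal(topo$slope, matrix(0, 6, 6))
  expect_equal(topo$aspect, matrix(0, 6, 6))

  # plane rising due north at 1 m per 1000 m: slope atan(0.001), aspect south
  lats <- seq(0, 5, 1)
  rise_per_deg <- 111.32
  plane <- matrix(rep(lats * rise_per_deg, 6), 6, 6)
  topo <- derive_topography(plane, lats, 1)
  inner <- topo$slope[2:5, 2:5]
  expect_equal(inner, matrix(atan(0.001) * 180 / pi, 4, 4), tolerance = 0.01)
  expect_equal(topo$aspect[2:5, 2:5], matrix(180, 4, 4), tolerance = 0.01)

  expect_error(derive_topography(matrix(1, 1, 1), 0, 1), "too small")
})
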