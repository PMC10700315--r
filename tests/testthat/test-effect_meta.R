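test_that("Hedges' g reproduces the hand-derived example and its symmetries", {
  es <- hedges_g(c(2, 3, 4), c(1, 2, 3))
  expect_equal(es$d, 1)
  expect_equal(es$J, 0.8)
  expect_equal(es$g, 0.8)
  expect_equal(es$var_g, 0.8^2 * (6 / 9 + 1 / 8))

  # identical groups -> zero effect, variance from the d = 0 formula
  es0 <- hedges_g(c(5, 6, 7, 8), c(5, 6, 7, 8))
  expect_identical(es0$g, 0)
  expect_equal(es0$var_g, es0$J^2 * (8 / 16))

  # antisymmetry: swapping groups negates g, keeps var_g
  set.seed(8)
  a <- rnorm(10, 1); b <- rnorm(10)
  e1 <- hedges_g(a, b); e2 <- hedges_g(b, a)
  expect_equal(e1$g, -e2$g)
  expect_equal(e1$var_g, e2$var_g)

  # location invariance and scale invariance
  e3 <- hedges_g(a + 7, b + 7)
  expect_equal(e3$g, e1$g, tolerance = 1e-12)
  e4 <- hedges_g(3 * a, 3 * b)
  expect_equal(e4$g, e1$g, tolerance = 1e-12)

  expect_error(hedges_g(c(1, 1, 1), c(2, 2, 2)),
               class = "gm_degenerate_variance_error")
  expect_error(hedges_g(1, c(1, 2)), class = "gm_domain_error")
})

test_that("spatial correlation functions satisfy their closed forms", {
  for (k in c("exponential", "gaussian", "rational_quadratic", "spherical")) {
    expect_equal(spatial_correlation(0, 5, k), 1)
  }
  expect_equal(spatial_correlation(1, 1, "exponential"), exp(-1))
  expect_equal(spatial_correlation(2, 1, "gaussian"), exp(-4))
  expect_equal(spatial_correlation(3, 1, "rational_quadratic"), 0.1)
  expect_equal(spatial_correlation(c(1, 1.5, 7), 1, "spherical"),
               c(0, 0, 0))
  expect_equal(spatial_correlation(0.5, 1, "spherical"),
               1 - 1.5 * 0.5 + 0.5 * 0.125)
  expect_error(spatial_correlation(1, 0, "gaussian"),
               class = "gm_domain_error")
  expect_error(spatial_correlation(-1, 1, "gaussian"),
               class = "gm_domain_error")
})

test_that("great-circle distances follow the haversine closed forms", {
  expect_equal(great_circle_distance(12, 34, 12, 34), 0)
  expect_equal(great_circle_distance(0, 0, 0, 90), 2 * pi * 6371 / 4,
               tolerance = 1e-6)
  expect_equal(great_circle_distance(10, 20, -30, 50),
               great_circle_distance(-30, 50, 10, 20))
  expect_error(great_circle_distance(100, 0, 0, 0),
               class = "gm_domain_error")
  D <- distance_matrix_km(c(0, 0, 45), c(0, 90, 90))
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 3))
})

test_that("REML tau^2 matches a grid-search restricted-likelihood oracle", {
  set.seed(13)
  for (rep in 1:3) {
    y <- rnorm(5, 0.4, 0.9)
    v <- runif(5, 0.05, 0.3)
    fit <- random_effects_fit(data.frame(g = y, var_g = v), "none")
    expect_equal(fit$tau2, grid_tau2(y, v), tolerance = 1e-4)
  }
})

test_that("structure-none fits agree with an independent REML implementation", {
  skip_if_not_installed("metafor")
  set.seed(14)
  y <- rnorm(12, 0.3, 1.2); v <- runif(12, 0.1, 0.4)
  x <- rnorm(12)
  fit <- random_effects_fit(data.frame(g = y, var_g = v), "none")
  ref <- metafor::rma(yi = y, vi = v, method = "REML", test = "knha",
                      control = list(tol = 1e-10))
  expect_equal(fit$tau2, ref$tau2, tolerance = 1e-5)
  expect_equal(fit$coefficients$estimate[1], as.numeric(ref$beta),
               tolerance = 1e-6)
  expect_equal(fit$coefficients$se[1], ref$se, tolerance = 1e-5)
  expect_equal(fit$I2, ref$I2 / 100, tolerance = 1e-4)

  mr <- meta_regression(data.frame(g = y, var_g = v), data.frame(x = x))
  ref2 <- metafor::rma(yi = y, vi = v, mods = ~x, method = "REML",
                       test = "knha", control = list(tol = 1e-10))
  expect_equal(mr$coefficients$estimate, as.numeric(ref2$beta),
               tolerance = 1e-5)
  expect_equal(mr$coefficients$se, ref2$se, tolerance = 1e-4)
  expect_equal(mr$F, as.numeric(ref2$QM), tolerance = 1e-4)
})

test_that("equal sampling variances make the pooled mean the arithmetic mean", {
  set.seed(15)
  y <- rnorm(9, 1, 0.8)
  fit <- random_effects_fit(data.frame(g = y, var_g = rep(0.2, 9)), "none")
  expect_equal(fit$coefficients$estimate[1], mean(y), tolerance = 1e-10)
})

test_that("spatial structures reduce to the independent fit as rho -> 0", {
  set.seed(16)
  eff <- simulate_effects(10, mu = 0.4, tau2 = 0.8)
  y <- eff$g; v <- eff$var_g
  X <- matrix(1, 10, 1)
  Dist <- distance_matrix_km(eff$latitude, eff$longitude)
  ll_none <- grazemeta:::reml_loglik(0.5, NULL, y, X, v, NULL, "none")
  for (k in c("exponential", "gaussian", "rational_quadratic",
              "spherical")) {
    ll_k <- grazemeta:::reml_loglik(0.5, 1e-8, y, X, v, Dist, k)
    expect_equal(ll_k, ll_none, tolerance = 1e-8)
  }
})

test_that("heterogeneity statistics match direct summation", {
  # all effects equal -> Q = 0
  eq <- data.frame(g = rep(0.7, 6), var_g = runif(6, 0.1, 0.2))
  h <- heterogeneity(eq)
  expect_equal(h$Q, 0, tolerance = 1e-20)
  expect_identical(h$df, 5L)

  # 4-effect fixture: brute-force Q
  y <- c(0.2, -0.5, 1.1, 0.4); v <- c(0.1, 0.2, 0.15, 0.12)
  h4 <- heterogeneity(data.frame(g = y, var_g = v))
  w <- 1 / v
  mu <- sum(w * y) / sum(w)
  expect_equal(h4$Q, sum(w * (y - mu)^2), tolerance = 1e-12)
  expect_equal(h4$p, pchisq(h4$Q, 3, lower.tail = FALSE))

  # homogeneous simulation: Q ~ chi-square(n-1)
  set.seed(17)
  n <- 10
  qs <- replicate(400, {
    v <- runif(n, 0.1, 0.3)
    heterogeneity(data.frame(g = rnorm(n, 0.3, sqrt(v)), var_g = v))$Q
  })
  expect_equal(mean(qs), n - 1, tolerance = 0.08)
})

test_that("I2, pseudo-R2 and VIF respect their ranges", {
  set.seed(18)
  for (i in 1:5) {
    eff <- simulate_effects(15, mu = 0.2, tau2 = runif(1, 0, 2),
                            slope = runif(1, -0.5, 0.5))
    fit <- meta_regression(eff, data.frame(x = eff$x, z = rnorm(15)))
    expect_true(fit$I2 >= 0 && fit$I2 < 1)
    expect_true(fit$pseudo_R2 >= 0 && fit$pseudo_R2 <= 1)
    expect_true(all(fit$vif >= 1 - 1e-12))
  }
  # orthogonal moderators have VIF exactly 1
  x1 <- c(-1, -1, 1, 1, -1, -1, 1, 1)
  x2 <- c(-1, 1, -1, 1, -1, 1, -1, 1)
  eff <- data.frame(g = rnorm(8), var_g = runif(8, 0.1, 0.2))
  fit <- meta_regression(eff, data.frame(x1 = x1, x2 = x2))
  expect_equal(unname(fit$vif), c(1, 1), tolerance = 1e-12)
})

test_that("meta-regression degrees of freedom follow n - m - 1", {
  set.seed(19)
  eff <- simulate_effects(38, mu = 0, tau2 = 2.25, slope = 0.4)
  mods <- data.frame(a = eff$x, b = rnorm(38), c = rnorm(38))
  fit <- meta_regression(eff, mods)
  expect_identical(fit$coefficients$df, rep(34L, 4))
  expect_equal(fit$F_df, c(3L, 34L))
  # collinear moderators are rejected with advice
  mods$b <- 2 * mods$a + 1e-9 * rnorm(38)
  expect_error(meta_regression(eff, mods), class = "gm_collinear_error")
})

test_that("structure selection returns the AICc minimizer with bookkeeping", {
  set.seed(20)
  eff <- simulate_effects(12, mu = 0.3, tau2 = 1)
  single <- select_structure(eff, candidates = "none")
  expect_identical(single$best$structure, "none")
  expect_identical(nrow(single$table), 1L)
  sel <- select_structure(eff, candidates = c("none", "exponential"))
  expect_identical(nrow(sel$table), 2L)
  expect_identical(sum(sel$table$converged), length(sel$fits))
  expect_equal(sel$best$AICc, min(sel$table$AICc, na.rm = TRUE))
})

test_that("strong spatial signal favours the generating structure", {
  # effects generated with exponential correlation; over seeds the
  # exponential structure should win AICc more often than 1/5 chance
  gen_spatial <- function(seed) {
    set.seed(seed)
    n <- 40
    lat <- runif(n, -5, 5); lon <- runif(n, -5, 5)
    Dist <- distance_matrix_km(lat, lon)
    R <- spatial_correlation(Dist, 600, "exponential")
    u <- drop(t(chol(R + diag(1e-8, n))) %*% rnorm(n)) * sqrt(2)
    v <- runif(n, 0.02, 0.05)
    data.frame(g = 0.3 + u + rnorm(n, 0, sqrt(v)), var_g = v,
               latitude = lat, longitude = lon)
  }
  wins <- 0
  for (s in 1:6) {
    sel <- select_structure(gen_spatial(100 + s),
                            candidates = c("none", "exponential",
                                           "gaussian", "spherical"))
    if (sel$best$structure == "exponential") wins <- wins + 1
    # a spatial structure always beats the independent model here
    expect_false(sel$best$structure == "none")
  }
  # exponential (the generating kernel) wins more often than 1/4 chance
  expect_gt(wins, 1)
})

test_that("parameter recovery at scale: mu and tau2 from 200 effects", {
  set.seed(22)
  eff <- simulate_effects(200, mu = 0.5, tau2 = 1)
  fit <- random_effects_fit(eff, "none")
  expect_lt(abs(fit$coefficients$estimate[1] - 0.5),
            4 * fit$coefficients$se[1])
  expect_lt(abs(fit$tau2 - 1), 0.4)
})

test_that("paired Wilcoxon matches its exact and degenerate contracts", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_warning(res <- paired_wilcoxon(x, x), "zero")
  expect_equal(res$p, 1)

  set.seed(23)
  a <- rnorm(8); b <- rnorm(8)
  expect_equal(paired_wilcoxon(a, b)$p, paired_wilcoxon(b, a)$p)

  # n = 6: exact enumeration over all 2^6 sign assignments
  for (i in 1:5) {
    d <- round(rnorm(6, 0.3, 1), 3)
    while (any(d == 0) || anyDuplicated(abs(d))) d <- round(rnorm(6, 0.3, 1), 3)
    res <- paired_wilcoxon(d, rep(0, 6))
    expect_identical(res$method, "exact")
    expect_equal(res$p, signrank_enum_p(d), tolerance = 1e-12)
  }
  # large n switches to the normal approximation
  set.seed(24)
  big <- paired_wilcoxon(rnorm(30, 0.5), rnorm(30))
  expect_identical(big$method, "normal approximation")
  expect_error(paired_wilcoxon(1:3, 1:4), class = "gm_domain_error")
})

test_that("effect sizes carry the low-minus-high sign and coordinates", {
  study <- small_study(seed = 9)
  rem <- removal_by_site(study$bundle)
  eff <- effect_sizes(rem$removal, study$bundle$sites)
  expect_identical(nrow(eff), 8L)
  expect_true(all(eff$var_g > 0))
  expect_true(all(eff$n_low == 10 & eff$n_high == 10))
  # recompute one landscape by hand
  land <- eff$landscape_id[1]
  lo <- rem$removal$DRR[rem$removal$site_id == paste0(land, "_low")]
  hi <- rem$removal$DRR[rem$removal$site_id == paste0(land, "_high")]
  expect_equal(eff$g[1], hedges_g(lo, hi)$g, tolerance = 1e-12)
})
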