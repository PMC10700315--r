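# Per-landscape Hedges' g effect sizes and the random-effects machinery:
# REML estimation of the between-site variance tau^2 with optionally
# spatially correlated random effects, AICc model comparison across
# correlation structures, heterogeneity statistics (Q, I^2), and
# meta-regression with moderators tested by Knapp-Hartung-style t and F
# statistics on n - m - 1 degrees of freedom.
#
# Model:  g_i = x_i' beta + u_i + e_i,
#         u ~ N(0, tau^2 R(rho)),  e_i ~ N(0, var_g_i) independent,
# with R(rho) a spatial correlation function of great-circle distance
# (identity when structure = "none"). (tau^2, rho) maximize the restricted
# likelihood; beta is the GLS estimate at the optimum.

SPATIAL_STRUCTURES <- c("none", "exponential", "gaussian",
                        "rational_quadratic", "spherical")

#' Hedges' g for two groups of replicates
#'
#' Bias-corrected standardized mean difference
#' `g = J * (mean(low) - mean(high)) / s_pooled` with
#' `J = 1 - 3 / (4(n1 + n2 - 2) - 1)` and sampling variance
#' `var_g = J^2 * ((n1 + n2)/(n1 n2) + d^2 / (2(n1 + n2 - 2)))`.
#' Positive g means higher values in the `low` group.
#'
#' @param low,high Numeric replicate vectors (>= 2 finite values each).
#' @return List with `g`, `var_g`, `d`, `J`, `n_low`, `n_high`.
#' @export
#' @examples
#' hedges_g(c(2, 3, 4), c(1, 2, 3)) # d = 1, J = 0.8, g = 0.8
hedges_g <- function(low, high) {
  low <- low[is.finite(low)]; high <- high[is.finite(high)]
  n1 <- length(low); n2 <- length(high)
  if (n1 < 2L || n2 < 2L) {
    gm_error("hedges_g: need >= 2 finite replicates per group",
             "gm_domain_error")
  }
  sp <- sqrt(((n1 - 1) * stats::var(low) + (n2 - 1) * stats::var(high)) /
               (n1 + n2 - 2))
  num <- mean(low) - mean(high)
  if (sp == 0) {
    if (num != 0) {
      gm_error("hedges_g: zero pooled SD with unequal means",
               "gm_degenerate_variance_error")
    }
    d <- 0
  } else {
    d <- num / sp
  }
  J <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
  g <- J * d
  var_g <- J^2 * ((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2 - 2)))
  list(g = g, var_g = var_g, d = d, J = J, n_low = n1, n_high = n2)
}

#' Per-landscape effect sizes of grazing intensification on dung removal
#'
#' Computes Hedges' g (low minus high intensity) from the unit-level
#' removal rates of each landscape's two pastures; positive g means higher
#' removal under low-intensity management. Landscape coordinates are the
#' mean of the two pasture coordinates.
#'
#' @param removal Unit-level removal table from [removal_by_site()]
#'   (`$removal`).
#' @param sites Site table of the bundle.
#' @return Data frame: landscape_id, g, var_g, n_low, n_high, latitude,
#'   longitude.
#' @export
effect_sizes <- function(removal, sites) {
  rows <- list()
  for (land in unique(sites$landscape_id)) {
    pair <- sites[sites$landscape_id == land, , drop = FALSE]
    sid_low <- pair$site_id[pair$regime == "low"]
    sid_high <- pair$site_id[pair$regime == "high"]
    es <- hedges_g(removal$DRR[removal$site_id == sid_low],
                   removal$DRR[removal$site_id == sid_high])
    rows[[land]] <- data.frame(
      landscape_id = land, g = es$g, var_g = es$var_g,
      n_low = es$n_low, n_high = es$n_high,
      latitude = mean(pair$latitude), longitude = mean(pair$longitude),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Great-circle distance in km
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance in km. Vectorized.
#' @export
great_circle_distance <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180)) {
    gm_error("great_circle_distance: coordinates out of range",
             "gm_domain_error")
  }
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371)
}

#' Pairwise great-circle distance matrix (km)
#' @param latitude,longitude Coordinate vectors.
#' @return Symmetric matrix of distances in km.
#' @export
distance_matrix_km <- function(latitude, longitude) {
  n <- length(latitude)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    D[i, ] <- great_circle_distance(latitude[i], longitude[i],
                                    latitude, longitude)
  }
  (D + t(D)) / 2
}

#' Spatial correlation functions
#'
#' `exponential`: exp(-d/rho); `gaussian`: exp(-(d/rho)^2);
#' `rational_quadratic`: 1 / (1 + (d/rho)^2); `spherical`:
#' 1 - 1.5 (d/rho) + 0.5 (d/rho)^3 for d < rho, 0 beyond.
#'
#' @param d Distance(s), >= 0 (same units as `rho`).
#' @param rho Range parameter, > 0.
#' @param kind One of `"exponential"`, `"gaussian"`,
#'   `"rational_quadratic"`, `"spherical"`.
#' @return Correlation value(s) in `[0, 1]`.
#' @export
#' @examples
#' spatial_correlation(1, 1, "exponential") # exp(-1)
spatial_correlation <- function(d, rho,
                                kind = c("exponential", "gaussian",
                                         "rational_quadratic", "spherical")) {
  kind <- match.arg(kind)
  if (rho <= 0) gm_error("spatial_correlation: rho must be > 0",
                         "gm_domain_error")
  if (any(d < 0)) gm_error("spatial_correlation: d must be >= 0",
                           "gm_domain_error")
  h <- d / rho
  switch(kind,
         exponential = exp(-h),
         gaussian = exp(-h^2),
         rational_quadratic = 1 / (1 + h^2),
         spherical = ifelse(h < 1, 1 - 1.5 * h + 0.5 * h^3, 0))
}

# Restricted log-likelihood of (tau2, rho) given y, X, known sampling
# variances v, and the distance matrix (NULL for structure "none").
reml_loglik <- function(tau2, rho, y, X, v, Dist, structure) {
  n <- length(y); p <- ncol(X)
  if (structure == "none") {
    V <- diag(v + tau2, n)
  } else {
    V <- tau2 * spatial_correlation(Dist, rho, structure) + diag(v, n)
  }
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi <- chol2inv(ch)
  XtViX <- crossprod(X, Vi %*% X)
  chx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chx)) return(-Inf)
  beta <- chol2inv(chx) %*% crossprod(X, Vi %*% y)
  r <- y - X %*% beta
  quad <- drop(crossprod(r, Vi %*% r))
  -0.5 * ((n - p) * log(2 * pi) + logdetV + 2 * sum(log(diag(chx))) + quad)
}

# Profile the restricted likelihood over log(tau2) (structure "none") or
# (log tau2, log rho) jointly (spatial structures).
reml_optimize <- function(y, X, v, Dist, structure) {
  if (structure == "none") {
    f <- function(lt) reml_loglik(exp(lt), NULL, y, X, v, NULL, "none")
    grid <- seq(-20, 8, length.out = 41)
    vals <- vapply(grid, f, numeric(1))
    i <- which.max(vals)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-10)
    tau2 <- exp(opt$maximum)
    if (f(-20) >= opt$objective) tau2 <- exp(-20) # boundary: tau2 ~ 0
    list(tau2 = tau2, rho = NA_real_,
         logLik = f(log(tau2)), k = 2L)
  } else {
    f <- function(par) {
      ll <- reml_loglik(exp(par[1]), exp(par[2]), y, X, v, Dist, structure)
      if (!is.finite(ll)) -1e10 else ll
    }
    d_pos <- Dist[upper.tri(Dist)]
    d_pos <- d_pos[d_pos > 0]
    if (!length(d_pos)) {
      gm_error("spatial structure requires distinct coordinates",
               "gm_domain_error")
    }
    starts <- lapply(stats::quantile(d_pos, c(0.25, 0.5, 0.9)),
                     function(r0) c(log(stats::var(y) + 1e-8), log(r0)))
    best <- NULL
    for (s in starts) {
      o <- stats::optim(s, f, control = list(fnscale = -1, maxit = 500,
                                             reltol = 1e-12))
      if (is.null(best) || o$value > best$value) best <- o
    }
    if (!is.finite(best$value) || best$value <= -1e9) {
      gm_error("REML optimization failed to find a finite optimum",
               "gm_convergence_error")
    }
    list(tau2 = exp(best$par[1]), rho = exp(best$par[2]),
         logLik = best$value, k = 3L)
  }
}

# GLS coefficients and Knapp-Hartung-scaled covariance at (tau2, rho).
gls_at <- function(tau2, rho, y, X, v, Dist, structure) {
  n <- length(y); p <- ncol(X)
  if (structure == "none") {
    V <- diag(v + tau2, n)
  } else {
    V <- tau2 * spatial_correlation(Dist, rho, structure) + diag(v, n)
  }
  Vi <- chol2inv(chol(V))
  XtViX <- crossprod(X, Vi %*% X)
  cov_beta <- chol2inv(chol(XtViX))
  beta <- drop(cov_beta %*% crossprod(X, Vi %*% y))
  r <- y - X %*% beta
  s2 <- drop(crossprod(r, Vi %*% r)) / (n - p)
  list(beta = beta, cov = s2 * cov_beta, cov_unscaled = cov_beta, s2 = s2)
}

typical_within_variance <- function(v) {
  w <- 1 / v
  (length(v) - 1) * sum(w) / (sum(w)^2 - sum(w^2))
}

#' Random-effects meta-analysis with optional spatial correlation
#'
#' Fits the pooled mean (or a meta-regression when `moderators` is given)
#' under the model described in the package vignette: between-site effects
#' with variance `tau^2`, correlated across sites through a spatial
#' correlation function of great-circle distance, plus known sampling
#' variances. `tau^2` (and the range `rho`) are estimated by REML;
#' coefficients are GLS at the optimum, tested with Knapp-Hartung-scaled t
#' statistics on `n - m - 1` degrees of freedom.
#'
#' @param effects Data frame with columns `g`, `var_g` and (for spatial
#'   structures) `latitude`, `longitude`.
#' @param structure Correlation structure: `"none"`, `"exponential"`,
#'   `"gaussian"`, `"rational_quadratic"` or `"spherical"`.
#' @param moderators Optional data frame / matrix of moderator columns
#'   (one row per effect).
#' @return Object of class `gm_metafit`: coefficient table (`coefficients`),
#'   `tau2`, `rho`, `Q`, `Q_df`, `Q_p`, `I2`, `logLik`, `AICc`, `structure`,
#'   and for meta-regressions `F`, `F_df`, `F_p`, `pseudo_R2`, `vif`.
#' @export
random_effects_fit <- function(effects, structure = "none",
                               moderators = NULL) {
  structure <- match.arg(structure, SPATIAL_STRUCTURES)
  y <- effects$g; v <- effects$var_g
  n <- length(y)
  if (n < 3L) gm_error("random_effects_fit: need >= 3 effects",
                       "gm_domain_error")
  if (any(v <= 0)) gm_error("random_effects_fit: var_g must be > 0",
                            "gm_domain_error")
  if (is.null(moderators)) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  } else {
    M <- as.matrix(moderators)
    if (nrow(M) != n || anyNA(M)) {
      gm_error("random_effects_fit: moderators must be complete, one row per effect",
               "gm_domain_error")
    }
    if (n <= ncol(M) + 2L) {
      gm_error("random_effects_fit: need n > m + 2", "gm_domain_error")
    }
    kappa_M <- kappa(stats::cor(M), exact = TRUE)
    if (ncol(M) > 1L && kappa_M > 1e6) {
      gm_error("random_effects_fit: moderators are collinear; summarize them (e.g. by PCA) first",
               "gm_collinear_error")
    }
    X <- cbind(intercept = 1, M)
  }
  Dist <- NULL
  if (structure != "none") {
    if (is.null(effects$latitude) || is.null(effects$longitude)) {
      gm_error("spatial structures need latitude/longitude columns",
               "gm_domain_error")
    }
    Dist <- distance_matrix_km(effects$latitude, effects$longitude)
  }
  opt <- reml_optimize(y, X, v, Dist, structure)
  gls <- gls_at(opt$tau2, opt$rho, y, X, v, Dist, structure)

  m <- ncol(X) - 1L
  df <- n - m - 1L
  se <- sqrt(diag(gls$cov))
  tstat <- gls$beta / se
  pvals <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  coef_tab <- data.frame(term = colnames(X), estimate = gls$beta, se = se,
                         t = tstat, df = df, p = pvals,
                         row.names = NULL, stringsAsFactors = FALSE)

  # heterogeneity on the fixed-effect intercept-only weights
  w <- 1 / v
  mu_fe <- sum(w * y) / sum(w)
  Q <- sum(w * (y - mu_fe)^2)
  Q_df <- n - 1L
  s2_typ <- typical_within_variance(v)
  I2 <- opt$tau2 / (opt$tau2 + s2_typ)

  k <- opt$k
  AICc <- -2 * opt$logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)

  fit <- list(coefficients = coef_tab, tau2 = opt$tau2, rho = opt$rho,
              structure = structure, n = n, m = m,
              Q = Q, Q_df = Q_df,
              Q_p = stats::pchisq(Q, Q_df, lower.tail = FALSE),
              I2 = I2, logLik = opt$logLik, k = k, AICc = AICc,
              s2_knha = gls$s2)
  if (m > 0L) {
    idx <- seq_len(m) + 1L
    bm <- gls$beta[idx]
    covm <- gls$cov[idx, idx, drop = FALSE]
    Fstat <- drop(crossprod(bm, solve(covm, bm))) / m
    fit$F <- Fstat
    fit$F_df <- c(m, df)
    fit$F_p <- stats::pf(Fstat, m, df, lower.tail = FALSE)
    null_fit <- reml_optimize(y, matrix(1, n, 1), v, Dist, structure)
    fit$tau2_null <- null_fit$tau2
    fit$pseudo_R2 <- if (null_fit$tau2 > 0)
      max(0, (null_fit$tau2 - opt$tau2) / null_fit$tau2) else 0
    fit$vif <- if (m == 1L) stats::setNames(1, colnames(X)[2]) else
      stats::setNames(diag(solve(stats::cor(X[, -1, drop = FALSE]))),
                      colnames(X)[-1])
  }
  structure(fit, class = "gm_metafit")
}

#' @export
print.gm_metafit <- function(x, ...) {
  cat(sprintf("Random-effects model (REML), structure = %s%s\n",
              x$structure,
              if (!is.na(x$rho)) sprintf(", rho = %.1f km", x$rho) else ""))
  cat(sprintf("tau^2 = %.4f   Q = %.2f (df = %d, p = %.3g)   I^2 = %.3f\n",
              x$tau2, x$Q, x$Q_df, x$Q_p, x$I2))
  cat(sprintf("logLik(REML) = %.3f   AICc = %.2f\n", x$logLik, x$AICc))
  tab <- x$coefficients
  tab[, -1] <- lapply(tab[, -1], function(z) round(z, 4))
  print(tab, row.names = FALSE)
  if (!is.null(x$F)) {
    cat(sprintf("Omnibus F(%d, %d) = %.3f, p = %.4f   pseudo-R^2 = %.3f\n",
                x$F_df[1], x$F_df[2], x$F, x$F_p, x$pseudo_R2))
  }
  invisible(x)
}

#' Heterogeneity statistics
#'
#' Cochran's Q against the fixed-effect weighted mean, with its chi-square
#' p-value, plus REML `tau^2` and `I^2` from the intercept-only
#' structure-free fit.
#'
#' @param effects Data frame with `g` and `var_g`.
#' @return List: `Q`, `df`, `p`, `tau2`, `I2`.
#' @export
heterogeneity <- function(effects) {
  if (nrow(effects) < 2L) gm_error("heterogeneity: need >= 2 effects",
                                   "gm_domain_error")
  if (nrow(effects) >= 3L) {
    fit <- random_effects_fit(effects, "none")
    tau2 <- fit$tau2; I2 <- fit$I2; Q <- fit$Q; df <- fit$Q_df; p <- fit$Q_p
  } else {
    w <- 1 / effects$var_g
    mu <- sum(w * effects$g) / sum(w)
    Q <- sum(w * (effects$g - mu)^2)
    df <- nrow(effects) - 1L
    p <- stats::pchisq(Q, df, lower.tail = FALSE)
    tau2 <- NA_real_; I2 <- NA_real_
  }
  list(Q = Q, df = df, p = p, tau2 = tau2, I2 = I2)
}

#' Fit all candidate correlation structures and select by AICc
#'
#' @param effects Effect-size data frame.
#' @param candidates Structures to try.
#' @param moderators Optional moderator matrix (passed through).
#' @return List: `best` (the minimum-AICc `gm_metafit`), `table`
#'   (structure, tau2, rho, logLik, AICc, converged), `fits` (all
#'   successful fits).
#' @export
select_structure <- function(effects, candidates = SPATIAL_STRUCTURES,
                             moderators = NULL) {
  fits <- list(); rows <- list()
  for (st in candidates) {
    f <- tryCatch(random_effects_fit(effects, st, moderators),
                  error = function(e) e)
    if (inherits(f, "error")) {
      rows[[st]] <- data.frame(structure = st, tau2 = NA, rho = NA,
                               logLik = NA, AICc = NA, converged = FALSE)
    } else {
      fits[[st]] <- f
      rows[[st]] <- data.frame(structure = st, tau2 = f$tau2, rho = f$rho,
                               logLik = f$logLik, AICc = f$AICc,
                               converged = TRUE)
    }
  }
  if (!length(fits)) {
    gm_error("select_structure: every candidate structure failed",
             "gm_convergence_error")
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "AICc"))]]
  list(best = best, table = tab, fits = fits)
}

#' Random-effects meta-regression
#'
#' Convenience wrapper around [random_effects_fit()] with moderators;
#' returns the fit with its coefficient table, omnibus F on `(m, n-m-1)`
#' degrees of freedom, pseudo-R^2 (proportional reduction of `tau^2`
#' relative to the intercept-only model under the same structure, floored
#' at 0) and variance inflation factors from the moderator correlation
#' matrix.
#'
#' @inheritParams random_effects_fit
#' @export
meta_regression <- function(effects, moderators, structure = "none") {
  random_effects_fit(effects, structure, moderators = moderators)
}

#' Paired two-tailed Wilcoxon signed-rank test
#'
#' Zero differences are dropped; the null distribution is exact for
#' n <= 25 untied differences and a normal approximation with continuity
#' correction otherwise.
#'
#' @param values_low,values_high Paired vectors (same length).
#' @return List: `statistic` (V), `p`, `n` (non-zero pairs), `method`.
#' @export
paired_wilcoxon <- function(values_low, values_high) {
  if (length(values_low) != length(values_high)) {
    gm_error("paired_wilcoxon: inputs must be paired (equal length)",
             "gm_domain_error")
  }
  d <- values_low - values_high
  d <- d[d != 0]
  if (!length(d)) {
    warning("paired_wilcoxon: all differences are zero; p = 1",
            call. = FALSE)
    return(list(statistic = NA_real_, p = 1, n = 0L, method = "degenerate"))
  }
  exact <- length(d) <= 25L && !anyDuplicated(abs(d))
  wt <- suppressWarnings(
    stats::wilcox.test(d, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p = wt$p.value, n = length(d),
       method = if (exact) "exact" else "normal approximation")
}
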