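# Synthetic study generator: complete, validated dataset bundles emulating
# the 38-landscape paired design (low/high grazing intensity, 10
# experimental + 5 control dung pats per pasture, regional species pools
# with guild and size structure, per-individual trait measurements,
# management covariates, 13 bioclim columns, clustered coordinates) with a
# recorded ground truth, so every pipeline stage has a recovery test.
#
# Effect model: each landscape's true standardized removal difference is
#   theta_i = gamma0 + gamma1 * x_i + u_i,   u_i ~ N(0, tau^2),
# where x_i is the z-scored low-minus-high difference in FDisBehavior of
# the generated communities. Pat weights are back-computed from the dry
# scale through a site-level water proportion so that the removal
# equations invert cleanly.

#' Configuration for the synthetic study generator
#'
#' Defaults define the emulated study conditions: 38 landscapes in 6
#' regions, 10 + 5 pats per pasture, a true moderator slope of 0.4,
#' between-site SD tau = 1.5 (tau^2 = 2.25) and a within-site replicate SD
#' giving sampling variances around 0.25, hence I^2 near 0.9.
#'
#' @param seed Master seed; every stream derives from it.
#' @param n_landscapes Number of paired landscapes.
#' @param n_regions Number of biogeographical regions.
#' @param pool_size Species-pool size per region.
#' @param richness_low Expected species richness of a low-intensity
#'   community.
#' @param thinning Per-species retention probability under high intensity
#'   (binomial thinning of the low community).
#' @param immigration Expected number of high-intensity-only species.
#' @param guild_probs Sampling probabilities of the four guilds
#'   (paracoprid, telecoprid, endocoprid, kleptocoprid); must sum to 1.
#' @param size_meanlog,size_sdlog Log-normal parameters of species mean
#'   body length (mm).
#' @param n_exp,n_ctl Experimental and control pats per pasture.
#' @param IWwet Initial wet weight of every pat (g).
#' @param wp_range Range of the site-level water proportion.
#' @param wp_noise SD of per-pat water-proportion jitter (forced to 0 when
#'   `replicate_sd` is 0 so the no-noise limit is exact).
#' @param baseline_range Range of the true high-intensity mean removal
#'   (g dry / 48 h).
#' @param gamma0 True intercept of the effect-size model.
#' @param gamma1 True moderator slope on the standardized FDisBehavior
#'   difference.
#' @param tau Between-landscape SD of true effects.
#' @param replicate_sd Within-pasture SD of per-pat removal (g dry).
#' @return Validated list of class `gm_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_landscapes = 38L,
                             n_regions = 6L,
                             pool_size = 40L,
                             richness_low = 12,
                             thinning = 0.75,
                             immigration = 0.5,
                             guild_probs = c(paracoprid = 0.40,
                                             telecoprid = 0.25,
                                             endocoprid = 0.25,
                                             kleptocoprid = 0.10),
                             size_meanlog = log(12), size_sdlog = 0.45,
                             n_exp = 10L, n_ctl = 5L,
                             IWwet = 300,
                             wp_range = c(0.70, 0.85),
                             wp_noise = 0.005,
                             baseline_range = c(15, 40),
                             gamma0 = 0, gamma1 = 0.4, tau = 1.5,
                             replicate_sd = 6) {
  cfg <- as.list(environment())
  if (abs(sum(guild_probs) - 1) > 1e-8) {
    gm_error("guild_probs must sum to 1", "gm_config_error")
  }
  if (tau < 0 || replicate_sd < 0 || wp_noise < 0) {
    gm_error("SDs must be >= 0", "gm_config_error")
  }
  min_capacity <- IWwet * (1 - max(wp_range))
  if (max(baseline_range) >= min_capacity) {
    gm_error("infeasible config: baseline removal can exceed initial dry mass",
             "gm_config_error")
  }
  if (replicate_sd == 0) cfg$wp_noise <- 0
  structure(cfg, class = "gm_config")
}

# independent stream per table so adding one table never perturbs others
with_stream <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((as.integer(seed) + offset) %% .Machine$integer.max)
  expr
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Generate a complete synthetic study
#'
#' @param config A [synthetic_config()].
#' @return List of class `gm_study`: `bundle` (validated dataset bundle)
#'   and `truth` (gamma0, gamma1, tau, and a per-landscape table with the
#'   moderator x, true effect theta, true removal means and water
#'   proportions).
#' @export
generate_study <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "gm_config"))
  cfg <- config
  nl <- cfg$n_landscapes
  lands <- sprintf("L%02d", seq_len(nl))
  region <- sprintf("R%d", rep_len(seq_len(cfg$n_regions), nl))

  ## --- sites & coordinates (regionally clustered, pair within ~15 km)
  sites <- with_stream(cfg$seed, 11L, {
    c_lat <- stats::runif(cfg$n_regions, -40, 52)
    c_lon <- stats::runif(cfg$n_regions, -120, 140)
    lat <- rtrunc_norm(nl, c_lat[as.integer(sub("R", "", region))], 3,
                       -55, 62)
    lon <- c_lon[as.integer(sub("R", "", region))] + stats::rnorm(nl, 0, 3)
    off <- stats::runif(nl, 0.02, 0.1) # ~2-11 km pair separation
    data.frame(
      site_id = c(paste0(lands, "_low"), paste0(lands, "_high")),
      landscape_id = c(lands, lands),
      region = c(region, region),
      regime = rep(c("low", "high"), each = nl),
      latitude = round(c(lat, lat + off), 5),
      longitude = round(c(lon, lon), 5),
      stringsAsFactors = FALSE
    )
  })

  ## --- covariates: management + 13 bioclim columns (landscape climate)
  covariates <- with_stream(cfg$seed, 23L, {
    lat <- sites$latitude[seq_len(nl)]
    t_ann <- 27 - 0.5 * abs(lat) + stats::rnorm(nl, 0, 1.5)
    seas <- 0.8 * abs(lat) + stats::rnorm(nl, 0, 3)
    clim <- cbind(
      bio1 = t_ann,
      bio2 = 8 + 0.2 * seas + stats::rnorm(nl, 0, 1),
      bio3 = 60 - 0.6 * seas + stats::rnorm(nl, 0, 4),
      bio4 = 100 * (seas / 10) + stats::rnorm(nl, 0, 20),
      bio5 = t_ann + 8 + 0.3 * seas + stats::rnorm(nl, 0, 1),
      bio6 = t_ann - 8 - 0.4 * seas + stats::rnorm(nl, 0, 1),
      bio7 = 16 + 0.7 * seas + stats::rnorm(nl, 0, 2),
      bio8 = t_ann + stats::rnorm(nl, 0, 2),
      bio9 = t_ann + stats::rnorm(nl, 0, 2.5),
      bio10 = t_ann + 5 + stats::rnorm(nl, 0, 1.2),
      bio11 = t_ann - 5 - 0.2 * seas + stats::rnorm(nl, 0, 1.2),
      bio12 = exp(6 + 0.03 * t_ann + stats::rnorm(nl, 0, 0.4)),
      bio13 = exp(4.4 + 0.03 * t_ann + stats::rnorm(nl, 0, 0.45))
    )
    clim <- round(clim[rep(seq_len(nl), 2L), ], 3)
    data.frame(
      site_id = sites$site_id,
      cattle_density = round(c(stats::runif(nl, 0.4, 1.9),
                               stats::runif(nl, 4.1, 9)), 2),
      anthelmintic_use = c(sample(0:1, nl, TRUE, prob = c(0.7, 0.3)),
                           sample(2:4, nl, TRUE)),
      land_history = rep(round(stats::runif(nl, 5, 120)), 2L),
      clim,
      stringsAsFactors = FALSE
    )
  })

  ## --- regional species pools with guilds, sizes and trait means
  pools <- with_stream(cfg$seed, 37L, {
    lapply(seq_len(cfg$n_regions), function(r) {
      ns <- cfg$pool_size
      size <- stats::rlnorm(ns, cfg$size_meanlog, cfg$size_sdlog)
      data.frame(
        species_id = sprintf("R%d_sp%02d", r, seq_len(ns)),
        guild = sample(GUILDS, ns, TRUE, prob = cfg$guild_probs),
        body_length = size,
        stringsAsFactors = FALSE
      )
    })
  })

  ## --- communities: low community sampled from the pool, high obtained
  ##     by binomial thinning plus a few disturbance-tolerant immigrants
  occ_truth <- with_stream(cfg$seed, 53L, {
    rows <- list()
    for (i in seq_len(nl)) {
      pool <- pools[[as.integer(sub("R", "", region[i]))]]
      r_low <- min(max(2L, stats::rpois(1, cfg$richness_low)), nrow(pool))
      low_sp <- sample(pool$species_id, r_low)
      keep <- low_sp[stats::runif(r_low) < cfg$thinning]
      extra <- setdiff(pool$species_id, low_sp)
      n_imm <- min(stats::rpois(1, cfg$immigration), length(extra))
      high_sp <- c(keep, if (n_imm > 0) sample(extra, n_imm))
      if (length(high_sp) < 2L) {
        high_sp <- c(high_sp, setdiff(low_sp, high_sp)[
          seq_len(2L - length(high_sp))])
      }
      ab <- function(sp) pmax(1L, stats::rnbinom(length(sp), mu = 12,
                                                 size = 1.2))
      rows[[i]] <- rbind(
        data.frame(site_id = paste0(lands[i], "_low"), species_id = low_sp,
                   abundance = ab(low_sp),
                   guild = pool$guild[match(low_sp, pool$species_id)],
                   stringsAsFactors = FALSE),
        data.frame(site_id = paste0(lands[i], "_high"),
                   species_id = high_sp, abundance = ab(high_sp),
                   guild = pool$guild[match(high_sp, pool$species_id)],
                   stringsAsFactors = FALSE)
      )
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })

  ## --- per-individual trait measurements (<= 10 individuals per species)
  traits <- with_stream(cfg$seed, 71L, {
    sp_all <- unique(occ_truth$species_id)
    pool_tab <- do.call(rbind, pools)
    L <- pool_tab$body_length[match(sp_all, pool_tab$species_id)]
    rows <- lapply(seq_along(sp_all), function(k) {
      n_ind <- sample(3:10, 1)
      noise <- function() stats::rlnorm(n_ind, 0, 0.05)
      hl <- 0.20 * L[k] * noise()
      pl <- 0.30 * L[k] * noise()
      el <- 0.50 * L[k] * noise()
      data.frame(
        species_id = sp_all[k],
        individual_id = sprintf("%s_i%02d", sp_all[k], seq_len(n_ind)),
        head_length = hl,
        head_width = 0.25 * L[k] * noise(),
        pronotum_length = pl,
        pronotum_width = 0.45 * L[k] * noise(),
        pronotum_height = 0.30 * L[k] * noise(),
        elytra_length = el,
        protibia_length = 0.22 * L[k] * noise(),
        protibia_width = 0.05 * L[k] * noise(),
        metatibia_length = 0.28 * L[k] * noise(),
        biomass = 0.025 * (L[k] / 10)^3 * stats::rlnorm(n_ind, 0, 0.1),
        stringsAsFactors = FALSE
      )
    })
    tr <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    tr[, 3:12] <- round(tr[, 3:12], 4)
    tr
  })

  ## --- moderator: z-scored low-minus-high FDisBehavior difference of the
  ##     generated communities (computed with the package's own metrics)
  pre_bundle <- list(sites = sites, covariates = covariates,
                     dungpats = empty_dungpats(sites, cfg),
                     occurrences = occ_truth, traits = traits)
  metrics <- community_metrics(suppressWarnings(
    validate_bundle(pre_bundle)))
  diffs <- diversity_differences(metrics)
  dfb <- diffs$d_FDisBehavior[match(lands, diffs$landscape_id)]
  x <- if (stats::sd(dfb) > 0) (dfb - mean(dfb)) / stats::sd(dfb) else dfb * 0

  ## --- true effects and dung pats, back-computed on the dry scale
  pats_truth <- with_stream(cfg$seed, 97L, {
    u <- stats::rnorm(nl, 0, cfg$tau)
    theta <- cfg$gamma0 + cfg$gamma1 * x + u
    baseline <- stats::runif(nl, cfg$baseline_range[1], cfg$baseline_range[2])
    sd_ref <- if (cfg$replicate_sd > 0) cfg$replicate_sd else 1
    mean_high <- baseline
    mean_low <- baseline + theta * sd_ref
    # the paired pastures sit a few km apart under the same weather, so
    # they share one landscape-level water proportion
    wp_land <- stats::runif(nl, cfg$wp_range[1], cfg$wp_range[2])
    rows <- list()
    for (i in seq_len(nl)) {
      for (rg in REGIMES) {
        sid <- paste0(lands[i], "_", rg)
        wp <- wp_land[i]
        mu_r <- if (rg == "low") mean_low[i] else mean_high[i]
        iwdry <- cfg$IWwet * (1 - wp)
        removal <- rtrunc_norm(cfg$n_exp, mu_r, cfg$replicate_sd,
                               0, iwdry - 0.5)
        fwdry_exp <- iwdry - removal
        wpu <- rep(wp, cfg$n_exp)
        wpc <- rep(wp, cfg$n_ctl)
        if (cfg$wp_noise > 0) {
          wpu <- wpu + stats::rnorm(cfg$n_exp, 0, cfg$wp_noise)
          wpc <- wpc + stats::rnorm(cfg$n_ctl, 0, cfg$wp_noise)
        }
        rows[[sid]] <- data.frame(
          site_id = sid,
          unit_id = c(sprintf("%s_e%02d", sid, seq_len(cfg$n_exp)),
                      sprintf("%s_c%02d", sid, seq_len(cfg$n_ctl))),
          role = c(rep("experimental", cfg$n_exp),
                   rep("control", cfg$n_ctl)),
          IWwet = cfg$IWwet,
          FWwet = round(c(fwdry_exp / (1 - wpu), iwdry / (1 - wpc)), 3),
          FWdry = round(c(fwdry_exp, rep(iwdry, cfg$n_ctl)), 3),
          exposure = 48,
          stringsAsFactors = FALSE
        )
      }
    }
    list(dungpats = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         site_truth = data.frame(landscape_id = lands, x = x,
                                 theta = theta, mean_low = mean_low,
                                 mean_high = mean_high, wp = wp_land,
                                 stringsAsFactors = FALSE))
  })

  bundle <- suppressWarnings(validate_bundle(list(
    sites = sites, covariates = covariates,
    dungpats = pats_truth$dungpats,
    occurrences = occ_truth, traits = traits
  )))
  structure(list(
    bundle = bundle,
    truth = list(gamma0 = cfg$gamma0, gamma1 = cfg$gamma1, tau = cfg$tau,
                 replicate_sd = cfg$replicate_sd, seed = cfg$seed,
                 site_truth = pats_truth$site_truth),
    config = cfg
  ), class = "gm_study")
}

# placeholder pat table so the pre-bundle validates before pats exist
empty_dungpats <- function(sites, cfg) {
  do.call(rbind, lapply(sites$site_id, function(sid) data.frame(
    site_id = sid,
    unit_id = c(sprintf("%s_e%02d", sid, seq_len(cfg$n_exp)),
                sprintf("%s_c%02d", sid, seq_len(cfg$n_ctl))),
    role = c(rep("experimental", cfg$n_exp), rep("control", cfg$n_ctl)),
    IWwet = cfg$IWwet, FWwet = 100, FWdry = 25, exposure = 48,
    stringsAsFactors = FALSE)))
}

#' Write a synthetic study to disk
#'
#' Emits the five CSV tables plus `ground_truth.json`.
#'
#' @param study A `gm_study` from [generate_study()].
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_study <- function(study, dir) {
  write_tables(study$bundle, dir)
  jsonlite::write_json(study$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Simulate effect sizes directly at the meta-analytic layer
#'
#' Draws `g_i = mu + slope * x_i + u_i + e_i` with `u ~ N(0, tau2)`,
#' moderator `x ~ N(0, 1)`, and sampling variances from the Hedges' g
#' variance formula at the drawn effect. A fast harness for calibration
#' studies of the meta-regression layer alone.
#'
#' @param n Number of effects.
#' @param mu True intercept.
#' @param tau2 True between-site variance.
#' @param slope True moderator slope.
#' @param n_rep Replicates per group entering the variance formula.
#' @return Data frame: g, var_g, x, latitude, longitude.
#' @export
simulate_effects <- function(n = 38, mu = 0, tau2 = 2.25, slope = 0,
                             n_rep = 10) {
  x <- stats::rnorm(n)
  theta <- mu + slope * x + stats::rnorm(n, 0, sqrt(tau2))
  v0 <- 2 / n_rep + theta^2 / (2 * (2 * n_rep - 2))
  g <- theta + stats::rnorm(n, 0, sqrt(v0))
  data.frame(g = g,
             var_g = 2 / n_rep + g^2 / (2 * (2 * n_rep - 2)),
             x = x,
             latitude = stats::runif(n, -50, 60),
             longitude = stats::runif(n, -130, 150))
}

#' Recovery experiment over repeated synthetic studies
#'
#' For each replicate: generate a study, compute removal rates and
#' per-landscape Hedges' g, and fit the meta-regression of g on the
#' generator's standardized FDisBehavior-difference moderator. Reports
#' bias, RMSE and 95% CI coverage for the intercept (gamma0), slope
#' (gamma1) and residual between-site variance (tau^2).
#'
#' @param config Base [synthetic_config()]; each replicate shifts the seed.
#' @param n_reps Number of replicates.
#' @param mode Water-proportion mode passed to [removal_by_site()].
#' @return List with `summary` (per-parameter bias/RMSE/coverage) and
#'   `estimates` (per-replicate table); failed replicates are recorded in
#'   `failures`.
#' @export
recovery_experiment <- function(config = synthetic_config(), n_reps = 100,
                                mode = "control") {
  est <- list(); failures <- list()
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- (config$seed + 7919L * r) %% .Machine$integer.max
    res <- tryCatch({
      study <- generate_study(cfg)
      rem <- removal_by_site(study$bundle, mode = mode)
      eff <- effect_sizes(rem$removal, study$bundle$sites)
      x <- study$truth$site_truth$x[
        match(eff$landscape_id, study$truth$site_truth$landscape_id)]
      fit <- meta_regression(eff, data.frame(x = x), structure = "none")
      co <- fit$coefficients
      tq <- stats::qt(0.975, co$df[1])
      data.frame(
        rep = r,
        gamma0_hat = co$estimate[1], gamma1_hat = co$estimate[2],
        tau2_hat = fit$tau2,
        cover0 = abs(co$estimate[1] - cfg$gamma0) <= tq * co$se[1],
        cover1 = abs(co$estimate[2] - cfg$gamma1) <= tq * co$se[2],
        p_slope = co$p[2]
      )
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- list(rep = r,
                                                message = conditionMessage(res))
    } else {
      est[[length(est) + 1L]] <- res
    }
  }
  if (!length(est)) gm_error("recovery_experiment: all replicates failed",
                             "gm_convergence_error")
  est <- do.call(rbind, est)
  tau2_true <- config$tau^2
  summ <- data.frame(
    parameter = c("gamma0", "gamma1", "tau2"),
    truth = c(config$gamma0, config$gamma1, tau2_true),
    mean_estimate = c(mean(est$gamma0_hat), mean(est$gamma1_hat),
                      mean(est$tau2_hat)),
    bias = c(mean(est$gamma0_hat) - config$gamma0,
             mean(est$gamma1_hat) - config$gamma1,
             mean(est$tau2_hat) - tau2_true),
    rmse = c(sqrt(mean((est$gamma0_hat - config$gamma0)^2)),
             sqrt(mean((est$gamma1_hat - config$gamma1)^2)),
             sqrt(mean((est$tau2_hat - tau2_true)^2))),
    coverage95 = c(mean(est$cover0), mean(est$cover1), NA),
    stringsAsFactors = FALSE
  )
  list(summary = summ, estimates = est, failures = failures)
}
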