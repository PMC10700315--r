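# End-to-end orchestration: bundle -> removal rates -> community metrics ->
# paired differences and PCA summaries -> effect sizes, structure selection,
# meta-regression, Wilcoxon comparisons -> piecewise SEM. Every stage's
# output is returned and, when `out_dir` is given, written as CSV/JSON.

#' Default SEM model file shipped with the package
#'
#' A plain-text reconstruction of the across-site conceptual model:
#' management regime, cattle density, anthelmintic use and climate drive
#' the four community metrics, which drive dung removal; climate also acts
#' on removal directly; richness feeds behavioural diversity; the two FDis
#' indices (and the exogenous management descriptors, and
#' abundance/richness) share correlated errors rather than causal paths.
#'
#' @return Path to the model file.
#' @export
default_sem_model <- function() {
  system.file("extdata", "sem_model_reconstruction.txt",
              package = "grazemeta", mustWork = TRUE)
}

#' Assemble the per-pasture SEM data table
#'
#' One row per pasture: management (0 = low, 1 = high), cattle density,
#' anthelmintic use, the landscape's climate PCA score, the four community
#' metrics, mean dung removal, and the region grouping factor.
#'
#' @param bundle Validated bundle.
#' @param site_summary Site-level removal from [removal_by_site()].
#' @param metrics Community metrics from [community_metrics()].
#' @param climate `gm_pca` from [climate_pca()].
#' @return Data frame keyed by site_id.
#' @export
sem_data <- function(bundle, site_summary, metrics, climate) {
  s <- bundle$sites
  cv <- bundle$covariates
  df <- data.frame(
    site_id = s$site_id,
    region = s$region,
    management = regime_code(s$regime),
    cattle_density = cv$cattle_density[match(s$site_id, cv$site_id)],
    anthelmintic = cv$anthelmintic_use[match(s$site_id, cv$site_id)],
    climate = unname(climate$scores[match(s$landscape_id,
                                          names(climate$scores))]),
    stringsAsFactors = FALSE
  )
  im <- match(s$site_id, metrics$site_id)
  for (v in c("abundance", "richness", "FDisBehavior", "FDisMorphology")) {
    df[[v]] <- metrics[[v]][im]
  }
  df$dung_removal <- site_summary$mean_DRR[match(s$site_id,
                                                 site_summary$site_id)]
  df
}

#' Run the full analysis pipeline
#'
#' @param bundle Validated dataset bundle (e.g. from [read_tables()] or
#'   `generate_study()$bundle`).
#' @param wp_mode Water-proportion mode for [removal_by_site()].
#' @param structures Candidate spatial correlation structures for
#'   [select_structure()].
#' @param dag_file SEM model file (default [default_sem_model()]).
#' @param out_dir Optional output directory; stage outputs are written as
#'   CSV/JSON when given.
#' @return List of class `gm_report` with elements `removal`,
#'   `site_summary`, `metrics`, `diffs`, `pca_climate`, `pca_diversity`,
#'   `effects`, `wilcoxon`, `pooled` (structure-selection result for the
#'   weighted mean), `metareg` (structure-selection result with the three
#'   moderators), `heterogeneity`, `sem`, `sem_table`.
#' @export
run_pipeline <- function(bundle, wp_mode = "control",
                         structures = SPATIAL_STRUCTURES,
                         dag_file = default_sem_model(),
                         out_dir = NULL) {
  stage <- "dung_removal"
  res <- tryCatch({
    rem <- removal_by_site(bundle, mode = wp_mode)

    stage <- "community_diversity"
    metrics <- community_metrics(bundle)

    stage <- "covariate_pca"
    diffs <- diversity_differences(metrics)
    pca_cl <- climate_pca(bundle)
    pca_dv <- diversity_pca(diffs)

    stage <- "effect_meta"
    eff <- effect_sizes(rem$removal, bundle$sites)
    het <- heterogeneity(eff)
    pooled <- select_structure(eff, candidates = structures)
    land <- eff$landscape_id
    cd <- merge(bundle$covariates[, c("site_id", "cattle_density")],
                bundle$sites[, c("site_id", "landscape_id", "regime")])
    d_cd <- tapply(ifelse(cd$regime == "low", 1, -1) * cd$cattle_density,
                   cd$landscape_id, sum)
    mods <- data.frame(
      PCA1_Climate = unname(pca_cl$scores[match(land,
                                                names(pca_cl$scores))]),
      d_cattle_density = unname(d_cd[match(land, names(d_cd))]),
      PCA1_Diversity = unname(pca_dv$scores[match(land,
                                                  names(pca_dv$scores))])
    )
    metareg <- select_structure(eff, candidates = structures,
                                moderators = mods)
    sm <- rem$site_summary
    wil <- do.call(rbind, lapply(
      c("abundance", "richness", "FDisBehavior", "FDisMorphology"),
      function(v) {
        lo <- metrics[metrics$regime == "low", ]
        hi <- metrics[metrics$regime == "high", ]
        w <- paired_wilcoxon(lo[[v]][order(lo$landscape_id)],
                             hi[[v]][order(hi$landscape_id)])
        data.frame(variable = v, statistic = w$statistic, p = w$p,
                   n = w$n, stringsAsFactors = FALSE)
      }))
    lo <- sm[sm$regime == "low", ]; hi <- sm[sm$regime == "high", ]
    w <- paired_wilcoxon(lo$mean_DRR[order(lo$landscape_id)],
                         hi$mean_DRR[order(hi$landscape_id)])
    wil <- rbind(wil, data.frame(variable = "dung_removal",
                                 statistic = w$statistic, p = w$p, n = w$n,
                                 stringsAsFactors = FALSE))

    stage <- "piecewise_sem"
    dag <- read_dag(dag_file)
    sdat <- sem_data(bundle, rem$site_summary, metrics, pca_cl)
    sem <- fit_sem(dag, sdat, group = "region")

    list(removal = rem$removal, site_summary = rem$site_summary,
         metrics = metrics, diffs = diffs,
         pca_climate = pca_cl, pca_diversity = pca_dv,
         effects = eff, moderators = mods, wilcoxon = wil,
         pooled = pooled, metareg = metareg, heterogeneity = het,
         sem = sem, sem_table = sdat)
  }, error = function(e) {
    gm_error(sprintf("pipeline failed at stage '%s': %s", stage,
                     conditionMessage(e)),
             "gm_pipeline_error")
  })
  if (!is.null(out_dir)) write_report(res, out_dir)
  structure(res, class = c("gm_report", "list"))
}

write_report <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wcsv(res$removal, "removal.csv")
  wcsv(res$site_summary, "site_summary.csv")
  wcsv(res$metrics, "metrics.csv")
  wcsv(res$diffs, "diversity_differences.csv")
  wcsv(res$effects, "effects.csv")
  wcsv(res$wilcoxon, "wilcoxon.csv")
  wcsv(cbind(res$metareg$best$coefficients,
             vif = c(NA, unname(res$metareg$best$vif))), "metareg.csv")
  for (nm in c("pca_climate", "pca_diversity")) {
    p <- res[[nm]]
    wcsv(data.frame(id = names(p$scores), score = unname(p$scores)),
         paste0(nm, "_scores.csv"))
    wcsv(data.frame(variable = names(p$loadings),
                    loading = unname(p$loadings),
                    var_fraction_axis1 = p$var_fraction),
         paste0(nm, "_loadings.csv"))
  }
  best <- res$pooled$best
  ci <- stats::qt(0.975, best$coefficients$df[1]) * best$coefficients$se[1]
  jsonlite::write_json(list(
    structure_table = res$pooled$table,
    chosen_structure = best$structure,
    pooled_g = best$coefficients$estimate[1],
    ci95_halfwidth = ci,
    t = best$coefficients$t[1], df = best$coefficients$df[1],
    p = best$coefficients$p[1],
    tau2 = best$tau2, Q = res$heterogeneity$Q,
    Q_df = res$heterogeneity$df, Q_p = res$heterogeneity$p,
    I2 = best$I2
  ), file.path(out_dir, "metafit.json"), auto_unbox = TRUE, digits = NA,
     dataframe = "rows")
  jsonlite::write_json(list(
    C = res$sem$C, df = res$sem$C_df, p = res$sem$C_p,
    coefficients = res$sem$coefficients,
    r2 = cbind(response = rownames(res$sem$r2), as.data.frame(res$sem$r2)),
    suggested_path = res$sem$suggested_path
  ), file.path(out_dir, "sem_fit.json"), auto_unbox = TRUE, digits = NA,
     dataframe = "rows")
  invisible(out_dir)
}

#' @export
print.gm_report <- function(x, ...) {
  best <- x$pooled$best
  cat("== Dung removal / diversity pipeline report ==\n")
  cat(sprintf("Landscapes: %d   chosen structure: %s\n",
              nrow(x$effects), best$structure))
  cat(sprintf("Pooled Hedges' g = %.3f (t = %.3f, df = %d, p = %.3f)\n",
              best$coefficients$estimate[1], best$coefficients$t[1],
              best$coefficients$df[1], best$coefficients$p[1]))
  cat(sprintf("Heterogeneity: tau^2 = %.3f, Q = %.2f (df = %d), I^2 = %.3f\n",
              best$tau2, x$heterogeneity$Q, x$heterogeneity$df, best$I2))
  cat("\nMeta-regression (best structure:",
      x$metareg$best$structure, ")\n")
  print(x$metareg$best)
  cat("\n")
  print(x$sem)
  invisible(x)
}
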