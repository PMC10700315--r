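# Dung removal rates from pat weights, with evaporation correction.
#
# Each experimental pat starts at IWwet grams of fresh dung. After 48 h its
# final wet and oven-dry weights are known. Water proportion
#   WP = (FWwet - FWdry) / FWwet
# estimates evaporative water content; the initial dry mass is then
#   IWdry = IWwet * (1 - WP)
# and the removal rate is the dry mass that disappeared,
#   DRR = IWdry - FWdry                                  [g dry / 48 h].
# WP can be taken from each experimental pat itself ("unit" mode) or, the
# default, from the mesh-covered control pats at the same pasture
# ("control" mode), which exist precisely to measure evaporation without
# beetle access.

#' Water proportion of a dung pat
#'
#' Fraction of the final wet weight that is water, `(FWwet - FWdry) / FWwet`.
#'
#' @param FWwet Final wet weight (g), > 0.
#' @param FWdry Final dry weight (g), in `[0, FWwet]`.
#' @return Water proportion in `[0, 1]`. Vectorized.
#' @export
#' @examples
#' water_proportion(300, 75) # 0.75
water_proportion <- function(FWwet, FWdry) {
  if (any(FWwet <= 0)) {
    gm_error("water_proportion: FWwet must be > 0", "gm_domain_error")
  }
  if (any(FWdry < 0) || any(FWdry > FWwet)) {
    gm_error("water_proportion: FWdry must lie in [0, FWwet]",
             "gm_domain_error")
  }
  (FWwet - FWdry) / FWwet
}

#' Dung removal rate of an experimental pat
#'
#' Estimates the initial dry mass as `IWwet * (1 - WP)` and returns the dry
#' mass removed, `IWdry - FWdry`. Negative values (mass gain, e.g. rain)
#' are returned unclamped unless `clamp = TRUE`.
#'
#' @param IWwet Initial wet weight (g), > 0.
#' @param FWdry Final dry weight (g), >= 0.
#' @param WP Water proportion in `[0, 1]`.
#' @param clamp Logical; clamp negative removal to 0.
#' @return Dung removal rate in g dry mass per exposure period. Vectorized.
#' @export
#' @examples
#' removal_rate(300, 37.5, 0.75) # 37.5
removal_rate <- function(IWwet, FWdry, WP, clamp = FALSE) {
  if (any(IWwet <= 0) || any(FWdry < 0)) {
    gm_error("removal_rate: IWwet must be > 0 and FWdry >= 0",
             "gm_domain_error")
  }
  if (any(WP < 0) || any(WP > 1)) {
    gm_error("removal_rate: WP must lie in [0, 1]", "gm_domain_error")
  }
  drr <- IWwet * (1 - WP) - FWdry
  if (clamp) drr <- pmax(drr, 0)
  drr
}

#' Per-unit removal results and site summary for one pasture
#'
#' @param units Data frame of dung pat records for a single pasture
#'   (columns as in the `dungpats` schema).
#' @param mode `"control"` (default): WP is the mean water proportion of the
#'   pasture's control pats, applied to every experimental pat.
#'   `"unit"`: each experimental pat supplies its own WP from its final
#'   weights.
#' @param clamp Logical; clamp negative removal to 0.
#' @return List with `units` (data frame: unit_id, WP, IWdry, DRR, flagged)
#'   and `summary` (mean, sd with n-1 denominator, n over experimental
#'   units).
#' @export
site_removal <- function(units, mode = c("control", "unit"), clamp = FALSE) {
  mode <- match.arg(mode)
  exp_u <- units[units$role == "experimental", , drop = FALSE]
  if (nrow(exp_u) == 0L) {
    gm_error("site_removal: no experimental units", "gm_config_error")
  }
  if (mode == "control") {
    ctl <- units[units$role == "control", , drop = FALSE]
    if (nrow(ctl) == 0L) {
      gm_error("site_removal: control mode requires >= 1 control pat",
               "gm_config_error")
    }
    wp <- rep(mean(water_proportion(ctl$FWwet, ctl$FWdry)), nrow(exp_u))
  } else {
    wp <- water_proportion(exp_u$FWwet, exp_u$FWdry)
  }
  drr <- removal_rate(exp_u$IWwet, exp_u$FWdry, wp, clamp = clamp)
  res <- data.frame(
    unit_id = exp_u$unit_id,
    WP = wp,
    IWdry = exp_u$IWwet * (1 - wp),
    DRR = drr,
    flagged = drr < 0,
    stringsAsFactors = FALSE
  )
  list(units = res,
       summary = c(mean = mean(drr),
                   sd = stats::sd(drr),
                   n = nrow(exp_u)))
}

#' Removal rates for every pasture in a bundle
#'
#' Applies [site_removal()] per pasture and assembles unit-level and
#' site-level tables.
#'
#' @param bundle Validated dataset bundle.
#' @inheritParams site_removal
#' @return List of data frames `removal` (unit level) and `site_summary`
#'   (site_id, regime, mean_DRR, sd_DRR, n).
#' @export
removal_by_site <- function(bundle, mode = c("control", "unit"),
                            clamp = FALSE) {
  mode <- match.arg(mode)
  dp <- bundle$dungpats
  sites <- bundle$sites
  out_units <- list(); out_sum <- list()
  for (sid in unique(dp$site_id)) {
    res <- site_removal(dp[dp$site_id == sid, , drop = FALSE], mode = mode,
                        clamp = clamp)
    res$units$site_id <- sid
    out_units[[sid]] <- res$units
    out_sum[[sid]] <- data.frame(
      site_id = sid,
      regime = sites$regime[match(sid, sites$site_id)],
      landscape_id = sites$landscape_id[match(sid, sites$site_id)],
      mean_DRR = res$summary[["mean"]],
      sd_DRR = res$summary[["sd"]],
      n = res$summary[["n"]],
      stringsAsFactors = FALSE
    )
  }
  list(removal = do.call(rbind, c(out_units, list(make.row.names = FALSE))),
       site_summary = do.call(rbind, c(out_sum, list(make.row.names = FALSE))))
}
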