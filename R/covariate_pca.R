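# First-axis PCA summaries of the climate table and of the paired
# low-minus-high diversity differences. Both PCAs run on the correlation
# matrix (columns z-scored) and the sign of axis 1 is anchored to a named
# variable so scores have a fixed, interpretable orientation.

#' First principal-component summary
#'
#' PCA on the correlation matrix of `X` (columns z-scored; constant columns
#' dropped with a warning). The arbitrary sign of axis 1 is fixed so the
#' anchor variable's loading (variable--axis correlation) has the requested
#' sign.
#'
#' @param X Numeric matrix or data frame, observations x variables; rows
#'   with missing values are dropped listwise.
#' @param anchor Column name anchoring the orientation (default: first
#'   column).
#' @param anchor_sign `+1` or `-1`, required sign of the anchor loading.
#' @return Object of class `gm_pca`: list with `scores` (axis-1 score per
#'   observation), `loadings` (correlation of each variable with axis 1),
#'   `var_fraction` (axis-1 share of total variance), `var_fractions`
#'   (all axes), `anchor`.
#' @export
#' @examples
#' X <- cbind(a = 1:8, b = (1:8) * 2 + 1)
#' pca_axis1(X, anchor = "a", anchor_sign = 1)$var_fraction # 1
pca_axis1 <- function(X, anchor = colnames(X)[1], anchor_sign = 1) {
  X <- as.matrix(X)
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  if (nrow(X) < 2L) gm_error("pca_axis1: need >= 2 complete observations",
                             "gm_domain_error")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("pca_axis1: dropping constant variable(s): %s",
                    paste(colnames(X)[sds == 0], collapse = ", ")),
            call. = FALSE)
    X <- X[, sds > 0, drop = FALSE]
  }
  if (ncol(X) < 2L) gm_error("pca_axis1: need >= 2 usable variables",
                             "gm_domain_error")
  if (!anchor %in% colnames(X)) {
    gm_error(sprintf("pca_axis1: anchor '%s' is not a usable column", anchor),
             "gm_domain_error")
  }
  p <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  fractions <- p$sdev^2 / sum(p$sdev^2)
  scores <- p$x[, 1]
  loadings <- stats::cor(X, scores)[, 1]
  if (sign(loadings[anchor]) != sign(anchor_sign) && loadings[anchor] != 0) {
    scores <- -scores
    loadings <- -loadings
  }
  structure(list(scores = scores, loadings = loadings,
                 var_fraction = fractions[1], var_fractions = fractions,
                 anchor = anchor),
            class = "gm_pca")
}

#' @export
print.gm_pca <- function(x, ...) {
  cat(sprintf("PCA axis 1: %.1f%% of variance (anchor: %s)\n",
              100 * x$var_fraction, x$anchor))
  print(round(x$loadings, 3))
  invisible(x)
}

#' Paired low-minus-high diversity differences
#'
#' One row per landscape with the difference (low minus high) of each
#' community metric, so positive values mean higher diversity under
#' low-intensity management.
#'
#' @param metrics Output of [community_metrics()] (both regimes present for
#'   every landscape).
#' @param vars Metric columns to difference.
#' @return Data frame: landscape_id and `d_<metric>` columns.
#' @export
diversity_differences <- function(metrics,
                                  vars = c("abundance", "richness",
                                           "FDisBehavior",
                                           "FDisMorphology")) {
  lands <- unique(metrics$landscape_id)
  low <- metrics[metrics$regime == "low", , drop = FALSE]
  high <- metrics[metrics$regime == "high", , drop = FALSE]
  if (!setequal(low$landscape_id, lands) ||
      !setequal(high$landscape_id, lands)) {
    gm_error("diversity_differences: every landscape needs both regimes",
             "gm_validation_error")
  }
  il <- match(lands, low$landscape_id)
  ih <- match(lands, high$landscape_id)
  out <- data.frame(landscape_id = lands, stringsAsFactors = FALSE)
  for (v in vars) out[[paste0("d_", v)]] <- low[[v]][il] - high[[v]][ih]
  out
}

#' Climate PCA over landscapes
#'
#' Runs [pca_axis1()] on the 13 bioclim columns, one observation per
#' landscape (the paired pastures share their climate; the landscape value
#' is the mean of its two pastures' rows). Orientation is anchored so mean
#' annual temperature (`bio1` by default) loads negatively: positive scores
#' mean colder, more seasonal climates.
#'
#' @param bundle Validated dataset bundle.
#' @param anchor Bioclim column used to fix the axis sign.
#' @return `gm_pca` with one score per landscape (named by landscape_id).
#' @export
climate_pca <- function(bundle, anchor = "bio1") {
  cv <- bundle$covariates
  s <- bundle$sites
  bio <- grep("^bio", names(cv), value = TRUE)
  land <- s$landscape_id[match(cv$site_id, s$site_id)]
  X <- apply(cv[, bio, drop = FALSE], 2,
             function(col) tapply(col, land, mean))
  pca_axis1(X, anchor = anchor, anchor_sign = -1)
}

#' Diversity-difference PCA over landscapes
#'
#' Runs [pca_axis1()] on the paired differences from
#' [diversity_differences()], anchored so the FDisBehavior difference loads
#' positively: positive scores mean higher diversity under low intensity.
#'
#' @param diffs Output of [diversity_differences()].
#' @return `gm_pca` with one score per landscape.
#' @export
diversity_pca <- function(diffs) {
  X <- as.matrix(diffs[, setdiff(names(diffs), "landscape_id"), drop = FALSE])
  rownames(X) <- diffs$landscape_id
  pca_axis1(X, anchor = "d_FDisBehavior", anchor_sign = 1)
}
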