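# Data containers, CSV schemas and validation for the paired grazing study.
#
# A "bundle" is a named list of five data frames:
#   sites       one row per pasture (two pastures, one per regime, per landscape)
#   covariates  management covariates + 13 bioclimatic columns, keyed by site_id
#   dungpats    one row per dung pat (experimental or control)
#   occurrences species abundances per pasture with a guild label
#   traits      per-individual morphological measurements
# All readers/writers use comma-separated UTF-8 text with a mandatory header
# row and "." as the decimal separator.

#' Table schemas used by the pipeline
#'
#' Required column names for the five CSV tables consumed and produced by
#' [read_tables()] and [write_tables()]. The covariate table additionally
#' carries 13 bioclimatic columns whose names must start with `"bio"`; any 13
#' such columns are accepted.
#'
#' @return Named list of character vectors of required column names.
#' @export
#' @examples
#' table_schemas()$sites
table_schemas <- function() {
  list(
    sites = c("site_id", "landscape_id", "region", "regime",
              "latitude", "longitude"),
    covariates = c("site_id", "cattle_density", "anthelmintic_use",
                   "land_history"),
    dungpats = c("site_id", "unit_id", "role", "IWwet", "FWwet", "FWdry",
                 "exposure"),
    occurrences = c("site_id", "species_id", "abundance", "guild"),
    traits = c("species_id", "individual_id", "head_length", "head_width",
               "pronotum_length", "pronotum_width", "pronotum_height",
               "elytra_length", "protibia_length", "protibia_width",
               "metatibia_length", "biomass")
  )
}

#' Canonical guild levels and accepted aliases
#'
#' The four food-relocation guilds, plus the common behavioural vocabulary
#' mapped onto them (tunneler, roller, dweller, kleptoparasite).
#'
#' @return Named character vector mapping accepted labels to canonical guilds.
#' @export
guild_aliases <- function() {
  c(paracoprid = "paracoprid", telecoprid = "telecoprid",
    endocoprid = "endocoprid", kleptocoprid = "kleptocoprid",
    tunneler = "paracoprid", roller = "telecoprid",
    dweller = "endocoprid", kleptoparasite = "kleptocoprid")
}

GUILDS <- c("paracoprid", "telecoprid", "endocoprid", "kleptocoprid")
REGIMES <- c("low", "high")
TRAIT_COLS <- c("head_length", "head_width", "pronotum_length",
                "pronotum_width", "pronotum_height", "elytra_length",
                "protibia_length", "protibia_width", "metatibia_length")

gm_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "gm_error")))
}

#' Numeric coding of a management regime
#'
#' @param regime Character vector with levels `"low"` / `"high"`.
#' @return Integer vector: low = 0, high = 1.
#' @export
regime_code <- function(regime) {
  if (!all(regime %in% REGIMES)) {
    gm_error("regime must be 'low' or 'high'", "gm_validation_error")
  }
  as.integer(regime == "high")
}

check_columns <- function(df, required, table) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    gm_error(sprintf("table '%s' is missing required column(s): %s",
                     table, paste(missing, collapse = ", ")),
             "gm_schema_error")
  }
}

#' Normalize guild labels through the alias map
#'
#' @param guild Character vector of guild labels.
#' @param aliases Logical; accept behavioural-vocabulary aliases
#'   ("roller" etc.). If `FALSE` only the four canonical labels validate.
#' @return Character vector of canonical guild labels.
#' @export
#' @examples
#' normalize_guild(c("roller", "paracoprid"))
normalize_guild <- function(guild, aliases = TRUE) {
  map <- guild_aliases()
  if (!aliases) map <- map[GUILDS]
  g <- unname(map[tolower(trimws(guild))])
  if (anyNA(g)) {
    bad <- unique(guild[is.na(g)])
    gm_error(sprintf("unknown guild label(s): %s",
                     paste(bad, collapse = ", ")),
             "gm_validation_error")
  }
  g
}

#' Validate a dataset bundle
#'
#' Checks the schema and the domain invariants of every table: coordinate
#' ranges, exactly two pastures (one per regime) per landscape, non-negative
#' weights with `FWdry <= FWwet`, guild levels, integer abundances, positive
#' traits and `anthelmintic_use` in 0..4. Design expectations that the data
#' may legitimately miss (10 experimental + 5 control pats per pasture,
#' cattle-density thresholds <2 / >4 per regime) raise warnings unless
#' `strict = TRUE`.
#'
#' @param bundle Named list with elements `sites`, `covariates`, `dungpats`,
#'   `occurrences`, `traits`.
#' @param strict Logical; escalate design-expectation warnings to errors.
#' @param aliases Logical; accept guild aliases (normalized in the returned
#'   bundle).
#' @return The validated (and guild-normalized) bundle, classed
#'   `"grazemeta_bundle"`.
#' @export
validate_bundle <- function(bundle, strict = FALSE, aliases = TRUE) {
  sch <- table_schemas()
  for (tb in names(sch)) {
    if (is.null(bundle[[tb]])) {
      gm_error(sprintf("bundle is missing table '%s'", tb), "gm_schema_error")
    }
    check_columns(bundle[[tb]], sch[[tb]], tb)
  }
  flag <- function(msg) {
    if (strict) gm_error(msg, "gm_validation_error") else warning(msg, call. = FALSE)
  }

  s <- bundle$sites
  if (!all(s$regime %in% REGIMES)) {
    gm_error("sites: regime must be 'low' or 'high'", "gm_validation_error")
  }
  if (any(s$latitude < -90 | s$latitude > 90) ||
      any(s$longitude < -180 | s$longitude > 180)) {
    gm_error("sites: coordinates out of range", "gm_validation_error")
  }
  if (anyDuplicated(s$site_id)) {
    gm_error("sites: duplicated site_id", "gm_validation_error")
  }
  per_land <- split(s$regime, s$landscape_id)
  bad <- names(per_land)[!vapply(per_land, function(r)
    length(r) == 2L && setequal(r, REGIMES), logical(1))]
  if (length(bad)) {
    gm_error(sprintf(
      "sites: landscape(s) without exactly one low and one high pasture: %s",
      paste(bad, collapse = ", ")), "gm_validation_error")
  }

  cv <- bundle$covariates
  if (!all(cv$site_id %in% s$site_id)) {
    gm_error("covariates: unknown site_id", "gm_validation_error")
  }
  if (!all(cv$anthelmintic_use %in% 0:4)) {
    gm_error("covariates: anthelmintic_use must be an integer in 0..4",
             "gm_validation_error")
  }
  if (any(cv$cattle_density <= 0)) {
    gm_error("covariates: cattle_density must be > 0", "gm_validation_error")
  }
  bio <- grep("^bio", names(cv), value = TRUE)
  if (length(bio) != 13L) {
    flag(sprintf("covariates: expected 13 'bio*' climate columns, found %d",
                 length(bio)))
  }
  reg <- s$regime[match(cv$site_id, s$site_id)]
  if (any(cv$cattle_density[reg == "low"] >= 2) ||
      any(cv$cattle_density[reg == "high"] <= 4)) {
    flag("covariates: cattle density outside the regime thresholds (<2 low, >4 high)")
  }

  dp <- bundle$dungpats
  if (!all(dp$role %in% c("experimental", "control"))) {
    gm_error("dungpats: role must be 'experimental' or 'control'",
             "gm_validation_error")
  }
  if (!all(dp$site_id %in% s$site_id)) {
    gm_error("dungpats: unknown site_id", "gm_validation_error")
  }
  neg <- dp$IWwet <= 0 | dp$FWwet < 0 | dp$FWdry < 0
  if (any(neg)) {
    gm_error(sprintf("dungpats: non-positive IWwet or negative weight in unit(s): %s",
                     paste(dp$unit_id[neg], collapse = ", ")),
             "gm_validation_error")
  }
  over <- dp$FWdry > dp$FWwet
  if (any(over)) {
    gm_error(sprintf("dungpats: FWdry > FWwet in unit(s): %s",
                     paste(dp$unit_id[over], collapse = ", ")),
             "gm_validation_error")
  }
  cnt <- table(dp$site_id, dp$role)
  if (!all(cnt[, "experimental"] == 10L) || !all(cnt[, "control"] == 5L)) {
    flag("dungpats: design expects 10 experimental + 5 control pats per pasture")
  }

  occ <- bundle$occurrences
  if (!all(occ$site_id %in% s$site_id)) {
    gm_error("occurrences: unknown site_id", "gm_validation_error")
  }
  if (any(occ$abundance < 0) || any(occ$abundance != round(occ$abundance))) {
    gm_error("occurrences: abundance must be a non-negative integer",
             "gm_validation_error")
  }
  occ$guild <- normalize_guild(occ$guild, aliases = aliases)
  bundle$occurrences <- occ

  tr <- bundle$traits
  num <- c(TRAIT_COLS, "biomass")
  vals <- as.matrix(tr[, num])
  if (any(!is.na(vals) & vals <= 0)) {
    gm_error("traits: all trait values and biomass must be > 0",
             "gm_validation_error")
  }
  measured <- setdiff(unique(occ$species_id[occ$abundance > 0]),
                      unique(tr$species_id))
  if (length(measured)) {
    flag(sprintf("traits: species without trait measurements: %s",
                 paste(measured, collapse = ", ")))
  }
  structure(bundle, class = c("grazemeta_bundle", "list"))
}

#' Read a validated dataset bundle from CSV files
#'
#' @param dir Directory containing `sites.csv`, `covariates.csv`,
#'   `dungpats.csv`, `occurrences.csv`, `traits.csv`.
#' @param paths Optional named list of file paths overriding the defaults.
#' @inheritParams validate_bundle
#' @return A validated `grazemeta_bundle`.
#' @export
read_tables <- function(dir = ".", paths = NULL, strict = FALSE,
                        aliases = TRUE) {
  tables <- names(table_schemas())
  if (is.null(paths)) {
    paths <- stats::setNames(file.path(dir, paste0(tables, ".csv")), tables)
  }
  bundle <- list()
  for (tb in tables) {
    p <- paths[[tb]]
    if (is.null(p) || !file.exists(p)) {
      gm_error(sprintf("input file for table '%s' not found: %s", tb,
                       if (is.null(p)) "<missing path>" else p),
               "gm_io_error")
    }
    bundle[[tb]] <- utils::read.csv(p, stringsAsFactors = FALSE)
  }
  validate_bundle(bundle, strict = strict, aliases = aliases)
}

#' Write a dataset bundle to CSV files
#'
#' Columns are emitted in schema order (extra columns, e.g. the bioclim
#' block, follow in name order) so output is deterministic and re-readable
#' by [read_tables()].
#'
#' @param bundle A validated bundle.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of files written.
#' @export
write_tables <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sch <- table_schemas()
  out <- character(0)
  for (tb in names(sch)) {
    df <- bundle[[tb]]
    extra <- sort(setdiff(names(df), sch[[tb]]))
    df <- df[, c(sch[[tb]], extra), drop = FALSE]
    path <- file.path(dir, paste0(tb, ".csv"))
    ok <- tryCatch({
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) gm_error(sprintf("cannot write %s", path), "gm_io_error")
    out[tb] <- path
  }
  invisible(out)
}

#' @export
print.grazemeta_bundle <- function(x, ...) {
  cat("grazemeta dataset bundle\n")
  for (tb in names(table_schemas())) {
    cat(sprintf("  %-12s %5d rows x %d cols\n", tb, nrow(x[[tb]]),
                ncol(x[[tb]])))
  }
  invisible(x)
}
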