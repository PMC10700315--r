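# Community metrics per pasture: abundance, richness, Pielou evenness, and
# two functional dispersion (FDis) indices computed as the mean pairwise
# distance among the species present:
#   FDisMorphology - Euclidean distance in a standardized space of nine
#     morphological traits plus log biomass;
#   FDisBehavior   - cophenetic distance on a behaviour-constrained phenetic
#     tree whose 12 tips are guild x size-class functional groups.

SIZE_CLASSES <- c("large", "medium", "small")

#' Body-size class of a species
#'
#' Large > 18.0 mm, medium 10.0--18.0 mm (boundaries inclusive),
#' small < 10.0 mm, on mean body length.
#'
#' @param size_mm Mean body length in mm, > 0.
#' @return Character vector of size classes.
#' @export
#' @examples
#' size_class(c(19, 18, 10, 9.9))
size_class <- function(size_mm) {
  if (any(size_mm <= 0)) {
    gm_error("size_class: body size must be > 0", "gm_domain_error")
  }
  ifelse(size_mm > 18, "large", ifelse(size_mm >= 10, "medium", "small"))
}

#' Functional group of a species (guild x size class)
#'
#' @param guild Guild label (aliases accepted).
#' @param mean_body_size Mean body length in mm.
#' @return Character vector like `"paracoprid_large"`; 12 possible levels.
#' @export
assign_functional_group <- function(guild, mean_body_size) {
  paste(normalize_guild(guild), size_class(mean_body_size), sep = "_")
}

#' All 12 functional-group labels
#' @return Character vector of the 12 guild x size-class combinations.
#' @export
functional_groups <- function() {
  as.vector(outer(GUILDS, SIZE_CLASSES, paste, sep = "_"))
}

#' Species-level trait profile
#'
#' Per-trait arithmetic means over the measured individuals of one species
#' (missing values skipped individual-wise per trait), plus mean body
#' length, where body length = head length + pronotum length + elytra
#' length per individual.
#'
#' @param traits Trait table (schema `traits`).
#' @param species_id Single species identifier.
#' @return Named numeric vector of the nine trait means, `biomass`, and
#'   `body_length`.
#' @export
species_trait_profile <- function(traits, species_id) {
  tr <- traits[traits$species_id == species_id, , drop = FALSE]
  if (nrow(tr) == 0L) {
    gm_error(sprintf("no measured individuals for species '%s'", species_id),
             "gm_missing_trait_error")
  }
  prof <- colMeans(tr[, c(TRAIT_COLS, "biomass")], na.rm = TRUE)
  bl <- tr$head_length + tr$pronotum_length + tr$elytra_length
  c(prof, body_length = mean(bl, na.rm = TRUE))
}

#' Trait profiles for a set of species
#'
#' @param traits Trait table.
#' @param species Character vector of species ids (default: all measured).
#' @return Matrix, species x (9 traits + biomass + body_length).
#' @export
trait_profiles <- function(traits, species = unique(traits$species_id)) {
  t(vapply(species, function(s) species_trait_profile(traits, s),
           numeric(length(TRAIT_COLS) + 2L)))
}

#' Standardized morphological distance matrix
#'
#' Z-scores each trait column (biomass log-transformed first) over the
#' species supplied, then computes Euclidean distances. Zero-variance
#' columns are dropped with a warning.
#'
#' @param profiles Species x trait matrix from [trait_profiles()]; the
#'   `body_length` column, if present, is ignored (it parameterizes the
#'   behavioural index, not the morphological space).
#' @param standardize Logical; z-score columns (default `TRUE`).
#' @param log_biomass Logical; log-transform biomass before scaling.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
trait_distance_matrix <- function(profiles, standardize = TRUE,
                                  log_biomass = TRUE) {
  x <- profiles[, intersect(colnames(profiles), c(TRAIT_COLS, "biomass")),
                drop = FALSE]
  if (log_biomass && "biomass" %in% colnames(x)) {
    x[, "biomass"] <- log(x[, "biomass"])
  }
  if (standardize) {
    sds <- apply(x, 2, stats::sd)
    if (nrow(x) > 1 && any(sds == 0)) {
      warning(sprintf("dropping zero-variance trait(s): %s",
                      paste(colnames(x)[sds == 0], collapse = ", ")),
              call. = FALSE)
      x <- x[, sds > 0, drop = FALSE]
    }
    if (nrow(x) > 1) x <- scale(x)
  }
  as.matrix(stats::dist(x))
}

#' Mean pairwise distance over the species present
#'
#' Mean of the `|S|(|S|-1)/2` unordered pairs; 0 when one or no species is
#' present. Abundance weighting (weights `n_i * n_j` per pair) is available
#' but off by default: presence only, as the index is defined.
#'
#' @param D Symmetric distance matrix with named rows/columns.
#' @param present Character vector of species present.
#' @param abundance Optional named abundance vector for weighted dispersion.
#' @return Non-negative dispersion value.
#' @export
mean_pairwise_distance <- function(D, present, abundance = NULL) {
  present <- unique(present)
  if (!all(present %in% rownames(D))) {
    gm_error(sprintf("species not in distance matrix: %s",
                     paste(setdiff(present, rownames(D)), collapse = ", ")),
             "gm_lookup_error")
  }
  if (length(present) <= 1L) return(0)
  Dm <- D[present, present]
  if (is.null(abundance)) {
    mean(Dm[lower.tri(Dm)])
  } else {
    w <- abundance[present]
    W <- outer(w, w)
    sum((Dm * W)[lower.tri(Dm)]) / sum(W[lower.tri(W)])
  }
}

#' Behaviour-constrained phenetic tree of functional groups
#'
#' Fixed topology: the root separates the dung-dwelling behaviours
#' (kleptocoprid, endocoprid) from the relocators (paracoprid, telecoprid);
#' a second split yields the four guild branches; each guild carries its
#' three size classes at the tips (12 tips). Unit branch lengths by default
#' make the tree ultrametric with all tips at depth 3.
#'
#' @param branch_length Length assigned to every edge (default 1).
#' @return An [ape::phylo] tree with 12 tips labelled as in
#'   [functional_groups()].
#' @export
#' @examples
#' tr <- build_behavior_tree()
#' ape::is.ultrametric(tr)
build_behavior_tree <- function(branch_length = 1) {
  guild_clade <- function(g) {
    sprintf("(%s_large:%f,%s_medium:%f,%s_small:%f):%f",
            g, branch_length, g, branch_length, g, branch_length,
            branch_length)
  }
  nw <- sprintf("((%s,%s):%f,(%s,%s):%f);",
                guild_clade("kleptocoprid"), guild_clade("endocoprid"),
                branch_length,
                guild_clade("paracoprid"), guild_clade("telecoprid"),
                branch_length)
  ape::read.tree(text = nw)
}

#' Behavioural functional dispersion of a community
#'
#' Mean pairwise cophenetic distance between the functional-group tips
#' occupied by the species present; species sharing a tip contribute
#' distance 0.
#'
#' @param tree Behaviour tree from [build_behavior_tree()].
#' @param groups Character vector of functional-group labels, one per
#'   species present.
#' @return Dispersion value (0 for a single-species or single-group-species
#'   set only when at most one species is present; species pairs at one tip
#'   count as zero-distance pairs).
#' @export
fdis_behavior <- function(tree, groups) {
  if (!all(groups %in% tree$tip.label)) {
    gm_error(sprintf("functional group(s) not on the tree: %s",
                     paste(setdiff(groups, tree$tip.label), collapse = ", ")),
             "gm_lookup_error")
  }
  if (length(groups) <= 1L) return(0)
  D <- ape::cophenetic.phylo(tree)[groups, groups]
  mean(D[lower.tri(D)])
}

shannon <- function(n) {
  p <- n[n > 0] / sum(n)
  -sum(p * log(p))
}

#' Community metrics for every pasture
#'
#' Computes abundance, richness, Pielou evenness (H' / ln richness; NA for
#' richness <= 1), FDisMorphology and FDisBehavior per pasture. The
#' morphological trait space is standardized over the two communities of
#' each landscape jointly, so the paired pastures share one trait space.
#'
#' @param bundle Validated dataset bundle.
#' @param tree Behaviour tree (default [build_behavior_tree()]).
#' @param abundance_weighted Logical; abundance-weighted dispersion.
#' @return Data frame, one row per pasture: site_id, landscape_id, regime,
#'   abundance, richness, evenness, FDisMorphology, FDisBehavior.
#' @export
community_metrics <- function(bundle, tree = build_behavior_tree(),
                              abundance_weighted = FALSE) {
  occ <- bundle$occurrences
  occ <- occ[occ$abundance > 0, , drop = FALSE]
  sites <- bundle$sites
  rows <- list()
  for (land in unique(sites$landscape_id)) {
    pair <- sites[sites$landscape_id == land, , drop = FALSE]
    pool <- unique(occ$species_id[occ$site_id %in% pair$site_id])
    if (length(pool)) {
      prof <- trait_profiles(bundle$traits, pool)
      Dm <- trait_distance_matrix(prof)
      g_occ <- occ[occ$site_id %in% pair$site_id, , drop = FALSE]
      guild_of <- g_occ$guild[match(pool, g_occ$species_id)]
      fg <- assign_functional_group(guild_of, prof[pool, "body_length"])
      names(fg) <- pool
    }
    for (i in seq_len(nrow(pair))) {
      sid <- pair$site_id[i]
      comm <- occ[occ$site_id == sid, , drop = FALSE]
      n_sp <- length(unique(comm$species_id))
      ab <- stats::setNames(comm$abundance, comm$species_id)
      H <- shannon(comm$abundance)
      rows[[sid]] <- data.frame(
        site_id = sid,
        landscape_id = land,
        regime = pair$regime[i],
        abundance = sum(comm$abundance),
        richness = n_sp,
        evenness = if (n_sp > 1) H / log(n_sp) else NA_real_,
        FDisMorphology = if (n_sp > 1)
          mean_pairwise_distance(Dm, comm$species_id,
                                 if (abundance_weighted) ab else NULL)
          else 0,
        FDisBehavior = if (n_sp > 1) {
          if (abundance_weighted) {
            Dt <- ape::cophenetic.phylo(tree)[fg[comm$species_id],
                                              fg[comm$species_id]]
            dimnames(Dt) <- list(comm$species_id, comm$species_id)
            mean_pairwise_distance(Dt, comm$species_id, ab)
          } else fdis_behavior(tree, fg[comm$species_id])
        } else 0,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
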