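# Independent oracles and fixture builders shared across test files.
# Everything here is deliberately written by a different route than the
# package code it checks (direct enumeration, closed forms, grid search).

# brute-force mean pairwise distance: explicit double loop over pairs
brute_mpd <- function(D, present) {
  present <- unique(present)
  if (length(present) <= 1) return(0)
  tot <- 0; np <- 0
  for (i in seq_along(present)) {
    for (j in seq_along(present)) {
      if (i < j) {
        tot <- tot + D[present[i], present[j]]
        np <- np + 1
      }
    }
  }
  tot / np
}

# closed-form intercept-only restricted log-likelihood for the
# random-effects model without spatial correlation (textbook form)
reml_ll_scalar <- function(tau2, y, v) {
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  -0.5 * (sum(log(v + tau2)) + log(sum(w)) + sum(w * (y - mu)^2)) -
    0.5 * (length(y) - 1) * log(2 * pi)
}

# grid-search REML tau2 estimate
grid_tau2 <- function(y, v, upper = 5, step = 2e-5) {
  grid <- seq(0, upper, by = step)
  ll <- vapply(grid, reml_ll_scalar, numeric(1), y = y, v = v)
  grid[which.max(ll)]
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
signrank_enum_p <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- drop(signs %*% r)
  pl <- mean(vs <= v_obs); pu <- mean(vs >= v_obs)
  min(1, 2 * min(pl, pu))
}

# random DAG on `n` nodes: independent edges following a random node order
random_dag <- function(n, p_edge = 0.4) {
  nodes <- LETTERS[seq_len(n)]
  ord <- sample(nodes)
  edges <- NULL
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (stats::runif(1) < p_edge) {
        edges <- rbind(edges, c(ord[i], ord[j]))
      }
    }
  }
  if (is.null(edges)) edges <- matrix(character(0), 0, 2)
  list(nodes = nodes, edges = edges)
}

# independent enumeration of non-adjacent, non-correlated-error unordered
# pairs of a DAG given as an edge matrix
enum_nonadjacent <- function(nodes, edges, correlated = NULL) {
  pairs <- list()
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (i >= j) next
      a <- nodes[i]; b <- nodes[j]
      touching <- FALSE
      if (nrow(edges)) {
        touching <- any((edges[, 1] == a & edges[, 2] == b) |
                        (edges[, 1] == b & edges[, 2] == a))
      }
      if (!touching && !is.null(correlated) && nrow(correlated)) {
        touching <- any((correlated[, 1] == a & correlated[, 2] == b) |
                        (correlated[, 1] == b & correlated[, 2] == a))
      }
      if (!touching) pairs[[length(pairs) + 1]] <- sort(c(a, b))
    }
  }
  pairs
}

# linear-Gaussian simulation from a gm_dag (unit coefficients scaled by
# `beta`, unit residual SD), for SEM calibration checks
simulate_from_dag <- function(dag, n, beta = 0.5) {
  ord <- grazemeta:::topological_order(dag)
  dat <- as.data.frame(stats::setNames(rep(list(numeric(n)), length(ord)),
                                       ord))
  for (nd in ord) {
    par <- dag$edges$from[dag$edges$to == nd]
    mu <- if (length(par)) rowSums(beta * dat[, par, drop = FALSE]) else 0
    dat[[nd]] <- mu + stats::rnorm(n)
  }
  dat
}

# tiny handcrafted bundle: 2 landscapes, 4 pastures, full design
tiny_bundle <- function() {
  sites <- data.frame(
    site_id = c("L1_low", "L1_high", "L2_low", "L2_high"),
    landscape_id = c("L1", "L1", "L2", "L2"),
    region = c("R1", "R1", "R2", "R2"),
    regime = c("low", "high", "low", "high"),
    latitude = c(40, 40.05, -3, -3.05),
    longitude = c(-4, -4, 30, 30),
    stringsAsFactors = FALSE
  )
  bio <- matrix(seq(0.5, 26, length.out = 52), 4, 13,
                dimnames = list(NULL, paste0("bio", 1:13)))
  covariates <- data.frame(
    site_id = sites$site_id,
    cattle_density = c(1.2, 5.5, 0.8, 6.1),
    anthelmintic_use = c(0L, 3L, 1L, 4L),
    land_history = c(30, 30, 55, 55),
    bio, stringsAsFactors = FALSE
  )
  pats <- do.call(rbind, lapply(sites$site_id, function(sid) data.frame(
    site_id = sid,
    unit_id = paste0(sid, "_u", 1:15),
    role = rep(c("experimental", "control"), c(10, 5)),
    IWwet = 300,
    FWwet = c(seq(150, 195, 5), rep(240, 5)),
    FWdry = c(seq(30, 39, 1), rep(60, 5)),
    exposure = 48, stringsAsFactors = FALSE)))
  occurrences <- data.frame(
    site_id = rep(sites$site_id, each = 3),
    species_id = c("sp1", "sp2", "sp3", "sp1", "sp2", "sp4",
                   "sp2", "sp3", "sp5", "sp1", "sp3", "sp5"),
    abundance = c(5L, 3L, 2L, 4L, 1L, 6L, 2L, 2L, 2L, 7L, 1L, 3L),
    guild = c("paracoprid", "telecoprid", "endocoprid",
              "paracoprid", "telecoprid", "kleptocoprid",
              "telecoprid", "endocoprid", "paracoprid",
              "paracoprid", "endocoprid", "paracoprid"),
    stringsAsFactors = FALSE
  )
  traits <- do.call(rbind, lapply(1:5, function(k) {
    L <- c(8, 12, 16, 20, 25)[k]
    n <- 3
    data.frame(
      species_id = paste0("sp", k),
      individual_id = paste0("sp", k, "_i", 1:n),
      head_length = 0.2 * L * c(0.95, 1, 1.05),
      head_width = 0.25 * L,
      pronotum_length = 0.3 * L * c(1.02, 1, 0.98),
      pronotum_width = 0.45 * L,
      pronotum_height = 0.3 * L,
      elytra_length = 0.5 * L * c(1, 1.01, 0.99),
      protibia_length = 0.22 * L,
      protibia_width = 0.05 * L,
      metatibia_length = 0.28 * L,
      biomass = 0.025 * (L / 10)^3,
      stringsAsFactors = FALSE
    )
  }))
  suppressWarnings(validate_bundle(list(
    sites = sites, covariates = covariates, dungpats = pats,
    occurrences = occurrences, traits = traits)))
}

# small synthetic study shared by several files (cheap to regenerate)
small_study <- function(seed = 7) {
  generate_study(synthetic_config(seed = seed, n_landscapes = 8L,
                                  n_regions = 3L, pool_size = 18L,
                                  richness_low = 8))
}
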