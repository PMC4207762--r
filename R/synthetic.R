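ENV_CATALOGUE <- data.frame(
  variable = c("depth", "water_temperature", "dissolved_oxygen",
               "transparency", "pH", "conductivity", "alkalinity",
               "turbidity", "total_nitrogen", "total_phosphorus",
               "chlorophyll_a", "suspended_matter", "dissolved_organic_matter"),
  mu = c(3, 25, 6, 1.2, 7, 60, 0.8, 15, 800, 50, 8, 10, 4),
  stringsAsFactors = FALSE)

GROUPS7 <- c("phytoplankton", "periphyton", "zooplankton",
             "macroinvertebrates", "migratory_fish", "sedentary_fish",
             "macrophytes")

#' Generate a synthetic braided floodplain network
#'
#' Two roughly parallel main river stems with sites strung along each,
#' joined by bidirectional lateral channels; mimics a floodplain where two
#' rivers can exchange organisms through laterals at different positions.
#' The four dispersal-route scenarios differ in which laterals are open:
#' `s1` all laterals, `s2` only the most downstream, `s3` only the most
#' upstream, `s4` the two extremes. All stem edges carry every scenario, so
#' each scenario connects all sites; `s3` (a tree) is the default input for
#' [aem_basis()]. Coordinates are metres; edge lengths exceed the straight
#' chord by a meander factor.
#'
#' @param n_sites Total number of sites (>= 6), split between the stems.
#' @param n_laterals Number of lateral channels (>= 1).
#' @param seed Integer seed; the generator is fully deterministic given
#'   `(parameters, seed)`.
#' @return List with `sites` (site table) and `network`
#'   (`channel_network`).
#' @export
generate_network <- function(n_sites = 36, n_laterals = 4, seed = 1) {
  if (n_sites < 6) stop("need at least 6 sites")
  if (n_laterals < 1)
    stop("n_laterals = 0 cannot connect the two stems in any scenario")
  set.seed(seed)
  nA <- ceiling(n_sites / 2)
  nB <- n_sites - nA
  mk_stem <- function(prefix, n, y0, subsystem) {
    data.frame(site_id = sprintf("%s%02d", prefix, seq_len(n)),
               x = seq(0, by = 2000, length.out = n) + runif(n, -300, 300),
               y = y0 + runif(n, -400, 400),
               subsystem = subsystem, stringsAsFactors = FALSE)
  }
  sites <- rbind(mk_stem("A", nA, 0, "parana"),
                 mk_stem("B", nB, 4000, "baia"))
  euclid <- function(i, j) sqrt((sites$x[i] - sites$x[j])^2 +
                                (sites$y[i] - sites$y[j])^2)
  idx <- function(id) match(id, sites$site_id)

  stem_edges <- function(prefix, n) {
    a <- sprintf("%s%02d", prefix, seq_len(n - 1))
    b <- sprintf("%s%02d", prefix, seq_len(n - 1) + 1)
    data.frame(node_a = a, node_b = b,
               length_m = vapply(seq_len(n - 1), function(k)
                 euclid(idx(a[k]), idx(b[k])) * runif(1, 1.1, 1.4), numeric(1)),
               flow_class = "main_unidirectional",
               scenarios = "s1;s2;s3;s4", stringsAsFactors = FALSE)
  }
  lat_pos <- unique(round(seq(1, min(nA, nB), length.out = n_laterals)))
  lat_tags <- vapply(seq_along(lat_pos), function(k) {
    tags <- "s1"
    if (k == length(lat_pos)) tags <- c(tags, "s2")  # most downstream
    if (k == 1) tags <- c(tags, "s3")                # most upstream
    if (k == 1 || k == length(lat_pos)) tags <- c(tags, "s4")
    paste(unique(tags), collapse = ";")
  }, character(1))
  lat_edges <- data.frame(
    node_a = sprintf("A%02d", lat_pos),
    node_b = sprintf("B%02d", lat_pos),
    length_m = vapply(seq_along(lat_pos), function(k)
      euclid(idx(sprintf("A%02d", lat_pos[k])),
             idx(sprintf("B%02d", lat_pos[k]))) * runif(1, 1.1, 1.4),
      numeric(1)),
    flow_class = "lateral_bidirectional",
    scenarios = lat_tags, stringsAsFactors = FALSE)

  edges <- rbind(stem_edges("A", nA), stem_edges("B", nB), lat_edges)
  list(sites = sites, network = channel_network(sites, edges))
}

#' Full site-by-period observation grid
#'
#' @param sites Site table.
#' @param n_periods Number of sampling periods (default 8).
#' @return Canonical (period-major, then site) observation table.
#' @export
generate_observations <- function(sites, n_periods = 8) {
  obs <- expand.grid(site_id = sites$site_id,
                     period_id = sprintf("p%d", seq_len(n_periods)),
                     stringsAsFactors = FALSE)
  canonical_obs(obs)
}

#' Generate synthetic limnological variables
#'
#' Each variable mixes a spatially autocorrelated site component (a random
#' combination of the coarsest half of the supplied eigenfunctions), a
#' random period effect, and white noise, in proportions `spatial_mix`,
#' `temporal_mix` and the remainder. The standardized latent is then mapped
#' to a plausible positive range per variable (lognormal around a
#' field-typical mean; pH stays linear around 7), so the downstream log
#' transform recovers the latent structure.
#'
#' @param sites Site table.
#' @param obs Observation table.
#' @param basis `spatial_basis` used for the spatial component.
#' @param n_vars Number of variables (taken in order from the built-in
#'   catalogue of 13 limnological variables; default 12 keeps pH and
#'   chlorophyll-a).
#' @param spatial_mix,temporal_mix Mixing weights in `[0, 1]`,
#'   `spatial_mix + temporal_mix <= 1`.
#' @param seed Integer seed.
#' @return Matrix (observations x variables) with `"site|period"` rownames
#'   and attribute `"mixes"`.
#' @export
generate_env <- function(sites, obs, basis, n_vars = 12,
                         spatial_mix = 0.5, temporal_mix = 0.3, seed = 1) {
  if (spatial_mix < 0 || temporal_mix < 0 || spatial_mix + temporal_mix > 1)
    stop("mixes must be in [0,1] with spatial_mix + temporal_mix <= 1")
  stopifnot(inherits(basis, "spatial_basis"))
  if (basis$empty) stop("empty spatial basis")
  if (n_vars > nrow(ENV_CATALOGUE)) stop("at most ", nrow(ENV_CATALOGUE), " variables")
  set.seed(seed)
  obs <- canonical_obs(obs)
  n <- nrow(obs)
  V <- basis$vectors[, seq_len(ceiling(ncol(basis$vectors) / 2)), drop = FALSE]
  periods <- sort(unique(obs$period_id))
  noise_w <- 1 - spatial_mix - temporal_mix
  out <- matrix(NA_real_, n, n_vars)
  cat_sub <- ENV_CATALOGUE[seq_len(n_vars), ]
  colnames(out) <- cat_sub$variable
  unit <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v
  for (j in seq_len(n_vars)) {
    site_eff <- drop(V %*% rnorm(ncol(V)))
    zs <- unit(site_eff)[match(obs$site_id, rownames(basis$vectors))]
    zt <- unit(rnorm(length(periods)))[match(obs$period_id, periods)]
    zn <- rnorm(n)
    z <- unit(spatial_mix * zs + temporal_mix * zt + noise_w * zn)
    out[, j] <- if (cat_sub$variable[j] == "pH") 7 + 0.5 * z
                else cat_sub$mu[j] * exp(0.3 * z)
  }
  rownames(out) <- paste(obs$site_id, obs$period_id, sep = "|")
  attr(out, "mixes") <- c(spatial = spatial_mix, temporal = temporal_mix,
                          noise = noise_w)
  out
}

#' Generate a synthetic metacommunity with known signal weights
#'
#' Species respond linearly (on the log-rate scale) to the supplied
#' predictor blocks: the latent matrix is
#' `L = w_env Z_E B_E + w_spa Z_S B_S + w_tmp Z_T B_T + sigma N`, each block
#' standardized to unit variance per latent column and the coefficient
#' matrices `B` drawn once per seed. Abundances are Poisson draws with rate
#' `base_abundance * exp(L - mean(L))` — a Poisson-lognormal model giving
#' realistically overdispersed counts while keeping the linear latent
#' structure that redundancy analysis assumes.
#'
#' @param env,spatial,temporal Row-aligned predictor matrices (observations
#'   in rows); standardized internally.
#' @param w_env,w_spa,w_tmp Nonnegative signal weights.
#' @param n_taxa Number of taxa.
#' @param sigma Latent noise standard deviation.
#' @param base_abundance Target mean count per cell.
#' @param presence_absence Emit 0/1 instead of counts (macrophyte-style
#'   data).
#' @param seed Integer seed.
#' @return Community matrix with attribute `"truth"` (the generating
#'   weights).
#' @export
generate_metacommunity <- function(env, spatial, temporal,
                                   w_env = 1, w_spa = 0, w_tmp = 0,
                                   n_taxa = 20, sigma = 0.5,
                                   base_abundance = 5,
                                   presence_absence = FALSE, seed = 1) {
  stopifnot(w_env >= 0, w_spa >= 0, w_tmp >= 0, sigma >= 0)
  set.seed(seed)
  n <- nrow(as.matrix(env))
  blocks <- list(list(w = w_env, M = env), list(w = w_spa, M = spatial),
                 list(w = w_tmp, M = temporal))
  latent_part <- function(M) {
    Z <- scale(as.matrix(M))
    Z[!is.finite(Z)] <- 0
    L <- Z %*% matrix(rnorm(ncol(Z) * n_taxa), ncol(Z), n_taxa)
    apply(L, 2, function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v)
  }
  L <- matrix(0, n, n_taxa)
  for (b in blocks) {
    P <- latent_part(b$M)  # always drawn: keeps RNG stream weight-independent
    if (b$w > 0) L <- L + b$w * P
  }
  L <- L + sigma * matrix(rnorm(n * n_taxa), n, n_taxa)
  draw <- function(Lcol) rpois(n, base_abundance * exp(Lcol - mean(Lcol)))
  comm <- vapply(seq_len(n_taxa), function(j) draw(L[, j]), numeric(n))
  for (attempt in seq_len(10)) {
    zero <- colSums(comm) == 0
    if (!any(zero)) break
    comm[, zero] <- vapply(which(zero), function(j)
      draw(L[, j] + rnorm(n, 0, 0.5)), numeric(n))
  }
  zero <- colSums(comm) == 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " all-zero taxon column(s)")
    comm <- comm[, !zero, drop = FALSE]
  }
  if (presence_absence) comm <- (comm > 0) * 1
  colnames(comm) <- paste0("taxon_", seq_len(ncol(comm)))
  rownames(comm) <- rownames(as.matrix(env))
  attr(comm, "truth") <- list(w_env = w_env, w_spa = w_spa, w_tmp = w_tmp,
                              sigma = sigma, n_taxa = n_taxa, seed = seed,
                              presence_absence = presence_absence)
  comm
}

#' Synthetic multi-group suite along a dispersal-ability gradient
#'
#' Builds one shared network, environment and temporal design, then
#' generates one community per organism group with environmental weight
#' decreasing and spatial weight increasing linearly with dispersal rank:
#' group 1 (best disperser, phytoplankton-like) has `(w_env, w_spa) = (1, 0)`,
#' the last group (macrophyte-like, emitted as presence/absence) `(0, 1)`.
#' This is the ground-truth analogue of the field pattern the package is
#' designed to detect.
#'
#' @param n_groups Number of groups (>= 4; default 7).
#' @param n_sites,n_periods,n_laterals Network/design sizes.
#' @param n_taxa Taxa per group.
#' @param w_tmp Shared temporal weight.
#' @param sigma Latent noise SD.
#' @param spatial_source `"overland"` (MEM of the overland distances) or a
#'   scenario tag (MEM of that watercourse matrix) for both generation and
#'   the returned predictor block.
#' @param seed Integer master seed.
#' @return List with the shared predictor blocks (`env_pred`, `spatial`,
#'   `temporal`), per-group community matrices (`communities`), the truth
#'   table (`truth`), and the underlying `sites`, `network`, `obs`, `basis`.
#' @export
dispersal_gradient_suite <- function(n_groups = 7, n_sites = 36,
                                     n_periods = 8, n_laterals = 4,
                                     n_taxa = 20, w_tmp = 0.2, sigma = 0.5,
                                     spatial_source = "overland", seed = 1) {
  if (n_groups < 4) stop("need at least 4 groups")
  net <- generate_network(n_sites, n_laterals, seed = seed)
  obs <- generate_observations(net$sites, n_periods)
  D <- if (identical(spatial_source, "overland")) overland_distances(net$sites)
       else watercourse_distances(net$network, spatial_source)
  basis <- select_positive(mem_basis(D))
  env <- generate_env(net$sites, obs, basis, seed = seed + 1)
  env_pred <- collinearity_filter(env_transform(env))
  temporal <- temporal_dummies(obs)
  spatial <- basis$vectors[obs$site_id, , drop = FALSE]
  rownames(spatial) <- rownames(env)

  groups <- if (n_groups == 7) GROUPS7 else paste0("group_", seq_len(n_groups))
  w_env <- seq(1, 0, length.out = n_groups)
  w_spa <- seq(0, 1, length.out = n_groups)
  communities <- lapply(seq_len(n_groups), function(g)
    generate_metacommunity(env_pred, spatial, temporal,
                           w_env = w_env[g], w_spa = w_spa[g], w_tmp = w_tmp,
                           n_taxa = n_taxa, sigma = sigma,
                           presence_absence = (g == n_groups),
                           seed = seed + 100 + g))
  names(communities) <- groups
  truth <- data.frame(group = groups, rank = seq_len(n_groups),
                      w_env = w_env, w_spa = w_spa, w_tmp = w_tmp,
                      stringsAsFactors = FALSE)
  list(sites = net$sites, network = net$network, obs = obs, basis = basis,
       env = env, env_pred = env_pred, spatial = spatial, temporal = temporal,
       communities = communities, truth = truth, seed = seed)
}

#' Partition every group of a gradient suite and correlate E - S with rank
#'
#' @param suite Output of [dispersal_gradient_suite()].
#' @param n_perm Permutations per pure-fraction test (0 skips tests).
#' @param seed Seed offset for the permutation tests.
#' @return List with `partitions`, `es` (E - S per group) and `spearman`
#'   (rho and p of rank vs E - S).
#' @export
run_gradient <- function(suite, n_perm = 0, seed = 1) {
  partitions <- lapply(seq_along(suite$communities), function(g)
    varpart3(hellinger(suite$communities[[g]]), suite$env_pred,
             suite$spatial, suite$temporal,
             n_perm = n_perm, seed = seed + 10 * g))
  names(partitions) <- names(suite$communities)
  es <- es_difference(partitions)
  sp <- spearman_exact(es, setNames(suite$truth$rank, suite$truth$group)[names(es)])
  list(partitions = partitions, es = es, spearman = sp)
}

#' Write a complete synthetic input bundle to disk
#'
#' Emits `sites.csv`, `edges.csv`, `env.csv`, `periods.csv`,
#' `community_<group>.csv` and `truth.json` in the formats the loaders
#' expect, so a full analysis can be replayed from files.
#'
#' @param dir Output directory (created if needed).
#' @param suite Output of [dispersal_gradient_suite()]; generated with
#'   default parameters and `seed` if omitted.
#' @param seed Seed used when `suite` is NULL.
#' @return Invisibly, the directory path.
#' @export
write_synthetic_bundle <- function(dir, suite = NULL, seed = 1) {
  if (is.null(suite)) suite <- dispersal_gradient_suite(seed = seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(suite$sites, file.path(dir, "sites.csv"), row.names = FALSE)
  edges <- suite$network$edges
  edges$scenarios <- vapply(edges$scenarios, paste, character(1), collapse = ";")
  write.csv(edges, file.path(dir, "edges.csv"), row.names = FALSE)
  keys <- do.call(rbind, strsplit(rownames(suite$env), "|", fixed = TRUE))
  env_df <- data.frame(site_id = keys[, 1], period_id = keys[, 2],
                       suite$env, check.names = FALSE, row.names = NULL)
  write.csv(env_df, file.path(dir, "env.csv"), row.names = FALSE)
  write.csv(data.frame(period_id = sort(unique(suite$obs$period_id))),
            file.path(dir, "periods.csv"), row.names = FALSE)
  for (g in names(suite$communities)) {
    cm <- suite$communities[[g]]
    cm_df <- data.frame(site_id = keys[, 1], period_id = keys[, 2],
                        cm, check.names = FALSE, row.names = NULL)
    write.csv(cm_df, file.path(dir, paste0("community_", g, ".csv")),
              row.names = FALSE)
  }
  jsonlite::write_json(
    list(truth = suite$truth, seed = suite$seed,
         note = "synthetic data bundle; not field observations"),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows", pretty = TRUE)
  invisible(dir)
}
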