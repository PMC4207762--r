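canonical_obs <- function(obs) {
  obs$site_id <- as.character(obs$site_id)
  obs$period_id <- as.character(obs$period_id)
  key <- paste(obs$site_id, obs$period_id)
  if (anyDuplicated(key))
    stop("duplicate (site, period) observation: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  obs[order(obs$period_id, obs$site_id), , drop = FALSE]
}

#' Log-transform and standardize limnological variables
#'
#' Applies a base-10 log to every variable except pH (limnological variables
#' are typically right-skewed concentrations or counts; pH is already a log
#' scale), then standardizes every column to zero mean and unit variance.
#'
#' @param env Numeric data.frame/matrix of environmental variables
#'   (observations in rows).
#' @param log_exempt Column names excluded from the log step (default `"pH"`,
#'   matched case-insensitively).
#' @param offset Added before the log for columns containing zeros; the
#'   default 0 makes nonpositive values an error.
#' @return Standardized matrix with attribute `"log_applied"`.
#' @export
env_transform <- function(env, log_exempt = "pH", offset = 0) {
  env <- as.matrix(env)
  if (is.null(colnames(env))) stop("environmental variables must be named")
  logged <- !(tolower(colnames(env)) %in% tolower(log_exempt))
  for (j in which(logged)) {
    v <- env[, j] + offset
    if (any(!is.finite(v)) || any(v <= 0)) {
      bad <- which(!is.finite(v) | v <= 0)[1]
      stop("nonpositive value in variable '", colnames(env)[j],
           "' (row ", bad, "); configure an offset or clean the data")
    }
    env[, j] <- log10(v)
  }
  out <- scale(env)
  if (any(!is.finite(out))) stop("constant environmental column after transform")
  attr(out, "log_applied") <- colnames(env)[logged]
  out
}

#' Greedy collinearity screening
#'
#' While any pairwise Pearson |r| exceeds `r_max`, the member of the
#' worst-offending pair with the larger mean |r| against all remaining
#' variables is removed. Every removal is logged with the triggering pair.
#'
#' @param env Numeric matrix of (transformed) environmental variables.
#' @param r_max Threshold on absolute pairwise correlation (default 0.7).
#' @return Filtered matrix with attribute `"removed"` (a data.frame log).
#' @export
collinearity_filter <- function(env, r_max = 0.7) {
  env <- as.matrix(env)
  if (ncol(env) < 2) stop("need at least 2 variables")
  removed <- data.frame(variable = character(), partner = character(),
                        r = numeric(), stringsAsFactors = FALSE)
  repeat {
    R <- abs(cor(env))
    diag(R) <- 0
    if (max(R) <= r_max) break
    worst <- which(R == max(R), arr.ind = TRUE)[1, ]
    i <- worst[1]; j <- worst[2]
    mean_i <- mean(R[i, -i]); mean_j <- mean(R[j, -j])
    drop_j <- if (mean_j > mean_i) j else if (mean_i > mean_j) i else max(i, j)
    removed <- rbind(removed, data.frame(
      variable = colnames(env)[drop_j],
      partner = colnames(env)[if (drop_j == i) j else i],
      r = max(R), stringsAsFactors = FALSE))
    env <- env[, -drop_j, drop = FALSE]
    if (ncol(env) < 1) stop("collinearity filter would leave no variables")
    if (ncol(env) == 1) break
  }
  attr(env, "removed") <- removed
  env
}

#' Remove chlorophyll-a when predicting algal communities
#'
#' Chlorophyll-a is a proxy for algal biomass, so using it to predict
#' phytoplankton or periphyton composition would be circular; it is removed
#' for those groups and kept for all others.
#'
#' @param env Environmental matrix.
#' @param group Organism-group label.
#' @return `env`, possibly without its chlorophyll column.
#' @export
drop_chlorophyll <- function(env, group) {
  env <- as.matrix(env)
  if (!group %in% c("periphyton", "phytoplankton")) return(env)
  chl <- grep("chlorophyll", colnames(env), ignore.case = TRUE)
  if (!length(chl)) {
    warning("no chlorophyll column found; nothing to drop")
    return(env)
  }
  env[, -chl, drop = FALSE]
}

#' Hellinger transformation of community data
#'
#' `y'_ij = sqrt(y_ij / sum_j y_ij)`: the square root of row-relative
#' abundances, making Euclidean-based ordination appropriate for species
#' data (applies to presence/absence too).
#'
#' @param comm Nonnegative community matrix (observations x taxa).
#' @return Transformed matrix; each row has unit sum of squares.
#' @export
hellinger <- function(comm) {
  comm <- as.matrix(comm)
  if (any(comm < 0)) stop("negative abundances")
  rs <- rowSums(comm)
  if (any(rs == 0)) {
    bad <- which(rs == 0)
    stop("all-zero observation row(s): ",
         paste(rownames(comm)[bad] %||% bad, collapse = ", "),
         "; drop these observations before transforming")
  }
  sqrt(comm / rs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Temporal dummy design matrix
#'
#' One indicator column per sampling period except the last (canonical
#' order), which serves as the reference level; eight periods give seven
#' dummy vectors. Partitioning results do not depend on the reference choice
#' (the column space is unchanged).
#'
#' @param obs Observation table with columns `site_id`, `period_id`.
#' @return Matrix of p-1 dummy columns aligned to the canonical observation
#'   order, with attribute `"obs"` (the canonical table).
#' @export
temporal_dummies <- function(obs) {
  obs <- canonical_obs(obs)
  periods <- sort(unique(obs$period_id))
  p <- length(periods)
  if (p < 2)
    stop("single sampling period: temporal component undefined; ",
         "use a two-matrix (environment vs space) partition instead")
  M <- outer(obs$period_id, periods[-p], "==") * 1
  colnames(M) <- paste0("period_", periods[-p])
  attr(M, "obs") <- obs
  M
}

#' Remove rare taxa (single-site occurrences)
#'
#' A taxon present at exactly one site — pooled over all sampling periods —
#' is removed. Intended for the sensitivity re-analysis, not the main run.
#'
#' @param comm Community matrix (observations x taxa).
#' @param site_id Site id of each observation row.
#' @return Filtered community matrix with attribute `"removed_taxa"`.
#' @export
drop_rare <- function(comm, site_id) {
  comm <- as.matrix(comm)
  stopifnot(length(site_id) == nrow(comm))
  n_sites <- apply(comm > 0, 2, function(pres) length(unique(site_id[pres])))
  keep <- n_sites != 1
  if (!any(keep)) stop("all taxa are single-site occurrences; refusing to drop everything")
  out <- comm[, keep, drop = FALSE]
  attr(out, "removed_taxa") <- colnames(comm)[!keep]
  out
}

#' Align predictors and response to the observation table
#'
#' Spatial eigenfunctions are per-site and constant over periods, so they are
#' replicated across each site's observations; environmental, community and
#' temporal matrices are row-matched to the canonical (period-major, then
#' site) observation order. Observations lacking an environmental or
#' community record are dropped with a warning.
#'
#' @param obs Observation table (`site_id`, `period_id`).
#' @param env Environmental matrix with rows keyed by `(site_id, period_id)`;
#'   pass the keys via `env_keys` (a two-column data.frame) or rownames of
#'   the form `"site|period"`.
#' @param comm Community matrix, keyed like `env` via `comm_keys`.
#' @param spatial A `spatial_basis` (per-site) or per-site matrix with site
#'   rownames.
#' @param temporal Optional output of [temporal_dummies()]; rebuilt from the
#'   final observation set if omitted.
#' @param env_keys,comm_keys Data frames with `site_id`, `period_id` for each
#'   row of `env` / `comm`.
#' @return List with elements `obs`, `env`, `comm`, `spatial`, `temporal`.
#' @export
align_observations <- function(obs, env, comm, spatial, temporal = NULL,
                               env_keys = NULL, comm_keys = NULL) {
  obs <- canonical_obs(obs)
  key <- function(s, p) paste(s, p, sep = "|")
  okey <- key(obs$site_id, obs$period_id)
  ekey <- if (!is.null(env_keys)) key(env_keys$site_id, env_keys$period_id)
          else rownames(env)
  ckey <- if (!is.null(comm_keys)) key(comm_keys$site_id, comm_keys$period_id)
          else rownames(comm)
  if (is.null(ekey) || is.null(ckey))
    stop("env and comm need (site, period) keys (rownames 'site|period' or *_keys)")
  have <- okey %in% ekey & okey %in% ckey
  if (!all(have)) {
    warning("dropping ", sum(!have), " observation(s) with missing records: ",
            paste(utils::head(okey[!have], 5), collapse = ", "))
    obs <- obs[have, , drop = FALSE]
    okey <- okey[have]
  }
  env_a <- as.matrix(env)[match(okey, ekey), , drop = FALSE]
  comm_a <- as.matrix(comm)[match(okey, ckey), , drop = FALSE]
  S <- if (inherits(spatial, "spatial_basis")) spatial$vectors else as.matrix(spatial)
  if (is.null(rownames(S))) stop("spatial basis must carry site ids")
  missing_sites <- setdiff(obs$site_id, rownames(S))
  if (length(missing_sites))
    stop("site(s) absent from spatial basis: ", paste(missing_sites, collapse = ", "))
  spa_a <- S[obs$site_id, , drop = FALSE]
  tmp_a <- temporal_dummies(obs)
  rownames(env_a) <- rownames(comm_a) <- rownames(spa_a) <- rownames(tmp_a) <- okey
  list(obs = obs, env = env_a, comm = comm_a, spatial = spa_a, temporal = tmp_a)
}
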