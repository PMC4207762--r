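CONFIG_KEYS <- c("synthetic", "paths", "scenarios", "use_overland", "use_aem",
                 "aem", "mem", "r_max", "n_perm", "seed", "groups",
                 "rank_schemes")

read_config <- function(config) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  unknown <- setdiff(names(config), CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(scenarios = c("s1", "s2", "s3", "s4"), use_overland = TRUE,
                   use_aem = TRUE, aem = list(scenario = "s3"),
                   mem = list(moran_cut = "expectation"),
                   r_max = 0.7, n_perm = 999, seed = 1)
  for (k in names(defaults)) if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (is.null(config$synthetic) && is.null(config$paths))
    stop("config needs either 'synthetic' parameters or input 'paths'")
  config
}

load_inputs <- function(config) {
  if (!is.null(config$synthetic)) {
    args <- config$synthetic
    args$seed <- config$seed
    suite <- do.call(dispersal_gradient_suite, args)
    keys <- do.call(rbind, strsplit(rownames(suite$env), "|", fixed = TRUE))
    return(list(sites = suite$sites, network = suite$network,
                obs = suite$obs, env = suite$env,
                env_keys = data.frame(site_id = keys[, 1], period_id = keys[, 2],
                                      stringsAsFactors = FALSE),
                communities = suite$communities, truth = suite$truth))
  }
  p <- config$paths
  nw <- load_network(p$sites, p$edges)
  env_df <- read.csv(p$env, check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(c("site_id", "period_id"), names(env_df))
  if (length(miss))
    stop("stage load, env table '", p$env, "': missing column(s) ",
         paste(miss, collapse = ", "))
  env_keys <- env_df[c("site_id", "period_id")]
  env <- as.matrix(env_df[setdiff(names(env_df), c("site_id", "period_id"))])
  rownames(env) <- paste(env_keys$site_id, env_keys$period_id, sep = "|")
  communities <- lapply(p$communities, function(path) {
    cm_df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    cm <- as.matrix(cm_df[setdiff(names(cm_df), c("site_id", "period_id"))])
    rownames(cm) <- paste(cm_df$site_id, cm_df$period_id, sep = "|")
    cm
  })
  obs <- unique(env_keys)
  list(sites = nw$sites, network = nw$network, obs = obs, env = env,
       env_keys = env_keys, communities = communities, truth = NULL)
}

spatial_sources <- function(config, inputs) {
  cut <- config$mem$moran_cut %||% "expectation"
  out <- list()
  if (isTRUE(config$use_overland)) {
    D <- overland_distances(inputs$sites)
    t <- config$mem$truncation %||% mst_truncation(D)
    out$D <- select_positive(mem_basis(D, t), cut = cut)
  }
  for (sc in config$scenarios) {
    W <- watercourse_distances(inputs$network, sc)
    t <- config$mem$truncation %||% mst_truncation(W)
    out[[paste0("W_", sc)]] <- select_positive(mem_basis(W, t), cut = cut)
  }
  if (isTRUE(config$use_aem)) {
    out$AEM <- aem_basis(inputs$network,
                         scenario = config$aem$scenario %||% "s3",
                         origin = config$aem$origin,
                         cut = cut)
  }
  out
}

#' Run the full metacommunity analysis
#'
#' End-to-end orchestration: build spatial eigenfunction bases for every
#' requested distance source (overland MEM, watercourse MEM per scenario,
#' AEM), prepare the environmental and community matrices per organism
#' group, fit the three-way variation partition for every group x source
#' combination, and synthesize the cross-group dispersal analysis. All
#' results are written to `out_dir` as full-precision JSON plus display CSV,
#' with a manifest of every setting used. Identical config + seed gives
#' identical outputs.
#'
#' @param config A named list or YAML path: either `synthetic` (parameter
#'   list for [dispersal_gradient_suite()]) or `paths` (with `sites`,
#'   `edges`, `env`, and a named list `communities`); optional `scenarios`,
#'   `use_overland`, `use_aem`, `aem`, `mem` (`truncation`, `moran_cut`),
#'   `r_max`, `n_perm`, `seed`. Unknown keys are rejected.
#' @param out_dir Results directory (created).
#' @return Invisibly, a list with `partitions` (group -> source ->
#'   `varpart3`), `es`, `robustness`, `manifest`.
#' @export
run_all <- function(config, out_dir) {
  config <- read_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- load_inputs(config)
  sources <- spatial_sources(config, inputs)

  partitions <- list()
  failures <- character()
  for (g in names(inputs$communities)) {
    res_g <- list()
    env_g <- tryCatch({
      e <- drop_chlorophyll(inputs$env, g)
      collinearity_filter(env_transform(e), r_max = config$r_max)
    }, error = function(e)
      stop("stage env_prep, group '", g, "': ", conditionMessage(e)))
    for (src in names(sources)) {
      res_g[[src]] <- tryCatch({
        al <- align_observations(inputs$obs, env_g, inputs$communities[[g]],
                                 sources[[src]])
        vp <- varpart3(hellinger(al$comm), al$env, al$spatial, al$temporal,
                       n_perm = config$n_perm, seed = config$seed)
        write_partition(vp, out_dir, g, src)
        vp
      }, error = function(e) {
        failures <<- c(failures,
                       paste0("stage partition, group '", g, "', source '",
                              src, "': ", conditionMessage(e)))
        NULL
      })
    }
    partitions[[g]] <- res_g
  }
  if (length(failures)) stop(paste(failures, collapse = "\n"))

  es_by_source <- lapply(setNames(names(sources), names(sources)), function(src)
    es_difference(lapply(partitions, `[[`, src)))
  es_df <- data.frame(group = names(es_by_source[[1]]),
                      sapply(es_by_source, identity), check.names = FALSE,
                      row.names = NULL)
  write.csv(es_df, file.path(out_dir, "es_difference.csv"), row.names = FALSE)

  schemes <- if (!is.null(config$rank_schemes)) config$rank_schemes
             else rank_schemes(names(inputs$communities))
  robustness <- rank_robustness(es_by_source, schemes)
  write.csv(robustness, file.path(out_dir, "robustness.csv"), row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("metapart")),
    seed = config$seed, n_perm = config$n_perm, r_max = config$r_max,
    scenarios = config$scenarios, use_overland = config$use_overland,
    use_aem = config$use_aem, aem = config$aem, mem = config$mem,
    moran_cut = config$mem$moran_cut %||% "expectation",
    truncation_rule = if (is.null(config$mem$truncation))
      "MST longest edge" else config$mem$truncation,
    permutation_scheme = "freedman_lane",
    groups = names(inputs$communities),
    sources = names(sources),
    robust_sign = attr(robustness, "robust"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(partitions = partitions, es = es_by_source,
                 robustness = robustness, manifest = manifest))
}

write_partition <- function(vp, out_dir, group, source) {
  stem <- file.path(out_dir, paste0("partition_", group, "_", source))
  jsonlite::write_json(
    list(group = group, source = source,
         fractions = as.list(vp$fractions), p = as.list(vp$p),
         n = vp$n, n_perm = vp$n_perm, seed = vp$seed, scheme = vp$scheme,
         fits = lapply(vp$fits, function(f)
           list(m = f$m, R2 = f$R2, R2adj = f$R2adj))),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  df <- data.frame(component = names(vp$fractions),
                   adj_fraction = unname(vp$fractions),
                   p_value = c(unname(vp$p), rep(NA_real_, 5)))
  write.csv(df, paste0(stem, ".csv"), row.names = FALSE)
}

#' Summarize a completed results directory
#'
#' Builds per-group stacked-fraction tables in percent with display rules
#' mirroring the usual figure convention: values below 0.5% are shown as
#' "0" (display only; stored JSON keeps full precision) and significant pure
#' fractions are starred.
#'
#' @param results_dir Directory written by [run_all()].
#' @param alpha Significance level for the stars.
#' @return List with `partition_table` (long data.frame of display strings
#'   and numeric fractions) and `es_table`.
#' @export
report <- function(results_dir, alpha = 0.05) {
  files <- list.files(results_dir, "^partition_.*\\.json$", full.names = TRUE)
  if (!length(files)) stop("no partition results in '", results_dir, "'")
  rows <- lapply(files, function(f) {
    x <- jsonlite::read_json(f, simplifyVector = TRUE)
    pct <- 100 * unlist(x$fractions)
    p <- unlist(x$p)
    star <- setNames(rep("", length(pct)), names(pct))
    star[names(p)] <- ifelse(!is.na(p) & p <= alpha, "*", "")
    data.frame(group = x$group, source = x$source, component = names(pct),
               percent = unname(pct),
               display = paste0(ifelse(abs(pct) < 0.5, "0",
                                       sprintf("%.1f", pct)),
                                unname(star[names(pct)])),
               stringsAsFactors = FALSE)
  })
  partition_table <- do.call(rbind, rows)
  es_path <- file.path(results_dir, "es_difference.csv")
  es_table <- if (file.exists(es_path))
    read.csv(es_path, check.names = FALSE) else NULL
  list(partition_table = partition_table, es_table = es_table)
}
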