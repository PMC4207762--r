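#' @importFrom stats cor dist p.adjust rnorm rpois runif sd setNames var
#' @importFrom utils read.csv write.csv
NULL

SCENARIOS <- c("s1", "s2", "s3", "s4")

#' Read a site table
#'
#' Sites are sampling locations with projected planar coordinates (metres).
#' Geographic (lat/lon) coordinates are not supported: Euclidean distances on
#' unprojected coordinates are meaningless.
#'
#' @param path CSV file with columns `site_id`, `x`, `y`, `subsystem`.
#' @return A validated `data.frame` of sites.
#' @export
read_sites <- function(path) {
  sites <- read.csv(path, stringsAsFactors = FALSE)
  validate_sites(sites)
}

validate_sites <- function(sites) {
  needed <- c("site_id", "x", "y", "subsystem")
  missing <- setdiff(needed, names(sites))
  if (length(missing))
    stop("site table lacks column(s): ", paste(missing, collapse = ", "))
  sites$site_id <- as.character(sites$site_id)
  if (anyDuplicated(sites$site_id))
    stop("duplicate site_id: ",
         paste(unique(sites$site_id[duplicated(sites$site_id)]), collapse = ", "))
  if (!all(is.finite(sites$x)) || !all(is.finite(sites$y)))
    stop("non-finite site coordinates")
  sites
}

#' Read a channel-network edge table
#'
#' @param path CSV file with columns `node_a`, `node_b`, `length_m`,
#'   `flow_class` (`main_unidirectional` or `lateral_bidirectional`) and
#'   `scenarios` (semicolon-separated subset of `s1;s2;s3;s4`).
#' @return A `data.frame` of edges with a `scenarios` list column.
#' @export
read_edges <- function(path) {
  edges <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("node_a", "node_b", "length_m", "flow_class", "scenarios")
  missing <- setdiff(needed, names(edges))
  if (length(missing))
    stop("edge table lacks column(s): ", paste(missing, collapse = ", "))
  edges$scenarios <- strsplit(as.character(edges$scenarios), ";", fixed = TRUE)
  edges
}

#' Construct a validated channel network
#'
#' The network represents the floodplain's channels: nodes are sites (plus
#' optional non-site junctions), edges are channel segments with a length in
#' metres, a flow class, and the set of dispersal-route scenarios in which
#' they participate. Every scenario's edge subset must connect all sites.
#'
#' @param sites Site table (see [read_sites()]).
#' @param edges Edge table; `scenarios` may be a character vector
#'   (semicolon-separated) or a list of character vectors.
#' @return An object of class `channel_network`.
#' @export
channel_network <- function(sites, edges) {
  sites <- validate_sites(sites)
  if (is.character(edges$scenarios))
    edges$scenarios <- strsplit(edges$scenarios, ";", fixed = TRUE)
  edges$node_a <- as.character(edges$node_a)
  edges$node_b <- as.character(edges$node_b)
  nodes <- unique(c(edges$node_a, edges$node_b))
  unknown_sites <- setdiff(sites$site_id, nodes)
  if (length(unknown_sites))
    stop("site(s) absent from the edge list: ",
         paste(unknown_sites, collapse = ", "))
  if (any(!is.finite(edges$length_m) | edges$length_m <= 0))
    stop("edge lengths must be strictly positive")
  bad_flow <- setdiff(edges$flow_class,
                      c("main_unidirectional", "lateral_bidirectional"))
  if (length(bad_flow))
    stop("unknown flow_class: ", paste(bad_flow, collapse = ", "))
  bad_tags <- setdiff(unlist(edges$scenarios), SCENARIOS)
  if (length(bad_tags))
    stop("unknown scenario tag(s): ", paste(bad_tags, collapse = ", "))

  net <- structure(list(sites = sites, edges = edges,
                        scenarios = intersect(SCENARIOS, unlist(edges$scenarios))),
                   class = "channel_network")
  for (sc in net$scenarios) check_scenario_connected(net, sc)
  net
}

#' @export
print.channel_network <- function(x, ...) {
  cat("Channel network:", nrow(x$sites), "sites,",
      length(unique(c(x$edges$node_a, x$edges$node_b))) - nrow(x$sites),
      "junctions,", nrow(x$edges), "edges\n")
  cat("Scenarios present:", paste(x$scenarios, collapse = ", "), "\n")
  invisible(x)
}

scenario_edges <- function(net, scenario) {
  keep <- vapply(net$edges$scenarios, function(s) scenario %in% s, logical(1))
  net$edges[keep, , drop = FALSE]
}

scenario_graph <- function(net, scenario) {
  e <- scenario_edges(net, scenario)
  if (!nrow(e)) stop("scenario '", scenario, "' has no edges")
  igraph::graph_from_data_frame(
    data.frame(from = e$node_a, to = e$node_b, weight = e$length_m),
    directed = FALSE)
}

check_scenario_connected <- function(net, scenario) {
  g <- scenario_graph(net, scenario)
  # sites missing from the scenario subgraph form their own components
  missing <- setdiff(net$sites$site_id, igraph::V(g)$name)
  comp <- igraph::components(g)
  memb <- split(names(comp$membership), comp$membership)
  site_comps <- Filter(function(m) any(m %in% net$sites$site_id), memb)
  if (length(missing) || length(site_comps) > 1) {
    if (length(missing)) site_comps <- c(site_comps, list(missing))
    stop("scenario '", scenario, "' does not connect all sites; components: ",
         paste(vapply(site_comps,
                      function(m) paste0("{", paste(intersect(m, net$sites$site_id),
                                                    collapse = ","), "}"),
                      character(1)),
               collapse = " "))
  }
  invisible(TRUE)
}

#' Load and validate a network from CSV files
#'
#' @param site_table_path,edge_table_path Paths to the site and edge CSVs.
#' @return A list with elements `sites` and `network`.
#' @export
load_network <- function(site_table_path, edge_table_path) {
  sites <- read_sites(site_table_path)
  edges <- read_edges(edge_table_path)
  list(sites = sites, network = channel_network(sites, edges))
}

new_site_dist <- function(values, site_ids, kind, scenario = NA_character_) {
  dimnames(values) <- list(site_ids, site_ids)
  structure(values, kind = kind, scenario = scenario, class = c("site_dist", "matrix"))
}

#' Overland (Euclidean) between-site distances
#'
#' @param sites Site table with projected coordinates in metres.
#' @return A symmetric `site_dist` matrix, kind `"overland_D"`.
#' @export
overland_distances <- function(sites) {
  sites <- validate_sites(sites)
  if (nrow(sites) < 2) stop("need at least 2 sites")
  d <- as.matrix(dist(cbind(sites$x, sites$y)))
  new_site_dist(d, sites$site_id, "overland_D")
}

#' Watercourse between-site distances for one dispersal scenario
#'
#' Shortest-path distances over the scenario's edge subset, with all edges
#' traversable in both directions; flow directionality enters the analysis
#' only through the asymmetric eigenvector maps ([aem_basis()]). Distances are
#' reported between sites only; junction nodes merely route paths.
#'
#' @param net A `channel_network`.
#' @param scenario One of `"s1" ... "s4"`.
#' @return A symmetric `site_dist` matrix, kind `"watercourse_W"`.
#' @export
watercourse_distances <- function(net, scenario = "s1") {
  stopifnot(inherits(net, "channel_network"))
  scenario <- match.arg(scenario, SCENARIOS)
  check_scenario_connected(net, scenario)
  g <- scenario_graph(net, scenario)
  ids <- net$sites$site_id
  d <- igraph::distances(g, v = ids, to = ids, weights = igraph::E(g)$weight)
  d <- d[ids, ids]
  new_site_dist(unname(d), ids, "watercourse_W", scenario)
}

#' The five distance matrices: one overland plus four watercourse scenarios
#'
#' @param net A `channel_network` carrying all four scenario tags.
#' @return Named list `D`, `W_s1` ... `W_s4` of `site_dist` matrices with a
#'   common site ordering.
#' @export
scenario_suite <- function(net) {
  stopifnot(inherits(net, "channel_network"))
  missing <- setdiff(SCENARIOS, net$scenarios)
  if (length(missing))
    stop("network lacks scenario tag(s): ", paste(missing, collapse = ", "))
  out <- c(list(D = overland_distances(net$sites)),
           setNames(lapply(SCENARIOS, watercourse_distances, net = net),
                    paste0("W_", SCENARIOS)))
  out
}

#' Write a distance matrix as square CSV
#'
#' @param d A `site_dist` matrix.
#' @param path Output CSV path (site ids as header row and first column).
#' @export
write_site_dist <- function(d, path) {
  write.csv(as.data.frame(unclass(d)), path, row.names = TRUE)
}
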