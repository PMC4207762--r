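#' Minimum-spanning-tree truncation distance
#'
#' The longest edge of a minimum spanning tree of the complete graph weighted
#' by the distance matrix: the smallest threshold at which the "neighbours
#' within t" graph is guaranteed connected. This is the conventional default
#' truncation for distance-based Moran's eigenvector maps.
#'
#' @param D A symmetric distance matrix (`site_dist` or plain matrix).
#' @return Truncation distance in the units of `D` (metres).
#' @export
mst_truncation <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2) stop("need at least 2 sites")
  D <- (D + t(D)) / 2  # remove floating-point asymmetry from path algorithms
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  mst <- igraph::mst(g, weights = igraph::E(g)$weight)
  max(igraph::E(mst)$weight)
}

#' Moran's I spatial autocorrelation coefficient
#'
#' `I = (n / sum(W)) * sum_ij(w_ij z_i z_j) / sum(z_i^2)` with
#' `z = v - mean(v)`. Its expectation under no autocorrelation is
#' `-1/(n-1)`.
#'
#' @param v Numeric vector (non-constant).
#' @param W n-by-n spatial weight matrix, zero diagonal, at least one positive
#'   off-diagonal entry.
#' @return Moran's I.
#' @export
morans_I <- function(v, W) {
  W <- as.matrix(W)
  n <- length(v)
  stopifnot(nrow(W) == n, ncol(W) == n)
  diag(W) <- 0
  s0 <- sum(W)
  if (s0 <= 0) stop("empty weight matrix")
  z <- v - mean(v)
  ss <- sum(z^2)
  if (ss < .Machine$double.eps * n) stop("constant vector: Moran's I undefined")
  (n / s0) * as.numeric(t(z) %*% W %*% z) / ss
}

new_spatial_basis <- function(vectors, eigenvalues, moran, method, source,
                              truncation = NA_real_, weights = NULL,
                              site_ids = NULL, n_dropped = 0L) {
  colnames(vectors) <- if (ncol(vectors))
    paste0(method, seq_len(ncol(vectors))) else character(0)
  rownames(vectors) <- site_ids
  structure(list(vectors = vectors, eigenvalues = eigenvalues,
                 moran_I = moran, method = method, source = source,
                 truncation = truncation, weights = weights,
                 site_ids = site_ids, n_dropped = n_dropped,
                 empty = ncol(vectors) == 0L),
            class = "spatial_basis")
}

#' @export
print.spatial_basis <- function(x, ...) {
  cat(x$method, " spatial basis (", x$source, "): ",
      ncol(x$vectors), " eigenfunctions for ", length(x$site_ids), " sites",
      if (x$n_dropped) paste0(" (", x$n_dropped, " dropped by Moran's I cut)"),
      "\n", sep = "")
  if (!is.na(x$truncation)) cat("truncation t =", format(x$truncation), "m\n")
  invisible(x)
}

#' Distance-based Moran's eigenvector maps (dbMEM)
#'
#' Builds the truncated distance matrix (entries beyond `t` replaced by
#' `4 t`), applies the principal-coordinates transformation
#' `A = -(1/2) D*^2`, double-centres it, and eigendecomposes. Eigenvectors
#' with numerically non-zero eigenvalue are retained, unit-normed, and sorted
#' by descending eigenvalue; each gets a Moran's I computed with binary
#' neighbour weights (`w_ij = 1` iff `0 < d_ij <= t`). No autocorrelation
#' filtering is applied here — see [select_positive()].
#'
#' @param D Symmetric distance matrix.
#' @param t Truncation distance; defaults to [mst_truncation()] of `D`.
#' @param tol Relative eigenvalue tolerance for dropping null axes.
#' @return A `spatial_basis` of method `"MEM"`.
#' @export
mem_basis <- function(D, t = mst_truncation(D), tol = 1e-9) {
  kind <- attr(D, "kind"); scen <- attr(D, "scenario")
  ids <- rownames(as.matrix(D))
  D <- unname(as.matrix(D))
  D <- (D + t(D)) / 2
  n <- nrow(D)
  if (t <= 0) stop("truncation distance must be positive")
  W <- (D > 0 & D <= t) * 1
  g <- igraph::graph_from_adjacency_matrix(W, mode = "max")
  if (igraph::components(g)$no > 1)
    stop("connectivity graph is disconnected at t = ", format(t))
  Dstar <- ifelse(D <= t, D, 4 * t)
  diag(Dstar) <- 0
  A <- -0.5 * Dstar^2
  G <- dbl_center(A)
  eig <- eigen(G, symmetric = TRUE)
  keep <- abs(eig$values) > tol * max(abs(eig$values))
  if (!any(keep)) stop("all eigenvalues numerically zero")
  vals <- eig$values[keep]
  vecs <- eig$vectors[, keep, drop = FALSE]
  ord <- order(vals, decreasing = TRUE)
  vals <- vals[ord]
  vecs <- vecs[, ord, drop = FALSE]
  vecs <- sweep(vecs, 2, sqrt(colSums(vecs^2)), "/")
  moran <- apply(vecs, 2, morans_I, W = W)
  src <- if (!is.null(kind) && identical(kind, "watercourse_W"))
    paste0("watercourse_", scen) else if (!is.null(kind)) kind else "distance"
  new_spatial_basis(vecs, vals, moran, "MEM", src, truncation = t,
                    weights = W, site_ids = ids)
}

dbl_center <- function(A) {
  r <- rowMeans(A); c <- colMeans(A); g <- mean(A)
  A - outer(r, rep(1, ncol(A))) - outer(rep(1, nrow(A)), c) + g
}

#' Keep eigenfunctions with positive spatial autocorrelation
#'
#' Retains columns whose Moran's I exceeds the no-autocorrelation expectation
#' `E(I) = -1/(n-1)` (or zero, with `cut = "zero"`). Order is preserved; the
#' number dropped is recorded. An empty result is allowed and flagged.
#'
#' @param basis A `spatial_basis`.
#' @param cut `"expectation"` (default, `I > -1/(n-1)`) or `"zero"` (`I > 0`).
#' @return A filtered `spatial_basis`.
#' @export
select_positive <- function(basis, cut = c("expectation", "zero")) {
  stopifnot(inherits(basis, "spatial_basis"))
  cut <- match.arg(cut)
  n <- length(basis$site_ids)
  thresh <- if (cut == "expectation") -1 / (n - 1) else 0
  keep <- basis$moran_I > thresh
  out <- new_spatial_basis(basis$vectors[, keep, drop = FALSE],
                           basis$eigenvalues[keep], basis$moran_I[keep],
                           basis$method, basis$source,
                           truncation = basis$truncation,
                           weights = basis$weights,
                           site_ids = basis$site_ids,
                           n_dropped = basis$n_dropped + sum(!keep))
  out
}

orient_edges <- function(net, scenario, lateral_orientation = NULL) {
  e <- scenario_edges(net, scenario)
  from <- e$node_a; to <- e$node_b
  if (!is.null(lateral_orientation)) {
    for (k in which(e$flow_class == "lateral_bidirectional")) {
      key <- paste(e$node_a[k], e$node_b[k], sep = "->")
      rev_key <- paste(e$node_b[k], e$node_a[k], sep = "->")
      if (!is.null(lateral_orientation[[rev_key]]) ||
          identical(lateral_orientation[[key]], "reverse")) {
        from[k] <- e$node_b[k]; to[k] <- e$node_a[k]
      }
    }
  }
  data.frame(from = from, to = to, length_m = e$length_m,
             flow_class = e$flow_class, stringsAsFactors = FALSE)
}

#' Asymmetric eigenvector maps (AEM) from a directed channel network
#'
#' Main-river edges are oriented downstream (as listed in the edge table,
#' `node_a` upstream of `node_b`); lateral channels follow
#' `lateral_orientation`. The oriented scenario subgraph must give every site
#' a unique directed path from the origin (i.e., be an out-tree). The
#' sites-by-edges incidence matrix `B` (`B[i,k] = 1` iff edge `k` lies on the
#' path from origin to site `i`) is column-centred and decomposed by SVD; the
#' left singular vectors with non-null singular value are the eigenfunctions,
#' with squared singular values stored as eigenvalues. Moran's I uses the
#' symmetrised adjacency of the oriented subgraph restricted to sites, and
#' eigenfunctions with positive autocorrelation are retained via
#' [select_positive()].
#'
#' @param net A `channel_network`.
#' @param scenario Scenario tag whose subgraph is used.
#' @param origin Origin node id; defaults to the most upstream
#'   main-river node (a main edge tail that is never a main edge head).
#' @param lateral_orientation Named list mapping `"a->b"` edge keys to
#'   `"forward"`/`"reverse"`; unlisted laterals keep their listed direction.
#' @param tol Relative singular-value tolerance.
#' @param cut Moran's I cut passed to [select_positive()].
#' @param select Apply the positive-autocorrelation selection (default). With
#'   `FALSE` the full basis is returned; its column space (unlike the
#'   selected subset when singular values are degenerate) is invariant to
#'   edge-list ordering.
#' @return A `spatial_basis` of method `"AEM"`.
#' @export
aem_basis <- function(net, scenario = "s3", origin = NULL,
                      lateral_orientation = NULL, tol = 1e-9,
                      cut = c("expectation", "zero"), select = TRUE) {
  stopifnot(inherits(net, "channel_network"))
  cut <- match.arg(cut)
  e <- orient_edges(net, scenario, lateral_orientation)
  g <- igraph::graph_from_data_frame(e[c("from", "to")], directed = TRUE)
  if (!igraph::is_dag(g)) stop("oriented scenario subgraph contains a cycle")
  if (is.null(origin)) {
    main <- e[e$flow_class == "main_unidirectional", ]
    heads <- setdiff(main$from, main$to)
    heads <- heads[order(match(heads, net$sites$site_id))]
    if (!length(heads)) stop("cannot infer origin: no main-river source node")
    origin <- heads[1]
  }
  ids <- net$sites$site_id
  vnames <- igraph::V(g)$name
  if (!origin %in% vnames) stop("origin '", origin, "' is not in the scenario subgraph")

  # unique directed path from origin to each site
  m <- nrow(e)
  B <- matrix(0, length(ids), m, dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    if (ids[i] == origin) next
    if (!ids[i] %in% vnames)
      stop("site '", ids[i], "' is not in the scenario subgraph")
    paths <- igraph::all_simple_paths(g, from = origin, to = ids[i], mode = "out")
    if (length(paths) == 0)
      stop("site '", ids[i], "' is unreachable from origin '", origin, "'")
    if (length(paths) > 1)
      stop("multiple directed paths from origin to site '", ids[i],
           "'; split the network by dispersal scenario so each route is unique")
    p <- names(paths[[1]])
    for (k in seq_len(length(p) - 1)) {
      idx <- which(e$from == p[k] & e$to == p[k + 1])
      B[i, idx[1]] <- 1
    }
  }
  Bc <- scale(B, center = TRUE, scale = FALSE)
  sv <- svd(Bc)
  keep <- sv$d > tol * max(sv$d)
  if (!any(keep)) stop("all singular values numerically zero")
  vecs <- sv$u[, keep, drop = FALSE]
  vals <- sv$d[keep]^2

  # symmetrised site-to-site adjacency of the oriented subgraph
  W <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  site_edges <- e$from %in% ids & e$to %in% ids
  for (k in which(site_edges)) {
    W[e$from[k], e$to[k]] <- 1
    W[e$to[k], e$from[k]] <- 1
  }
  moran <- apply(vecs, 2, morans_I, W = W)
  basis <- new_spatial_basis(vecs, vals, moran, "AEM",
                             paste0("aem_", scenario),
                             weights = W, site_ids = ids)
  if (select) select_positive(basis, cut = cut) else basis
}

#' Write a spatial basis as CSV plus metadata JSON
#'
#' @param basis A `spatial_basis`.
#' @param path Output CSV path; metadata goes to `<path>.meta.json`.
#' @export
write_spatial_basis <- function(basis, path) {
  df <- data.frame(site_id = basis$site_ids, basis$vectors,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  meta <- list(method = basis$method, source = basis$source,
               eigenvalues = basis$eigenvalues, moran_I = basis$moran_I,
               truncation = basis$truncation, n_dropped = basis$n_dropped)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
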