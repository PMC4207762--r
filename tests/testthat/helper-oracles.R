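# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths.

# all simple paths between two nodes by exhaustive DFS; returns min total length
brute_shortest <- function(edges, from, to) {
  best <- Inf
  walk <- function(node, visited, len) {
    if (len >= best) return(invisible(NULL))
    if (node == to) { best <<- len; return(invisible(NULL)) }
    inc <- which(edges$node_a == node | edges$node_b == node)
    for (k in inc) {
      nxt <- if (edges$node_a[k] == node) edges$node_b[k] else edges$node_a[k]
      if (!nxt %in% visited) walk(nxt, c(visited, nxt), len + edges$length_m[k])
    }
  }
  walk(from, from, 0)
  best
}

# smallest threshold t such that the "distance <= t" graph is connected,
# found by scanning sorted unique distances with a hand-rolled BFS
connect_threshold <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  for (t in sort(unique(D[upper.tri(D)]))) {
    adj <- D <= t & D > 0
    seen <- c(1L); frontier <- c(1L)
    while (length(frontier)) {
      nxt <- setdiff(which(apply(adj[frontier, , drop = FALSE], 2, any)), seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    if (length(seen) == n) return(t)
  }
  stop("disconnected")
}

# column-wise ordinary-least-squares R2: explained SS over total SS of Y
ols_r2_oracle <- function(Y, X) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  ss_exp <- 0; ss_tot <- 0
  for (j in seq_len(ncol(Y))) {
    fit <- lm(Y[, j] ~ X)
    ss_exp <- ss_exp + sum((fitted(fit) - mean(Y[, j]))^2)
    ss_tot <- ss_tot + sum((Y[, j] - mean(Y[, j]))^2)
  }
  ss_exp / ss_tot
}

# explicit dbMEM construction for comparison with mem_basis()
mem_oracle <- function(D, t) {
  D <- as.matrix(D)
  Dstar <- ifelse(D <= t, D, 4 * t); diag(Dstar) <- 0
  A <- -0.5 * Dstar^2
  n <- nrow(A)
  H <- diag(n) - matrix(1 / n, n, n)
  eigen(H %*% A %*% H, symmetric = TRUE)
}

# small fixture: 3 sites on a path, all scenario tags
path3_network <- function() {
  sites <- data.frame(site_id = c("A", "B", "C"),
                      x = c(0, 10, 15), y = c(0, 0, 0),
                      subsystem = "main", stringsAsFactors = FALSE)
  edges <- data.frame(node_a = c("A", "B"), node_b = c("B", "C"),
                      length_m = c(10, 5),
                      flow_class = "main_unidirectional",
                      scenarios = "s1;s2;s3;s4", stringsAsFactors = FALSE)
  channel_network(sites, edges)
}

# 8-node fixture with two junction nodes and several loops
junction_network <- function() {
  sites <- data.frame(site_id = paste0("S", 1:6),
                      x = c(0, 2, 4, 0, 2, 4) * 1000,
                      y = c(0, 0, 0, 3, 3, 3) * 1000,
                      subsystem = rep(c("parana", "baia"), each = 3),
                      stringsAsFactors = FALSE)
  edges <- data.frame(
    node_a = c("S1", "S2", "S4", "S5", "S1", "J1", "S3", "J2"),
    node_b = c("S2", "S3", "S5", "S6", "J1", "S4", "J2", "S6"),
    length_m = c(2400, 2300, 2500, 2200, 1700, 1600, 1800, 1900),
    flow_class = c(rep("main_unidirectional", 4),
                   rep("lateral_bidirectional", 4)),
    scenarios = c(rep("s1;s2;s3;s4", 4),
                  "s1;s3;s4", "s1;s3;s4", "s1;s2;s4", "s1;s2;s4"),
    stringsAsFactors = FALSE)
  list(sites = sites, network = channel_network(sites, edges))
}

expect_same_subspace <- function(U, V, tol = 1e-8) {
  # equal column spaces <=> equal projection matrices
  Pu <- U %*% solve(crossprod(U), t(U))
  Pv <- V %*% solve(crossprod(V), t(V))
  expect_lt(max(abs(Pu - Pv)), tol)
}
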