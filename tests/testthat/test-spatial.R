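test_that("MST truncation equals the smallest connecting threshold", {
  line <- as.matrix(dist(c(0, 1, 10)))
  expect_equal(mst_truncation(line), 9)

  equi <- matrix(7, 3, 3); diag(equi) <- 0
  expect_equal(mst_truncation(equi), 7)

  set.seed(21)
  pts <- cbind(runif(8, 0, 50), runif(8, 0, 50))
  D <- as.matrix(dist(pts))
  expect_equal(mst_truncation(D), connect_threshold(D))
})

test_that("mem_basis on two sites yields the single zero-sum direction", {
  D <- matrix(c(0, 6, 6, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  b <- mem_basis(D, t = 6)
  expect_equal(ncol(b$vectors), 1)
  v <- b$vectors[, 1]
  expect_equal(abs(unname(v)), rep(1 / sqrt(2), 2), tolerance = 1e-12)
  expect_equal(sum(v), 0, tolerance = 1e-12)
})

test_that("MEM eigenvectors are zero-sum, unit-norm and mutually orthogonal", {
  net <- generate_network(15, 3, seed = 4)
  b <- mem_basis(overland_distances(net$sites))
  expect_equal(unname(colSums(b$vectors)), rep(0, ncol(b$vectors)),
               tolerance = 1e-8)
  G <- crossprod(b$vectors)
  expect_equal(G, diag(ncol(b$vectors)), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(b$eigenvalues) <= 1e-9))
})

test_that("mem_basis matches a dense eigendecomposition of the explicit centred matrix", {
  # 5 equidistant sites on a line
  D <- as.matrix(dist(seq(0, 40, by = 10)))
  dimnames(D) <- list(paste0("s", 1:5), paste0("s", 1:5))
  t <- 10
  b <- mem_basis(D, t = t)
  oracle <- mem_oracle(D, t)
  keep <- abs(oracle$values) > 1e-9 * max(abs(oracle$values))
  expect_equal(b$eigenvalues, sort(oracle$values[keep], decreasing = TRUE),
               tolerance = 1e-8)
  for (k in seq_len(ncol(b$vectors))) {
    ov <- oracle$vectors[, keep, drop = FALSE][, k]
    ov <- ov / sqrt(sum(ov^2))
    expect_equal(abs(sum(b$vectors[, k] * ov)), 1, tolerance = 1e-8)
  }
})

test_that("Moran's I follows the formula and rejects degenerate input", {
  # alternating values on a 4-cycle give perfect negative autocorrelation
  W <- matrix(0, 4, 4)
  W[cbind(1:4, c(2, 3, 4, 1))] <- 1
  W <- W + t(W)
  expect_equal(morans_I(c(1, -1, 1, -1), W), -1, tolerance = 1e-12)

  skip_if_not_installed("ape")
  set.seed(31)
  v <- rnorm(10)
  Wr <- matrix(runif(100) < 0.4, 10, 10) * 1
  Wr <- Wr * upper.tri(Wr); Wr <- Wr + t(Wr)
  # ape row-standardizes internally; feed morans_I the same weights
  Wn <- Wr / rowSums(Wr)
  expect_equal(morans_I(v, Wn),
               ape::Moran.I(v, Wr, scaled = FALSE)$observed,
               tolerance = 1e-10)

  expect_error(morans_I(rep(3, 5), Wr[1:5, 1:5]), "constant")
  expect_error(morans_I(v, matrix(0, 10, 10)), "empty")
})

test_that("the leading MEM eigenfunction is spatially smooth (positive I)", {
  D <- as.matrix(dist(seq(0, 90, by = 10)))
  dimnames(D) <- list(paste0("s", 1:10), paste0("s", 1:10))
  b <- mem_basis(D, t = 10)
  n <- 10
  expect_gt(b$moran_I[1], -1 / (n - 1))
  # on a regular transect, retained positive-I eigenfunctions go coarse -> fine
  sel <- select_positive(b)
  expect_true(all(diff(sel$moran_I) <= 1e-9))
})

test_that("select_positive filters by the E(I) threshold, is idempotent, flags empty", {
  net <- generate_network(12, 2, seed = 8)
  b <- mem_basis(overland_distances(net$sites))
  n <- nrow(net$sites)
  sel <- select_positive(b)
  expect_equal(ncol(sel$vectors), sum(b$moran_I > -1 / (n - 1)))
  expect_identical(sel$moran_I, b$moran_I[b$moran_I > -1 / (n - 1)])
  sel2 <- select_positive(sel)
  expect_equal(sel2$vectors, sel$vectors)
  expect_equal(sel2$n_dropped, sel$n_dropped)
  # stricter zero cut drops at least as many
  expect_lte(ncol(select_positive(b, cut = "zero")$vectors), ncol(sel$vectors))
})

test_that("AEM encodes nested directed paths and matches an explicit SVD", {
  sites <- data.frame(site_id = c("O", "A", "B"), x = c(0, 1, 2) * 1000, y = 0,
                      subsystem = "m", stringsAsFactors = FALSE)
  edges <- data.frame(node_a = c("O", "A"), node_b = c("A", "B"),
                      length_m = 1000, flow_class = "main_unidirectional",
                      scenarios = "s1;s2;s3;s4", stringsAsFactors = FALSE)
  net <- channel_network(sites, edges)
  a <- aem_basis(net, "s1", origin = "O")
  # oracle: rows O:(0,0), A:(1,0), B:(1,1), column-centred, SVD
  B <- rbind(O = c(0, 0), A = c(1, 0), B = c(1, 1))
  Bc <- scale(B, scale = FALSE)
  sv <- svd(Bc)
  keep <- sv$d > 1e-9 * max(sv$d)
  U <- sv$u[, keep, drop = FALSE]
  # same column space (selection keeps both smooth axes here or a subset of U)
  for (k in seq_len(ncol(a$vectors))) {
    proj <- drop(U %*% crossprod(U, a$vectors[, k]))
    expect_equal(unname(proj), unname(a$vectors[, k]), tolerance = 1e-8)
  }
  expect_equal(unname(colSums(a$vectors)), rep(0, ncol(a$vectors)),
               tolerance = 1e-10)
})

test_that("AEM errors on unreachable sites and ambiguous routes", {
  sites <- data.frame(site_id = c("O", "A", "B"), x = c(0, 1, 2) * 1000, y = 0,
                      subsystem = "m", stringsAsFactors = FALSE)
  # B only reachable against the flow
  edges <- data.frame(node_a = c("O", "B"), node_b = c("A", "A"),
                      length_m = 1000, flow_class = "main_unidirectional",
                      scenarios = "s1;s2;s3;s4", stringsAsFactors = FALSE)
  net <- channel_network(sites, edges)
  expect_error(aem_basis(net, "s1", origin = "O"), "unreachable.*'B'|'B'.*unreachable")

  # two parallel routes O->A make the path ambiguous
  sites2 <- data.frame(site_id = c("O", "M", "A"), x = c(0, 1, 2) * 1000,
                       y = c(0, 500, 0), subsystem = "m",
                       stringsAsFactors = FALSE)
  edges2 <- data.frame(node_a = c("O", "M", "O"), node_b = c("M", "A", "A"),
                       length_m = c(1000, 1000, 2000),
                       flow_class = c("main_unidirectional",
                                      "main_unidirectional",
                                      "lateral_bidirectional"),
                       scenarios = "s1;s2;s3;s4", stringsAsFactors = FALSE)
  net2 <- channel_network(sites2, edges2)
  expect_error(aem_basis(net2, "s1", origin = "O"), "multiple directed paths")
})

test_that("AEM basis is invariant to edge-list ordering", {
  gen <- generate_network(14, 3, seed = 6)
  # selection on a degenerate singular space is order-sensitive, so the
  # invariant object is the full (unselected) basis
  a1 <- aem_basis(gen$network, "s3", select = FALSE)
  net_shuffled <- gen$network
  set.seed(2)
  net_shuffled$edges <- net_shuffled$edges[sample(nrow(net_shuffled$edges)), ]
  a2 <- aem_basis(net_shuffled, "s3", select = FALSE)
  expect_same_subspace(a1$vectors, a2$vectors)
  expect_equal(sort(a1$eigenvalues), sort(a2$eigenvalues), tolerance = 1e-8)
})
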