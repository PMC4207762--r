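test_that("generated networks are deterministic, connected in every scenario", {
  g1 <- generate_network(36, 4, seed = 7)
  g2 <- generate_network(36, 4, seed = 7)
  expect_identical(g1$sites, g2$sites)
  expect_identical(g1$network$edges, g2$network$edges)
  expect_equal(nrow(g1$sites), 36)
  # channel_network() already validates per-scenario connectivity; assert
  # the suite is computable for all five sources
  suite <- scenario_suite(g1$network)
  expect_length(suite, 5)

  g3 <- generate_network(36, 4, seed = 8)
  expect_false(identical(g1$network$edges$length_m, g3$network$edges$length_m))

  expect_error(generate_network(36, 0, seed = 1), "cannot connect")
  expect_error(generate_network(4, 2, seed = 1), "at least 6")
})

test_that("synthetic environmental variables honour the mixing weights", {
  net <- generate_network(36, 4, seed = 2)
  obs <- generate_observations(net$sites, 8)
  b <- select_positive(mem_basis(overland_distances(net$sites)))

  env <- generate_env(net$sites, obs, b, seed = 3)
  expect_identical(env, generate_env(net$sites, obs, b, seed = 3))
  expect_true(all(env > 0))
  expect_true(all(c("pH", "chlorophyll_a") %in% colnames(env)))

  # spatial_mix = 0: variables uncorrelated with the MEM axes
  env0 <- generate_env(net$sites, obs, b, spatial_mix = 0,
                       temporal_mix = 0, seed = 4)
  spa <- b$vectors[obs$site_id, , drop = FALSE]
  cors <- abs(cor(log10(env0[, colnames(env0) != "pH"]), spa))
  expect_lt(max(cors), 0.3)

  # spatial_mix = 1: latent (log-scale, centred) lies in the MEM half-span
  env1 <- generate_env(net$sites, obs, b, spatial_mix = 1,
                       temporal_mix = 0, seed = 5)
  V <- b$vectors[, seq_len(ceiling(ncol(b$vectors) / 2)), drop = FALSE]
  Vo <- V[obs$site_id, , drop = FALSE]
  Q <- qr.Q(qr(scale(Vo, scale = FALSE)))
  z <- scale(log10(env1[, "conductivity"]), scale = FALSE)
  resid <- z - Q %*% crossprod(Q, z)
  expect_lt(max(abs(resid)), 1e-8)

  expect_error(generate_env(net$sites, obs, b, spatial_mix = 0.8,
                            temporal_mix = 0.5), "mixes")
})

test_that("synthetic metacommunities are integer counts (or 0/1) and deterministic", {
  net <- generate_network(16, 3, seed = 6)
  obs <- generate_observations(net$sites, 3)
  b <- select_positive(mem_basis(overland_distances(net$sites)))
  env <- generate_env(net$sites, obs, b, seed = 7)
  ep <- env_transform(env)
  tm <- temporal_dummies(obs)
  spa <- b$vectors[obs$site_id, , drop = FALSE]
  rownames(spa) <- rownames(env)

  cm <- generate_metacommunity(ep, spa, tm, w_env = 1, w_spa = 0.3,
                               w_tmp = 0.2, n_taxa = 15, seed = 8)
  expect_true(all(cm >= 0))
  expect_true(all(cm == round(cm)))
  expect_identical(cm, generate_metacommunity(ep, spa, tm, w_env = 1,
                                              w_spa = 0.3, w_tmp = 0.2,
                                              n_taxa = 15, seed = 8))
  pa <- generate_metacommunity(ep, spa, tm, w_env = 0.5, w_spa = 0.5,
                               presence_absence = TRUE, n_taxa = 10, seed = 9)
  expect_true(all(pa %in% c(0, 1)))
  truth <- attr(cm, "truth")
  expect_equal(truth$w_env, 1)
  expect_equal(truth$w_spa, 0.3)
})

test_that("all-noise communities leave the variation unexplained", {
  net <- generate_network(16, 3, seed = 10)
  obs <- generate_observations(net$sites, 3)
  b <- select_positive(mem_basis(overland_distances(net$sites)))
  env <- generate_env(net$sites, obs, b, spatial_mix = 0, temporal_mix = 0,
                      seed = 11)
  ep <- collinearity_filter(env_transform(env))
  tm <- temporal_dummies(obs)
  spa <- b$vectors[obs$site_id, , drop = FALSE]
  rownames(spa) <- rownames(env)
  cm <- generate_metacommunity(ep, spa, tm, w_env = 0, w_spa = 0, w_tmp = 0,
                               sigma = 0.5, n_taxa = 12, seed = 12)
  vp <- varpart3(hellinger(cm), ep, spa, tm, n_perm = 0)
  expect_gt(unname(vp$fractions["U"]), 0.8)
  expect_lt(max(abs(vp$fractions[c("E", "S", "T")])), 0.1)
})

test_that("increasing the spatial weight does not decrease the expected pure-S fraction", {
  net <- generate_network(16, 3, seed = 13)
  obs <- generate_observations(net$sites, 3)
  b <- select_positive(mem_basis(overland_distances(net$sites)))
  env <- generate_env(net$sites, obs, b, spatial_mix = 0, temporal_mix = 0.2,
                      seed = 14)
  ep <- collinearity_filter(env_transform(env))
  tm <- temporal_dummies(obs)
  spa <- b$vectors[obs$site_id, , drop = FALSE]
  rownames(spa) <- rownames(env)
  mean_S <- vapply(c(0.2, 0.6, 1.0), function(w) {
    mean(vapply(1:8, function(s) {
      cm <- generate_metacommunity(ep, spa, tm, w_env = 0.3, w_spa = w,
                                   w_tmp = 0.2, n_taxa = 10, seed = 100 + s)
      unname(varpart3(hellinger(cm), ep, spa, tm, n_perm = 0)$fractions["S"])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_S) > 0))
})

test_that("the dispersal-gradient suite has the designed weight structure", {
  suite <- dispersal_gradient_suite(n_groups = 7, n_sites = 16, n_periods = 3,
                                    n_taxa = 8, seed = 4)
  expect_equal(suite$truth$w_env, seq(1, 0, length.out = 7))
  expect_equal(suite$truth$w_spa, seq(0, 1, length.out = 7))
  expect_equal(names(suite$communities)[1], "phytoplankton")
  expect_true(all(suite$communities$macrophytes %in% c(0, 1)))
  # same seed, same truth and abundances; different seed, same truth only
  suite2 <- dispersal_gradient_suite(n_groups = 7, n_sites = 16, n_periods = 3,
                                     n_taxa = 8, seed = 4)
  expect_identical(suite$communities, suite2$communities)
  suite3 <- dispersal_gradient_suite(n_groups = 7, n_sites = 16, n_periods = 3,
                                     n_taxa = 8, seed = 5)
  expect_equal(suite3$truth$w_env, suite$truth$w_env)
  expect_false(identical(suite$communities[[1]], suite3$communities[[1]]))
})

test_that("a synthetic bundle round-trips through the file loaders", {
  suite <- dispersal_gradient_suite(n_groups = 4, n_sites = 12, n_periods = 2,
                                    n_taxa = 6, seed = 21)
  tmp <- withr::local_tempdir()
  write_synthetic_bundle(tmp, suite)
  expect_true(all(file.exists(file.path(tmp,
    c("sites.csv", "edges.csv", "env.csv", "periods.csv", "truth.json")))))
  loaded <- load_network(file.path(tmp, "sites.csv"),
                         file.path(tmp, "edges.csv"))
  expect_equal(loaded$sites$site_id, suite$sites$site_id)
  env_df <- read.csv(file.path(tmp, "env.csv"), check.names = FALSE)
  expect_equal(nrow(env_df), nrow(suite$env))
  truth <- jsonlite::read_json(file.path(tmp, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$truth$w_spa, suite$truth$w_spa)
})
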