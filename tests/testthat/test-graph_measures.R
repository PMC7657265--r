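test_that("star graph: center carries all betweenness, leaves none", {
  W <- matrix(0, 5, 5)
  W[1, 2:5] <- W[2:5, 1] <- 0.5
  co <- wrap_connectome(W)
  lg <- weights_to_lengths(co)
  ps <- all_pairs_paths(lg)
  sm <- structural_measures(co, lg, ps)
  expect_equal(sm$betweenness[1], 4 * 3)  # ordered leaf pairs
  expect_equal(sm$betweenness[2:5], rep(0, 4))
  expect_equal(sm$degree, c(4, 1, 1, 1, 1))
})

test_that("betweenness matches pair-counting oracle on random graphs", {
  set.seed(44)
  for (rep in 1:5) {
    W <- random_weight_graph(20, p = 0.25)
    co <- wrap_connectome(W)
    lg <- weights_to_lengths(co)
    ps <- all_pairs_paths(lg)
    sm <- structural_measures(co, lg, ps)
    # oracle: count interior memberships by reconstructing every path
    btw <- rep(0, 20)
    for (i in 1:20) for (j in 1:20) {
      if (i == j || !is.finite(ps$dist[i, j])) next
      p <- retrieve_path(ps, i, j)
      if (length(p) > 2)
        for (v in p[-c(1, length(p))]) btw[v] <- btw[v] + 1
    }
    expect_equal(sm$betweenness, btw)
    # closeness: inverse mean shortest-path distance
    d1 <- ps$dist[1, -1]
    expect_equal(sm$closeness[1], 1 / mean(d1[is.finite(d1)]))
  }
})

test_that("hand-built degree, clustering and mean edge length", {
  W <- matrix(0, 5, 5)
  edges <- list(c(1, 2, 0.8), c(1, 3, 0.4), c(2, 3, 0.6), c(3, 4, 0.2))
  for (e in edges) W[e[1], e[2]] <- W[e[2], e[1]] <- e[3]
  coords <- cbind(c(0, 3, 0, 4, 10), c(0, 4, 5, 8, 0), 0)
  co <- wrap_connectome(W, coords = coords)
  lg <- weights_to_lengths(co)
  ps <- all_pairs_paths(lg)
  sm <- structural_measures(co, lg, ps)
  expect_equal(sm$degree, c(2, 2, 3, 1, 0))
  # Onnela clustering of node 1: one triangle (1,2,3)
  What <- W / max(W)
  c1 <- (What[1, 2] * What[1, 3] * What[2, 3])^(1 / 3) / (2 * 1)
  expect_equal(sm$clustering[1], 2 * c1)  # both orderings of the pair
  expect_equal(sm$clustering[4], 0)
  expect_equal(sm$mean_edge_length[1],
               mean(c(sqrt(9 + 16), 5)))
  expect_true(is.na(sm$mean_edge_length[5]))
})

test_that("participation coefficient closed forms", {
  # node with all strength inside its own module -> 0
  fcv <- diag(4)
  fcv[1, 2] <- fcv[2, 1] <- 0.8
  fm <- functional_measures(functional_matrix(fcv), c(1, 1, 2, 2))
  expect_equal(fm$participation[1], 0)
  # strength split equally over m modules -> 1 - 1/m
  fc2 <- diag(3)
  fc2[1, 2] <- fc2[2, 1] <- 0.5
  fc2[1, 3] <- fc2[3, 1] <- 0.5
  fm2 <- functional_measures(functional_matrix(fc2), c(1, 2, 3))
  expect_equal(fm2$participation[1], 1 - 1 / 2)
  # hand 4-node 2-module fixture
  fc3 <- diag(4)
  fc3[1, 2] <- fc3[2, 1] <- 0.6
  fc3[1, 3] <- fc3[3, 1] <- 0.2
  fc3[1, 4] <- fc3[4, 1] <- 0.2
  part <- c(1, 1, 2, 2)
  fm3 <- functional_measures(functional_matrix(fc3), part)
  expect_equal(fm3$participation[1], 1 - (0.6 / 1)^2 - (0.4 / 1)^2)
  expect_equal(fm3$fc_strength[1], 1.0)
  # negative links excluded; zero positive strength flagged
  fc4 <- diag(2); fc4[1, 2] <- fc4[2, 1] <- -0.5
  fm4 <- functional_measures(functional_matrix(fc4), c(1, 2))
  expect_true(all(is.na(fm4$participation)))
})

test_that("correlation table: schema, self-correlation, constant flags", {
  set.seed(10)
  n <- 30
  co <- generate_cohort(synthetic_config(n_nodes = n, n_subjects = 3,
                                         seed = 10, n_partitions = 2))
  geom <- co$connectome_template
  cons <- consensus_sc(co$subject_weights, geom$coords, geom$hemisphere)
  sc <- connectome(cons$weights, geom$coords, geom$sphere_coords,
                   geom$hemisphere, geom$partition)
  lg <- weights_to_lengths(sc)
  ps <- all_pairs_paths(lg)
  hm <- bin_hierarchy(co$true_gradient, 5)
  fs <- flow_stats(ps, hm)
  sm <- structural_measures(sc, lg, ps)
  fm <- functional_measures(co$fc, geom$partition)
  smf <- cbind(sm, fm[, c("fc_strength", "participation")])
  nav <- success_curves(sc, hm, nav_config(beta_grid = c(0, 0.5, 1)))
  bs <- select_beta(nav)
  tab <- correlate_measures(smf, fs, bs)
  expect_equal(nrow(tab), 7 * 4)
  expect_true(all(tab$r >= -1 - 1e-12 & tab$r <= 1 + 1e-12, na.rm = TRUE))
  # a measure correlated with itself gives r = 1
  fs_self <- fs; fs_self$mean_slope <- smf$degree
  tab_self <- correlate_measures(smf, fs_self, bs)
  expect_equal(tab_self$r[tab_self$simple == "degree" &
                          tab_self$motif == "mean_slope"], 1)
  # constant column flagged NA
  smc <- smf; smc$clustering <- 0
  tabc <- correlate_measures(smc, fs, bs)
  expect_true(is.na(tabc$r[tabc$simple == "clustering" &
                           tabc$motif == "mean_slope"]))
})
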