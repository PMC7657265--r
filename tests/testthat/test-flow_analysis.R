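test_that("worked example: two opposite traversals of a 4-chain", {
  set.seed(77)
  for (rep in 1:20) {
    h <- rnorm(4)
    hm <- hierarchy_map(h, rank(h, ties.method = "first"), n_bins = 4)
    ps <- as_path_set(list(c(1, 2, 3, 4), c(4, 3, 2, 1)), 4)
    s <- node_slopes(ps, hm)
    expect_equal(s$mean_slope[3], (h[4] + h[2] - 2 * h[3]) / 2)
    expect_equal(s$mean_slope[2], (h[3] + h[1] - 2 * h[2]) / 2)
    expect_identical(s$n_interior, c(0L, 2L, 2L, 0L))
    expect_true(is.na(s$mean_slope[1]) && is.na(s$mean_slope[4]))
  }
})

test_that("turning-point event classification on explicit motifs", {
  # (0.3, 0.1, 0.4): middle node is a local minimum -> turning up
  hm <- hierarchy_map(c(0.3, 0.1, 0.4), c(2, 1, 3), 3)
  tp <- turning_points(as_path_set(list(c(1, 2, 3)), 3), hm)
  expect_equal(tp$p_turn_up[2], 1)
  expect_equal(tp$p_turn_down[2], 0)
  # (0.1, 0.5, 0.2): local maximum -> turning down
  hm2 <- hierarchy_map(c(0.1, 0.5, 0.2), c(1, 3, 2), 3)
  tp2 <- turning_points(as_path_set(list(c(1, 2, 3)), 3), hm2)
  expect_equal(tp2$p_turn_down[2], 1)
  # monotone chain: all interior slopes positive, no turning events
  hmono <- hierarchy_map(1:5 / 5, 1:5, 5)
  psm <- as_path_set(list(c(1, 2, 3, 4, 5)), 5)
  sm <- node_slopes(psm, hmono)
  expect_true(all(sm$mean_slope[2:4] > 0))
  tpm <- turning_points(psm, hmono)
  expect_true(all(tpm$n_up == 0) && all(tpm$n_down == 0))
  # zero-slope segments are neither up nor down
  hflat <- hierarchy_map(c(0.2, 0.2, 0.2), c(1, 1, 1), 2)
  tpf <- turning_points(as_path_set(list(c(1, 2, 3)), 3), hflat)
  expect_equal(tpf$n_up[2] + tpf$n_down[2], 0L)
  expect_equal(tpf$n_interior[2], 1L)
})

test_that("flow statistics match exhaustive enumeration on small graphs", {
  set.seed(14)
  for (rep in 1:8) {
    n <- sample(5:8, 1)
    W <- random_weight_graph(n, p = 0.5)
    h <- rnorm(n)
    hm <- bin_hierarchy(h, min(4, n))
    ps <- all_pairs_paths(weights_to_lengths(W))
    ep <- hierpath:::extract_all_paths(ps)
    oracle <- oracle_flow(ep$paths, hm$gradient)
    fs <- flow_stats(ps, hm)
    expect_equal(fs$mean_slope, oracle$mean_slope)
    expect_equal(fs$p_turn_up, oracle$p_turn_up)
    expect_equal(fs$p_turn_down, oracle$p_turn_down)
    expect_equal(fs$n_interior, oracle$n_interior)
    # event conservation: sum n_interior = sum over paths of (hops - 1)
    expect_equal(sum(fs$n_interior), sum(pmax(ep$len - 1L, 0L)))
    # up/down/neither partition interior traversals
    tp <- turning_points(ps, hm)
    expect_true(all(tp$n_up + tp$n_down <= tp$n_interior))
  }
})

test_that("network aggregation over partitions", {
  fs <- data.frame(node = 1:6,
                   mean_slope = c(0.2, -0.1, 0.4, NA, 0.3, -0.2),
                   p_turn_up = c(0.1, 0.2, 0.3, NA, 0.5, 0.6),
                   p_turn_down = c(0, 0.1, 0, NA, 0.2, 0.1),
                   n_interior = c(3L, 5L, 2L, 0L, 1L, 4L))
  # single label: grand mean over valid nodes
  agg1 <- network_aggregate(fs, rep(1, 6))
  expect_equal(agg1$mean_slope, mean(fs$mean_slope[fs$n_interior > 0]))
  # two labels, hand computation; label 2 contains the invalid node
  part <- c(1, 1, 2, 2, 2, 1)
  agg <- network_aggregate(fs, part)
  expect_equal(agg$mean_slope[1], mean(c(0.2, -0.1, -0.2)))
  expect_equal(agg$mean_slope[2], mean(c(0.4, 0.3)))
  expect_equal(agg$n_valid, c(3L, 2L))
  # consistent relabeling leaves means unchanged
  perm <- c(2, 1)
  agg_r <- network_aggregate(fs, perm[part])
  expect_equal(agg_r$mean_slope[2], agg$mean_slope[1])
  # label with no valid nodes is flagged
  agg0 <- network_aggregate(fs[4, , drop = FALSE], 1)
  expect_true(is.na(agg0$mean_slope))
  expect_equal(agg0$n_valid, 0L)
})

test_that("slope-hierarchy correlation and its spin p-value behave", {
  geom <- toy_geometry(n = 40, seed = 2)
  g <- generate_gradient(synthetic_config(n_nodes = 40, n_partitions = 2,
                                          seed = 2), geom)
  hm <- bin_hierarchy(g, 5)
  spins <- spin_permutation(geom$sphere_coords, geom$hemisphere,
                            n_reps = 99, seed = 3)
  # slope = -gradient: perfect anticorrelation, smallest attainable p
  fs <- data.frame(mean_slope = -g, n_interior = rep(1L, 40))
  res <- slope_hierarchy_correlation(fs, hm, spins)
  expect_equal(res$r, -1)
  expect_lte(res$p_spin, 5 / 100)  # spins of a smooth map rarely tie |r|=1
  # random slopes: |r| small, p large (Monte Carlo sanity)
  ps <- sapply(1:20, function(s) {
    set.seed(1000 + s)
    fs2 <- data.frame(mean_slope = rnorm(40), n_interior = rep(1L, 40))
    slope_hierarchy_correlation(fs2, hm, spins)$p_spin
  })
  expect_gt(mean(ps > 0.05), 0.7)
  expect_error(slope_hierarchy_correlation(
    data.frame(mean_slope = c(1, NA, NA, rep(NA, 37)),
               n_interior = c(1L, rep(0L, 39))), hm, spins), "3 nodes")
})
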