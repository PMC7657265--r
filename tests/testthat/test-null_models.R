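test_that("rewiring preserves degrees, weights and per-bin lengths exactly", {
  co <- generate_cohort(synthetic_config(n_nodes = 60, n_subjects = 3,
                                         seed = 6, n_partitions = 3))
  geom <- co$connectome_template
  cons <- consensus_sc(co$subject_weights, geom$coords, geom$hemisphere)
  sc <- connectome(cons$weights, geom$coords, geom$sphere_coords,
                   geom$hemisphere)
  n_bins <- 6
  ens <- rewire_length_preserving(sc, n_bins = n_bins, n_reps = 10, seed = 4)
  D <- as.matrix(dist(sc$coords))
  ut <- upper.tri(D)
  brk <- seq(min(D[ut & sc$weights > 0]), max(D[ut & sc$weights > 0]),
             length.out = n_bins + 1)
  binc <- function(W) tabulate(findInterval(D[ut & W > 0], brk,
                                            rightmost.closed = TRUE,
                                            all.inside = TRUE), n_bins)
  deg0 <- rowSums(sc$weights > 0)
  w0 <- sort(sc$weights[ut][sc$weights[ut] > 0])
  b0 <- binc(sc$weights)
  swaps <- sapply(ens$members, attr, "n_swaps")
  expect_gt(mean(swaps), 0)
  for (M in ens$members) {
    expect_equal(M, t(M))
    expect_identical(rowSums(M > 0), deg0)
    expect_equal(sort(M[ut][M[ut] > 0]), w0)
    expect_identical(binc(M), b0)
  }
  # at least some replicate actually differs from the original
  expect_true(any(sapply(ens$members, function(M) any(M != sc$weights))))
})

test_that("4-cycle rewiring keeps the (2,2,2,2) degree sequence", {
  W <- matrix(0, 4, 4)
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
    W[e[1], e[2]] <- W[e[2], e[1]] <- 0.5
  co <- wrap_connectome(W)
  ens <- rewire_length_preserving(co, n_bins = 1, n_reps = 5, seed = 2)
  for (M in ens$members) expect_identical(rowSums(M > 0), rep(2, 4))
})

test_that("spin permutation: isometry, hemisphere closure, identity case", {
  geom <- toy_geometry(n = 40, seed = 3)
  ens <- spin_permutation(geom$sphere_coords, geom$hemisphere,
                          n_reps = 20, seed = 5)
  left <- geom$hemisphere == "L"
  for (idx in ens$members) {
    # values drawn from the same hemisphere's node set
    expect_true(all(left[idx[left]]))
    expect_true(all(!left[idx[!left]]))
    expect_true(all(idx >= 1 & idx <= 40))
  }
  # rotations are isometries: pairwise geodesics of rotated points match
  set.seed(5)
  R <- hierpath:::random_rotation()
  expect_equal(crossprod(R), diag(3), tolerance = 1e-12)
  expect_equal(det(R), 1, tolerance = 1e-12)
  pts <- geom$sphere_coords[left, ]
  G0 <- pts %*% t(pts)
  G1 <- (pts %*% t(R)) %*% t(pts %*% t(R))
  expect_equal(G0, G1, tolerance = 1e-9)
  # identity rotation -> identity assignment (nearest rotated parcel is
  # the parcel itself)
  cross <- pts %*% t(pts)
  expect_identical(max.col(cross, ties.method = "first"),
                   seq_len(nrow(pts)))
  expect_error(spin_permutation(geom$sphere_coords, rep("L", 40), 2, 1),
               "hemisphere")
})

test_that("label permutations are seeded bijections", {
  e1 <- label_permutation(15, n_reps = 8, seed = 9)
  e2 <- label_permutation(15, n_reps = 8, seed = 9)
  expect_identical(e1$members, e2$members)
  for (p in e1$members) expect_identical(sort(p), 1:15)
  vals <- rnorm(15)
  for (p in e1$members) expect_identical(sort(vals[p]), sort(vals))
})

test_that("permutation p-values: closed forms and BH step-up", {
  nulls <- rnorm(2000)
  obs <- max(nulls) + 1
  expect_equal(permutation_pvalue(obs, nulls, tail = "right"), 1 / 2001)
  med <- mean(nulls)
  expect_gt(permutation_pvalue(med, nulls, tail = "two"), 0.9)
  expect_error(permutation_pvalue(1, numeric(0)), "empty")

  # BH on a hand-listed vector: step-up rule applied by hand
  p <- c(0.001, 0.02, 0.03, 0.4)
  adj <- fdr_bh(p)
  # hand: p_(i) * m / i, cummin from the largest
  hand <- rev(cummin(rev(p * 4 / seq_len(4))))
  expect_equal(adj, hand)
  expect_identical(adj <= 0.05, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("spin nulls preserve smooth-gradient Moran's I, permutation kills it", {
  # reduced-scale spot check; the full criterion runs in test-acceptance
  cfg <- synthetic_config(n_nodes = 80, seed = 11, n_partitions = 4)
  geom <- generate_geometry(cfg)
  g <- generate_gradient(cfg, geom)
  D <- as.matrix(dist(geom$coords))
  Wk <- exp(-D^2 / (2 * cfg$smoothness^2)); diag(Wk) <- 0
  i_obs <- oracle_moran(g, Wk)
  spins <- spin_permutation(geom$sphere_coords, geom$hemisphere, 30, seed = 2)
  perms <- label_permutation(80, 30, seed = 2)
  i_spin <- sapply(spins$members, function(ix) oracle_moran(g[ix], Wk))
  i_perm <- sapply(perms$members, function(ix) oracle_moran(g[ix], Wk))
  expect_gt(i_obs, 0.1)                      # gradient is spatially smooth
  expect_gt(median(i_spin), 0.5 * i_obs)     # spins keep autocorrelation
  expect_lt(abs(median(i_perm)), 0.05)       # permutation collapses it
  expect_gt(median(i_spin), 5 * abs(median(i_perm)))
})
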