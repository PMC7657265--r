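# brute-force consensus oracle: pool, split by hemisphere class, bin by
# length (equal width), keep round(mean subject count) most frequent
oracle_consensus_mask <- function(subject_weights, coords, hemisphere,
                                  n_bins) {
  n <- nrow(subject_weights[[1]])
  D <- as.matrix(dist(coords))
  keep <- matrix(FALSE, n, n)
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  freq <- apply(pairs, 1, function(p)
    sum(sapply(subject_weights, function(w) w[p[1], p[2]] > 0)))
  mw <- apply(pairs, 1, function(p)
    mean(sapply(subject_weights, function(w) w[p[1], p[2]])))
  len <- D[pairs]
  inter <- hemisphere[pairs[, 1]] != hemisphere[pairs[, 2]]
  for (cl in c(FALSE, TRUE)) {
    sel <- which(inter == cl & freq > 0)
    if (!length(sel)) next
    brk <- seq(min(len[sel]), max(len[sel]), length.out = n_bins + 1)
    b <- findInterval(len[sel], brk, rightmost.closed = TRUE,
                      all.inside = TRUE)
    for (bb in unique(b)) {
      mem <- sel[b == bb]
      k <- round(sum(freq[mem]) / length(subject_weights))
      if (k <= 0) next
      o <- order(-freq[mem], -mw[mem], pairs[mem, 1], pairs[mem, 2])
      ch <- mem[o[seq_len(min(k, length(mem)))]]
      keep[pairs[ch, , drop = FALSE]] <- TRUE
    }
  }
  keep | t(keep)
}

test_that("identical subjects reproduce their own mask and weights", {
  set.seed(3)
  W <- random_weight_graph(10, p = 0.4)
  co <- wrap_connectome(W)
  res <- consensus_sc(list(W, W, W), co$coords, co$hemisphere, n_bins = 4)
  expect_equal(res$weights, W)
  expect_equal(res$report$density,
               sum(W[upper.tri(W)] > 0) / choose(10, 2))
})

test_that("kept edges match the brute-force frequency-ranking oracle", {
  set.seed(7)
  for (rep in 1:5) {
    subs <- replicate(3, random_weight_graph(6, p = 0.5), simplify = FALSE)
    co <- wrap_connectome(subs[[1]])
    res <- consensus_sc(subs, co$coords, co$hemisphere, n_bins = 2)
    oracle <- oracle_consensus_mask(subs, co$coords, co$hemisphere, 2)
    expect_identical(res$weights > 0, oracle)
  }
})

test_that("single-bin one-hemisphere run is plain frequency thresholding", {
  set.seed(21)
  subs <- replicate(4, random_weight_graph(8, p = 0.5), simplify = FALSE)
  coords <- cbind(rnorm(8), rnorm(8), rnorm(8))
  hemi <- rep("L", 8)
  res <- consensus_sc(subs, coords, hemi, n_bins = 1)
  ut <- which(upper.tri(diag(8)))
  freq <- Reduce(`+`, lapply(subs, function(w) (w[ut] > 0) + 0))
  k <- round(sum(freq) / 4)
  kept_oracle <- ut[order(-freq, ut)[seq_len(k)]]  # ties: lower index pair
  # same number kept; kept set has frequencies >= every dropped frequency
  kept <- which(res$weights[ut] > 0)
  expect_length(kept, k)
  expect_gte(min(freq[kept]), max(freq[-kept]) - 0L)
  expect_true(all(freq[kept] >= sort(freq, decreasing = TRUE)[k]))
})

test_that("per-bin kept counts equal rounded per-bin mean subject counts", {
  co <- generate_cohort(synthetic_config(n_nodes = 80, n_subjects = 5,
                                         seed = 2))
  geom <- co$connectome_template
  res <- consensus_sc(co$subject_weights, geom$coords, geom$hemisphere)
  b <- res$report$bins
  expect_true(all(b$kept <= b$available))
  # density within 1 percentage point of mean subject density
  dens_diff <- sapply(1:10, function(s) {
    co <- generate_cohort(synthetic_config(n_nodes = 80, n_subjects = 5,
                                           seed = s))
    geom <- co$connectome_template
    r <- consensus_sc(co$subject_weights, geom$coords, geom$hemisphere)
    msd <- mean(sapply(co$subject_weights,
                       function(w) mean(w[upper.tri(w)] > 0)))
    abs(r$report$density - msd)
  })
  expect_lt(max(dens_diff), 0.01)
})

test_that("consensus weight modes: mean over all vs expressing subjects", {
  W1 <- matrix(0, 4, 4); W1[1, 2] <- W1[2, 1] <- 0.4
  W2 <- matrix(0, 4, 4); W2[1, 2] <- W2[2, 1] <- 0.8
  W3 <- matrix(0, 4, 4)  # edge absent for subject 3
  coords <- cbind(1:4, 0, 0)
  hemi <- rep("L", 4)
  all_mode <- consensus_sc(list(W1, W2, W3), coords, hemi, n_bins = 1)
  nz_mode <- consensus_sc(list(W1, W2, W3), coords, hemi, n_bins = 1,
                          weight_mean = "nonzero")
  expect_equal(all_mode$weights[1, 2], (0.4 + 0.8 + 0) / 3)
  expect_equal(nz_mode$weights[1, 2], (0.4 + 0.8) / 2)
})

test_that("mean_fc averages element-wise and resets the diagonal", {
  a <- functional_matrix(diag(3) * 0.2 + 0.8)
  expect_equal(unclass(mean_fc(list(a))), unclass(a))
  b <- matrix(c(1, -0.4, -0.4, 1), 2, 2)
  d <- matrix(c(1, 0.6, 0.6, 1), 2, 2)
  avg <- mean_fc(list(functional_matrix(b), functional_matrix(d)))
  expect_equal(avg[1, 2], 0.1)
  expect_equal(diag(unclass(avg)), c(1, 1))
  expect_error(mean_fc(list(b, diag(3))), "shape")
})
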