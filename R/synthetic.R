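# Synthetic cohort generator.
#
# The generator emulates, at desk scale, the statistical structure the
# downstream analyses assume of a multi-subject imaging cohort: bilateral
# node geometry on a sphere, a spatially smooth planted hierarchy gradient
# mirrored across hemispheres, per-subject structural matrices whose edge
# probability decays with Euclidean distance and with hierarchy
# dissimilarity, and a correlation-valued FC matrix whose leading axis is
# the planted gradient. All randomness flows from one global seed through
# named streams (see stream_seed), so each stage is independently
# reproducible.

#' Synthetic cohort configuration
#'
#' @param n_nodes even number of nodes (default 200, standing in for the
#'   1,000-node parcellation at reduced scale).
#' @param n_subjects cohort size (default 20, standing in for N = 66).
#' @param seed global integer seed.
#' @param lambda_space spatial decay scale of connection probability, in
#'   coordinate units (sphere radius = 100).
#' @param mu_hier hierarchy-similarity decay scale (gradient sd units).
#' @param density_target expected subject edge density in (0, 1).
#' @param weight_sigma log-normal spread of nonzero edge weights.
#' @param fc_noise isotropic noise variance added to the FC covariance;
#'   the default 1 puts the median absolute off-diagonal correlation near
#'   0.25, the magnitude typical of group-average resting-state FC.
#' @param n_partitions number of spatially contiguous partitions
#'   (default 7, standing in for the intrinsic networks).
#' @param smoothness Gaussian kernel width of the planted gradient's smooth
#'   component, in coordinate units.
#' @return list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_nodes = 200L, n_subjects = 20L, seed = 1L,
                             lambda_space = 60, mu_hier = 1.5,
                             density_target = 0.05, weight_sigma = 1,
                             fc_noise = 1, n_partitions = 7L,
                             smoothness = 30) {
  cfg <- list(n_nodes = as.integer(n_nodes), n_subjects = as.integer(n_subjects),
              seed = as.integer(seed), lambda_space = lambda_space,
              mu_hier = mu_hier, density_target = density_target,
              weight_sigma = weight_sigma, fc_noise = fc_noise,
              n_partitions = as.integer(n_partitions), smoothness = smoothness)
  stopifnot(cfg$n_nodes >= 2, cfg$n_nodes %% 2L == 0L, cfg$n_subjects >= 1,
            cfg$lambda_space > 0, cfg$mu_hier > 0,
            cfg$density_target > 0, cfg$density_target < 1,
            cfg$weight_sigma > 0, cfg$fc_noise >= 0, cfg$n_partitions >= 1,
            cfg$smoothness > 0)
  class(cfg) <- "synthetic_config"
  cfg
}

# sample k points uniformly on the spherical cap x in [cap_lo, cap_hi]
# (uniform-on-sphere has x ~ U(-1, 1))
sample_cap <- function(k, cap_lo, cap_hi) {
  x <- runif(k, cap_lo, cap_hi)
  phi <- runif(k, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - x^2))
  cbind(x, r * cos(phi), r * sin(phi))
}

# map full-sphere projection points to a spherical cap around the pole
# `pole` by compressing the polar angle (theta -> theta * theta_max / pi),
# the same kind of monotone radial warp that relates a cortical
# hemisphere to its inflated full-sphere projection
project_to_cap <- function(p, pole, theta_max) {
  ct <- pmin(1, pmax(-1, drop(p %*% pole)))
  theta <- acos(ct)
  tp <- theta * theta_max / pi
  tang <- p - ct %o% pole
  tn <- sqrt(rowSums(tang^2))
  tang <- tang / ifelse(tn > 1e-12, tn, 1)
  cos(tp) %o% pole + sin(tp) * tang
}

#' Generate bilateral node geometry
#'
#' Samples `n/2` points per hemisphere uniformly on that hemisphere's own
#' full unit sphere -- the spherical projection used by the spin null,
#' where a rotation is a bijective isometry, as for an inflated cortical
#' hemisphere. The right-hemisphere projection is the mirror image
#' (`x -> -x`) of an independent sample, so homologue pairing is by
#' index, not by exact position. Physical Euclidean coordinates place the
#' two hemispheres on opposing caps of a radius-100 sphere via a
#' deterministic monotone radial warp of the projection, preserving
#' neighborhood structure between the two coordinate systems. The
#' partition is built by farthest-point seeding plus nearest-seed
#' assignment on the left hemisphere and copied to the right by homologue
#' index, giving `n_partitions` spatially contiguous bilateral clusters.
#'
#' @param cfg a [synthetic_config()].
#' @return a [connectome()] with all-zero weights (geometry carrier).
#' @export
generate_geometry <- function(cfg) {
  n <- cfg$n_nodes
  if (n < 2L * cfg$n_partitions)
    stop("n_nodes must be at least 2 * n_partitions")
  half <- n %/% 2L
  sphere <- with_stream(cfg$seed, "geometry", {
    left <- sample_cap(half, -1, 1)             # full projection sphere
    right <- sample_cap(half, -1, 1)
    right[, 1] <- -right[, 1]                   # mirror x -> -x
    rbind(left, right)
  })
  hemisphere <- rep(c("L", "R"), each = half)
  theta_max <- acos(0.1)                        # caps: |x| >= 0.1
  coords <- 100 * rbind(
    project_to_cap(sphere[seq_len(half), , drop = FALSE],
                   c(-1, 0, 0), theta_max),
    project_to_cap(sphere[half + seq_len(half), , drop = FALSE],
                   c(1, 0, 0), theta_max))

  # farthest-point seeding on the left hemisphere
  left_xy <- coords[seq_len(half), , drop = FALSE]
  seeds <- integer(cfg$n_partitions)
  seeds[1] <- 1L
  dmin <- sqrt(rowSums(sweep(left_xy, 2, left_xy[1, ])^2))
  if (cfg$n_partitions > 1) {
    for (s in 2:cfg$n_partitions) {
      seeds[s] <- which.max(dmin)
      dmin <- pmin(dmin, sqrt(rowSums(sweep(left_xy, 2, left_xy[seeds[s], ])^2)))
    }
  }
  d_seed <- sapply(seeds, function(s)
    sqrt(rowSums(sweep(left_xy, 2, left_xy[s, ])^2)))
  part_left <- max.col(-d_seed, ties.method = "first")
  partition <- c(part_left, part_left)  # mirrored by homologue index

  connectome(weights = matrix(0, n, n), coords = coords,
             sphere_coords = sphere, hemisphere = hemisphere,
             partition = partition)
}

#' Plant a smooth hierarchy gradient over the geometry
#'
#' The gradient is the standardized sum of a linear field along a random 3D
#' direction and spatially smoothed white noise (Gaussian kernel
#' `exp(-d^2 / (2 * smoothness^2))` applied to i.i.d. normals), both
#' computed on the left hemisphere and copied to right-hemisphere
#' homologues so mirrored node pairs share values.
#'
#' @param cfg a [synthetic_config()].
#' @param geometry output of [generate_geometry()].
#' @return numeric per-node gradient, mean 0, sd 1.
#' @export
generate_gradient <- function(cfg, geometry) {
  n <- geometry$n_nodes
  half <- n %/% 2L
  left <- geometry$coords[seq_len(half), , drop = FALSE]
  g_left <- with_stream(cfg$seed, "gradient", {
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    lin <- drop(left %*% u)
    D <- as.matrix(dist(left))
    K <- exp(-D^2 / (2 * cfg$smoothness^2))
    sm <- drop(K %*% rnorm(half))
    std <- function(x) {
      s <- sd(x)
      if (!is.finite(s) || s < 1e-12)
        stop("degenerate gradient field (zero variance)")
      (x - mean(x)) / s
    }
    std(std(lin) + std(sm))
  })
  g <- c(g_left, g_left)
  (g - mean(g)) / sd(g)
}

# group edge probability p_ij = c * exp(-d/lambda) * exp(-|gi-gj|/mu),
# with c solved so that mean(pmin(1, c*score)) hits density_target
edge_probability <- function(cfg, geometry, g) {
  D <- as.matrix(dist(geometry$coords))
  H <- abs(outer(g, g, "-"))
  score <- exp(-D / cfg$lambda_space) * exp(-H / cfg$mu_hier)
  diag(score) <- 0
  ut <- upper.tri(score)
  s <- score[ut]
  f <- function(cc) mean(pmin(1, cc * s)) - cfg$density_target
  if (f(1e9) < 0)
    stop("infeasible density_target for this geometry")
  cc <- uniroot(f, c(1e-12, 1e9), tol = 1e-12)$root
  p <- pmin(cc * score, 1)   # matrix first: pmin keeps its attributes
  diag(p) <- 0
  p
}

#' Generate per-subject structural connectivity matrices
#'
#' A group edge mask is drawn once with probability
#' `p_ij` proportional to `exp(-d_ij/lambda_space) * exp(-|g_i-g_j|/mu_hier)`
#' scaled to the target density; each subject's mask is the group mask with
#' 15% of its edges randomly deleted and an equal number inserted (absent
#' pairs sampled proportionally to `p_ij`, preserving the distance decay),
#' so subjects share roughly 70% of edges with the group. Nonzero weights
#' are log-normal, rescaled per subject into `(0, 0.95]`; the 0.95 cap
#' keeps `-log(w)` edge lengths strictly positive.
#'
#' @param cfg a [synthetic_config()].
#' @param geometry output of [generate_geometry()].
#' @param g planted gradient from [generate_gradient()].
#' @return list of `n_subjects` symmetric weight matrices.
#' @export
generate_subject_sc <- function(cfg, geometry, g) {
  n <- geometry$n_nodes
  p <- edge_probability(cfg, geometry, g)
  ut <- which(upper.tri(p))
  pv <- p[ut]
  group_idx <- with_stream(cfg$seed, "group_mask",
                           ut[runif(length(ut)) < pv])
  lapply(seq_len(cfg$n_subjects), function(s) {
    idx <- with_stream(cfg$seed, paste0("subject_mask_", s), {
      ne <- length(group_idx)
      ndel <- round(0.15 * ne)
      keep <- if (ndel > 0) sample(ne, ne - ndel) else seq_len(ne)
      kept <- group_idx[keep]
      absent <- setdiff(ut, group_idx)
      wabs <- pv[match(absent, ut)]
      ins <- if (ndel > 0 && length(absent))
        sample(absent, min(ndel, length(absent)), prob = wabs) else integer(0)
      sort(c(kept, ins))
    })
    w <- with_stream(cfg$seed, paste0("subject_weights_", s), {
      raw <- exp(rnorm(length(idx), 0, cfg$weight_sigma))
      raw / max(raw) * 0.95
    })
    m <- matrix(0, n, n)
    m[idx] <- w
    m + t(m)
  })
}

#' Generate the functional connectivity matrix
#'
#' FC is the correlation normalization of `Sigma = F F' + fc_noise * I`
#' where the latent loadings `F` hold the planted gradient and a weaker
#' smooth nuisance field (loading 0.5). Symmetric, unit diagonal, positive
#' semidefinite by construction; the leading structure is the gradient, as
#' the hierarchy-embedding stage assumes of real FC.
#'
#' @param cfg a [synthetic_config()].
#' @param geometry output of [generate_geometry()].
#' @param g planted gradient.
#' @return a [functional_matrix()].
#' @export
generate_fc <- function(cfg, geometry, g) {
  n <- geometry$n_nodes
  half <- n %/% 2L
  left <- geometry$coords[seq_len(half), , drop = FALSE]
  nuis_left <- with_stream(cfg$seed, "fc_nuisance", {
    D <- as.matrix(dist(left))
    K <- exp(-D^2 / (2 * cfg$smoothness^2))
    drop(K %*% rnorm(half))
  })
  nuis <- c(nuis_left, nuis_left)
  nuis <- (nuis - mean(nuis)) / sd(nuis)
  F_load <- cbind(g, 0.5 * nuis)
  Sigma <- F_load %*% t(F_load)
  diag(Sigma) <- diag(Sigma) + cfg$fc_noise
  if (cfg$fc_noise == 0 && any(diag(Sigma) < 1e-12))
    stop("degenerate FC: zero-variance node with fc_noise = 0")
  functional_matrix(stats::cov2cor(Sigma))
}

#' Generate a full synthetic cohort
#'
#' Runs geometry, gradient, subject SC and FC generation under one seed.
#'
#' @param cfg a [synthetic_config()].
#' @return list of class `"cohort_sample"` with `connectome_template`
#'   (geometry carrier), `subject_weights`, `fc`, `true_gradient`, `config`.
#' @export
generate_cohort <- function(cfg = synthetic_config()) {
  geometry <- generate_geometry(cfg)
  g <- generate_gradient(cfg, geometry)
  subs <- generate_subject_sc(cfg, geometry, g)
  fc <- generate_fc(cfg, geometry, g)
  structure(list(connectome_template = geometry, subject_weights = subs,
                 fc = fc, true_gradient = g, config = cfg),
            class = "cohort_sample")
}

#' @export
print.cohort_sample <- function(x, ...) {
  dens <- vapply(x$subject_weights,
                 function(w) mean(w[upper.tri(w)] > 0), 0)
  cat(sprintf("<cohort_sample> %d nodes, %d subjects, mean density %.3f\n",
              x$connectome_template$n_nodes, length(x$subject_weights),
              mean(dens)))
  invisible(x)
}
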