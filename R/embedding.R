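# Diffusion-map estimation of the hierarchy gradient.
#
# Each node's FC row is treated as its feature vector. A Gaussian affinity
# over row distances is alpha-normalized (alpha = 1 removes the influence
# of sampling density, recovering Laplace-Beltrami geometry), row-
# normalized into a Markov operator, and eigendecomposed through its
# symmetric conjugate. Component l is lambda_l * psi_l (diffusion time
# t = 1); the trivial constant eigenvector is dropped. The first component
# is the continuous unimodal-transmodal hierarchy estimate.

#' Diffusion map embedding of a functional connectivity matrix
#'
#' @param fc a [functional_matrix()] (or plain symmetric matrix).
#' @param alpha diffusion-rate normalization exponent (default 1).
#' @param sigma Gaussian affinity width (default 1); the kernel is
#'   `exp(-d^2 / (2 * sigma^2))` over Euclidean distances between FC rows
#'   (the `2 sigma^2` bandwidth convention; set `bandwidth = "sigma2"` for
#'   `exp(-d^2 / sigma^2)`).
#' @param m number of nontrivial components to return.
#' @param affinity `"gaussian"` (default) on raw FC rows, or `"cosine"` on
#'   rows thresholded to their top `(1 - row_threshold)` quantile.
#' @param row_threshold quantile for the cosine variant (default 0.9).
#' @param bandwidth `"2sigma2"` (default) or `"sigma2"`.
#' @return list of class `"embedding_result"`: `components` (n x m, scaled
#'   by eigenvalue), `eigenvalues`, `alpha`, `sigma`, `orientation_sign`.
#' @export
diffusion_map <- function(fc, alpha = 1, sigma = 1, m = 10L,
                          affinity = c("gaussian", "cosine"),
                          row_threshold = 0.9,
                          bandwidth = c("2sigma2", "sigma2")) {
  affinity <- match.arg(affinity)
  bandwidth <- match.arg(bandwidth)
  X <- unclass(as.matrix(fc))
  n <- nrow(X)
  if (n < 3) stop("need at least 3 nodes")
  if (anyNA(X)) stop("FC contains NaN")

  if (affinity == "gaussian") {
    D2 <- as.matrix(dist(X))^2
    denom <- if (bandwidth == "2sigma2") 2 * sigma^2 else sigma^2
    K <- exp(-D2 / denom)
  } else {
    Xt <- X
    thr <- apply(Xt, 1, quantile, probs = row_threshold)
    Xt[Xt < thr] <- 0
    nrm <- sqrt(rowSums(Xt^2))
    nrm[nrm == 0] <- 1
    K <- (Xt / nrm) %*% t(Xt / nrm)
    K[K < 0] <- 0
  }

  q <- rowSums(K)
  if (any(q <= 0)) stop("degenerate affinity: isolated node")
  Ka <- K / (q^alpha %o% q^alpha)
  d <- rowSums(Ka)
  # symmetric conjugate of the Markov operator P = D^-1 Ka
  A <- Ka / sqrt(d %o% d)
  eig <- eigen(A, symmetric = TRUE)
  lam <- eig$values
  psi <- eig$vectors / sqrt(d)          # right eigenvectors of P
  # normalize sign-free scale: psi columns to unit norm
  psi <- sweep(psi, 2, sqrt(colSums(psi^2)), "/")
  if (sd(psi[, 1]) > 1e-6 * mean(abs(psi[, 1])))
    warning("leading eigenvector is not constant; affinity graph may be disconnected")
  keep <- seq(2L, min(n, m + 1L))
  comp <- sweep(psi[, keep, drop = FALSE], 2, lam[keep], "*")
  if (sd(comp[, 1]) < 1e-14)
    stop("degenerate embedding: no nontrivial component (all-identical rows)")
  structure(list(components = comp, eigenvalues = lam[keep],
                 alpha = alpha, sigma = sigma, orientation_sign = 1),
            class = "embedding_result")
}

#' Orient the first embedding component against a reference
#'
#' The eigenvector sign is arbitrary; this fixes it so the first component
#' correlates non-negatively with `reference`. Idempotent.
#'
#' @param emb an `embedding_result`.
#' @param reference numeric per-node reference vector.
#' @return the embedding with `orientation_sign` applied to component 1.
#' @export
orient_gradient <- function(emb, reference) {
  stopifnot(inherits(emb, "embedding_result"),
            length(reference) == nrow(emb$components),
            all(is.finite(reference)))
  if (sd(emb$components[, 1]) == 0) stop("zero-variance component")
  s <- if (cor(emb$components[, 1], reference) < 0) -1 else 1
  emb$components[, 1] <- s * emb$components[, 1]
  emb$orientation_sign <- s * emb$orientation_sign
  emb
}

#' Bin a gradient into equal-size hierarchy classes
#'
#' Nodes are ranked by `(gradient, node index)` and the ranking is split
#' into `n_bins` contiguous classes whose sizes differ by at most one node
#' (a remainder of r is absorbed by the r lowest classes). Class 1 holds
#' the lowest gradient values (unimodal end), class `n_bins` the highest
#' (transmodal end).
#'
#' @param gradient numeric per-node gradient.
#' @param n_bins number of classes (default 10).
#' @return a [hierarchy_map()].
#' @export
bin_hierarchy <- function(gradient, n_bins = 10L) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  n <- length(gradient)
  if (n < n_bins) stop("need at least n_bins nodes")
  if (!all(is.finite(gradient))) stop("gradient must be finite")
  base <- n %/% n_bins
  r <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, r), rep(0L, n_bins - r))
  o <- order(gradient, seq_len(n))   # stable: ties broken by node index
  classes <- integer(n)
  classes[o] <- rep(seq_len(n_bins), times = sizes)
  hierarchy_map(gradient, classes, n_bins)
}
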