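# Null models.
#
# Three reference nulls: (1) distance-binned degree-preserving rewiring
# of the structural network, in which edge swaps are constrained to stay
# inside their Euclidean length bin so the degree sequence, the weight
# multiset and the per-bin edge-length histogram are all preserved
# exactly; (2) the spin null: a uniform random 3D rotation applied to
# one hemisphere's spherical parcel coordinates and mirrored to the
# other, with values reassigned from the nearest rotated parcel, which
# permutes an annotation while preserving its spatial autocorrelation;
# (3) plain label permutation.

new_null_ensemble <- function(kind, members, seed) {
  structure(list(kind = kind, n_reps = length(members), members = members,
                 seed = seed), class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble:%s> %d replicates (seed %d)\n",
              x$kind, x$n_reps, x$seed))
  invisible(x)
}

#' Distance-binned degree-preserving rewiring null
#'
#' Per replicate, `10 x edge count` swap attempts are made: a random
#' length bin (with at least two edges) is chosen, two of its edges
#' `a-b`, `c-d` are picked at random and rewired to `a-d`, `c-b` when the
#' result creates no self-loop or multi-edge and both new edges fall in
#' the same length bin. Weights travel with their reassigned edges.
#'
#' @param c a [connectome()].
#' @param n_bins number of equal-width Euclidean length bins.
#' @param n_reps number of replicates (default 2000).
#' @param seed integer seed.
#' @return a `null_ensemble` of kind `"rewire"` whose members are rewired
#'   weight matrices; replicates where no swap was possible are kept as
#'   copies of the original with an attribute `n_swaps = 0`.
#' @export
rewire_length_preserving <- function(c, n_bins = 10L, n_reps = 2000L,
                                     seed = 1L) {
  W <- c$weights
  n <- nrow(W)
  D <- as.matrix(dist(c$coords))
  ut <- which(upper.tri(W) & W > 0)
  if (length(ut) < 2) stop("graph too small to swap")
  ii <- row(W)[ut]; jj <- col(W)[ut]
  ww <- W[ut]
  elen <- D[ut]
  rng <- range(elen)
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  binof <- function(len) findInterval(len, brk, rightmost.closed = TRUE,
                                      all.inside = TRUE)
  bin <- binof(elen)
  ne <- length(ut)
  bins_ok <- which(tabulate(bin, nbins = n_bins) >= 2L)
  if (!length(bins_ok)) stop("no length bin holds two edges")

  members <- with_stream(seed, "rewire", lapply(seq_len(n_reps), function(rep) {
    ei <- ii; ej <- jj; eb <- bin
    adj <- W > 0
    n_swaps <- 0L
    for (att in seq_len(10L * ne)) {
      b <- bins_ok[sample.int(length(bins_ok), 1L)]
      cand <- which(eb == b)
      if (length(cand) < 2L) next
      pick <- cand[sample.int(length(cand), 2L)]
      a <- ei[pick[1]]; bb <- ej[pick[1]]
      cc <- ei[pick[2]]; dd <- ej[pick[2]]
      # proposed: a-dd, cc-bb
      if (a == dd || cc == bb) next
      if (adj[a, dd] || adj[cc, bb]) next
      if (binof(D[a, dd]) != b || binof(D[cc, bb]) != b) next
      adj[a, bb] <- adj[bb, a] <- FALSE
      adj[cc, dd] <- adj[dd, cc] <- FALSE
      adj[a, dd] <- adj[dd, a] <- TRUE
      adj[cc, bb] <- adj[bb, cc] <- TRUE
      ej[pick[1]] <- dd
      ej[pick[2]] <- bb
      n_swaps <- n_swaps + 1L
    }
    M <- matrix(0, n, n)
    M[cbind(ei, ej)] <- ww
    M[cbind(ej, ei)] <- ww
    attr(M, "n_swaps") <- n_swaps
    M
  }))
  new_null_ensemble("rewire", members, as.integer(seed))
}

# uniform random rotation matrix via normalized quaternion
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Spherical-rotation (spin) permutation null
#'
#' Per replicate a uniform random rotation (normalized quaternion) is
#' applied to the left hemisphere's unit-sphere parcel coordinates and its
#' x-mirrored conjugate to the right hemisphere; each original parcel is
#' then assigned the value of the nearest rotated parcel within its own
#' hemisphere (many-to-one allowed).
#'
#' @param sphere_coords n x 3 unit-norm coordinates.
#' @param hemisphere per-node `"L"`/`"R"` labels.
#' @param n_reps number of replicates (default 2000).
#' @param seed integer seed.
#' @return a `null_ensemble` of kind `"spin"` whose members are
#'   assignment index vectors: `value_null = value[idx]`.
#' @export
spin_permutation <- function(sphere_coords, hemisphere, n_reps = 2000L,
                             seed = 1L) {
  sphere_coords <- as.matrix(sphere_coords)
  hemisphere <- as.character(hemisphere)
  left <- which(hemisphere == "L"); right <- which(hemisphere == "R")
  if (!length(left) || !length(right))
    stop("both hemispheres must be populated")
  Mx <- diag(c(-1, 1, 1))
  assign_nearest <- function(orig, rot) {
    # for each original point, index (into rot's rows) of nearest rotated pt
    cross <- orig %*% t(rot)                # points are unit norm
    max.col(cross, ties.method = "first")   # max cosine = min distance
  }
  members <- with_stream(seed, "spin", lapply(seq_len(n_reps), function(r) {
    R <- random_rotation()
    Rm <- Mx %*% R %*% Mx                   # conjugate by x-reflection
    idx <- integer(length(hemisphere))
    rotL <- sphere_coords[left, , drop = FALSE] %*% t(R)
    rotR <- sphere_coords[right, , drop = FALSE] %*% t(Rm)
    idx[left] <- left[assign_nearest(sphere_coords[left, , drop = FALSE], rotL)]
    idx[right] <- right[assign_nearest(sphere_coords[right, , drop = FALSE], rotR)]
    idx
  }))
  new_null_ensemble("spin", members, as.integer(seed))
}

#' Plain label-permutation null
#'
#' @param n_nodes number of nodes.
#' @param n_reps number of replicates (default 2000).
#' @param seed integer seed.
#' @return a `null_ensemble` of kind `"permute"` whose members are
#'   permutation index vectors.
#' @export
label_permutation <- function(n_nodes, n_reps = 2000L, seed = 1L) {
  if (n_nodes < 2) stop("need at least 2 nodes")
  members <- with_stream(seed, "permute",
                         lapply(seq_len(n_reps),
                                function(r) sample.int(n_nodes)))
  new_null_ensemble("permute", members, as.integer(seed))
}

#' Permutation p-value with the +1 correction
#'
#' `p = (1 + #\{nulls as-or-more extreme\}) / (1 + n_nulls)`; the
#' two-tailed version measures absolute deviation from the null mean.
#'
#' @param observed scalar observed statistic.
#' @param nulls numeric vector of null statistics.
#' @param tail `"two"` (default), `"left"` or `"right"`.
#' @return p-value in `(0, 1]`.
#' @export
permutation_pvalue <- function(observed, nulls, tail = c("two", "left", "right")) {
  tail <- match.arg(tail)
  if (!length(nulls)) stop("empty null distribution")
  k <- switch(tail,
              right = sum(nulls >= observed),
              left = sum(nulls <= observed),
              two = {
                mu <- mean(nulls)
                sum(abs(nulls - mu) >= abs(observed - mu))
              })
  (1 + k) / (1 + length(nulls))
}

#' Benjamini-Hochberg adjusted p-values for a declared family
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, kept as an explicit
#' operation so every multiple-comparison family in the pipeline is
#' declared at its call site.
#'
#' @param p numeric p-values.
#' @return adjusted p-values.
#' @export
fdr_bh <- function(p) p.adjust(p, method = "BH")
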