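# All-pairs weighted shortest paths.
#
# Weights are mapped to lengths by L = -log(W), so stronger connections
# are shorter; the alternative inverse transform L = 1/W is available but
# non-default because it produces highly skewed length distributions.
# Distances, a predecessor matrix, per-pair hop counts and equal-cost tie
# flags come from a Floyd-Warshall sweep with deterministic tie-breaking
# (strict relaxation, ascending intermediate order).

#' Transform a weight matrix to a length graph
#'
#' @param c a [connectome()] object, or a plain symmetric weight matrix in
#'   `[0, 1]`.
#' @param transform `"log"` (default): `L = -log(W)`; `"inv"`: `L = 1/W`.
#' @return list of class `"length_graph"`: `lengths` (n x n, `Inf` for
#'   absent edges and the diagonal), `adjacency` (logical), `transform`.
#'   Any weight equal to 1 is first rescaled globally by `1 - 1e-9` with a
#'   warning, so no edge has zero length.
#' @export
weights_to_lengths <- function(c, transform = c("log", "inv")) {
  transform <- match.arg(transform)
  W <- if (inherits(c, "connectome")) c$weights else as.matrix(c)
  if (any(W < 0)) stop("negative weights")
  if (any(W > 1 + 1e-12)) stop("weights must lie in [0, 1]")
  if (any(W == 1)) {
    warning("weight(s) equal to 1: rescaling all weights by 1 - 1e-9")
    W <- W * (1 - 1e-9)
  }
  adj <- W > 0
  L <- matrix(Inf, nrow(W), ncol(W))
  L[adj] <- if (transform == "log") -log(W[adj]) else 1 / W[adj]
  diag(L) <- Inf
  structure(list(lengths = L, adjacency = adj, transform = transform),
            class = "length_graph")
}

#' All-pairs shortest paths via Floyd-Warshall
#'
#' @param lg a `length_graph` from [weights_to_lengths()].
#' @return list of class `"path_set"`: `dist` (n x n path lengths, 0 on the
#'   diagonal, `Inf` for disconnected pairs), `pred` (predecessor of column
#'   node on the path from the row node; `NA` where no path), `hops`
#'   (integer hop counts, `NA` off-diagonal where disconnected),
#'   `diameter_hops` (max finite hop count), `tie_flags` (logical, `TRUE`
#'   where an equal-cost alternative path exists).
#' @export
all_pairs_paths <- function(lg) {
  stopifnot(inherits(lg, "length_graph"))
  L <- lg$lengths
  n <- nrow(L)
  d <- L
  diag(d) <- 0
  pred <- matrix(NA_integer_, n, n)
  pred[lg$adjacency] <- row(L)[lg$adjacency]
  for (k in seq_len(n)) {
    via <- outer(d[, k], d[k, ], "+")
    upd <- via < d
    if (any(upd)) {
      d[upd] <- via[upd]
      pk <- matrix(pred[k, ], n, n, byrow = TRUE)
      pred[upd] <- pk[upd]
    }
  }
  diag(pred) <- NA_integer_

  hops <- matrix(NA_integer_, n, n)
  diag(hops) <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || !is.finite(d[i, j])) next
      h <- 0L
      cur <- j
      while (cur != i) {
        cur <- pred[i, cur]
        h <- h + 1L
        if (h > n) stop("predecessor cycle detected")
      }
      hops[i, j] <- h
    }
  }

  # equal-cost alternative detection: count intermediates k with
  # d_ik + d_kj == d_ij; the chosen path contributes exactly hops+1 such k
  # (its own nodes, endpoints included), so any excess marks a tie.
  cnt <- matrix(0L, n, n)
  for (k in seq_len(n)) {
    via <- outer(d[, k], d[k, ], "+")
    eq <- is.finite(via) & is.finite(d) & abs(via - d) <= 1e-12
    cnt <- cnt + eq
  }
  tie <- is.finite(d) & (cnt > hops + 1L)
  diag(tie) <- FALSE

  structure(list(dist = d, pred = pred, hops = hops,
                 diameter_hops = if (any(is.finite(d) & row(d) != col(d)))
                   max(hops[row(hops) != col(hops)], na.rm = TRUE) else 0L,
                 tie_flags = tie),
            class = "path_set")
}

#' @export
print.path_set <- function(x, ...) {
  off <- row(x$dist) != col(x$dist)
  cat(sprintf("<path_set> %d nodes, %d/%d connected pairs, hop diameter %d\n",
              nrow(x$dist), sum(is.finite(x$dist[off])), sum(off),
              x$diameter_hops))
  invisible(x)
}

#' Reconstruct one shortest path
#'
#' @param ps a `path_set`.
#' @param s source node index.
#' @param t target node index (`s != t`).
#' @return integer node sequence from `s` to `t`.
#' @export
retrieve_path <- function(ps, s, t) {
  s <- as.integer(s); t <- as.integer(t)
  if (s == t) stop("source and target must differ")
  if (!is.finite(ps$dist[s, t])) stop("target unreachable from source")
  path <- t
  cur <- t
  while (cur != s) {
    cur <- ps$pred[s, cur]
    path <- c(cur, path)
  }
  path
}

#' Wrap an explicit list of paths as a path set
#'
#' Lets the motif, flow and transition operations run on a hand-listed
#' collection of node sequences instead of the all-pairs set of a graph;
#' used for worked examples and toy fixtures.
#'
#' @param paths list of integer node sequences (each of length >= 2).
#' @param n_nodes number of nodes in the underlying graph.
#' @return object of class `"path_set"` carrying the explicit paths.
#' @export
as_path_set <- function(paths, n_nodes) {
  stopifnot(length(paths) >= 1, all(vapply(paths, length, 0L) >= 2L))
  paths <- lapply(paths, as.integer)
  if (any(unlist(paths) > n_nodes | unlist(paths) < 1L))
    stop("path node out of range")
  d <- matrix(Inf, n_nodes, n_nodes)
  diag(d) <- 0
  lens <- vapply(paths, length, 0L) - 1L
  structure(list(dist = d, pred = NULL, hops = NULL,
                 diameter_hops = max(lens), tie_flags = NULL,
                 explicit = paths),
            class = "path_set")
}

# Extract every finite s->t path once, as a long table used by the motif,
# flow, transition and betweenness stages. Returns a list:
#   paths: list of integer node sequences (ordered pairs, s != t)
#   src, tgt, len: per-path source, target, hop count
extract_all_paths <- function(ps) {
  if (!is.null(ps$explicit)) {
    paths <- ps$explicit
    return(list(paths = paths,
                src = vapply(paths, function(p) p[1L], 0L),
                tgt = vapply(paths, function(p) p[length(p)], 0L),
                len = vapply(paths, length, 0L) - 1L))
  }
  n <- nrow(ps$dist)
  paths <- vector("list", n * (n - 1L))
  src <- integer(0); cnt <- 0L
  srcs <- integer(n * (n - 1L)); tgts <- integer(n * (n - 1L))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || !is.finite(ps$dist[i, j])) next
      cnt <- cnt + 1L
      p <- j
      cur <- j
      while (cur != i) {
        cur <- ps$pred[i, cur]
        p <- c(cur, p)
      }
      paths[[cnt]] <- p
      srcs[cnt] <- i; tgts[cnt] <- j
    }
  }
  length(paths) <- cnt
  list(paths = paths, src = srcs[seq_len(cnt)], tgt = tgts[seq_len(cnt)],
       len = vapply(paths, length, 0L) - 1L)
}
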