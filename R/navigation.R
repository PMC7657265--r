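# Greedy navigation under a beta-mixed metric.
#
# An agent at node v forwards towards the structurally connected neighbor
# minimizing d(neighbor, target) where
#   d(i, j) = beta * ||coords_i - coords_j||_norm + (1 - beta) * |h_i - h_j|_norm,
# both terms normalized to [0, 1] over all node pairs. beta = 1 is pure
# spatial navigation, beta = 0 pure hierarchical navigation. The hierarchy
# term uses the absolute difference: a signed difference cannot rank
# neighbors. A walk fails when it revisits a node or exceeds the hop cap.
# Success means the target is reached; strict mode additionally requires
# the walk to equal the shortest-path node sequence.

#' Navigation configuration
#'
#' @param beta_grid ascending beta values in `[0, 1]`
#'   (default `seq(0, 1, by = 0.05)`).
#' @param max_hops walk hop cap (default: number of nodes, set at run
#'   time when `NULL`).
#' @param strict if `TRUE`, success requires reproducing the exact
#'   shortest-path sequence (needs a `path_set`).
#' @return list of class `"nav_config"`.
#' @export
nav_config <- function(beta_grid = seq(0, 1, by = 0.05), max_hops = NULL,
                       strict = FALSE) {
  stopifnot(all(beta_grid >= 0), all(beta_grid <= 1),
            !is.unsorted(beta_grid), is.null(max_hops) || max_hops >= 1)
  structure(list(beta_grid = beta_grid, max_hops = max_hops,
                 strict = strict), class = "nav_config")
}

# normalized distance components shared by all navigation entry points
nav_metrics <- function(coords, hmap) {
  D <- as.matrix(dist(coords))
  H <- abs(outer(hmap$gradient, hmap$gradient, "-"))
  dmax <- max(D); hmax <- max(H)
  if (dmax <= 0 || hmax <= 0) stop("degenerate geometry or gradient")
  list(D = D / dmax, H = H / hmax)
}

#' Combined spatial-hierarchical distance between two nodes
#'
#' @param i,j node indices.
#' @param beta mixing weight in `[0, 1]` (1 = pure space).
#' @param coords n x 3 Euclidean coordinates.
#' @param hmap a [hierarchy_map()].
#' @return nonnegative scalar.
#' @export
combined_distance <- function(i, j, beta, coords, hmap) {
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]")
  m <- nav_metrics(coords, hmap)
  beta * m$D[i, j] + (1 - beta) * m$H[i, j]
}

# next-hop table for one beta: next_hop[v, t] = neighbor of v minimizing
# the combined distance to t, ties to the lower node index; NA if v has
# no neighbors.
next_hop_table <- function(adj, Dmix) {
  n <- nrow(adj)
  nh <- matrix(NA_integer_, n, n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ])
    if (!length(nb)) next
    sub <- Dmix[nb, , drop = FALSE]
    nh[v, ] <- nb[max.col(-t(sub), ties.method = "first")]
  }
  diag(nh) <- NA_integer_
  nh
}

#' Run one greedy navigation walk
#'
#' @param source,target node indices, `source != target`.
#' @param beta mixing weight.
#' @param c a [connectome()].
#' @param hmap a [hierarchy_map()].
#' @param cfg a [nav_config()].
#' @return list `outcome` (`"success"` or `"failure"`) and `walk`
#'   (node sequence, including both endpoints on success).
#' @export
greedy_navigate <- function(source, target, beta, c, hmap,
                            cfg = nav_config()) {
  stopifnot(source != target)
  adj <- c$weights > 0
  if (!any(adj[source, ])) stop("isolated source node")
  m <- nav_metrics(c$coords, hmap)
  Dmix <- beta * m$D + (1 - beta) * m$H
  nh <- next_hop_table(adj, Dmix)
  max_hops <- if (is.null(cfg$max_hops)) c$n_nodes else cfg$max_hops
  walk_one(nh, source, target, max_hops)
}

walk_one <- function(nh, source, target, max_hops) {
  source <- as.integer(source); target <- as.integer(target)
  walk <- source
  visited <- logical(nrow(nh))
  visited[source] <- TRUE
  cur <- source
  for (h in seq_len(max_hops)) {
    nxt <- nh[cur, target]
    if (is.na(nxt)) return(list(outcome = "failure", walk = walk))
    walk <- c(walk, nxt)
    if (nxt == target) return(list(outcome = "success", walk = walk))
    if (visited[nxt]) return(list(outcome = "failure", walk = walk))
    visited[nxt] <- TRUE
    cur <- nxt
  }
  list(outcome = "failure", walk = walk)
}

#' Per-source navigation success curves over the beta grid
#'
#' For every source node and every beta, the success ratio `S_R` is the
#' fraction of the `n - 1` targets reached by greedy navigation.
#'
#' @param c a [connectome()].
#' @param hmap a [hierarchy_map()].
#' @param cfg a [nav_config()]; with `strict = TRUE`, `ps` must be given
#'   and success additionally requires matching the shortest-path
#'   sequence.
#' @param ps optional `path_set` for strict mode.
#' @return list of class `"navigation_result"`: `success` (n_sources x
#'   n_beta matrix), `beta_grid`, `mean_curve`.
#' @export
success_curves <- function(c, hmap, cfg = nav_config(), ps = NULL) {
  n <- c$n_nodes
  adj <- c$weights > 0
  m <- nav_metrics(c$coords, hmap)
  max_hops <- if (is.null(cfg$max_hops)) n else cfg$max_hops
  if (cfg$strict && is.null(ps))
    stop("strict mode needs a path_set")
  S <- matrix(0, n, length(cfg$beta_grid))
  for (b in seq_along(cfg$beta_grid)) {
    beta <- cfg$beta_grid[b]
    Dmix <- beta * m$D + (1 - beta) * m$H
    nh <- next_hop_table(adj, Dmix)
    for (s in seq_len(n)) {
      ok <- 0L
      for (t in seq_len(n)) {
        if (t == s) next
        w <- walk_one(nh, s, t, max_hops)
        if (w$outcome == "success") {
          if (cfg$strict) {
            sp <- tryCatch(retrieve_path(ps, s, t), error = function(e) NULL)
            if (!is.null(sp) && identical(as.integer(w$walk), as.integer(sp)))
              ok <- ok + 1L
          } else ok <- ok + 1L
        }
      }
      S[s, b] <- ok / (n - 1L)
    }
  }
  structure(list(success = S, beta_grid = cfg$beta_grid,
                 mean_curve = colMeans(S)),
            class = "navigation_result")
}

#' Select each source's preferred beta from detrended success curves
#'
#' The global trend (mean curve over sources) is subtracted from each
#' source's curve; `beta_star` is the grid value maximizing the residual,
#' ties resolved to the smallest beta. Sources whose detrended curve is
#' constant (to `1e-12`) are flagged with `NA`.
#'
#' @param nr a `navigation_result`.
#' @return data.frame with columns `source`, `beta_star`, `detrended_max`.
#' @export
select_beta <- function(nr) {
  S <- nr$success
  det <- sweep(S, 2, nr$mean_curve)
  out <- data.frame(source = seq_len(nrow(S)),
                    beta_star = NA_real_, detrended_max = NA_real_)
  for (s in seq_len(nrow(S))) {
    v <- det[s, ]
    if (max(v) - min(v) <= 1e-12) next  # flat: no preference
    i <- which.max(v)                   # which.max takes the first maximum
    out$beta_star[s] <- nr$beta_grid[i]
    out$detrended_max[s] <- v[i]
  }
  out
}
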