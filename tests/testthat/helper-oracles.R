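# Independent oracles and small fixture builders. Everything here is
# deliberately naive (single-source relaxation, exhaustive enumeration,
# direct formula evaluation) and shares no code path with the package
# implementations it checks.

# single-source shortest-path relaxation (Dijkstra without a heap)
oracle_sssp <- function(L, s) {
  n <- nrow(L)
  dist <- rep(Inf, n)
  dist[s] <- 0
  done <- logical(n)
  for (it in seq_len(n)) {
    u <- which(!done & is.finite(dist))
    if (!length(u)) break
    u <- u[which.min(dist[u])]
    done[u] <- TRUE
    for (v in seq_len(n)) {
      if (is.finite(L[u, v]) && dist[u] + L[u, v] < dist[v])
        dist[v] <- dist[u] + L[u, v]
    }
  }
  dist
}

# random connected-ish symmetric weight matrix, weights in (0, 0.95]
random_weight_graph <- function(n, p = 0.3) {
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W))
  on <- ut[runif(length(ut)) < p]
  W[on] <- runif(length(on), 0.05, 0.95)
  W + t(W)
}

# per-node flow statistics recomputed from an explicit path list by the
# hand rule: interior position i contributes outgoing slope h[v_{i+1}] -
# h[v_i]; local min/max of the motif are turning up/down events
oracle_flow <- function(paths, h) {
  n <- length(h)
  ssum <- rep(0, n); nint <- rep(0L, n)
  nup <- rep(0L, n); ndown <- rep(0L, n)
  for (p in paths) {
    if (length(p) < 3) next
    for (i in 2:(length(p) - 1)) {
      v <- p[i]
      nint[v] <- nint[v] + 1L
      ssum[v] <- ssum[v] + (h[p[i + 1]] - h[v])
      a <- h[v] - h[p[i - 1]]
      b <- h[p[i + 1]] - h[v]
      if (a < 0 && b > 0) nup[v] <- nup[v] + 1L
      if (a > 0 && b < 0) ndown[v] <- ndown[v] + 1L
    }
  }
  list(mean_slope = ifelse(nint > 0, ssum / nint, NA_real_),
       p_turn_up = ifelse(nint > 0, nup / nint, NA_real_),
       p_turn_down = ifelse(nint > 0, ndown / nint, NA_real_),
       n_interior = nint)
}

# transition matrices by exhaustive (path, t) enumeration
oracle_transitions <- function(paths, classes, n_bins, kind = c("T", "M")) {
  kind <- match.arg(kind)
  kmax <- max(vapply(paths, length, 0L)) - 1L
  out <- vector("list", kmax)
  for (k in seq_len(kmax)) {
    num <- matrix(0, n_bins, n_bins)
    den <- 0L
    for (p in paths) {
      L <- length(p)
      ts <- if (kind == "T") k else seq_len(max(0L, L - k))
      for (t in ts) {
        if (L >= t + (if (kind == "T") 1L else k)) {
          den <- den + 1L
          j <- if (kind == "T") t + 1L else t + k
          num[classes[p[t]], classes[p[j]]] <- num[classes[p[t]], classes[p[j]]] + 1
        }
      }
    }
    out[[k]] <- if (den > 0) num / den else num
  }
  out
}

# exhaustive greedy walk in a single metric given explicitly
oracle_greedy <- function(adj, metric, s, t, max_hops) {
  cur <- s; visited <- s
  for (h in seq_len(max_hops)) {
    nb <- which(adj[cur, ])
    if (!length(nb)) return(FALSE)
    nxt <- nb[which.min(metric[nb, t])]
    if (nxt == t) return(TRUE)
    if (nxt %in% visited) return(FALSE)
    visited <- c(visited, nxt)
    cur <- nxt
  }
  FALSE
}

# Moran's I, direct formula (row-standardized weights not applied)
oracle_moran <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  (n / sum(W)) * sum(W * outer(z, z)) / sum(z^2)
}

# small bilateral geometry for null-model tests
toy_geometry <- function(n = 20, seed = 1) {
  generate_geometry(synthetic_config(n_nodes = n, n_partitions = 2,
                                     seed = seed))
}

# a connectome around an explicit weight matrix with simple geometry
wrap_connectome <- function(W, coords = NULL, h = NULL) {
  n <- nrow(W)
  if (is.null(coords)) {
    ang <- 2 * pi * (seq_len(n) - 1) / n
    sphere <- cbind(cos(ang), sin(ang), 0)
  } else {
    sphere <- coords / sqrt(rowSums(coords^2))
    sphere[!is.finite(sphere)] <- 0
  }
  if (is.null(coords)) coords <- sphere * 100
  connectome(W, coords = coords, sphere_coords = sphere,
             hemisphere = rep(c("L", "R"), length.out = n))
}
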