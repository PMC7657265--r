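# Per-node flow statistics through the hierarchy.
#
# For a path v_1, ..., v_n and interior position i, the slope at v_i is
# h(v_{i+1}) - h(v_i): the outgoing segment only, which for the two
# traversals {A,B,C,D} and {D,C,B,A} gives node C the mean slope
# (h(D) + h(B) - 2 h(C)) / 2. A positive mean slope marks a node that
# directs flow up the hierarchy. Interior local minima of the motif are
# turning-up events, local maxima turning-down events; zero-slope
# segments count as neither.

# shared accumulation over all interior traversals
flow_events <- function(ps, hmap) {
  if (nrow(ps$dist) != length(hmap$gradient))
    stop("path set and hierarchy map node counts differ")
  ep <- extract_all_paths(ps)
  h <- hmap$gradient
  keep <- ep$len >= 2L
  paths <- ep$paths[keep]
  node <- unlist(lapply(paths, function(p) p[-c(1L, length(p))]))
  prev <- unlist(lapply(paths, function(p) p[seq_len(length(p) - 2L)]))
  nxt <- unlist(lapply(paths, function(p) p[-c(1L, 2L)]))
  list(node = node,
       slope_out = h[nxt] - h[node],
       slope_in = h[node] - h[prev],
       n_nodes = length(h))
}

#' Per-node mean slope through the hierarchy
#'
#' @param ps a `path_set`.
#' @param hmap a [hierarchy_map()].
#' @return data.frame with columns `node`, `mean_slope`, `n_interior`;
#'   `mean_slope` is `NA` (flagged undefined) for nodes that never appear
#'   in a path interior.
#' @export
node_slopes <- function(ps, hmap) {
  ev <- flow_events(ps, hmap)
  n <- ev$n_nodes
  n_int <- tabulate(ev$node, nbins = n)
  ssum <- rep(0, n)
  if (length(ev$node)) {
    agg <- rowsum(ev$slope_out, ev$node)
    ssum[as.integer(rownames(agg))] <- agg[, 1]
  }
  data.frame(node = seq_len(n),
             mean_slope = ifelse(n_int > 0, ssum / n_int, NA_real_),
             n_interior = n_int)
}

#' Per-node turning-point probabilities
#'
#' @param ps a `path_set`.
#' @param hmap a [hierarchy_map()].
#' @return data.frame with columns `node`, `p_turn_up`, `p_turn_down`,
#'   `n_up`, `n_down`, `n_interior`; probabilities `NA` where
#'   `n_interior = 0`.
#' @export
turning_points <- function(ps, hmap) {
  ev <- flow_events(ps, hmap)
  n <- ev$n_nodes
  n_int <- tabulate(ev$node, nbins = n)
  up <- ev$slope_in < 0 & ev$slope_out > 0    # local minimum
  down <- ev$slope_in > 0 & ev$slope_out < 0  # local maximum
  n_up <- tabulate(ev$node[up], nbins = n)
  n_down <- tabulate(ev$node[down], nbins = n)
  data.frame(node = seq_len(n),
             p_turn_up = ifelse(n_int > 0, n_up / n_int, NA_real_),
             p_turn_down = ifelse(n_int > 0, n_down / n_int, NA_real_),
             n_up = n_up, n_down = n_down, n_interior = n_int)
}

#' Combined per-node flow statistics table
#'
#' @param ps a `path_set`.
#' @param hmap a [hierarchy_map()].
#' @return data.frame `node, mean_slope, p_turn_up, p_turn_down,
#'   n_interior`.
#' @export
flow_stats <- function(ps, hmap) {
  s <- node_slopes(ps, hmap)
  tp <- turning_points(ps, hmap)
  data.frame(node = s$node, mean_slope = s$mean_slope,
             p_turn_up = tp$p_turn_up, p_turn_down = tp$p_turn_down,
             n_interior = s$n_interior)
}

#' Aggregate flow statistics over a partition
#'
#' Unweighted mean over member nodes with at least one interior traversal.
#' Labels with no valid node are reported with `NA` means and
#' `n_valid = 0`.
#'
#' @param fs output of [flow_stats()] (or [node_slopes()] /
#'   [turning_points()]).
#' @param partition integer per-node labels.
#' @return data.frame with one row per label.
#' @export
network_aggregate <- function(fs, partition) {
  stopifnot(length(partition) == nrow(fs))
  labs <- sort(unique(partition))
  cols <- intersect(c("mean_slope", "p_turn_up", "p_turn_down"), names(fs))
  out <- lapply(labs, function(l) {
    sel <- partition == l & fs$n_interior > 0
    row <- data.frame(partition = l, n_valid = sum(sel))
    for (cc in cols)
      row[[cc]] <- if (any(sel)) mean(fs[[cc]][sel]) else NA_real_
    row
  })
  do.call(rbind, out)
}

#' Correlation between mean slope and hierarchy position, with spin p-value
#'
#' Pearson correlation over nodes with a defined mean slope; significance
#' from a spatial-autocorrelation-preserving spin ensemble, recomputing the
#' correlation against each spun gradient:
#' `p = (1 + #\{|r_null| >= |r|\}) / (1 + n_nulls)` (two-tailed by default).
#'
#' @param fs output of [node_slopes()] or [flow_stats()].
#' @param hmap a [hierarchy_map()].
#' @param nulls a `null_ensemble` of kind `"spin"` or `"permute"` (index
#'   vectors into the original nodes).
#' @param tail `"two"` (default), `"left"` or `"right"`.
#' @return list `r`, `p_spin`, `n_valid`.
#' @export
slope_hierarchy_correlation <- function(fs, hmap, nulls,
                                        tail = c("two", "left", "right")) {
  tail <- match.arg(tail)
  valid <- !is.na(fs$mean_slope)
  if (sum(valid) < 3) stop("fewer than 3 nodes with defined slope")
  s <- fs$mean_slope[valid]
  g <- hmap$gradient
  r <- cor(s, g[valid])
  rn <- vapply(nulls$members, function(idx) cor(s, g[idx][valid]), 0)
  # two-tailed in the |r| sense: correlations are naturally centred on 0
  p <- switch(tail,
              two = (1 + sum(abs(rn) >= abs(r))) / (1 + length(rn)),
              left = (1 + sum(rn <= r)) / (1 + length(rn)),
              right = (1 + sum(rn >= r)) / (1 + length(rn)))
  list(r = r, p_spin = p, n_valid = sum(valid))
}
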