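# Simple per-node network measures and their correlation with the
# motif-derived measures (mean slope, turning probabilities, beta_star).
#
# Betweenness is deliberately counted over the same unique shortest-path
# set used by every motif analysis (interior memberships in the path_set),
# not re-derived independently, so the comparison is internally
# consistent. Weighted clustering uses the Onnela geometric-mean triangle
# formulation on weights normalized by their maximum.

#' Structural per-node measures
#'
#' @param c a [connectome()].
#' @param lg the `length_graph` used for paths (for bookkeeping; closeness
#'   is computed from `ps$dist`).
#' @param ps the `path_set` of the pipeline.
#' @return data.frame with columns `node`, `betweenness` (interior
#'   membership count over unique shortest paths), `closeness` (inverse
#'   mean shortest-path distance over reachable nodes; flagged via
#'   `n_reachable` when the graph is disconnected), `clustering`,
#'   `degree`, `mean_edge_length`.
#' @export
structural_measures <- function(c, lg, ps) {
  n <- c$n_nodes
  ep <- extract_all_paths(ps)
  interior <- unlist(lapply(ep$paths[ep$len >= 2L],
                            function(p) p[-c(1L, length(p))]))
  btw <- tabulate(interior, nbins = n)

  d <- ps$dist
  diag(d) <- NA
  closeness <- apply(d, 1, function(row) {
    r <- row[is.finite(row)]
    if (!length(r)) 0 else 1 / mean(r)
  })
  n_reachable <- apply(d, 1, function(row) sum(is.finite(row)))

  W <- c$weights
  What <- W / max(W)
  deg <- rowSums(W > 0)
  cube <- What^(1 / 3)
  num <- diag(cube %*% cube %*% cube)
  clustering <- ifelse(deg > 1, num / (deg * (deg - 1)), 0)

  D <- as.matrix(dist(c$coords))
  mel <- vapply(seq_len(n), function(i) {
    nb <- which(W[i, ] > 0)
    if (!length(nb)) NA_real_ else mean(D[i, nb])
  }, 0)

  data.frame(node = seq_len(n), betweenness = btw, closeness = closeness,
             n_reachable = n_reachable, clustering = clustering,
             degree = deg, mean_edge_length = mel)
}

#' Functional per-node measures
#'
#' Strength is the FC row sum excluding the diagonal. The participation
#' coefficient `P_i = 1 - sum_s (kappa_is / k_i)^2` is computed on
#' positive FC values against the partition; nodes with zero positive
#' strength are flagged `NA`.
#'
#' @param fc a [functional_matrix()].
#' @param partition integer per-node module labels.
#' @return data.frame with columns `node`, `fc_strength`, `participation`.
#' @export
functional_measures <- function(fc, partition) {
  X <- unclass(as.matrix(fc))
  n <- nrow(X)
  stopifnot(length(partition) == n)
  diag(X) <- 0
  strength <- rowSums(X)
  P <- X
  P[P < 0] <- 0
  k <- rowSums(P)
  labs <- sort(unique(partition))
  kappa <- sapply(labs, function(l) rowSums(P[, partition == l, drop = FALSE]))
  part <- ifelse(k > 0, 1 - rowSums((kappa / pmax(k, .Machine$double.eps))^2),
                 NA_real_)
  data.frame(node = seq_len(n), fc_strength = strength, participation = part)
}

#' Correlate simple measures with motif-derived measures
#'
#' @param sm merged simple-measure data.frame ([structural_measures()]
#'   columns plus [functional_measures()] columns).
#' @param fs flow statistics from [flow_stats()].
#' @param nr beta preferences from [select_beta()].
#' @return data.frame with one row per (simple, motif) pair: Pearson `r`
#'   over nodes valid in both, `n`; constant columns are flagged `NA`.
#' @export
correlate_measures <- function(sm, fs, nr) {
  simple_cols <- c("betweenness", "closeness", "clustering", "degree",
                   "mean_edge_length", "fc_strength", "participation")
  simple_cols <- intersect(simple_cols, names(sm))
  motif <- data.frame(mean_slope = fs$mean_slope,
                      p_turn_up = fs$p_turn_up,
                      p_turn_down = fs$p_turn_down,
                      beta_star = nr$beta_star)
  out <- list()
  for (sc in simple_cols) {
    for (mc in names(motif)) {
      x <- sm[[sc]]; yv <- motif[[mc]]
      ok <- is.finite(x) & is.finite(yv)
      r <- if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(yv[ok]) == 0) NA_real_
           else cor(x[ok], yv[ok])
      out[[length(out) + 1L]] <- data.frame(simple = sc, motif = mc,
                                            r = r, n = sum(ok))
    }
  }
  do.call(rbind, out)
}
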