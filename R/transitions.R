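# Transition-probability matrices over hierarchy bins.
#
# Positions are 1-based and length(sp) is the node count of the path, so
# "length(sp) >= t + 1" guarantees sp(t+1) exists. The 1-hop matrix at
# position t is
#   T_ij(t) = #{sp : sp(t) in bin i, sp(t+1) in bin j} / #{sp : length(sp) >= t+1},
# and the multi-hop (memory) matrix at lag k pools all valid start
# positions across paths,
#   M_ij(k) = sum_t #{sp : sp(t)=i, sp(t+k)=j} / sum_t #{sp : length(sp) >= t+k},
# which makes each populated matrix total-mass 1 and makes M(1) the
# position-pooled version of the T stack. Rows need not sum to 1.

transition_stack <- function(ps, hmap, by = c("position", "lag")) {
  by <- match.arg(by)
  if (nrow(ps$dist) != length(hmap$gradient))
    stop("path set and hierarchy map node counts differ")
  ep <- extract_all_paths(ps)
  nb <- hmap$n_bins
  cls <- hmap$classes
  nodecount <- ep$len + 1L
  kmax <- max(nodecount) - 1L
  mats <- vector("list", kmax)
  support <- integer(kmax)
  for (k in seq_len(kmax)) {
    num <- matrix(0, nb, nb)
    den <- 0L
    for (p in seq_along(ep$paths)) {
      path <- ep$paths[[p]]
      L <- length(path)
      if (by == "position") {
        # k plays the role of the position t at lag 1
        if (L >= k + 1L) {
          den <- den + 1L
          i <- cls[path[k]]; j <- cls[path[k + 1L]]
          num[i, j] <- num[i, j] + 1
        }
      } else {
        ts <- seq_len(max(0L, L - k))
        den <- den + length(ts)
        for (t in ts) {
          i <- cls[path[t]]; j <- cls[path[t + k]]
          num[i, j] <- num[i, j] + 1
        }
      }
    }
    support[k] <- den
    mats[[k]] <- if (den > 0) num / den else num
  }
  list(matrices = mats, support = support, n_bins = nb)
}

#' 1-hop transition matrices by path position
#'
#' @param ps a `path_set`.
#' @param hmap a [hierarchy_map()].
#' @return list of class `"transition_stack"`: `matrices` (one `n_bins x
#'   n_bins` matrix per position `t = 1 .. max path node count - 1`),
#'   `support` (eligible-path counts), `n_bins`.
#' @export
one_hop <- function(ps, hmap) {
  out <- transition_stack(ps, hmap, by = "position")
  out$kind <- "one_hop"
  class(out) <- "transition_stack"
  out
}

#' Multi-hop (memory) transition matrices by lag
#'
#' @param ps a `path_set`.
#' @param hmap a [hierarchy_map()].
#' @return list of class `"transition_stack"` with `matrices` indexed by
#'   lag `k`; `M(1)` equals the position-pooled 1-hop counts.
#' @export
multi_hop <- function(ps, hmap) {
  out <- transition_stack(ps, hmap, by = "lag")
  out$kind <- "multi_hop"
  class(out) <- "transition_stack"
  out
}

#' @export
print.transition_stack <- function(x, ...) {
  cat(sprintf("<transition_stack:%s> %d matrices (%d x %d), supports %s\n",
              x$kind, length(x$matrices), x$n_bins, x$n_bins,
              paste(x$support, collapse = ", ")))
  invisible(x)
}

#' Diagonal-dominance summary of a transition stack
#'
#' For each matrix in the stack, reports the total diagonal mass
#' `sum_i M_ii`, the mass on the diagonal plus first off-diagonals, and
#' the mean `|i - j|` spread weighted by transition mass.
#'
#' @param tt a `transition_stack`.
#' @return data.frame with columns `k`, `support`, `diag_mass`,
#'   `near_diag_mass`, `mean_spread`.
#' @export
memory_profile <- function(tt) {
  nb <- tt$n_bins
  ij <- abs(outer(seq_len(nb), seq_len(nb), "-"))
  out <- lapply(seq_along(tt$matrices), function(k) {
    M <- tt$matrices[[k]]
    tot <- sum(M)
    data.frame(k = k, support = tt$support[k],
               diag_mass = sum(diag(M)),
               near_diag_mass = sum(M[ij <= 1]),
               mean_spread = if (tot > 0) sum(M * ij) / tot else NA_real_)
  })
  do.call(rbind, out)
}
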