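# Group-consensus connectome assembly.
#
# The consensus procedure preserves (a) the mean subject density and
# (b) the pooled edge-length distribution: extant edges are pooled across
# subjects, split into intra- and interhemispheric sets so interhemispheric
# edges are not underrepresented, binned by Euclidean length into
# equal-width bins, and within each bin the k most frequently occurring
# edges are kept, k being the rounded mean subject edge count of that bin.

#' Default number of length bins
#'
#' The default follows the edge-count reading of the square-root heuristic:
#' `round(sqrt(mean number of extant edges per subject))`. The literal
#' density-as-a-fraction reading would give fewer than 2 bins and is
#' selectable via `interpretation = "density"`.
#'
#' @param subject_weights list of subject weight matrices.
#' @param interpretation `"edges"` (default) or `"density"`.
#' @return integer bin count, at least 1.
#' @export
consensus_nbins <- function(subject_weights, interpretation = c("edges", "density")) {
  interpretation <- match.arg(interpretation)
  n <- nrow(subject_weights[[1]])
  cnt <- vapply(subject_weights, function(w) sum(w[upper.tri(w)] > 0), 0)
  x <- if (interpretation == "edges") mean(cnt)
       else mean(cnt / (n * (n - 1) / 2))
  max(1L, as.integer(round(sqrt(x))))
}

#' Assemble a group-consensus structural connectome
#'
#' @param subject_weights list of >= 2 symmetric weight matrices of common
#'   shape, entries in `[0, 1]`.
#' @param coords n x 3 Euclidean node coordinates.
#' @param hemisphere per-node `"L"`/`"R"` labels.
#' @param n_bins number of equal-width edge-length bins; default from
#'   [consensus_nbins()].
#' @param weight_mean `"all"` (default): consensus edge weight is the mean
#'   across all subjects, zeros included; `"nonzero"`: mean over the
#'   subjects expressing the edge.
#' @return list with `weights` (symmetric consensus matrix) and `report`
#'   (per-bin kept counts, final binary density, inter/intra edge counts).
#' @export
consensus_sc <- function(subject_weights, coords, hemisphere, n_bins = NULL,
                         weight_mean = c("all", "nonzero")) {
  weight_mean <- match.arg(weight_mean)
  if (length(subject_weights) < 2) stop("need at least 2 subjects")
  n <- nrow(subject_weights[[1]])
  for (w in subject_weights)
    if (!all(dim(w) == c(n, n))) stop("subject matrices differ in shape")
  if (is.null(n_bins)) n_bins <- consensus_nbins(subject_weights)
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("n_bins must be >= 1")

  ut <- which(upper.tri(matrix(0, n, n)))
  ii <- row(diag(n))[ut]; jj <- col(diag(n))[ut]
  D <- as.matrix(dist(coords))
  elen <- D[ut]
  inter <- hemisphere[ii] != hemisphere[jj]

  nsub <- length(subject_weights)
  freq <- Reduce(`+`, lapply(subject_weights, function(w) (w[ut] > 0) + 0))
  wsum <- Reduce(`+`, lapply(subject_weights, function(w) w[ut]))
  mean_all <- wsum / nsub
  mean_nonzero <- ifelse(freq > 0, wsum / freq, 0)

  if (!any(freq > 0)) stop("empty pooled edge set")

  keep <- logical(length(ut))
  bin_rows <- list()
  for (hemi_class in c(FALSE, TRUE)) {     # intra, inter
    sel <- which(inter == hemi_class & freq > 0)
    if (!length(sel)) next
    rng <- range(elen[sel])
    brk <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    bin <- findInterval(elen[sel], brk, rightmost.closed = TRUE,
                        all.inside = TRUE)
    for (b in seq_len(n_bins)) {
      members <- sel[bin == b]
      if (!length(members)) next
      # k = round(mean subject edge count in this bin) -- per-subject counts
      # of extant edges among this bin's pooled pairs
      k <- round(sum(freq[members]) / nsub)
      if (k <= 0) next
      # rank by frequency, ties by larger mean weight, then lower (i, j)
      o <- order(-freq[members], -mean_all[members],
                 ii[members], jj[members])
      chosen <- members[o[seq_len(min(k, length(members)))]]
      keep[chosen] <- TRUE
      bin_rows[[length(bin_rows) + 1L]] <- data.frame(
        hemi = if (hemi_class) "inter" else "intra", bin = b,
        length_lo = brk[b], length_hi = brk[b + 1L],
        available = length(members), kept = min(k, length(members)))
    }
  }

  wcons <- matrix(0, n, n)
  vals <- if (weight_mean == "all") mean_all else mean_nonzero
  wcons[ut[keep]] <- vals[keep]
  wcons <- wcons + t(wcons)

  report <- list(n_bins = n_bins,
                 bins = do.call(rbind, bin_rows),
                 density = sum(keep) / length(ut),
                 n_edges_inter = sum(keep & inter),
                 n_edges_intra = sum(keep & !inter),
                 weight_mean = weight_mean)
  list(weights = wcons, report = report)
}

#' Average functional connectivity across subjects
#'
#' Element-wise mean with the diagonal reset to 1.
#'
#' @param subject_fcs list of >= 1 [functional_matrix()] objects (or plain
#'   symmetric correlation matrices).
#' @return a [functional_matrix()].
#' @export
mean_fc <- function(subject_fcs) {
  if (!length(subject_fcs)) stop("need at least one FC matrix")
  n <- nrow(subject_fcs[[1]])
  for (m in subject_fcs)
    if (!all(dim(m) == c(n, n))) stop("FC matrices differ in shape")
  avg <- Reduce(`+`, lapply(subject_fcs, unclass)) / length(subject_fcs)
  diag(avg) <- 1
  functional_matrix(avg)
}
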