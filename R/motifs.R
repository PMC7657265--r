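# Path motifs: the sequence of hierarchy values met along a shortest path,
# averaged within (source class, target class, hop length) cells.

#' Trace the hierarchy motif of one path
#'
#' @param path integer node sequence.
#' @param hmap a [hierarchy_map()].
#' @return numeric sequence `h(v_1), ..., h(v_n)`.
#' @export
trace_motif <- function(path, hmap) {
  if (!length(path)) stop("empty path")
  if (any(path < 1L) || any(path > length(hmap$gradient)))
    stop("path contains out-of-range nodes")
  hmap$gradient[path]
}

#' Mean path motifs by source class, target class and path length
#'
#' For every (source class, target class, hop length) cell with at least
#' one path, computes the per-position mean of hierarchy values over all
#' member paths with a normal-approximation 95% CI half-width
#' `1.96 * sd / sqrt(n_paths)`. Direct edges are included as two-point
#' motifs. Motifs carry continuous gradient values by default; `y = "bins"`
#' averages class indices instead.
#'
#' @param ps a `path_set` from [all_pairs_paths()].
#' @param hmap a [hierarchy_map()] on the same node set.
#' @param y `"gradient"` (default) or `"bins"`.
#' @return data.frame with columns `src_class`, `tgt_class`, `length`,
#'   `position` (0-based hop position), `mean`, `ci`, `n`.
#' @export
mean_motifs <- function(ps, hmap, y = c("gradient", "bins")) {
  y <- match.arg(y)
  if (nrow(ps$dist) != length(hmap$gradient))
    stop("path set and hierarchy map node counts differ")
  ep <- extract_all_paths(ps)
  vals <- if (y == "gradient") hmap$gradient else as.numeric(hmap$classes)
  cls <- hmap$classes
  np <- length(ep$paths)
  if (!np) return(data.frame(src_class = integer(0), tgt_class = integer(0),
                             length = integer(0), position = integer(0),
                             mean = numeric(0), ci = numeric(0), n = integer(0)))
  long <- data.table::data.table(
    src_class = rep(cls[ep$src], ep$len + 1L),
    tgt_class = rep(cls[ep$tgt], ep$len + 1L),
    length = rep(ep$len, ep$len + 1L),
    position = unlist(lapply(ep$len, function(l) 0:l)),
    h = vals[unlist(ep$paths)])
  agg <- long[, list(mean = mean(h),
                     ci = if (.N > 1) 1.96 * sd(h) / sqrt(.N) else 0,
                     n = .N),
              by = c("src_class", "tgt_class", "length", "position")]
  data.table::setorderv(agg, c("src_class", "tgt_class", "length", "position"))
  as.data.frame(agg)
}
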