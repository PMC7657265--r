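#' Construct and validate a connectome object
#'
#' A connectome bundles the symmetric weight matrix `W` (fiber-density
#' values in `[0, 1]`, zero diagonal) with node geometry: 3D Euclidean
#' coordinates, unit-sphere projection coordinates used by the spin null,
#' a hemisphere label per node, and an optional intrinsic-network style
#' partition.
#'
#' @param weights n x n numeric matrix, symmetric, entries in `[0, 1]`,
#'   zero diagonal. Asymmetries up to `sym_tol` are averaged away with a
#'   warning; anything larger is an error.
#' @param coords n x 3 numeric matrix of node positions (arbitrary length
#'   units, typically mm).
#' @param sphere_coords n x 3 numeric matrix of unit-norm spherical
#'   projection coordinates.
#' @param hemisphere character vector of `"L"`/`"R"` labels, one per node.
#' @param partition optional integer vector of module labels forming a
#'   contiguous `1..m` set.
#' @param names optional character node identifiers; defaults to
#'   `node_1 ... node_n`.
#' @param sym_tol tolerance below which asymmetric input is symmetrized.
#' @return an object of class `"connectome"`: a list with elements
#'   `n_nodes`, `weights`, `coords`, `sphere_coords`, `hemisphere`,
#'   `partition`, `names`.
#' @export
connectome <- function(weights, coords, sphere_coords, hemisphere,
                       partition = NULL, names = NULL, sym_tol = 1e-9) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) stop("weight matrix must be square")
  if (anyNA(weights)) stop("weight matrix contains NA/NaN entries")
  if (any(weights < 0)) stop("negative weights are not allowed")
  if (any(weights > 1 + 1e-12)) stop("weights must lie in [0, 1]")
  asym <- max(abs(weights - t(weights)))
  if (asym > sym_tol) {
    stop(sprintf("weight matrix asymmetric beyond tolerance (max |w_ij - w_ji| = %.3g)",
                 asym))
  }
  if (asym > 0) {
    warning(sprintf("symmetrizing weight matrix (max asymmetry %.3g)", asym))
    weights <- (weights + t(weights)) / 2
  }
  diag(weights) <- 0

  coords <- as.matrix(coords)
  sphere_coords <- as.matrix(sphere_coords)
  if (nrow(coords) != n || ncol(coords) != 3L)
    stop("coords must be an n x 3 matrix matching the weight matrix")
  if (nrow(sphere_coords) != n || ncol(sphere_coords) != 3L)
    stop("sphere_coords must be an n x 3 matrix matching the weight matrix")
  if (!all(is.finite(coords)) || !all(is.finite(sphere_coords)))
    stop("coordinates must be finite")

  hemisphere <- as.character(hemisphere)
  if (length(hemisphere) != n) stop("hemisphere label required for every node")
  if (!all(hemisphere %in% c("L", "R")))
    stop("hemisphere labels must be 'L' or 'R'")

  if (!is.null(partition)) {
    partition <- as.integer(partition)
    if (length(partition) != n) stop("partition must label every node")
    labs <- sort(unique(partition))
    if (!identical(labs, seq_along(labs)))
      stop("partition labels must form a contiguous 1..m set")
  }
  if (is.null(names)) names <- paste0("node_", seq_len(n))
  if (length(names) != n) stop("names must have one entry per node")

  structure(list(n_nodes = n, weights = unname(weights),
                 coords = unname(coords), sphere_coords = unname(sphere_coords),
                 hemisphere = hemisphere, partition = partition,
                 names = as.character(names)),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  dens <- mean(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("<connectome> %d nodes, binary density %.2f%%, hemispheres L=%d R=%d%s\n",
              x$n_nodes, 100 * dens, sum(x$hemisphere == "L"),
              sum(x$hemisphere == "R"),
              if (is.null(x$partition)) ""
              else sprintf(", %d partitions", max(x$partition))))
  invisible(x)
}

#' Construct and validate a functional connectivity matrix
#'
#' @param values n x n symmetric matrix of Pearson correlations, unit
#'   diagonal, entries in `[-1, 1]`.
#' @param tol numerical slack for the range/diagonal/symmetry checks.
#' @return object of class `"functional_matrix"` (the validated matrix).
#' @export
functional_matrix <- function(values, tol = 1e-8) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("FC matrix must be square")
  if (anyNA(values)) stop("FC matrix contains NA/NaN entries")
  if (max(abs(values - t(values))) > tol) stop("FC matrix must be symmetric")
  values <- (values + t(values)) / 2
  if (max(abs(diag(values) - 1)) > tol) stop("FC diagonal must equal 1")
  if (any(values < -1 - tol) || any(values > 1 + tol))
    stop("FC entries must lie in [-1, 1]")
  values[values > 1] <- 1
  values[values < -1] <- -1
  diag(values) <- 1
  structure(unname(values), class = c("functional_matrix", "matrix"))
}

#' Construct a hierarchy map
#'
#' Pairs each node's continuous gradient value `h(v)` with its decile class
#' (1 = bottom of the hierarchy, `n_bins` = top).
#'
#' @param gradient numeric per-node gradient values.
#' @param classes integer per-node class in `1..n_bins`.
#' @param n_bins number of classes.
#' @return object of class `"hierarchy_map"`.
#' @export
hierarchy_map <- function(gradient, classes, n_bins = 10L) {
  stopifnot(length(gradient) == length(classes))
  if (!all(is.finite(gradient))) stop("gradient must be finite")
  classes <- as.integer(classes)
  if (any(classes < 1L) || any(classes > n_bins))
    stop("classes out of range")
  # class must be nondecreasing in gradient
  o <- order(gradient)
  if (is.unsorted(classes[o]))
    stop("classes must be nondecreasing in gradient")
  structure(list(gradient = as.numeric(gradient), classes = classes,
                 n_bins = as.integer(n_bins)),
            class = "hierarchy_map")
}

#' @export
print.hierarchy_map <- function(x, ...) {
  cat(sprintf("<hierarchy_map> %d nodes in %d classes, gradient range [%.3g, %.3g]\n",
              length(x$gradient), x$n_bins, min(x$gradient), max(x$gradient)))
  invisible(x)
}
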