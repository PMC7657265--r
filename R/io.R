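# Readers and writers for the pipeline's on-disk artifacts.
#
# Input matrices are plain delimited numeric text, either bare or wrapped
# with a header row and row-label column; the delimiter is auto-detected
# among comma, tab and whitespace. All output is tab-delimited with a
# header, numbers printed with 15 significant digits so a write->read
# round trip is value-identical to at least 12 significant digits.
# Node indices are 0-based internally (R vectors are 1-based; "internal"
# index i means row i of the matrix) and 1-based in every written table.

detect_sep <- function(line) {
  if (grepl("\t", line)) "\t" else if (grepl(",", line)) "," else " "
}

num_fmt <- function(x) {
  ifelse(is.finite(x), sprintf("%.15g", x),
         ifelse(is.na(x), "NA", ifelse(x > 0, "Inf", "-Inf")))
}

#' Read a delimited numeric matrix
#'
#' Accepts a bare numeric matrix or one wrapped with a header row and/or a
#' row-label first column; comma, tab or whitespace delimited.
#'
#' @param path file path.
#' @return numeric matrix (dimnames kept when labels are present).
#' @export
read_matrix_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- detect_sep(first)
  toks <- strsplit(trimws(first), if (sep == " ") "\\s+" else sep)[[1]]
  toks <- toks[nzchar(toks)]
  # header iff any token in the first line is non-numeric
  has_header <- anyNA(suppressWarnings(as.numeric(toks)))
  dt <- data.table::fread(path, header = has_header, sep = "auto",
                          data.table = FALSE)
  row_labels <- NULL
  label_col <- ncol(dt) > 1 &&
    (is.character(dt[[1]]) || is.factor(dt[[1]]) ||
       (has_header && identical(tolower(names(dt)[1]), "node")))
  if (label_col) {
    row_labels <- as.character(dt[[1]])
    dt <- dt[, -1, drop = FALSE]
  }
  m <- as.matrix(dt)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("matrix file contains non-numeric or NA entries: ", path)
  if (!is.null(row_labels)) rownames(m) <- row_labels
  if (!has_header) colnames(m) <- NULL
  m
}

#' Write a numeric matrix as tab-delimited text
#'
#' @param m numeric matrix.
#' @param path output path.
#' @param labels optional character vector used for both row and column
#'   labels; when given, the file carries a header row and a leading label
#'   column.
#' @export
write_matrix_file <- function(m, path, labels = NULL) {
  m <- as.matrix(m)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(m))
    writeLines(paste(c("node", labels), collapse = "\t"), con)
    for (i in seq_len(nrow(m)))
      writeLines(paste(c(labels[i], num_fmt(m[i, ])), collapse = "\t"), con)
  } else {
    for (i in seq_len(nrow(m)))
      writeLines(paste(num_fmt(m[i, ]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a node table
#'
#' Expects a delimited text file with named header columns `name, x, y, z,
#' sx, sy, sz, hemisphere` and optionally `partition`.
#'
#' @param path file path.
#' @return data.frame with one row per node.
#' @export
read_node_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c("name", "x", "y", "z", "sx", "sy", "sz", "hemisphere")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("node table missing required columns: ", paste(miss, collapse = ", "))
  dt
}

#' Read a connectome from a weight-matrix file and a node table
#'
#' @param weights_path delimited numeric n x n matrix file.
#' @param nodes_path node table (see [read_node_table()]).
#' @return validated [connectome()] object. Input asymmetric within `1e-9`
#'   is symmetrized by averaging with a warning; larger asymmetry errors.
#' @export
read_connectome <- function(weights_path, nodes_path) {
  w <- read_matrix_file(weights_path)
  nodes <- read_node_table(nodes_path)
  if (nrow(nodes) != nrow(w))
    stop(sprintf("dimension mismatch: %d x %d matrix vs %d-row node table",
                 nrow(w), ncol(w), nrow(nodes)))
  connectome(weights = w,
             coords = as.matrix(nodes[, c("x", "y", "z")]),
             sphere_coords = as.matrix(nodes[, c("sx", "sy", "sz")]),
             hemisphere = nodes$hemisphere,
             partition = if ("partition" %in% names(nodes)) nodes$partition,
             names = nodes$name)
}

#' Write a node table
#' @param c a [connectome()] object (weights ignored).
#' @param path output path.
#' @export
write_node_table <- function(c, path) {
  df <- data.frame(name = c$names,
                   x = c$coords[, 1], y = c$coords[, 2], z = c$coords[, 3],
                   sx = c$sphere_coords[, 1], sy = c$sphere_coords[, 2],
                   sz = c$sphere_coords[, 3],
                   hemisphere = c$hemisphere)
  if (!is.null(c$partition)) df$partition <- c$partition
  write_table(df, path)
}

#' Write a stage output table
#'
#' Data frames are written as tab-delimited text with a header row;
#' matrices via [write_matrix_file()] with 1-based node labels. Numbers are
#' printed with 15 significant digits.
#'
#' @param obj data.frame or numeric matrix.
#' @param path output path.
#' @export
write_table <- function(obj, path) {
  if (is.matrix(obj)) {
    labs <- rownames(obj)
    if (is.null(labs)) labs <- as.character(seq_len(nrow(obj)))
    return(write_matrix_file(obj, path, labels = labs))
  }
  if (!is.data.frame(obj)) stop("write_table expects a data.frame or matrix")
  out <- obj
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- num_fmt(out[[j]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  invisible(path)
}

#' Read a stage output table written by [write_table()]
#' @param path file path.
#' @return data.frame.
#' @export
read_table_file <- function(path) {
  data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
}
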