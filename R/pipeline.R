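# End-to-end orchestration from one run configuration.
#
# run_all() executes simulate -> consensus -> embed -> paths -> motifs ->
# flow -> transitions -> navigate -> nulls -> measures in dependency
# order, writes every stage table under the output directory, and records
# a manifest (file hashes, seeds, stage wall-times) so a rerun with the
# same config is hash-identical.

#' Default run configuration
#'
#' @param out_dir output directory.
#' @param seed global seed driving every named randomness stream.
#' @param simulate a [synthetic_config()] (its own `seed` is overridden by
#'   `seed`), or `NULL` to read matrices from `inputs`.
#' @param inputs list with `subjects` (character vector of weight-matrix
#'   paths), `fc`, `nodes` when `simulate` is `NULL`.
#' @param n_bins hierarchy class count.
#' @param beta_step grid step for navigation.
#' @param null_reps replicates for the rewire/spin/permute ensembles.
#' @param consensus_nbins optional length-bin count for the consensus
#'   stage (default heuristic otherwise).
#' @return list of class `"run_config"`.
#' @export
run_config <- function(out_dir, seed = 1L, simulate = synthetic_config(),
                       inputs = NULL, n_bins = 10L, beta_step = 0.05,
                       null_reps = 200L, consensus_nbins = NULL) {
  if (is.null(simulate) && is.null(inputs))
    stop("either a simulate block or explicit inputs are required")
  if (!is.null(inputs)) {
    need <- setdiff(c("subjects", "fc", "nodes"), names(inputs))
    if (length(need))
      stop("inputs block missing: ", paste(need, collapse = ", "))
    for (f in c(inputs$subjects, inputs$fc, inputs$nodes))
      if (!file.exists(f)) stop("input file not found: ", f)
  }
  if (!is.null(simulate)) simulate$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, inputs = inputs,
                 n_bins = as.integer(n_bins), beta_step = beta_step,
                 null_reps = as.integer(null_reps),
                 consensus_nbins = consensus_nbins),
            class = "run_config")
}

#' Run the full pipeline
#'
#' @param cfg a [run_config()].
#' @param verbose print one line per stage.
#' @return invisibly, a manifest list (also written to `manifest.json`):
#'   per-stage output files with md5 hashes and wall-times, plus the key
#'   in-memory results (`consensus`, `hierarchy`, `paths`, `flow`,
#'   `navigation`, `correlations`).
#' @export
run_all <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, stages = list())
  t_stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(code)
    dt <- proc.time()[["elapsed"]] - t0
    if (verbose) message(sprintf("[%s] %.2fs", name, dt))
    manifest$stages[[name]] <<- list(seconds = round(dt, 3))
    res
  }
  outf <- function(...) file.path(cfg$out_dir, ...)

  # --- inputs -------------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    cohort <- t_stage("simulate", generate_cohort(cfg$simulate))
    geom <- cohort$connectome_template
    subject_weights <- cohort$subject_weights
    fc <- cohort$fc
    write_node_table(geom, outf("nodes.tsv"))
    write_table(data.frame(node = seq_len(geom$n_nodes),
                           true_gradient = cohort$true_gradient),
                outf("truth.tsv"))
    for (s in seq_along(subject_weights))
      write_matrix_file(subject_weights[[s]],
                        outf(sprintf("subject_%02d.tsv", s)))
    write_matrix_file(unclass(fc), outf("fc.tsv"))
    reference <- cohort$true_gradient
  } else {
    nodes <- read_node_table(cfg$inputs$nodes)
    subject_weights <- lapply(cfg$inputs$subjects, read_matrix_file)
    fc <- functional_matrix(read_matrix_file(cfg$inputs$fc))
    geom <- connectome(matrix(0, nrow(nodes), nrow(nodes)),
                       coords = as.matrix(nodes[, c("x", "y", "z")]),
                       sphere_coords = as.matrix(nodes[, c("sx", "sy", "sz")]),
                       hemisphere = nodes$hemisphere,
                       partition = if ("partition" %in% names(nodes))
                         nodes$partition,
                       names = nodes$name)
    reference <- NULL
  }

  # --- consensus ----------------------------------------------------------
  cons <- t_stage("consensus",
                  consensus_sc(subject_weights, geom$coords, geom$hemisphere,
                               n_bins = cfg$consensus_nbins))
  sc <- connectome(cons$weights, geom$coords, geom$sphere_coords,
                   geom$hemisphere, geom$partition, geom$names)
  write_matrix_file(sc$weights, outf("consensus.tsv"))
  jsonlite::write_json(cons$report[c("n_bins", "density", "n_edges_inter",
                                     "n_edges_intra", "weight_mean")],
                       outf("consensus_report.json"), auto_unbox = TRUE)

  # --- hierarchy ----------------------------------------------------------
  hmap <- t_stage("embed", {
    emb <- diffusion_map(fc)
    if (!is.null(reference)) emb <- orient_gradient(emb, reference)
    bin_hierarchy(emb$components[, 1], n_bins = cfg$n_bins)
  })
  write_table(data.frame(node = seq_len(geom$n_nodes),
                         gradient = hmap$gradient, class = hmap$classes),
              outf("gradient.tsv"))

  # --- paths --------------------------------------------------------------
  ps <- t_stage("paths", all_pairs_paths(weights_to_lengths(sc)))
  write_matrix_file(ps$dist, outf("dist.tsv"))
  write_matrix_file(ps$hops, outf("hops.tsv"))

  # --- motifs / flow / transitions ---------------------------------------
  motifs <- t_stage("motifs", mean_motifs(ps, hmap))
  write_table(motifs, outf("motifs.tsv"))

  fs <- t_stage("flow", flow_stats(ps, hmap))
  write_table(fs, outf("flow.tsv"))
  if (!is.null(geom$partition))
    write_table(network_aggregate(fs, geom$partition),
                outf("flow_by_partition.tsv"))

  tt1 <- t_stage("transitions", one_hop(ps, hmap))
  ttk <- multi_hop(ps, hmap)
  dir.create(outf("transitions"), showWarnings = FALSE)
  for (k in seq_along(tt1$matrices))
    write_matrix_file(tt1$matrices[[k]],
                      outf("transitions", sprintf("T_%d.tsv", k)))
  for (k in seq_along(ttk$matrices))
    write_matrix_file(ttk$matrices[[k]],
                      outf("transitions", sprintf("M_%d.tsv", k)))
  jsonlite::write_json(list(one_hop = tt1$support, multi_hop = ttk$support),
                       outf("transitions", "supports.json"))

  # --- navigation ---------------------------------------------------------
  nav <- t_stage("navigate", {
    ncfg <- nav_config(beta_grid = seq(0, 1, by = cfg$beta_step))
    success_curves(sc, hmap, ncfg)
  })
  bstar <- select_beta(nav)
  write_table(data.frame(source = bstar$source, beta_star = bstar$beta_star),
              outf("beta_star.tsv"))

  # --- nulls + slope-hierarchy correlation --------------------------------
  spins <- t_stage("nulls",
                   spin_permutation(geom$sphere_coords, geom$hemisphere,
                                    n_reps = cfg$null_reps,
                                    seed = stream_seed(cfg$seed, "nulls")))
  shc <- slope_hierarchy_correlation(fs, hmap, spins)

  # --- measures -----------------------------------------------------------
  corr <- t_stage("measures", {
    sm <- structural_measures(sc, weights_to_lengths(sc), ps)
    if (!is.null(geom$partition)) {
      fm <- functional_measures(fc, geom$partition)
      sm <- cbind(sm, fm[, c("fc_strength", "participation")])
    }
    write_table(sm, outf("measures.tsv"))
    correlate_measures(sm, fs, bstar)
  })
  write_table(corr, outf("measure_correlations.tsv"))

  # --- manifest -----------------------------------------------------------
  files <- setdiff(list.files(cfg$out_dir, recursive = TRUE),
                   "manifest.json")
  manifest$slope_hierarchy <- shc[c("r", "p_spin")]
  manifest$files <- as.list(tools::md5sum(file.path(cfg$out_dir, files)))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, outf("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(manifest = manifest, consensus = cons, hierarchy = hmap,
                 paths = ps, flow = fs, navigation = nav,
                 beta_star = bstar, slope_hierarchy = shc,
                 correlations = corr))
}
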