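# hierpath

Tracing communication paths through cortical hierarchies.

Structural brain networks (connectomes) support signalling between
regions, and the cerebral cortex is organized along a continuous
unimodal–transmodal hierarchy: a gradient running from primary
sensory/motor cortex to transmodal association cortex, recoverable as the
first diffusion-map component of resting-state functional connectivity.
`hierpath` implements a complete analysis pipeline for asking how that
hierarchy shapes communication on the structural network:

1. **Consensus connectome** — assemble a group-representative weighted
   matrix from per-subject matrices, preserving density and the edge
   length distribution (distance-binned frequency selection, done
   separately for intra- and interhemispheric edges).
2. **Hierarchy gradient** — diffusion map embedding of the FC matrix
   (Gaussian affinity over FC rows, α = 1, σ = 1); the first nontrivial
   component h(v) is binned into 10 equal-size classes (1 = unimodal end,
   10 = transmodal end).
3. **Shortest paths** — weights W ∈ [0,1] become lengths L = −log W, and
   all-pairs weighted shortest paths are computed by Floyd–Warshall with
   full node-sequence reconstruction, hop counts and equal-cost tie
   flags.
4. **Path motifs** — each path is labelled by the hierarchy values of its
   nodes; mean motifs are stratified by source class, target class and
   hop length, with 95% CIs.
5. **Flow statistics** — the slope of a path at interior node v_i is
   s(v_i) = h(v_{i+1}) − h(v_i); per-node mean slopes, turning-up (local
   minimum) and turning-down (local maximum) probabilities, partition
   aggregates, and the slope–hierarchy correlation with a spin p-value.
6. **Transition matrices** — 1-hop matrices T(t) by path position and
   multi-hop memory matrices M(k) by lag over the 10 hierarchy bins,
   T_ij(t) = #{sp : sp(t)=i, sp(t+1)=j} / #{sp : length(sp) ≥ t+1}.
7. **Greedy navigation** — decentralized routing to the neighbor
   minimizing d(i,j) = β‖x_i−x_j‖ + (1−β)|h_i−h_j| (both terms
   normalized to [0,1]); per-source success-ratio curves S_R(β) and a
   detrended per-source optimum β*.
8. **Null models** — distance-binned degree-preserving edge rewiring,
   spherical-rotation (spin) label permutation with hemisphere
   mirroring, plain label permutation, permutation p-values with the +1
   correction, and Benjamini–Hochberg FDR.
9. **Simple measures** — betweenness (counted on the pipeline's own
   unique-path set), closeness, weighted clustering, degree, mean edge
   length, FC strength and participation, correlated against the four
   motif-derived measures.
10. **Synthetic cohort generator** — bilateral spherical geometry, a
    planted smooth mirrored hierarchy gradient, distance- and
    hierarchy-dependent subject connectomes, and an FC matrix whose
    leading axis is the planted gradient, so the entire pipeline is
    testable offline.

## Worked example

```r
library(hierpath)

cfg    <- synthetic_config(n_nodes = 100, n_subjects = 5, seed = 42)
cohort <- generate_cohort(cfg)
geom   <- cohort$connectome_template
cons   <- consensus_sc(cohort$subject_weights, geom$coords, geom$hemisphere)
emb    <- orient_gradient(diffusion_map(cohort$fc), cohort$true_gradient)
hmap   <- bin_hierarchy(emb$components[, 1], 10)
ps     <- all_pairs_paths(weights_to_lengths(cons$weights))
fs     <- flow_stats(ps, hmap)
spins  <- spin_permutation(geom$sphere_coords, geom$hemisphere,
                           n_reps = 500, seed = 9)
slope_hierarchy_correlation(fs, hmap, spins)
```

Output printed by the code above:

```
<cohort_sample> 100 nodes, 5 subjects, mean density 0.051
consensus density: 0.0505 (16 length bins)
gradient recovery |r| = 0.974
<hierarchy_map> 100 nodes in 10 classes, gradient range [-0.126, 0.115]
<path_set> 100 nodes, 9900/9900 connected pairs, hop diameter 7
slope-hierarchy r = -0.738, p_spin = 0.0020
```

Reading it: the consensus preserved the subjects' ~5% density; the
diffusion-map gradient recovered the planted hierarchy almost perfectly
(|r| = 0.97); and nodes high in the hierarchy direct flow downward
(negative slope–hierarchy correlation, significant against 500 spins) —
the synthetic cohort reproduces the qualitative signature expected of
real connectome data, where transmodal regions send signals down the
hierarchy and unimodal regions send them up.

Multi-hop transition structure from the same run:

```r
memory_profile(multi_hop(ps, hmap))
#>   k support diag_mass near_diag_mass mean_spread
#> 1 1   31416     0.164          0.509       1.968
#> 2 2   21516     0.095          0.306       2.801
#> 3 3   12116     0.078          0.253       3.318
#> 4 4    4594     0.073          0.226       3.724
```

1-hop transitions concentrate near the diagonal (half the mass within
one bin of it): communication steps follow the hierarchy.

## Command line

Every stage also runs from the shell (installed under
`<library>/hierpath/exec/hierpath`):

```sh
hierpath simulate  --nodes 100 --subjects 5 --seed 1 --out sim/
hierpath consensus --subjects 'sim/subject_*.tsv' --nodes sim/nodes.tsv --out consensus.tsv
hierpath embed     --fc sim/fc.tsv --reference sim/truth.tsv --out gradient.tsv
hierpath paths     --sc consensus.tsv --out pathset/
hierpath all       --out run/ --seed 1 --nodes 100 --subjects 5
```

All artifacts are plain tab-delimited text (full 15-digit precision) plus
JSON reports; `hierpath all` writes a `manifest.json` with file hashes so
reruns are verifiably reproducible.

## Documentation

The methods vignette (`vignettes/hierpath-methods.Rmd`) describes the
model, every tunable parameter, what the synthetic generator does and
does not emulate, numerical choices and known limitations.
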