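---
title: "hierpath: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hierpath: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`hierpath` studies how a continuous cortical hierarchy, estimated from
functional connectivity, constrains communication on a structural
connectome. The object of analysis is the set of all-pairs weighted
shortest paths of the structural graph; each path is annotated with the
per-node hierarchy value h(v), and everything downstream — motifs, slopes,
turning points, transition matrices — is descriptive statistics of those
annotated node sequences. Greedy navigation asks the converse question:
how far does hierarchy information alone (mixed with spatial proximity)
go toward recovering the path structure without global topology
knowledge.

Key assumptions, stated explicitly:

* **Weights are fiber densities in [0, 1]** and larger weight means a
  "shorter" connection; the log transform L = −log W makes path cost the
  negative log product of weights. The inverse transform L = 1/W is
  available (`transform = "inv"`) but non-default because it concentrates
  path structure on a few very strong edges.
* **The hierarchy is one-dimensional.** Only the first diffusion-map
  component is consumed downstream.
* **Unique shortest paths.** With continuous weights, ties are measure
  zero; ties are nonetheless detected (`tie_flags`) by the relaxation
  test |d_ik + d_kj − d_ij| ≤ 1e-12 and the deterministic tie-break
  (strict relaxation, ascending intermediate order) picks a single path.

## Tunable parameters

| parameter | default | units | notes |
|---|---|---|---|
| diffusion `alpha` | 1 | — | density-compensating normalization |
| diffusion `sigma` | 1 | FC-row distance | Gaussian affinity width; bandwidth convention `2*sigma^2` by default, `sigma^2` selectable (the cited toolbox convention is not documented) |
| `n_bins` (hierarchy) | 10 | classes | equal-size classes from the gradient's empirical CDF |
| consensus `n_bins` | `round(sqrt(mean edge count))` | bins | see below |
| `beta_grid` | 0, 0.05, …, 1 | — | navigation mixing weight |
| `max_hops` | n_nodes | hops | walk cap; failure also on any node revisit |
| null `n_reps` | 2000 | replicates | rewire/spin/permute ensembles |
| rewire attempt budget | 10 × edges | attempts/replicate | acceptance logged per replicate |

The consensus bin-count heuristic is printed in the source literature as
"the square root of the mean binary density across participants"; taken
literally (density as a fraction in [0,1]) this gives fewer than two
bins, so the package defaults to the edge-count reading,
`round(sqrt(mean number of extant edges per subject))`, which matches
the consensus-connectome literature the procedure comes from. The
density reading remains selectable (`consensus_nbins(..., "density")`).

Consensus edge weights default to the mean across **all** subjects
(zeros included), with `weight_mean = "nonzero"` offering the
mean-over-expressing-subjects alternative; the source text is ambiguous
and neither mode is asserted as canonical.

## The synthetic cohort generator

The generator's job is to produce a world with the statistical structure
the analysis assumes, at desk scale (default 200 nodes, 20 subjects
standing in for 1,000 parcels and 66 subjects):

* **Geometry.** Each hemisphere gets n/2 points sampled uniformly on its
  own full unit sphere — this is the *spherical projection* used by the
  spin null, where a rotation is a bijective isometry (the analogue of an
  inflated FreeSurfer hemisphere). Physical coordinates are a
  deterministic monotone radial warp of the projection onto opposing caps
  (|x| ≥ 0.1) of a radius-100 sphere, preserving neighborhood structure.
  An earlier design sampled the projection directly on the caps; a
  uniform rotation is not closed on a cap, so ~70% of parcels collapsed
  onto rim neighbors and the spun maps came out *more* autocorrelated
  than the originals. The full-sphere projection restores the real
  procedure's geometry.
* **Gradient.** Standardized sum of a linear field along a random 3D
  direction and Gaussian-smoothed white noise (kernel width
  `smoothness = 30` coordinate units ≈ a third of the hemisphere radius),
  computed on the left hemisphere and mirrored to homologues by index.
* **Subject connectomes.** Group edge probability ∝
  exp(−d/λ) · exp(−|Δh|/μ) with λ = 60 (spatial decay over ~half the
  hemisphere) and μ = 1.5 gradient SDs, scaled to a 5% expected density.
  Subject masks are the group mask with 15% random deletions plus an
  equal count of insertions sampled proportionally to the same edge
  probability (so subjects share ≈70% of edges with the group and the
  distance decay survives). Nonzero weights are log-normal, rescaled per
  subject into (0, 0.95]; the 0.95 cap keeps −log W strictly positive.
* **FC.** Correlation normalization of F Fᵀ + `fc_noise`·I with loadings
  F = [g, 0.5 · nuisance]. `fc_noise = 1` was chosen so the median
  absolute off-diagonal correlation lands near 0.25, the magnitude
  typical of group-average resting-state FC. This is not cosmetic: with
  near-±1 correlations the σ = 1 Gaussian affinity saturates into a
  near-disconnected graph and the leading diffusion component can
  localize; at realistic FC magnitudes the kernel resolves neighborhoods
  and the planted gradient is recovered with |r| ≳ 0.9.

What the generator does **not** emulate: BOLD time series (FC is drawn
directly as a correlation matrix), realistic parcel counts, hemispheric
asymmetries (homologues share gradient values exactly), streamline-count
noise models, or negative FC blocks with network structure. A green
recovery test therefore establishes that the pipeline recovers a planted
one-dimensional smooth gradient from a realistic-magnitude correlation
matrix — not that it would resolve competing gradients in empirical
data.

## Numerical choices

* **Zero-length edges.** A weight of exactly 1 would make a zero-length
  edge; inputs containing 1 are globally rescaled by 1 − 1e-9 with a
  warning. The generator caps weights at 0.95 so this never triggers on
  synthetic data.
* **Slope convention.** The per-node slope uses the outgoing segment
  only: at interior position i, the contribution is h(v_{i+1}) − h(v_i).
  For the two traversals {A,B,C,D} and {D,C,B,A} this yields node C the
  mean slope (h(D) + h(B) − 2h(C))/2, which pins the convention; the
  alternative (mean of both incident segments) is not implemented.
  Zero-slope segments (tied gradient values) count as neither turning
  direction and contribute 0 to slopes.
* **Transition denominators.** `length(sp)` is the node count, so
  "length(sp) ≥ t+1" exactly guarantees sp(t+1) exists. M(k) pools all
  valid (path, start) pairs in one numerator and one denominator, which
  makes every populated matrix total-mass 1 and makes M(1) the
  position-pooled T stack — the test suite anchors both identities.
  Rows of T and M need not sum to 1 and the tests assert a
  counterexample.
* **Navigation.** Hierarchy distance uses |h_i − h_j| (the printed
  linear combination omits the absolute value, but a signed quantity
  cannot rank neighbors). Both distance terms are normalized by their
  global maxima over all node pairs, once. Failure is node revisit or
  the hop cap, the standard greedy-routing convention; "success" means
  reaching the target, with a strict mode requiring the exact
  shortest-path sequence. Neighbor ties break to the lower node index.
* **Rewiring stays in-bin.** A swap (a–b, c–d → a–d, c–b) is accepted
  only if it creates no self-loop or multi-edge *and both new edges fall
  in the same length bin*, so the degree sequence, weight multiset and
  per-bin edge-length histogram are preserved exactly, replicate by
  replicate (each is asserted in the tests).
* **Spin rotations** are uniform over SO(3) via normalized quaternions,
  applied to the left-hemisphere projection and conjugated by the
  x-reflection for the right; nearest-parcel assignment is independent
  per parcel (many-to-one allowed).
* **Permutation p-values** carry the +1 correction and are never exactly
  zero; the declared FDR family for partition-level turning statistics
  is Benjamini–Hochberg over the (partitions × 2 directions) grid.
* **Gradient orientation.** The eigenvector sign is arbitrary and is
  only ever fixed against an explicit reference vector
  (`orient_gradient`); nothing anatomical is assumed silently.

## A note on the label-permutation motif control

One might expect permuted hierarchy labels to "flatten" mean motif
curves. In a stratified analysis they cannot: motif endpoints are pinned
by the (source class, target class) strata in both the empirical and the
permuted analysis, so permuted-label curves must jump from pinned
endpoints to hierarchy-random interiors and come out *steeper* — this
package measured exactly that, consistently, on its synthetic world.
What permutation genuinely destroys is the hierarchy-adjacency of
individual steps: the mean |Δh| along empirical paths is well below its
permuted-label counterpart (equivalently, the 1-hop transition matrix
loses its diagonal concentration). The property tests assert that
direction.

## Known limitations

* Floyd–Warshall is O(n³) in plain R; fine to ~500 nodes, not tuned for
  the 1,000-node scale of the original data (a single 1,000-node run is
  feasible but slow; the design favors transparency over speed).
* The spin null at small n (≲ 100 nodes) inflates spatial
  autocorrelation measurably because nearest-parcel assignment on few
  random points duplicates heavily; at the default 200 nodes the effect
  is within the original gradients' seed-to-seed spread.
* Betweenness is counted over the single deterministic path per pair;
  on graphs with genuine ties this undercounts relative to
  all-shortest-paths betweenness (ties are flagged, not enumerated).
* Disconnected pairs keep infinite distance and are excluded from all
  path statistics; closeness is computed over the reachable set with the
  reachable count reported alongside.
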