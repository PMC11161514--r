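---
title: "Growing and analyzing physical networks as networks-of-networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growing and analyzing physical networks as networks-of-networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A physical network lives on a substrate `S`, here a d-dimensional cubic
lattice with linear size `L` and periodic boundaries. Each node is an
extended object — a connected subgraph of `S` — and nodes exclude volume:
no site belongs to two nodes. Bonds between nodes sit on single lattice
edges, so the coarse-grained combinatorial network `G` (one vertex per
node, one link per bond) forgets the geometry entirely. The package's
central question is what that forgetting costs.

Growth proceeds in `grow_network()` as follows. An initial node of volume
`v0` is grown freely from a random site. Every subsequent node starts at
a uniformly random unoccupied site and extends by a trajectory process
until its head proposes a step onto a site owned by *another* node; that
lattice edge becomes the node's single bond, so the combinatorial network
of a completed run is a tree. Growth stops after `n_max` nodes or when
the lattice saturates.

Two trajectory families are implemented:

* **Loop-erased random walk** (`"lerw"`): a simple random walk whose
  loops are deleted the moment they close. It never traps itself (unlike
  the kinetic self-avoiding walk, which does in d = 2 and 3) and has
  well-known fractal dimensions, `d_f = 5/4` (d=2), `≈ 1.6236` (d=3) and
  `2` for d ≥ 4 (`df_lookup()`); at saturation the union of within-node
  edges and bonds is a uniform spanning tree of the lattice (this is
  Wilson's algorithm, and the tests verify both the spanning-tree
  property exactly and the uniformity statistically against Kirchhoff
  counts).
* **Straight rays** (`"straight_random_dir"`, `"straight_axis"`):
  digitized lines with `d_f = 1`. Random directions keep the growth
  isotropic on average and give mean-field behavior; fixed axis
  directions are the degenerate counterexample in which parallel rays
  never meet.

The scaling theory (`theory_params()` and friends) estimates the
probability that two randomly placed nodes intersect by box counting,
`p_ij ~ v_i v_j^{d/d_f−1} / L^d`, integrates the resulting growth law to
`V_t ~ t^{1−d_f/d}`, and derives `k_t ∝ v_t` and a degree exponent
`γ = 1 + d/d_f`. When `d_f ≤ d/2` trajectories avoid each other and
everything reduces to the mean-field forms (`p_ij ~ v_i v_j / L^d`,
diffusive `V_t ~ t^{1/2}`, `γ = 3`). All five predictions are implemented
with a single substitution `d_f_eff = max(d_f, d/2)`, which reproduces
the mean-field branch and makes every formula continuous at `d_f = d/2`
by construction. The box-counting prefactors are deliberately not
modeled: predictions are scaling forms, and comparison utilities fit a
single multiplicative constant (for the total volume, the integration
constant `c` defaults to the value that makes `V_0 = v0`).

## Parameters that matter

* `d`, `L` — substrate dimension and size (sites, dimensionless).
  Production runs need `L ≥ 3`; at `L = 2` the periodic wrap makes the
  lattice a multigraph and neighbor lists are deduplicated instead.
* `v0` — initial node volume (sites). Default `"span"` uses
  `round(L^d_f)` so the first node spans the available space, which makes
  the integration constant `c` independent of `L`.
* `d_f` — trajectory fractal dimension, defaulted from the process and
  dimension via `df_lookup()`. At d = 4 the LERW value 2 carries a
  logarithmic correction that is *not* modeled; d = 4 predictions are
  pure powers.
* `w` — inter-node coupling weight in the layout Laplacian; within-node
  links have weight 1. The physical Laplacian emerges in the `w → 0`
  limit.
* Fit windows — the growth-exponent fit uses `t ∈ [100, N/2]` by
  default, excluding the transient governed by `c` and the saturation
  tail; the degree–volume relation uses logarithmic volume bins with
  base 1.5. Both are exposed as arguments; neither choice comes from a
  stated convention, so they are package defaults.

## Numerical and design choices

* **Step proposal and loop erasure.** The walk proposes a uniform
  neighbor of its head. Empty → extend; own trajectory → erase the loop
  and continue from the revisit point; foreign → stop and bond. This
  makes "hit" and "loop" mutually exclusive by site ownership. Erased
  sites are released from the occupancy immediately — loops are deleted
  as soon as they form, and retaining them would block other nodes with
  phantom volume. A node seeded with all neighbors foreign becomes a
  volume-1 node with one bond, with no special casing.
* **Seed-node proposal budget.** A free LERW needs about `m^{d/d_f}`
  proposals to reach post-erasure length `m` (the walk is diffusive, the
  trajectory is fractal), so the budget is `50 · v0^{d/d_f}` proposals —
  a linear-in-`v0` budget would starve exactly the large-`L` runs the
  model is for. Exhaustion is flagged, never silently truncated.
* **Straight-ray digitization.** Rays use face-adjacent voxel traversal
  (Amanatides–Woo): track per-axis crossing times `tMax_k`, step along
  the axis with the smallest, ties broken by the lowest axis index. The
  trajectory is a lattice path (one step at a time). A ray that meets its
  own trail after wrapping the torus closes without a bond.
* **Uniform unoccupied sampling.** The compiled growth loop keeps an
  exact empty-site list with O(1) swap-remove, so seeding is uniform at
  every occupancy level; the R-level `sample_unoccupied()` uses rejection
  sampling below 50% occupancy and an explicit list above.
* **Eigensolvers.** Dense symmetric decompositions up to dimension 2000,
  ARPACK (via igraph) beyond. The known zero mode (constant vector for
  `Q_G`, `sqrt(v)` for `Q_phys`) is deflated by a rank-one spectral shift
  before computing the algebraic connectivity `λ_2`. Ties in
  localization arg-maxes are broken toward the smallest node id.
  Spectral CCDFs are stored raw; any shifting for tail comparison is a
  plotting concern.
* **Tail exponent.** Discrete MLE in the Clauset continuous
  approximation, `xmin` selected by KS minimization over at most 60
  log-spaced candidates with at least 100 tail samples (the operation's
  precondition). The goodness-of-fit p-value uses a semiparametric
  bootstrap that re-selects `xmin` on every replicate — without the
  re-selection the observed statistic has an optimization advantage and
  the test has essentially no power. Because even the honest KS test is
  weak against exponential tails once `xmin` is optimized, the
  plausibility flag also requires a Vuong-style likelihood-ratio
  comparison against a geometric alternative on the top quartile of the
  data not to favor the geometric at 1% significance.
* **Fractal dimension.** Free trajectories (infinite lattice, hash-map
  occupancy) are grown to controlled target lengths; the regression is of
  mean log-extent on log-length with the slope inverted, because the
  extent is the noisy variable and the pooled regression of `log v` on
  `log l` is attenuated by errors-in-variables. Unwrapped coordinates are
  used throughout so periodic wrapping cannot shrink bounding boxes.
* **Real networks.** Directed multiplicities are symmetrized by summing
  both directions; self-links are dropped and counted; analysis is
  restricted to the largest connected component (localization and `λ_2`
  are ill-defined across components); volumes are normalized to mean 1,
  the unit convention that makes the spectra of `Q_G` and `Q_phys`
  comparable. Normalization is idempotent.

## What the synthetic generator does and does not emulate

`generate_fixture()` builds connectome-*like* test data: a tree whose
degree sequence is drawn from a discrete power law and realized exactly
through a Prüfer sequence, with volumes tied to degree (`linear`),
decorrelated (`shuffled`), or following a planted power law `k ~ v^slope`
with lognormal noise (`planted`). This covers the code paths the real
loaders exercise — heavy-tailed weighted degrees, tunable degree–volume
correlation, spectral comparisons — but it does not emulate link
multiplicity structure beyond unit weights, clustering or community
structure (it is a tree), spatial embedding, or measurement noise in
volume estimates. A green fixture test therefore establishes that the
estimators recover planted structure, not that any particular real
system has that structure.

## Known limitations

* Substrates are periodic cubic lattices only; branched (tree-shaped)
  nodes, guided growth and evolving substrates are out of scope.
* The d = 4 logarithmic corrections to LERW scaling are not modeled.
* Full eigendecompositions are limited to ~2000 dimensions; beyond that
  only extremal pairs are computed, and networks beyond ~1e5 sites are
  not intended targets for layout-Laplacian analysis.
* Tail-exponent estimates on finite saturated networks carry a small
  downward bias relative to the asymptotic `γ`: the far tail is bent by
  the finite-size cutoff, and the KS-selected `xmin` sometimes lands in
  that region. The acceptance checks run at their stated scales and
  tolerances; the bias is visible but within them.
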