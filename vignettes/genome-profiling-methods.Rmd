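---
title: "Genome profiling with genoprof: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome profiling with genoprof: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genoprof)
```

## The method in outline

Genome profiling (GP) classifies organisms from a DNA fingerprint rather
than from sequence. Random PCR samples fragments across a genome; a
temperature gradient gel (TGGE) spreads each fragment into a curved
trajectory, and the point where the double-stranded to single-stranded
transition begins — the feature point — is recorded as a
(mobility, temperature) coordinate. After normalization against a
co-migrated internal reference fragment (nominal melting temperature
60 °C), these become *spiddos* (species identification dots), a small 2D
point set that acts as a genome-specific signature.

`genoprof` implements everything downstream of the gel image:

1. **Normalization** (`normalize_point()`, `normalize_profile()`):
   componentwise ratio to the reference feature point,
   $\mu = m/m_\mathrm{ref}$, $\theta = T/T_\mathrm{ref}$.
2. **Pattern similarity** (`pass_score()`): the PaSS statistic between
   two spiddos sets, maximized over point correspondences.
3. **Genome distance** (`genome_distance()`, `genome_distance_matrix()`):
   $d_G = 1 - \mathrm{PaSS}$.
4. **Clustering** (`build_tree()`): Lance–Williams agglomeration (Ward,
   group average, median) of the $d_G$ matrix.
5. **Tree congruence** (`congruence_value()`, `modified_congruence()`):
   the cluster matching score (CMS), the congruence value $V_c$, and the
   coarse-grained variant $V_c'$.
6. **Simulation** (`sim_config()`, `simulate_tree()`,
   `simulate_profiles()`): synthetic profiles evolving along a known
   ultrametric tree, standing in for wet-lab data.

## PaSS and its matching problem

For matched spiddo pairs $(P_i, P_i')$ the per-pair contribution is

$$ s(P_i, P_i') \;=\; 1 - \frac{\lVert P_i - P_i' \rVert_w}
   {\lVert P_i \rVert_w + \lVert P_i' \rVert_w}, $$

where $\lVert \cdot \rVert_w$ is the Euclidean norm with the $\theta$
axis scaled by the weight `w_theta`. Each term lies in $(0, 1]$, equals 1
exactly for coincident points, and is invariant to a common rescaling of
both points. PaSS is the *mean* of these terms over the matching of size
$k = \min(n_A, n_B)$ that maximizes their sum — the computational reading
of "the maximum over all combinations of feature points". Identical
profiles therefore score exactly 1, and $d_G = 1 - \mathrm{PaSS}$ is 0.

Three matching strategies are provided:

* `optimal` (default): an exact linear-assignment solver
  (Kuhn–Munkres with potentials, $O(n^3)$). Among equally optimal
  matchings, the lexicographically smallest pair list is returned so the
  reported correspondence is deterministic.
* `exhaustive`: full enumeration of all injective matchings, capped at
  $\min(n) \le 8$ (40 320 assignments). It exists to *check* the solver,
  and the test suite asserts their equality on hundreds of random pairs.
* `monotone`: the best order-preserving matching of exactly $k$ pairs,
  by dynamic programming — for data where the serial order of spiddos
  along the gel is trusted.

Open design points resolved here: the matching is over unconstrained
injections by default (serial numbers are bookkeeping, not constraints);
profiles of unequal size are scored on their best $k$ pairs, with an
optional `size_penalty` multiplying PaSS by $k/\max(n_A, n_B)$ (off by
default, since dropout of faint bands should not dominate the score);
and `w_theta` defaults to 1 — the empirical value used with real gels is
not published, and on the normalized scale both axes are already
dimensionless and comparable.

## Clustering

`build_tree()` merges the globally closest pair of clusters and updates
distances with the Lance–Williams recurrence

$$ d_{cx} = \alpha_a d_{xa} + \alpha_b d_{xb} + \beta d_{ab}
   + \gamma\,\lvert d_{xa} - d_{xb}\rvert, $$

with the standard Ward, group-average and median parameterizations
(`linkage_params()`). Two choices deserve a note:

* **No squaring.** $d_G$ is not claimed to be Euclidean, so Ward updates
  run on the distances as supplied (the behavior of `hclust`'s
  `ward.D`). Implementations that assume squared Euclidean input are
  reproduced with `ward_squared = TRUE` (square first, take square roots
  of the heights — `ward.D2`'s convention). The test suite checks both
  against `stats::hclust`.
* **Determinism under ties.** Equal minimum distances are resolved by
  the lexicographically smallest pair of smallest-member labels.

Merge heights are the pre-merge distances. Ward and group-average trees
are height-monotone; median linkage can produce inversions, which are
kept as-is and flagged with a warning.

A practical caveat surfaced by the simulator (below): on distance
matrices that are monotone transforms of an ultrametric — exactly the
idealized situation for these data — the unsquared Ward update does
*not* always reconstruct the generating hierarchy, because its
size-dependent inflation of merged-cluster distances can reorder merges
across true clusters. Group average (UPGMA) recovers such matrices
exactly. Ward remains the default for fidelity to established GP
practice, but `method = "average"` is the safer choice when the goal is
topology recovery, and the acceptance report quantifies the difference.

## Congruence of two dendrograms

`clusters_of()` reduces a tree to its non-root internal-node leaf sets.
Matching those of a *subject* tree against those of an *object* tree
gives the cluster matching score: with the `exact` criterion a subject
cluster scores 1 when an identical leaf set exists in the object (the
default — the strictness matches how low published congruence values run
for unrelated tree pairs); with `jaccard`, clusters are paired one-to-one
to maximize the summed Jaccard index, reusing the assignment solver.
Then

$$ V_c = \mathrm{CMS} / n_\mathrm{subject\ clusters} \in [0, 1], $$

which is 1 for identical trees. The score is directional; both
directions and their mean are always computed. Degenerate subjects (no
non-root clusters, e.g. a star) score 1 against an equally empty object
and 0 otherwise, with a message.

**Coarse-graining.** Fine structure that a comparison should ignore is
removed by `coarse_grain()`: an internal node collapses into its parent
when their relative height gap is below 15 %
(`(h_p - h_c)/h_p < 0.15`), iterated to a fixed point — so the operation
is idempotent and never adds internal nodes. The gap is measured
relative to the *parent* height by default; "15 % height difference" is
ambiguous, and normalization by the total tree height is available via
`norm = "tree"`. $V_c'$ (`modified_congruence()`) coarse-grains the more
finely structured partner (both, on ties) before scoring; it heals
shallow spurious splits, and the suite pins a constructed example where
a single sub-threshold split is the only disagreement:
$V_c = 2/3$, $V_c' = 1$.

## The simulator: what it emulates, and what it does not

`simulate_profiles()` draws an ancestral profile uniformly on
$[0.3, 1.7]^2$ (centred on the reference point $(1,1)$; typical
normalized gel coordinates), then evolves it along an ultrametric tree
(Yule by default — the standard null model for species trees —
coalescent optionally; root height rescaled to 1). Along a branch of
length $\ell$ each coordinate gains Gaussian noise of sd
$\sigma\sqrt{\ell}$; each point is lost with probability `p_loss` (a
floor of 3 bands mimics the detection limit) and new points appear with
probability `p_gain` per existing point. Defaults: 12 spiddos (a typical
per-gel count), $\sigma = 0.05$, `p_loss = p_gain = 0.05` — plausible
magnitudes for gel-to-gel variation. All draws flow from named
substreams of one master seed, so tree shape and noise are independently
reproducible.

Two structural facts about this generator matter when reading test
results:

* **The jitter is both signal and noise.** Divergence between leaf
  profiles *is* accumulated jitter, so to first order every pairwise
  $d_G$ is proportional to $\sigma$ and the clustering problem is
  scale-invariant: shrinking $\sigma$ does not make topology recovery
  easier. What limits recovery is the number of spiddos (12 points give
  each $d_G$ a relative sampling error of roughly 15 %) and the Ward
  caveat above. Consequently the pipeline's exact-topology recovery rate
  for 10-leaf trees at 12 spiddos is a few percent — the acceptance
  report computes it — while mean $V_c$ degrades only mildly and
  monotonically as $\sigma$ grows through 0.01–0.1 (second-order
  effects: matching errors and the 0.05 coordinate clamp).
* **Real data differ** in having batch effects across gels, correlated
  (not iid) feature-point displacements, and detection artifacts near
  the gel edge; none of these are modeled. Passing tests demonstrate
  the correctness of the computations, not field performance.

`perturb_tree()` (random leaf-label swaps) provides the controlled
degradation used for the congruence monotonicity checks: mean $V_c$
between a tree and its $k$-swap copy falls from 1 (at $k=0$) towards
zero as $k$ grows.

## Numerical and interface choices

* Per-pair similarities use direct coordinate differences (not the
  polarization identity) so identical points give exactly 0 distance and
  `pass_score(a, a)` is exactly 1.
* Heights in Newick output are encoded as parent/child branch-length
  differences; a two-leaf tree merged at height $h$ is `(A:h,B:h);`.
  Parsing accepts polytomies and named internal nodes (required after
  coarse-graining). Round trips preserve topology and heights to 1e-9.
* PHYLIP square matrices are written with 6 decimals, in the strict
  10-character-label dialect or a relaxed tab-separated one.
* Problem sizes in the test and acceptance runs — 8×8 oracle matrices,
  200 matching pairs, 2 000–10 000 congruence fuzz pairs, 100 pipeline
  replicates per noise level, 500 swap replicates — were chosen to give
  stable Monte-Carlo estimates at interactive runtimes.

## Known limitations

* $d_G$ is not shown to satisfy the triangle inequality; it is treated
  as a dissimilarity, not a metric.
* The exact printed form of the published PaSS and congruence formulas
  is not recoverable from the available text; the forms above are the
  package's explicit, documented choices, with the matching criterion
  and normalization kept behind flags (`criterion`, `norm`,
  `ward_squared`) so alternative readings remain expressible.
* Published congruence values for real insect datasets cannot be
  recomputed here: the underlying trees and gel data are available only
  as figures.
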