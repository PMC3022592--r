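---
title: "Combining overlapping multi-gene data sets: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining overlapping multi-gene data sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`supercomb` implements and benchmarks the three levels at which overlapping
per-gene sequence data can be combined into one species phylogeny. This
vignette documents the underlying models, the tunable parameters, and the
design decisions taken where the design space was genuinely open — in the
spirit in which model-based omics packages document their statistical
machinery.

## The combination methods

**Early level (superalignment, SA).** Gene alignments are concatenated over
the union taxon set, with missing gene-by-taxon blocks as gaps
(`concatenate()`). Pairwise distances are estimated by maximizing, for each
pair independently, the HKY85+Γ likelihood of its 4×4 site-pattern counts
over the mutually determined sites (`ml_pairwise_distances()`), and a tree
is fitted by weighted least squares (`fm_tree()`,
`superalignment_tree()`).

**Medium level (AvCon, SDM).** Per-gene partial distance matrices are
combined entry-wise. `average_consensus()` takes the plain mean over the
genes covering each pair. `sdm_combine()` jointly fits a positive scale
factor per gene and, optionally, an additive constant per taxon per gene,
minimizing the dispersion of the rescaled matrices around the consensus
matrix, subject to the normalization `sum_g w_g alpha_g = sum_g w_g` with
`w_g` the number of available pairs in gene g (fixing the overall scale).
The problem is linear least squares, solved exactly through the profiled
(pair-mean) objective; because alpha = 1, a = 0 is feasible, the SDM
objective can never exceed the plain-average objective. Rank-deficient
systems (which arise, e.g., for exactly additive inputs, where scalings and
shifts trade off) fall back to a minimum-norm solution with a warning.

**Late level (supertrees).** Per-gene trees are encoded as binary matrices
with `?` for absent taxa — one column per interior edge (Baum/Ragan,
`encode_br()`; for rooted trees the root side is 0) or one column per
interior node scoring the node's cluster against its sister group (Purvis,
`encode_pu()`). `mr_supertree()` searches for the tree optimizing one of
four objectives (`mr_score()`): Fitch parsimony length with `?` as the full
state set; irreversible Camin–Sokal parsimony (only 0→1 changes, all-0 root
state); the minimum number of definite-entry flips making every column
congruent with the tree (MRF); or the number of congruent columns (MRC).
`build_supertree()` implements the rooted-triplet Build recursion, and
`cut_supertree()` its MinCut and modified MinCut extensions: at each level
taxa are connected when a restricted source tree places them together in a
proper cluster below its root; a connected (conflicting) graph is
disconnected by removing a global minimum-weight edge cut after contracting
edges supported by every source tree seeing both endpoints (and, for
modified MinCut, edges inside clusters contradicted by no source tree, in
the triplet sense). Majority-rule and strict consensus
(`majority_consensus()`, `strict_consensus()`) complete the late-level
family; a split present in exactly the threshold fraction of trees is
excluded (strictly "more than half").

### Design choices in the matrix-representation machinery

* **Purvis coding and the ancestral row.** A Purvis matrix restricted to
  leaf rows is nearly uninformative under unrooted parsimony: most of its
  columns have so few definite entries that almost every topology attains
  the same score (easily verified by enumeration on 7 taxa). The classic
  worked example therefore carries an all-zero ancestral row `R`.
  `mr_supertree(root = TRUE)` appends that row, attaches it as outgroup, and
  returns a rooted supertree; the Purvis-coded methods use it throughout.
* **Search heuristic.** The objectives are NP-hard; the original analyses
  used branch-swapping heuristics in external programs. Here each restart
  builds a stepwise random-addition parsimony tree, then alternates
  first-improvement NNI descent with single-taxon repositioning sweeps
  (prune one leaf, regraft on the best edge), plus a small number of
  ratchet rounds (re-climb under randomly upweighted columns, then under
  the true weights). Plain NNI from random starts demonstrably stalls in
  poor local optima; the combined scheme attains the exhaustive optimum in
  at least 95% of random 6-taxon instances (enforced by an acceptance
  test). If several distinct optima are found, their strict consensus is
  returned, as is conventional.
* **Tie-breaking.** Global min-cut ties in `cut_supertree()` are resolved
  by the deterministic min-cut routine on a graph built in sorted taxon
  order; runs are reproducible, but the cut chosen among ties is not
  guaranteed to be the lexicographically smallest one.
* **Scoring kernels.** The per-column Fitch, Camin–Sokal and flip counts
  are small C++ loops (as is usual for parsimony software); independent R
  oracles (assignment enumeration, subset enumeration, and a second
  parsimony implementation) verify them in the test suite.

### Design choices in the distance machinery

* **Least-squares weights.** `fm_tree()` minimizes
  Σ w_ij (D_ij − d_ij)² / D_ij^p over topologies (NNI from a
  neighbor-joining start on the shortest-path-completed matrix) and branch
  lengths (weighted least squares per topology, negative lengths clamped at
  zero). The default is the classic power p = 2 criterion. The
  superalignment route instead passes replicate weights w_ij = (pairwise
  overlap length) with p = 1: the sampling variance of an ML distance is
  approximately proportional to d/L, so this approximates inverse-variance
  weighting and markedly improves the superalignment tree when coverage is
  patchy (distances estimated from a few hundred overlapping sites would
  otherwise carry the same weight as distances from the full
  concatenation). Zero distances have their denominator floored at 1e-6.
  Only genuinely available entries enter the objective; shortest-path
  imputed entries seed the starting tree only.
* **Distance estimation.** Each pair's likelihood is profiled on a
  log-spaced grid and refined by golden-section search; the
  transition/transversion ratio is either supplied (the benchmark passes
  the generating value, as analyses fitted to real data would use their ML
  estimate) or estimated per gene by profile likelihood
  (`estimate_hky()`). Saturated pairs are clamped at d_max = 10
  substitutions/site with a warning; base frequencies default to empirical
  counts. Four discrete Gamma categories are used for inference while
  simulation draws continuous Gamma rates — the standard asymmetry between
  simulators and estimators, which introduces a small (< 0.02 at d = 0.3)
  downward bias absorbed by the stated tolerances.

## The simulation engine and what it emulates

One replicate (`simulate_dataset()`) draws: a Yule species tree rescaled to
root-to-tip height `tree_height`; true gene trees per the configured mode —
identical to the species tree (`E`), branch lengths multiplied by
Gamma(α, mean 1) factors (`R`), multispecies-coalescent gene trees (`T`), or
user-supplied trees (`G`); per-gene alignments under HKY85+Γ; and a taxon
occupancy pattern deleting taxa per gene.

* **Coalescent scale.** Species-tree branch lengths are read directly as
  coalescent-time units with pairwise coalescence rate 2/θ, so the expected
  coalescence time of two lineages is θ/2 (checked by Monte Carlo). The
  θ = 0 limit returns the species tree itself. Absolute θ values are
  meaningful only relative to the branch-length scale; only the monotone
  increase of gene-tree incongruence with θ is claimed. Under the default
  height, θ = 0.001 produces mild incongruence (mean true-gene-tree RF
  ≈ 0.02, below the reconstruction error) and θ = 0.03 severe incongruence
  (≈ 0.4).
* **Occupancy.** Real multi-gene matrices are heterogeneous in both
  directions: taxa differ widely in sampling depth and genes range from a
  handful of taxa to nearly all. The sampler multiplies a per-taxon Beta
  propensity (concentration 3) with a per-gene Beta coverage level
  (concentration 2.5), repairs the draw to the structural constraints
  (every gene in ≥ 4 taxa, every taxon in ≥ 1 gene, connected gene overlap,
  and — outside the large regime — one fully covered taxon to root at), and
  retries until the mean coverage matches the regime (65.2% for the small
  25 × 10 regime, 15.8% for the large 69 × 254 one). Gene lengths are
  log-normal (sdlog 0.8), scaled to the regime's total (6,681 sites for the
  small regime), so a few long genes dominate the superalignment as they do
  in real data.
* **Tree height.** The default height of 0.08 substitutions/site places
  single-gene information in the empirically typical regime: a single gene
  of a few hundred sites leaves a sizable fraction of internal edges
  unresolved (single-gene baseline distance ≈ 0.13–0.14), while the full
  concatenation resolves nearly all of them. This is the regime in which
  the combination methods genuinely differ; with strongly informative
  single genes all reasonable methods converge and the comparison
  degenerates.
* **What the simulator does not emulate.** No indels (gaps arise only from
  occupancy), no substitution-model misspecification (inference uses the
  generating model family), no gene-specific substitution parameters, no
  alignment error, and no among-lineage rate variation beyond what the
  coalescent induces. Passing benchmarks therefore demonstrate the methods'
  behavior under clean model conditions, not robustness to real-data
  violations.

## The evaluation protocol

`run_benchmark()` runs a paired design: within a replicate every method
sees the same simulated alignments. Per-gene trees for the supertree
methods are neighbor-joining trees on the per-gene ML distances, rooted at
the designated fully covered taxon where rooted methods require it. Methods
inapplicable to a setting (consensus without complete coverage; rooted
methods without a fully covered taxon) are skipped with a logged reason.
Accuracy is the normalized Robinson–Foulds distance RF/(2(n−3)) to the true
species tree, computed on unrooted splits with the full-taxon denominator
even for polytomous estimates (missing resolution counts as error). By
default each replicate draws a fresh species tree and occupancy pattern, so
summaries average over tree space rather than conditioning on a single
draw; fixed objects can be supplied to reproduce a conditioned design.
`baseline_distance()` gives the single-gene reference accuracy.
`wilcoxon_signed_rank()` performs the paired two-sided test, dropping zero
differences and using the exact distribution up to 25 non-zero pairs
(midranks and the normal approximation with continuity correction
otherwise); the point estimate and confidence interval are the
Hodges–Lehmann pseudomedian and its signed-rank interval, one conventional
choice among the signed-rank CI constructions.

## Problem sizes used in the shipped tests

The acceptance tests run the benchmark at 24 taxa × 10 genes with 50
replicates per coverage setting and 100 replicates per coalescent setting,
and validate the scoring machinery exhaustively at 5–8 taxa; these sizes
make the full suite comfortably reproducible on a single CPU while leaving
the qualitative contrasts statistically decisive (paired tests at p < 0.05).

## Known limitations

* The superalignment route is distance-based; a full-likelihood
  concatenation analysis would be more accurate in absolute terms, so
  cross-method comparisons are the meaningful output, not absolute RF
  levels. The gap is largest under heavily incomplete coverage: pairwise
  distances estimated on short mutual overlaps discard information a joint
  likelihood would share across pairs, so the distance-based
  superalignment does not retain the full dominance over supertree methods
  that a likelihood-based concatenation shows on incomplete data
  (reflected in the shipped acceptance results).
* The min-cut recursion removes one global minimum cut per level rather
  than all minimum cuts; on heavily conflicting inputs different
  published MinCut variants can return different (equally defensible)
  trees.
* `wilcoxon_signed_rank()` falls back to the normal approximation in the
  presence of ties even below 25 pairs, as the exact distribution is not
  defined with midranks.
* The Build/MinCut family requires rooted inputs; rooting errors in the
  per-gene trees propagate.
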