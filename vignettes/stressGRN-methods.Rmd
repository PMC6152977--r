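---
title: "Methods: regulatory network inference from time-course stress RNA-seq"
author: "stressGRN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regulatory network inference from time-course stress RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressGRN)
```

# Overview

stressGRN infers a bipartite transcription-factor (TF) to target-gene (TG)
regulatory network from a replicated, two-ecotype, treated/control
time-course of RNA-seq counts, and organizes the response into a temporal
map with bifurcation events. The stages are:

1. **Normalization** — TMM scaling factors between libraries, CPM, and an
   expression filter (CPM > 2 in strictly more than 90% of samples).
2. **Differential expression** — a per-time-point exact negative-binomial
   test of treated vs matched control replicates; DEG = |log2FC| > 1 and
   raw p < 0.05; *stress affected* = DEG at two or more time points;
   per-ecotype selection capped at the 1500 lowest p-values; the union
   over ecotypes is the *stress responding* set.
3. **Network construction** — an initial edge for every TF-TG pair with
   |PCC| > 0.70 on log2(CPM+1); pruning to NCA identifiability; the NCA
   decomposition `X = A P` by alternating least squares; final edges at
   |PCC| >= 0.75.
4. **Validation** — ortholog transfer against reference interaction sets,
   and Wang GO semantic similarity of co-regulated targets against a
   randomized background (cutoff 0.3, one-sided Wilcoxon).
5. **Temporal maps** — a tree-structured Gaussian-emission model over
   log2 fold-change trajectories with at most two children per node;
   per-TF hypergeometric split scores at bifurcations (cutoff 0.001).
6. **GO enrichment** — hypergeometric over-representation (classic, or
   the elim adjustment), enriched at raw p < 0.01.

A synthetic-data generator plants a complete ground truth (connectivity,
activities, bifurcation, orthologs, GO structure) so every stage is
verifiable without any external download.

# The NCA model

Expression of the selected targets is modelled bilinearly on the log
scale, `X ≈ A P`: `X` (TGs × samples) holds centered log2(CPM+1) values,
`A` (TGs × TFs) is the signed *control strength* matrix supported on the
network topology, and `P` (TFs × samples) holds latent *TF activities*,
which are distinct from the TFs' own expression. The decomposition
minimizes `||X − A P||²_F` under three identifiability constraints:

* `A` has full column rank (generically, given its support);
* removing any TF column together with all rows it regulates leaves a
  support of full column rank;
* `P` has full row rank.

`checkIdentifiability()` evaluates the first two structurally: the
generic rank of a support pattern equals the rank of a random real
instantiation (almost surely), computed with a fixed seed. The third is
a property of the recovered `P`; `ncaDecompose()` reports it post hoc
(`pRankOk`, numerical rank at 1e-8 relative tolerance) rather than
enforcing it during fitting.

**Fitting.** Alternating least squares: given `A`, `P` solves a dense
least-squares problem; given `P`, each TG row of `A` solves a small
least-squares problem over its incident TFs only, so the support never
grows. After each sweep every column of `A` is rescaled to unit
Euclidean norm, the scale absorbed into the matching row of `P`, and the
sign fixed so the column's largest-magnitude entry is positive — this
resolves the scale/sign ambiguity completely, which is why two runs from
different seeds agree to numerical precision on identifiable data. `A`
is initialized with the signed PCC values on the support; the objective
trace is non-increasing by construction and iteration stops when its
relative decrease falls below `tol` (default 1e-6, 1000 sweeps max).
Rank-deficient subproblems fall back to a small ridge (1e-8) with a
warning. The printed model objective is dimensionally `X − A P`, with
`A` acting on the left of `P`.

**Conventions.** Both PCC thresholds act on |PCC| and the edge sign is
the sign of the PCC (positive = activation, negative = repression), so
repressive edges survive thresholding. The initial cut (0.70) is strict
and the final cut (0.75) inclusive. The final-edge PCC is computed
between TF and TG *expression*; correlating TG expression against the
recovered TFA instead is available via the decomposition output but is
not the default, since the high-confidence re-thresholding is a
co-expression statement.

# Differential expression

The exact test conditions on the per-gene sum of counts across the two
groups after equalizing effective library sizes to their geometric mean
("pseudo-counts"). Under NB sampling with shared dispersion φ (variance
μ + φμ²), the group sum of n replicates is NB with size n/φ, so the
conditional distribution of the treated sum given the total is a ratio
of NB point masses; the two-sided p-value doubles the smaller tail
(capped at 1), and φ = 0 reduces to the exact binomial/Poisson case.
When φ is not supplied it is estimated by a pooled method of moments,
`φ̂ = Σ(v_g − m_g) / Σ m_g²` over genes and groups — a deliberately
simple estimator whose adequacy is enforced by a calibration test
(type-I error 0.05 ± 0.02 and near-uniform null p-values at 2000 genes)
rather than by matching any particular reference implementation. Fold
changes are `log2((CPM_trt + 0.5)/(CPM_ctl + 0.5))`.

Two readings the package fixes explicitly: "absolute fold change > 2" is
interpreted on the linear scale, i.e. |log2FC| > 1, boundary exclusive;
and p-values are used raw (no multiple-testing correction) — both
tested at their boundaries. Ranking for the per-ecotype cap uses each
gene's *minimum* p-value over its DEG time points (a `rankBy = "mean"`
alternative is exposed); ties at the cap break lexicographically by gene
id so selection is deterministic and row-order invariant.

# Temporal maps

Trajectories are log2 fold changes vs the matched control per time
point, with an artificial all-zero column at t0 so every gene has a
value at time zero. The map is a tree with one Gaussian node per (time,
branch): a gene follows one root-to-leaf chain, its likelihood the
product of the node emissions along the chain, with equal chain priors.
EM alternates per-gene chain posteriors with posterior-weighted node
means/variances (variance floored at 1e-3 to keep emissions proper).

Structure search starts from a single chain and proposes, for each node
in time order, replacing its child subtree with two copies whose entry
means are initialized by a deterministic 2-means (centers at the member
quartiles). A proposal is acceptable when BIC = −2 logL + 2·#nodes·ln(#genes)
improves and both children retain at least 5 expected members; the
*best* acceptable proposal of each scan is taken. Best-improvement
matters: a divergence at time t can also be explained by splitting any
earlier node, but the split at t−1 duplicates the fewest nodes and so
has the best BIC — first-improvement would stop at the root. With at
most two children per node, the number of chains is bounded by 2^(T−1)
and in practice by the accepted splits.

TF split scores are hypergeometric: at a bifurcation whose parent is
passed by N genes, with n going to one child and K of them targets of a
TF, the score is the smaller upper-tail probability of the observed
target count in either child; TFs below the 0.001 cutoff are reported
with their enriched branch. Scoring uses hard (max-posterior)
assignments; this keeps the score exactly the classical tail probability
a practitioner expects. The split-score definition is a documented
stand-in honoring the cutoff's semantics, since only the interface
(fold changes and TF-TG interactions in; TF-annotated chains out) is
fixed; input-dependent transition models are out of scope.

# Validation

**Ortholog transfer.** An edge validates when some reference source
contains an interaction between a reference-species ortholog of its TF
and one of its TG. Co-orthologs are allowed; duplicated reference rows
do not change counts; per-source tallies report validated edges and the
distinct TFs involved.

**Functional relevance.** Wang similarity propagates each term's
semantic contribution along child-to-parent edges with decay 0.8 (is_a)
and 0.6 (part_of), taking the best path; the pair similarity is the
shared ancestors' contribution relative to both terms' totals. Gene
similarity is the best-match average over the two BP term sets. Edge
validation uses the mean similarity of a target to its co-targets
(cutoff 0.3); validating a TF wholesale when its Wilcoxon test is
significant is available as `mode = "tf"` — the edge-level rule is the
default because it yields a per-interaction verdict. The background
pools pairwise similarities of `nBackground` random same-size sets from
the annotated universe; the one-sided Wilcoxon rank-sum test is exact
for pooled n ≤ 25 and otherwise uses the normal approximation with
continuity and tie correction. The advisory `saturationCutoff()` returns
the knee (maximum chord distance) of the retained-fraction curve; the
pipeline default stays 0.3.

**Enrichment.** Annotations are propagated to ancestors (true-path
rule) before testing, so K(parent) ≥ K(child) always. The elim variant
processes terms deepest-first and removes the study genes of any term
with p below the elimination threshold from all its ancestors before
they are tested. Classic Fisher is the default; which adjustment the
original analyses used is not fixed, and elim is provided as the
signature alternative.

# The synthetic study

The generator's defaults *are* the study conditions the package is
tested under: 2 ecotypes × {treated, control} × 6 time points × 3
replicates (8 time points supported), 5 TFs, 80 candidate targets, 10
housekeeping spike-ins and 2 always-zero genes, NB dispersion φ = 0.05,
library sizes uniform in 3–5 × 10⁵, and edge weights ± Uniform(0.5, 2).
Counts are NB draws around `L_s · softmax(baseline + clip(A P, ±8))`;
control samples use a flat (all-zero) activity matrix so every DE
contrast has matched controls; the two ecotypes share the gene universe
and the planted network but draw independent activities.

Design choices that required care:

* **Sparsity (edgeDensity = 0.06, ≥3 targets per TF).** A target with
  two regulators of comparable weight can keep at most one edge at
  |PCC| ≥ 0.75, because the squared correlations with uncorrelated
  drivers sum to ~1. The density is therefore set so most regulated
  targets have a single dominant regulator, which makes the planted
  edge set actually recoverable by a correlation-thresholding pipeline;
  the repair floor of 3 targets per TF keeps a TF alive in the pruning
  stage even if one edge is lost to noise.
* **Decorrelated activities.** Random smooth curves over only 6 points
  frequently correlate above 0.8 by chance, which creates duplicate
  supports and spurious pruning. Each TF's activity is therefore built
  on a TF-specific discrete-cosine mode (orthogonal over the time grid)
  plus a small random polynomial, amplitude ~2–2.8 sd.
* **Bifurcation.** Two branch-driver TFs share one trajectory before
  the bifurcation index and diverge ±1.6 (plus independent smooth
  wiggle) from it on, so the planted branch trajectories coincide
  exactly before the split and separate by 3.2 after — large against
  the 0.35-sd emission noise of the trajectory fixture, and the two
  drivers stay only weakly correlated overall. Regulated targets
  inherit a branch from their dominant driver, sign-aware.

What the generator does **not** emulate: gene-length and GC biases,
outlier genes and sample swaps, batch effects, count-level correlation
between replicates, realistic GO topologies (the planted DAG is a
three-level caricature with one clade per TF), or sequencing depths of
real libraries. Passing tests therefore demonstrate the pipeline's
internal correctness and its behaviour under its own model assumptions,
not field performance on real switchgrass data.

Desk-scale problem sizes were chosen so the full suite and the
acceptance script each run in well under a minute of compute per stage:
the bundled study has ~100 genes × 72 samples, the calibration nulls use
2000 genes and 100 enrichment draws, and bifurcation recovery uses 120
genes × 20 seeds.

# Numerical choices and degenerate inputs

* TMM: reference = sample whose 75th-percentile CPM is closest to the
  mean; 30%/5% two-tailed trims on M/A ranks; precision-weighted mean;
  factors normalized to geometric mean 1; a sample with fewer than
  `minGenes` surviving genes falls back to factor 1 with a warning.
  Exact invariance to rescaling one library is impossible because the
  precision weights depend on absolute counts; the effect is of order
  the inverse counts.
* Expression filter: strictly more than `sampleFraction` of samples — a
  gene at the boundary (exactly 90%) is dropped, and this boundary is
  tested.
* PCC: zero-variance genes are dropped with a warning; fewer than 3
  samples is an error.
* Pruning removes, to a fixed point: TFs with <2 targets; all but the
  best (mean |PCC|, ties by id) of any duplicate-support group; then the
  identifiability violator whose removal costs fewest edges.
* ALS on an all-zero X returns zero factors and objective 0 via the
  ridge fallback.
* Temporal fitting: variance floor 1e-3; EM stops at relative logL
  change < 1e-8 or 500 iterations; proposals with a child under 5
  expected members are rejected; quartile-seeded 2-means makes the
  search fully deterministic given the seed.
* All generator routines draw from sub-streams derived from the master
  seed and restore the caller's RNG state, so outputs are byte-identical
  across runs and independent of call order.

# Known limitations

* The exact NB test uses a single pooled dispersion; genewise or
  trended dispersion estimation is out of scope, and the calibration
  guarantee is the test suite's null simulation, not asymptotic theory.
* The temporal model has no input-dependent transition probabilities and
  no merge moves; maps are trees, not HMM lattices.
* Only GO biological-process terms, is_a/part_of edges, and the Wang
  measure are supported; no information-content measures.
* The orthology validation trusts the supplied ortholog map; no
  ortholog inference is performed.
* With very small time courses (<3 measured points) the temporal stage
  refuses to fit rather than guessing.
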