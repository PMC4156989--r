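---
title: "Methods: stage-specific drug repositioning with batch meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-specific drug repositioning with batch meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repometa)
```

# Overview

`repometa` implements a desk pipeline for finding drugs that may reverse a
stage-specific cancer expression signature. The pipeline's statistical
chain is: paired moderated-t differential expression → up/down signature
intersection across batches → clique-percolation communities on
direction-specific PPI subnetworks → over-representation analysis →
Fisher-z meta-analysis of per-batch drug enrichment scores → ranking,
Jaccard comparison, and target mapping. This vignette explains each model,
its assumptions, the tunable parameters, the numerical choices made, and
what the bundled simulations do and do not demonstrate.

# Paired differential expression

## Model

Each patient contributes a tumor and a matched normal log2 profile, so a
gene's data reduce to per-patient differences d_1..d_n; pairing removes
between-patient baseline variation, which is the design's point. The
per-gene mean difference is the log2 fold change. Testing uses a moderated
t: with sample variance s²_g on d_g = n − 1 degrees of freedom and a prior
(d0, s0²) shared across genes,

    s̃²_g = (d0·s0² + d_g·s²_g) / (d0 + d_g),
    t_g = log2fc_g / (s̃_g / √n),   df = d0 + d_g.

The prior is estimated by method of moments on log s²_g: writing
e_g = log s²_g − digamma(d_g/2) + log(d_g/2), the model implies
E[e] = log s0² − digamma(d0/2) + log(d0/2) and
Var[e] = trigamma(d_g/2) + trigamma(d0/2), so d0 solves a trigamma
inversion (Newton iteration, relative tolerance 1e-8) and s0² follows from
the mean. When the observed spread of log s² is no larger than its pure
sampling expectation the estimate is d0 = ∞ and every gene uses the common
variance s0²; the t is then referred to a normal distribution (t with
infinite df). Genes with zero sample variance carry no information about
the prior and are excluded from the fit (no pseudo-count offset is added);
estimation errors out only when *every* gene is constant, since no variance
scale is identifiable then.

## Selection and signature export

Genes with Benjamini–Hochberg adjusted p below `deg_alpha` (default 0.005,
a deliberately strict threshold for signature construction rather than
discovery) are split by the sign of the fold change: positive = up in
tumor. A fold change of exactly zero is excluded from both groups — a
measure-zero event on real data, but the rule keeps the up/down sets
disjoint by construction. The multiple-testing procedure is BH because it
is the default of the empirical-Bayes microarray workflow this stage
follows; note BH is monotone and order-preserving but *not* idempotent, so
it is applied exactly once, to raw p-values.

Stage signatures are the per-direction intersections across all batches:
a gene must be called in the same direction on every platform. For export
to connectivity-map-style query tools, fold-change magnitudes below
`fc_floor` = log2(50) ≈ 5.64 are reset to the floor with sign preserved —
the query format rewards strongly contrasted signatures, and the floor is
applied after selection and intersection, at export time only; it never
influences testing.

# PPI communities

An interaction is an "up PPI" when both endpoints are upregulated; the up
(down) subnetwork is the edge-induced subgraph on the up (down) signature.
Communities are standard k-clique percolation: enumerate all cliques of
size exactly k, declare two adjacent when they share k − 1 nodes, and take
node-unions of connected components of that adjacency. Communities may
overlap in genes; the census counts each distinct gene once. Adjacency is
resolved by hashing each clique's (k − 1)-subsets, which is exact: two
distinct k-cliques share k − 1 nodes iff they share a (k − 1)-subset.
Output order is deterministic (size descending, then lexicographically
smallest member), so reruns are byte-identical.

k defaults to {3, 4, 5}: 3 is the smallest size with clique structure and
the workflow's canonical choice; larger k rarely yields communities on
signature-sized subnetworks. Clique enumeration is worst-case exponential,
so a `max_nodes` guard (default 10,000) refuses degenerate inputs;
signature-induced subgraphs are far smaller in practice. Genes outside
every community are treated as weakly connected and dropped before
enrichment and drug-target mapping.

# Over-representation analysis

For a query set of size n drawn from a background of size N, a pathway
with K members in the background, and overlap x, the p-value is the
one-sided hypergeometric tail P(X ≥ x). The background is the set of genes
on the (here: simulated) platform, not the genome — the microarray ORA
convention, and configurable. Overlap 0 gives p = 1 under the
at-least-observed convention. BH adjustment runs across all pathways in the
collection before the report threshold (`ora_alpha`, default 0.05) is
applied to raw p-values, and results are ranked by ascending raw p with
pathway name as the tie-break. Query genes outside the background are
dropped with a warning; an empty restricted query is an error rather than
an empty report.

# Meta-analysis of drug enrichment scores

## Effect size and models

A drug's per-batch enrichment score ρ ∈ (−1, 1) is treated as a sample
correlation and moved to the Fisher z scale, z = ½·ln((1+ρ)/(1−ρ)), with
sampling variance V = 1/(N − 3), N the drug's instance count; N ≤ 3 is a
hard error since the variance is undefined. All combination happens on the
z scale; summaries and confidence limits are back-transformed with tanh at
the end, which guarantees the reported score CI stays inside (−1, 1).

Fixed-effect weights are W_i = 1/V_i (equal weights in the unweighted
mode); the summary is M = ΣW_iY_i/ΣW_i with V_M = 1/ΣW_i. The test
statistic is Z = M/SE_M, algebraically identical to ΣW_iY_i/√ΣW_i. The CI
multiplier is the literal 1.96 rather than a recomputed normal quantile,
for bit-reproducibility of the formula as published. Heterogeneity uses
Cochran's Q = ΣW_i(Y_i − M)² on k − 1 df, I² = max(0, (Q − df)/Q)·100 (0
when Q = 0), and the DerSimonian–Laird moment estimator
τ² = max(0, (Q − df)/C), C = ΣW_i − ΣW_i²/ΣW_i. The random-effects model
re-weights with W*_i = 1/(V_i + τ²); at τ̂² = 0 it coincides with the
fixed-effect result.

## Model selection and p-values

The model is chosen per drug by the heterogeneity test: p_het ≥ 0.1 →
fixed, otherwise random, with the boundary value 0.1 mapping to fixed
("greater than or equal"). The primary p-value is one-tailed in the
negative direction — the pipeline seeks signature-*reversing* drugs, so
evidence means a negative combined effect — with a two-sided option in the
API. A drug present in a single batch is passed through as a k = 1
fixed-effect result with `k_studies` recording the fact; the CLI warns in
that case. The alternative route combines per-batch p-values with Fisher's
method, F = −2Σln p ~ χ²_2k; zero p-values (which score services do emit)
are floored at 1e-16 with a warning rather than producing an infinite
statistic.

Drugs missing an instance count are dropped with a warning, or given a
configured global default N — the instance count is the one quantity
score tables routinely omit.

# Ranking, comparison, targets

Candidates must have a strictly negative score (es < `es_max` = 0; a zero
score is not evidence of reversal) and optionally a per-batch p below
`cmap_p_max`. Drugs with combined p < `ma_p_max` (default 0.05) are ranked
by ascending p with lexicographic tie-break, making lists deterministic.
Lists are compared with the Jaccard index |A∩B|/|A∪B| — defined as 0 when
both sets are empty to avoid 0/0 — and rendered in the triangular layout
with intersection counts below and indices above the diagonal. Drug names
are normalized case-insensitively (score services vary in casing). Target
mapping intersects each drug's known targets with the up and down
community gene sets separately and aggregates unique genes per direction;
the neighbor export writes each target's incident PPI edges with
target/partner role annotations.

# The synthetic-data module

The generators are first-class, tested code; their defaults are the study
conditions the rest of the package is exercised under.

* **Paired expression.** Defaults: 4 batches of 8/15/35/25 patient pairs
  (an early-stage multi-platform design), 5% of genes planted up and 10%
  down (the ~2:1 down:up imbalance typical of paired tumor/normal cancer
  signatures), planted |log2FC| ~ Normal(2, 0.5²), residual sd 1 on the
  log2 scale — a typical single-array noise level. Planted effects are
  drawn once and shared across batches (optionally jittered per batch,
  default 0), which is exactly the common-signature structure cross-batch
  intersection assumes. Tumor profiles are normal + difference, with
  normal-tissue baselines Normal(7, 2²) on the log2 scale.
* **PPI.** Each planted gene set is wired as a chain of k-cliques
  overlapping in k − 1 nodes, the minimal structure guaranteeing it forms
  exactly one k-community; background edges are independent Bernoulli.
* **Drug scores.** Each drug has a true score ρ; a batch observes
  z ~ Normal(atanh ρ, 1/(N−3) + τ²), back-transformed with tanh, with a
  two-sided normal p for z/√(1/(N−3)). The default instance count is
  N = 10 — connectivity-map compounds typically have on the order of 5–20
  instances — and τ² is the explicit between-batch heterogeneity dial.

What the generators do *not* emulate: probe-level structure, RMA
normalization, array-specific intensity distributions, correlated noise
across genes, scale-free PPI topology, or permutation-based score
p-values. Passing tests therefore demonstrate the statistical machinery is
correct under its stated model, not that the pipeline's biological outputs
on real arrays are reproduced.

# Numerical choices and degenerate inputs

* Trigamma inversion: Newton iteration, asymptotic guards at x < 1e-6 and
  x > 1e7, relative tolerance 1e-8.
* Fisher z round-trips are exact to < 1e-12 over ρ ∈ (−0.999, 0.999)
  (hyperbolic-function implementation).
* Q = 0 (all effects identical) gives p_het = 1, I² = 0, τ² = 0; Q below
  its df floors both I² and τ² at 0.
* Degenerate meta inputs: empty effect lists, k = 1 heterogeneity
  requests, N ≤ 3, and C = 0 weight configurations are errors with
  explicit messages, not NaNs.
* Ties: all ranked outputs (ORA rows, drug lists, communities) break ties
  lexicographically; reruns of the pipeline with an identical
  configuration produce byte-identical TSVs, verified by checksum in the
  tests.

# Verification strategy and problem sizes

Each nontrivial computation is checked against an independent oracle:
clique percolation against brute-force enumeration (all k-subsets +
union-find) on random graphs of up to 30 nodes for k ∈ {3, 4, 5}; the
hypergeometric tail against exhaustive enumeration of all C(N, n) draws
for backgrounds up to 20 genes; the meta-analysis chain against a
straight-from-formula reimplementation on 1,000 random inputs (agreement
to 1e-10) and against `metafor::rma(method = "DL")`; the moderated t
against `limma::eBayes`, whose prior fit uses the same moment method.
Simulation-backed checks use 2,000 replicates for random-effects CI
coverage (k = 4, τ² = 0.1), 500 replicates for effect recovery, and
1,000-gene single-batch designs for DEG sensitivity/FDR and null type-I
error — sizes chosen to keep Monte-Carlo error around half a percentage
point while the full suite runs in minutes.

# Known limitations

* DerSimonian–Laird random-effects intervals with the normal-quantile
  multiplier are known to undercover slightly at very small k; with k = 4
  batches and τ² comparable to the sampling variance, measured coverage of
  the 95% CI sits near 93% rather than 95%. This is a property of the
  published estimator the package reproduces faithfully, not an
  implementation artifact (the implementation matches `metafor` to 1e-8);
  users combining very few batches should read the CIs with that in mind.
* The moderated-t prior fit assumes a common variance prior across genes;
  strongly bimodal variance structure weakens the shrinkage benefit.
* Clique percolation is exponential in the worst case; the node-count
  guard exists because the intended inputs are small signature-induced
  subgraphs, not whole interactomes.
* The one-tailed direction convention (negative = interesting) is baked
  into the default ranking; use the two-sided option when screening for
  mimics rather than reversers.
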