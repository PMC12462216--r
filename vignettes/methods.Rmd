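---
title: "Methods: ROI-based nigral transcriptomics with network propagation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROI-based nigral transcriptomics with network propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nigraspace)
```

# The analysis problem

GeoMx-style digital spatial profiling of the substantia nigra pars compacta
(SNpc) yields transcript counts for a few thousand targets in a few dozen
regions of interest (ROIs) — circular tissue segments selected per slide
across the dorsomedial, dorsolateral, ventromedial and ventrolateral
quadrants of the nucleus. In a case–control design (healthy controls,
Parkinson disease, MSA-P), the questions are: which genes change between
groups, overall and per quadrant; which pathways those changes implicate;
and which of the changed genes act as *hubs* — genes whose network position
amplifies their influence on the rest of the differential signal.

`nigraspace` implements that pipeline with the hub-gene stage — random walk
with restart (RWR) plus betweenness centrality on a protein–protein
interaction (PPI) network — as its core, and a ground-truth synthetic-data
generator as its calibration surface.

# Model and procedure

## ROI filtering

ROIs are retained when `nuclei_count > min_nuclei` (default 90, a strict
inequality: an ROI with exactly 90 nuclei is removed). Genes are never
filtered; targeted panels are small enough that independent filtering
yields little and complicates multiplicity accounting.

## Between-lane normalization and unwanted variation

`between_lane_normalize()` offers three modes. The default, upper-quartile,
scales each ROI so the 75th percentile of its nonzero counts equals the
geometric mean of the per-ROI upper quartiles; it is idempotent and robust
for targeted panels where a minority of high-expressors dominates totals.
Full-quantile normalization forces identical count distributions (ties
receive the mean over their tied positions) and is offered for strongly
distorted libraries at the price of stronger assumptions.

Unwanted variation — slide, batch, fixation — is estimated RUV-style from
control genes: the ROI × control matrix of `log(norm + 1)` values is
centered per gene (removing baselines, the orientation in which a shared
nuisance factor is the leading direction) and its first *k* left singular
vectors in ROI space become mean-centered loading columns. Controls are
chosen empirically by `select_empirical_controls()`: a first-pass
negative-binomial group test (joint Wald across group coefficients when
more than two groups are present), keeping the least group-associated genes
among those with above-median expression. The default *k* = 1 reflects one
dominant batch axis (slide/subject) in a two-slides-per-group design; it is
configurable and *k* = 0 disables the stage.

Deliberately, the loadings are passed downstream as design covariates
rather than used to "correct" the counts: the count model keeps raw
integers and offsets, which is both statistically cleaner and simpler to
reason about.

## Differential expression

The DE stage is a compact negative-binomial Wald test:

* **Size factors** — median-of-ratios over genes expressed in every ROI,
  rescaled to geometric mean 1 (upper-quartile fallback when no gene is
  expressed everywhere).
* **Dispersions** — method-of-moments per gene within design cells,
  `α = max(0, (var − μ·mean(1/s)) / μ²)`, shrunk toward a fitted
  `a₀ + a₁/μ` trend with weight `df_res : prior_df` (prior df fixed at 6).
  Genes with constant counts get dispersion 0 and skip shrinkage.
* **GLM** — per-gene log-link NB regression with `log(size factor)`
  offsets and coefficients for intercept, group and the RUV loadings,
  fitted by iteratively reweighted least squares; Wald statistic
  `β̂/se(β̂)`, two-sided normal p, Benjamini–Hochberg adjustment;
  DEG = adjusted p < 0.05. Non-converging genes are flagged with p = 1.

There is intentionally no Cox–Reid adjustment, fold-change shrinkage,
outlier replacement or independent filtering: the package's claim is not
concordance with any particular DE tool but *calibration*, demonstrated on
synthetic truth (below). Quadrant-stratified contrasts re-run the test
inside each quadrant's ROIs with per-stratum adjustment, since quadrant
analyses are reported as separate comparisons.

A self-contrast (test group = reference group) duplicates the group's ROIs
into two identical design cells; the group coefficient is then exactly 0,
which the suite uses as a degenerate-input check.

## Enrichment

Over-representation uses the hypergeometric upper tail
`P(X ≥ k | N, K, n)` on overlap counts (query and sets intersected with
the universe first), BH-adjusted across terms. The ranking statistic is a
combined score `c = −ln(p)·z` with `z = (k − E[X]) / sd(X)` under the
hypergeometric null — a deliberate, documented substitute for Enrichr's
rank-corrected z, whose precomputed random-set tables cannot be
reproduced; published Enrichr combined scores are therefore not comparable
numbers. The universe defaults to all genes in the filtered count matrix,
the standard over-representation convention when an assay panel defines
what could have been detected.

Redundant terms are clustered by average-linkage hierarchical clustering on
`1 − Jaccard` distance of their overlap gene sets, cut at
`1 − similarity_threshold` (default 0.5); gene-overlap similarity is used
instead of ontology-graph semantic similarity to avoid an ontology
dependency, at the cost of treating terms with disjoint annotated genes as
unrelated even when semantically close. Directional Venn summaries report
shared/exclusive DEG counts and shared percentages under two denominator
conventions (directional list size and total DEG count), since the
denominator convention materially changes the quoted percentage.

## Network propagation and key genes

Significant DEGs are mapped onto the PPI network by uppercased symbol
(unmapped symbols are reported, not fatal — no alias resolution is
attempted). Their |log2FC| values form the seed vector `p⁰`, rescaled to
sum 1; the absolute value is the default because `p⁰` is a probability
vector and cannot carry sign. Sign is retained for display, and
positive-part or signed-split (two runs) seeding are available options.

The walk iterates `p⁽ᵗ⁺¹⁾ = (1 − r)·W′·p⁽ᵗ⁾ + r·p⁰` on the
column-normalized adjacency `W′` until the L1 change falls below `tol`
(default 1e-8). Because the map is a contraction with factor `1 − r`, it
converges for any `r ∈ (0, 1)`; the implementation still verifies the
fixed-point residual and conservation of total mass (exact for a
column-stochastic `W′`) at every iteration. The default restart rate
`r = 0.7` follows the common convention in propagation analyses of PPI
networks; larger `r` keeps mass near the seeds, smaller `r` diffuses
further. Zero-degree nodes get a self-loop (identity column), preserving
stochasticity without teleporting their mass elsewhere.

Betweenness centrality is computed by Brandes' algorithm with the
undirected convention (each unordered pair counted once; disconnected
pairs contribute 0), on the largest connected component of the *full* PPI
network rather than the DEG-induced subgraph — bridges through non-DEG
nodes are part of a hub's importance. Key genes are the significant DEGs
reaching the `prob_quantile` of DEG probabilities *and* the `bc_quantile`
of DEG betweenness values (defaults 0.90/0.90, computed over DEG nodes
only). Ranked output sorts by probability, ties broken by betweenness then
symbol, so reruns are order-stable.

# The synthetic-data generator

`generate_dataset()` emulates the study design: 3 groups × 2 subjects ×
1 slide × 12 ROIs, quadrants assigned cyclically (3 ROIs per quadrant per
subject, a balanced default since per-quadrant ROI counts are a design
choice), nuclei counts uniform in 50–300. Counts are negative binomial
with `var = μ + α·μ²`, per-gene dispersions log-normal around
`nb_dispersion` (sdlog 0.3, default center 0.1 — a typical targeted-panel
overdispersion), baselines log-normal spanning roughly three orders of
magnitude (sdlog 1.5 around 50), library-size factors log-normal
(sdlog 0.25, a free parameter as no per-ROI depth summary constrains it),
planted effects of magnitude `effect_log2fc` with random sign on a
`frac_de` fraction of genes, and slide-correlated unwanted factors (shared
subject loading plus ROI noise, per-gene susceptibilities with sd
`unwanted_sigma` = 0.5 on the log2 scale). Control genes are a random
subset of the non-DE genes and are *not* exempt from unwanted variation —
that is precisely what makes them informative for RUV.

`generate_ppi()` grows a preferential-attachment graph (connected, simple,
heavy-tailed) as a stand-in for a BioGRID-style network;
`generate_gene_sets()` draws random GMT-writable sets and can plant one
term that fully contains a chosen gene list for recovery testing.

What the generator does **not** emulate: spatial autocorrelation between
neighbouring ROIs, cell-type composition differences (the morphology
markers that guide real ROI selection), probe-level noise, zero inflation
beyond NB sampling, and realistic PPI topology beyond degree heavy-tails.
Passing tests therefore demonstrate the algorithms' correctness and
calibration under the generative model, not robustness to every artefact
of real GeoMx data.

# Numerical choices and verified behaviour

The test suite (all values computed at test time) verifies, among others:

* RWR equals the closed-form solve `p = r(I − (1 − r)W′)⁻¹p⁰` to ≤ 1e-8 on
  random connected graphs up to 50 nodes, conserves mass to 1e-9 at every
  iteration, and reproduces the hand-derived two-node fixed point
  `(2/3, 1/3)` at `r = 0.5`.
* Brandes betweenness matches an exhaustive simple-path enumeration oracle
  exactly on hundreds of random ≤ 7-node graphs (and igraph's
  implementation on larger ones), including the path (`BC = 1`) and star
  (`BC = 3`) closed forms.
* The DE test at 2000 genes and 12 vs 12 ROIs is null-uniform
  (mean KS statistic ≈ 0.02), holds empirical FDR ≈ 0.06 at a BH 0.05
  threshold with 10% planted effects, and has sensitivity ≈ 1 for
  |log2FC| = 2 at baseline mean ≥ 100.
* RUV recovers a planted slide-correlated factor with
  |correlation| > 0.9 from known controls across seeds.
* Hypergeometric tails match brute-force summation to 1e-12 relative;
  a planted enriched term ranks first by adjusted p in ≥ 95% of seeds.
* Two pipeline runs from identical configs produce byte-identical result
  tables.

Problem sizes in tests and in `scripts/acceptance.R` (2000 genes, 12–72
ROIs, 1000-node networks, 5–20 seeds per experiment) were chosen as the
smallest scales at which these properties are stable, keeping the whole
suite under a minute.

# Known limitations

* **Pseudoreplication.** With 2 subjects per group and ~12 ROIs per
  subject, ROI-level modeling treats within-subject ROIs as replicates.
  Combined with slide-correlated unwanted variation this inflates the
  whole-pipeline false-discovery proportion well above the nominal level
  even after RUV adjustment — visible in the synthetic full-design runs,
  where many "significant" genes carry subject-level nuisance signal
  rather than group signal. The DE test itself is calibrated (see above);
  the inflation is a property of the design. ROIs can be collapsed to
  subject means for a conservative analysis, at the cost of n = 2 per
  group.
* The empirical-control convention can admit weak true DE genes into the
  control set when effects are dense; known negative controls are
  preferable when available.
* The combined score is not Enrichr's; use adjusted p for inference and
  the score only for ranking.
* Symbol-based network mapping loses DEGs whose symbols differ from the
  network's labels; the mapping report should be inspected.
* The propagation stage ranks genes; it attaches no significance to
  probabilities. Permutation-based significance is out of scope.
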