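---
title: "Methods: assembling and propagating heterogeneous complex-trait networks"
author: "traitnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assembling and propagating heterogeneous complex-trait networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitnet)
```

## The data model

`traitnet` represents a complex-trait network as a typed multi-partite
graph with four node classes — gene, disease, tissue, drug — and six edge
classes: `disease_gene`, `protein_protein`, `protein_dna`,
`disease_tissue`, `tissue_gene`, `drug_gene`. Genes, SNPs and proteins
deliberately share one node class: a SNP is resolved to its nearest gene
when the association layer is built, and the gene's protein product carries
the interaction layers, so the graph stays 4-partite. Only `protein_dna`
edges (TF → target gene) are directed. Disease–gene edges carry
−log₁₀ of the association p-value; every other class is unweighted
(weight 1).

Undirected edges are stored with endpoints in lexicographic order, which
makes duplicate detection independent of input orientation. Duplicate
`(source, target, type)` triples are rejected at read time rather than
merged: the only place association reports are merged is the assembly
stage, where the Fisher rule applies, so the merging policy lives in
exactly one place. Protein–protein self-interactions (present in some PPI
snapshots) and TF autoregulatory self-edges are accepted but flagged with a
warning; self-edges of any other class are structural errors.

## Assembly

The pipeline is map → combine → weight → filter(τ) → attach layers →
expand(ds).

**Nearest-gene mapping.** The distance from a SNP to a gene is 0 inside
the gene body `[start, end]` and the distance to the nearer boundary
outside. We use the gene *body* for SNP mapping but the transcriptional
start site (TSS) *point* for TF-binding-site windows, because the two
operations answer different questions (which gene does this variant most
plausibly tag, vs. is this site in a promoter). Exact ties — equidistant
genes or TSSs — are broken toward the lexicographically smaller symbol,
purely for determinism. Internally all coordinates are 1-based inclusive;
BED input (0-based half-open) is converted at the reader boundary by
`rtracklayer`, so only one convention exists inside the package. The
nearest-feature search itself is delegated to `GenomicRanges::nearest()`;
because that function measures gap distance (adjacent ranges have distance
0), the returned tie set is re-scored with the exact point-to-interval
distance before the tie-break, which matters in the corner case of a SNP
one base outside one gene but inside an adjacent one.

**Combination order.** Replicated reports of the same *phenotype–SNP* pair
are combined first with Fisher's method (X² = −2Σln pᵢ against χ² with 2k
df; a single study passes through unchanged), and then the *best* (smallest)
combined p across a gene's SNPs defines the disease–gene edge weight. SNP
level first, best-SNP second is the one order consistent with both natural
readings of "combine replicated evidence" and "the most significant SNP
defines the gene–trait edge"; combining across *different* SNPs of a gene
would conflate partially independent signals and is not done. Edge
provenance is the union of all contributing PubMed ids.

**Threshold.** τ is expressed on the −log₁₀(p) scale and the boundary is
inclusive (weight ≥ τ, i.e. p ≤ 10^−τ): "significant at 10⁻⁸" naturally
includes p = 10⁻⁸. p-values reported as 0 are clamped to 1e−300 with a
warning so the weight stays finite. Diseases whose every association fails
τ are dropped by default (`keep_isolated_diseases = FALSE`), because an
isolated disease node contributes nothing to propagation; the flag exists
for users who want the full disease inventory.

**TF-binding sites.** The confidence filter is strict (score > 4.0) while
the promoter window is inclusive (|pos − TSS| ≤ 5,000 bp): the filter is a
printed inequality, the window a "within". Both are parameters
(`z_min`, `promoter_window`).

**Degrees of separation.** `ds` expands the network over the *combined*
protein–protein ∪ protein–DNA layer with directions ignored — regulation
and physical interaction both count as one step of functional proximity.
`ds = 0` adds only interactions among already-present genes; `ds = k` adds
every gene within graph distance k of a directly associated gene (computed
with `igraph::ego`) plus all gene–gene edges among the enlarged set. The
tissue and drug layers are attached only around the retained core: tissues
of retained diseases, then tissue–gene and drug–gene edges restricted to
genes already present.

## Similarity projection

`project_similarity()` replaces indirect two-hop connections by direct
edges whose weight is the *number of shared intermediate neighbours*
(a count, not Jaccard — the count is what a shared-genes display colours
by; Jaccard is available behind a flag). Disease–gene weights are ignored
during projection: presence/absence of a thresholded association is the
relevant signal. The computation is a sparse incidence product B·Bᵀ with
entries of B clamped to 1 so each intermediate node is counted at most once
per pair. `normalized_weight = weight / max(weight)` is exported for colour
mapping; the rendering itself is out of scope.

## Propagation

Both prioritizers iterate

p^(t+1) = (1 − r) W p^t + r p⁰

until the L1 change falls below `tol`. Defaults: r = 0.5, tol = 1e−6,
max_iter = 1000 — standard for propagation methods; with r > 0 the spectral
radius of (1 − r)W is below 1 in both normalizations, so the iteration is a
contraction and these defaults converge in a few dozen iterations on
connected graphs. Non-convergence is reported honestly
(`converged = FALSE` plus a warning), never silently truncated. The
per-iteration cost is one sparse matrix–vector product, linear in the edge
count.

**Normalizations.** `rwr()` defaults to the column-stochastic random-walk
operator A·D⁻¹ (scores are a probability distribution: with no isolated
nodes and Σp⁰ = 1, Σp^t = 1 at every step); `prince_extended()` defaults to
the symmetric D^(−1/2)·A·D^(−1/2) of network-propagation methods. The two
conventions follow the respective source algorithms; either can be selected
for either method. Zero-degree nodes keep zero rows/columns; by the update
their fixed-point score is exactly r·p⁰ — documented, not special-cased.

**Seeds and candidates.** Genes whose disease–gene weight reaches τ are
"associated" (seeds); `rwr()` starts from the uniform distribution over
them. All other gene nodes are "candidates", ranked by descending converged
score with ties broken by ascending node id (dense ranks 1..m); seeds never
appear in the candidate ranking.

**The extended propagation prior.** `prince_extended()` runs over the full
heterogeneous adjacency, unweighted and undirected (including
`protein_dna`: direction-aware propagation is deliberately not attempted,
as no principled row/column convention exists for mixing directed and
undirected layers). The walk runs on the *thresholded* network — only
associations the user accepts as true carry propagation, consistent with
every other layer being curated rather than probabilistic. The prior over
genes is derived from the GWAS data itself:

* disease similarity sim(d₁, d₂) = shared genes / min(set sizes), computed
  on the thresholded layer via the projection module. Min-normalization
  (rather than union or geometric mean) keeps sim ∈ [0, 1] with the bound
  attained by nested sets, which is what the logistic transfer expects;
* logistic transfer L(x) = 1/(1 + exp(c·x + d)) with c = −15,
  d = ln(9999), so L(0) = 10⁻⁴ and L(1) ≈ 0.997 — the classic
  network-propagation prior shape with pinned extremes. Both are exposed
  parameters;
* each gene linked to a thresholded disease gets y(g) = max over its
  diseases of L(sim(query, d)); the query disease node itself gets prior 1;
  tissue and drug nodes get 0 (no evidence links them to causality
  directly).

A query disease with no thresholded associations and no similar disease
has a prior at the L(0) baseline; the function warns and the resulting
scores are near zero rather than an error — the honest answer to "there is
no signal to propagate". An explicit `prior` vector can be supplied
instead, which also exposes the algebraic degeneracy used in testing: on a
gene-only network with a uniform seed prior and shared normalization the
two prioritizers are the same fixed point.

## What the synthetic generator emulates — and what it does not

`generate_fixture()` emulates the *edge-level statistical structure* the
downstream methods consume: per-disease modules of truly associated genes
with p-values log-uniform on [1e−30, 1e−8]; spurious associations uniform
on [1e−6, 0.05]; a held-out quarter of each module emitted at noise level
only (recoverable by propagation, invisible to thresholding); PPI density
boosted ×20 within modules over a 0.01 background (Erdős–Rényi by default,
scale-free optional); designated disease pairs sharing 20% of their
modules; TF-binding sites scattered around TSSs with scores straddling the
4.0 cutoff; and small tissue/drug layers. The signal and noise supports
leave a deliberate gap at p = 10⁻⁷, so τ = 7 is an exact separator and
filter tests can be exact. Genes are laid out at a fixed 10 kb spacing with
2 kb bodies on four synthetic chromosomes, so every distance in a test is
hand-checkable; association SNPs are placed inside their gene body, making
the fixture's SNP→gene mapping unambiguous (equidistant-tie behaviour is
exercised directly in unit tests instead). Default sizes — 400 genes, 6
diseases, 20-gene modules — are large enough for rank percentiles to be
meaningful and small enough that a 20-replicate recovery experiment runs in
well under a minute.

The generator is *not* a GWAS simulator: there is no linkage
disequilibrium, no genotypes, no effect sizes, no population structure,
and the PPI background is far sparser and more homogeneous than a real
interactome. Passing recovery tests therefore demonstrates that the
propagation machinery exploits module structure when it exists — not that
it will achieve any particular accuracy on real data, where signal-to-noise
is worse and module boundaries are blurry.

All stochastic draws flow through R's generator seeded once from
`rng_seed`, so a fixture is a pure function of its configuration; replicate
experiments derive per-replicate seeds as `rng_seed + i`.

## Numerical choices and degenerate inputs

* Weights round-trip through text via `%.17g`, preserving at least 15
  significant digits.
* Fisher combination uses the exact χ² upper tail (`pchisq(lower = FALSE)`)
  — no approximation; combined p-values are floored at 1e−300 before
  taking −log₁₀.
* At r = 1 the update returns p⁰ after one iteration with an exact zero
  L1 change — no special case needed.
* Empty networks: projection of a layer with no edges returns an empty
  similarity network with a warning; normalizing an empty adjacency is a
  domain error; an empty seed set is a domain error.
* The recovery experiment scores a held-out gene missing from the
  assembled network at the 100th percentile (the conservative choice); at
  the default `ds = 2` this is rare.

## Problem sizes used by the test suite

The suite verifies the propagation fixed point on 200 random graphs of up
to 50 nodes (three restart ratios, both normalizations, tolerance 1e−8
against a dense linear solve), Fisher combination on 1,000 random p-vectors
against numerical χ² tail integration (1e−10), projection and TFBS
derivation against brute-force loops (exact), and planted-module recovery
over 20 replicate fixtures per method. These sizes make the full suite run
in about a minute and a half while keeping every check statistically
meaningful.

## Known limitations

* Tie-breaking by lexicographic symbol is arbitrary (though deterministic);
  real pipelines may prefer distance-to-TSS or functional annotations.
* The disease-similarity construction (min-normalized shared counts) is one
  defensible choice among several; Jaccard or weight-aware variants would
  change PRINCE-style priors for diseases with very unequal gene sets.
* No liftover between genome builds, no statistical significance of
  projection overlaps (hypergeometric tests), and no head-to-head accuracy
  claims between the two prioritizers — the package exposes both and the
  recovery harness, and leaves the comparison to the user's data.
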