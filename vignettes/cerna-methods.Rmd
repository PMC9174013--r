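---
title: "Methods: ceRNA network inference in cernet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ceRNA network inference in cernet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernet)
```

## The model

`cernet` infers competing-endogenous-RNA regulation from three layers of
evidence: differential expression between tumor and matched normal tissue,
curated or predicted interaction pairs, and the sponge hypothesis itself.
The sponge hypothesis supplies the direction constraint that does the
statistical work: a circRNA that sequesters a miRNA should move opposite
to that miRNA, and the miRNA's mRNA targets should move opposite to the
miRNA again. A (circRNA, miRNA, mRNA) path is therefore accepted only in
the **up–down–up** or **down–up–down** configuration. Everything else —
co-expression, kinetics, binding-site affinity — is outside the model;
the network is a direction-consistent candidate set, not a causal claim.

## Differential expression

Expression is analyzed on the log2 scale (`log2_normalize()`, pseudocount
1.0 by default so that a raw value of 0 maps to 0). Per feature we compute
the log2 fold change (tumor − normal; for paired designs the mean of
within-pair differences) and the residual variance s² with df degrees of
freedom (pooled two-sample: df = n₁+n₂−2; paired: df = n−1).

Variance moderation follows the empirical-Bayes scheme standard in
microarray analysis. A scaled inverse-chi-square prior with hyperparameters
(d₀, s₀²) is fitted by moment-matching the distribution of z = log s²:

- d₀ solves trigamma(d₀/2) = var(z) − trigamma(df/2), a strictly
  decreasing one-dimensional equation solved by `uniroot` on a bracket
  grown geometrically from [10⁻⁶, 10¹²] (tolerance 10⁻¹⁰);
- s₀² = exp(mean(z) − digamma(df/2) + digamma(d₀/2) + log(df/d₀)).

When var(z) ≤ trigamma(df/2) the observed spread is explained by sampling
alone; we return d₀ = ∞ with s₀² = exp(mean(z) − digamma(df/2) +
log(df/2)), which is the continuous limit of the finite-d₀ expression and
keeps the estimator continuous at the boundary. The moderated statistic is
t = logFC / (s̃ · c) with s̃² = (d₀s₀² + df·s²)/(d₀ + df), c the
standard-error scale of the mean difference, and df + d₀ total degrees of
freedom (normal tail at d₀ = ∞). With d₀ = 0 this is exactly the
classical t, which the test suite verifies to 10⁻¹⁰, and the whole
pipeline agrees with the reference limma implementation on random data,
which the suite checks independently.

Features with zero residual variance cannot be tested without a prior;
they are excluded from the prior fit but **retained with a flag** and NA
statistics. Silent drops would corrupt downstream overlap counts.

Direction calls use strict inequalities: `up` iff logFC > cutoff **and**
BH-adjusted p < α; boundary values are `ns`. The default cutoff is 1.5
log2 units with α = 0.05; a cutoff of 0 gives the relaxed rule used for
the second circRNA dataset before intersection, mirroring the asymmetric
calling of the motivating study design (one dataset yields balanced
up/down calls, the other is down-skewed, and the relaxed rule prevents the
intersection from collapsing). `intersect_de()` keeps only sign-consistent
calls; a feature up in one dataset and down in the other is evidence of
inconsistency, not of differential expression, and is excluded from both
sets.

One ambiguity deserves note: the conventional miRNA screening criterion is
sometimes written as a threshold on |log2(RPM)|, an abundance unit rather
than a fold change. We read it as the same log2 fold-change threshold used
for mRNAs (1.5); an abundance filter would not define a two-group test.
Similarly, whether the original analyses used paired designs is unstated;
we default to paired for the small matched circRNA cohorts and unpaired
for the large unmatched tumor collections, configurable per study.

## Interaction catalogs and consensus

Pair tables carry one row per (source, target, database) attestation and
merge by unioning databases. Only circRNA→miRNA and miRNA→mRNA edges are
admitted. miRNA identifiers are case-folded and stripped of the species
prefix before matching, because published tables mix spellings (including
a frequent "has-" typo for "hsa-"), and an identifier mismatch silently
deletes a triad.

How multiple target-prediction databases should be combined is genuinely
open: union maximizes sensitivity, intersection precision. We default to
`min_databases = 1` (union) — the conservative reading of "mapped into
five databases to obtain pairs" — and expose the ≥ k consensus as a
parameter. `consensus_filter()` is nested in k, so raising the threshold
can only shrink the catalog.

## Triad assembly

`assemble_cerna()` performs the join-and-crosscheck in a single pass:
inner-join the two catalogs on the shared miRNA, attach the three
direction calls, keep paradigm-consistent rows, and collapse duplicates
arising from multi-database attestations. This is set-algebraically
identical to the two-pass construction (join against all miRNAs, then
crosscheck against the DE miRNAs) and the suite verifies equivalence
against a brute-force triple loop on catalogs of up to 50 features per
class. All outputs are ordered lexicographically (circRNA, miRNA, mRNA)
so exports diff stably. Networks export to GraphML (node attributes
`type`, `direction`; edge attribute `type_pair`) and to a triad TSV; both
round-trip exactly, because a direction-consistent network is fully
determined by its typed, direction-labelled edges.

The packaged subnetwork reference table prints 23 triad rows while its
distinct miRNA–mRNA edge count is 22; summaries elsewhere sometimes quote
the latter. The package reports what it computes — 23 re-assembled triads,
22 distinct miRNA–mRNA edges — and does not attempt to resolve the
discrepancy.

## Enrichment

Over-representation uses the exact hypergeometric upper tail (`phyper`,
no approximation), verified in the suite against exhaustive enumeration of
all draws for universes up to 12 genes. Screening keeps terms with **raw**
p < 0.05, matching common practice in this literature; the BH-adjusted p
is computed within each category and reported but not used for the
filter. Ranking is by ascending p with ties broken by larger overlap and
then term id; the top 15 per category are reported. The default universe
is every gene in the annotation collection — the choice is consequential
and configurable (e.g. to "all measured mRNAs"); a smaller universe
inflates significance.

## PPI hubs

Edges are undirected, deduplicated keeping the maximum confidence,
self-loops dropped, and filtered at confidence **strictly** greater than
0.4 (the "medium confidence" convention). Hub genes are ranked by plain
degree with a default minimum of 2; the published hub table's "Freq"
column is interpreted as interaction degree per its caption, and no other
centrality metric is attempted. The hub subnetwork keeps exactly the
triads whose mRNA is a hub.

## qPCR quantification

Relative expression uses 2^−ΔΔCt with within-tissue normalization to the
reference gene. Technical replicates are averaged on the Ct scale.
Patients missing either tissue are reported and excluded. The
tumor-vs-normal test is a **paired, two-sided** t on per-patient ΔCt
values — the standard practice; testing fold changes directly is possible
from the tidy per-patient output but ΔCt is closer to normal. Summary
fold changes are reported as mean ± SD of the per-patient 2^−ΔΔCt; note
that by Jensen's inequality this mean slightly exceeds 2^−mean(ΔΔCt)
under Ct noise.

## The synthetic-data generator

`generate_study()` emulates the data regimes the pipeline assumes:

- two circRNA datasets of `n_pairs_per_dataset = 5` matched tumor/normal
  pairs (the scale of small paired profiling cohorts), sharing planted
  truth but with independent noise, so the intersection step has real
  work;
- per-feature baselines Normal(8, 2) on the log2 scale (typical
  microarray/RNA-seq log-intensities), condition shifts of
  ±`effect_lfc` (default 2 log2 units) on a planted `frac_de = 10%` of
  features, a per-feature-per-pair effect Normal(0, 0.5·noise_sd) to make
  paired and unpaired analyses genuinely differ, and residual noise
  `noise_sd = 0.5`;
- `n_true_triads = 20` planted paradigm-consistent triads on disjoint
  features; true miRNA–mRNA pairs reported by each of
  `n_databases = 5` pseudo-databases independently with
  `db_detect_prob = 0.9`; direction-agnostic decoy pairs at
  `decoy_pair_rate = 2` per source feature so the direction filter is
  tested for specificity, not just sensitivity;
- a PPI clique of `ppi_clique_size = 6` on upregulated triad mRNAs at
  confidence 0.9 plus Uniform(0,1)-scored background edges
  (`ppi_background_edge_prob = 0.05`);
- annotation term sets (random plus planted) and a Ct table with 52
  patients encoding the planted circRNA fold change with 0.2-cycle
  measurement noise.

Identifiers are deterministic strings (`circ_0001`, `mir_0001`,
`gene_0001`) and the same seed reproduces the study exactly. What the
generator does **not** emulate: between-array normalization artifacts,
count-data mean–variance relationships, batch effects, correlated
features, miRNA seed-sequence biology, or realistic PPI topology. Passing
recovery tests therefore demonstrates the pipeline's correctness under
its own assumptions, not robustness to real-data pathologies.

## Problem sizes and numerical choices in the test suite

The suite runs at deliberately modest scale: feature counts of a few
hundred, oracle comparisons on catalogs of ≤ 50 features per class,
enumeration oracles for universes ≤ 12, prior-recovery simulation at
10,000 features, and the end-to-end recovery study at 10 pairs with 20
planted triads. For the recovery study we set the planted effect to 3
log2 units with noise SD 0.75 — the 4:1 effect-to-noise ratio that makes
recovery a property of the method rather than of sampling luck, with the
planted effect at twice the 1.5 call cutoff so that direction calls are
not borderline. Ties everywhere are broken deterministically
(lexicographic ids, larger overlap first in enrichment), and degenerate
inputs (zero-variance features, constant qPCR differences, empty
catalogs, infeasible triad plans) raise typed conditions rather than
producing NaN.

## Known limitations

- The network is assembled from direction consistency and catalog
  membership only; no expression-correlation weighting of edges.
- Enrichment assumes independent genes; term-graph redundancy is not
  trimmed.
- Only degree-based hub ranking is provided.
- No amplification-efficiency correction in the qPCR module.
- No between-array normalization or batch correction; inputs are assumed
  already normalized and log2-transformed.
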