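---
title: "Methods: junction-based PSI and cross-species variance partitioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction-based PSI and cross-species variance partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices, and numerical
conventions behind `altisplice`. The package quantifies cassette-exon
inclusion (PSI) from splice-junction reads, computes a simplified
expression measure, and partitions cross-sample variance over the factors
of a multi-species, multi-tissue, two-altitude design. A built-in
simulator generates every input the pipeline consumes.

## Read quality control

Three removal rules are applied in order, and a removed read is attributed
to the first rule it violates:

1. fraction of undetermined bases (N) **≥ 10%** (inclusive bound);
2. an ungapped alignment of the adapter against the read covering
   **m > 10** read bases with at most `floor(0.10 · m)` mismatches;
3. **strictly more than 50%** of bases with phred quality **< 5**.

Rule 2 scans every offset of the adapter against the read, allowing
overhangs on both sides. The practical consequence is that a short adapter
fragment qualifies only where a contiguous overlap of more than 10 bases
exists within the mismatch budget — adapter read-through at the 3′ end of
the read, or a fully contained adapter. Reads are removed, never trimmed,
so downstream stages always see fixed-length reads. The adapter sequence
is a required parameter: it is a property of the library preparation and
no universal default is safe.

## Junction construction and the 8-nt overlap guarantee

For every transcript, every internal exon A with neighbours C1 and C2
yields three junctions — C1A, AC2 (inclusion) and C1C2 (skipping). Each
side contributes its terminal `k − 8` nt (`k` = read length), or the whole
exon when shorter; junctions are read 5′→3′ in transcript orientation,
with minus-strand exon sequence reverse-complemented. With both parts at
full length, a junction has `L = 2(k − 8)` nt and `L − k + 1 = k − 15`
possible read placements, and any placement overlaps each exon by at least
8 nt — the design rationale for the `k − 8` retrieval rule. Identical
junction sequences are collapsed to one record that remembers all its
(triplet, type) members. `k ≥ 17` is enforced so both `k − 8 > 8` and
`k − 15 ≥ 2` hold.

## Mappability and count normalization

Junction read counts are comparable across junctions only after correcting
for how many of a junction's placements are actually usable. For each
junction, all `L − k + 1` k-mers are checked: a k-mer is *effective* iff

* it has no genomic alignment within 2 mismatches on either strand, and
* it occurs at exactly one position across the whole nonredundant junction
  set.

Counts are scaled by `(k − 15) / effective_positions`. The ceiling is
`k − 15` even for short-exon junctions whose own maximum is smaller; we
follow the formula as stated, which can up-scale such junctions beyond
their own placement count — a deliberate fidelity choice, flagged in the
docs. Junctions with zero effective positions make their triplet
*unquantifiable* (PSI undefined) rather than raising an error.

Two conventions were genuinely open:

* **Uniqueness matching.** The mismatch tolerance is attached to the
  *genome* pre-screen; junction-uniqueness is evaluated by exact matching
  on the forward junction sequences (junctions are transcript-oriented
  canonical sequences, whereas reads are strand-ambiguous against the
  genome). A mismatch-tolerant uniqueness mode is available behind
  `junction_mismatch = TRUE`.
* **Confidence-filter counts.** The alternative/high-confidence filters
  are evaluated on normalized counts by default (`use_normalized = FALSE`
  switches to raw), since normalization precedes PSI in the processing
  order.

## Alignment

The internal aligner is a pigeonhole seed-and-verify matcher: a read is
split into `max_mismatch + 1` parts, any placement within the budget must
match one part exactly, exact part hits are enumerated with a
constant-width dictionary index, and candidates are verified by direct
mismatch counting. It searches both genome strands; against junctions,
both the read and its reverse complement are tried, with exact matching.
A read is counted only when *exactly one* target placement exists within
budget — any co-optimal hit disqualifies it. This matcher is exhaustive by
construction and is cross-checked in the test suite against a brute-force
scan of every placement. Reads containing non-ACGT letters are treated as
unalignable (the dictionary index cannot hold them); QC removes N-rich
reads beforehand.

## Expression

FPKM is intentionally simple: a gene's count is the number of uniquely
genome-aligned reads lying fully inside the gene's exonic union plus the
uniquely junction-mapped reads attributable to that gene alone, and
`FPKM = count · 1e9 / (library_size · union_length)`. No isoform
deconvolution, no coverage model. The comparative layer consumes only
relative expression, for which this estimator's rank fidelity is tested on
simulation. Genes are analysed when FPKM exceeds 0.5 in strictly more than
80% of samples, as `log2(FPKM + 1)`.

## PSI

`PSI = 100 · a / (#C1C2 + a)` with `a = mean(#C1A, #AC2)` (arithmetic
mean; the conventional choice). PSI is undefined when the denominator is
zero. Alternative: `5 ≤ PSI ≤ 95`, both bounds inclusive. High confidence
requires `max(min(#C1A,#AC2), #C1C2) ≥ 5` and `min(#C1A,#AC2) + #C1C2 ≥ 10`,
plus balance (`|log2(#C1A/#AC2)| ≤ 1`) or skipping dominance
(`max(#C1A,#AC2) < #C1C2`). When an inclusion count is zero the log-ratio
clause is declared false and confidence rests on skipping dominance,
avoiding undefined arithmetic while preserving the clause's intent.
Fractional normalized counts are compared without rounding.

The cross-species matrix keeps exon groups that are single-copy in every
species (groups with multiple overlapping exon variants in any species are
excluded), have defined PSI in every sample, and are confidently
alternative (both flags) in at least one sample.

## Comparative layer

* **Correlations** are stratified by the design: altitude (same species
  and tissue), species (same tissue), tissue (same species). Spearman ties
  use average ranks.
* **Neighbor joining** is implemented in full (Q-criterion agglomeration);
  ties break at the first minimal pair in row-major order, and negative
  branch lengths are clamped to zero — correlation distances are not
  guaranteed additive. On additive matrices the implementation is exact,
  which the tests verify against an exhaustive least-squares fit over all
  topologies and against an independent NJ implementation.
* **Bootstrap** resamples features (genes/exons) with replacement,
  rebuilds the 1 − Spearman NJ tree, and supports each original
  bipartition by the fraction of replicates containing it. Degenerate
  replicates (a constant sample profile, undefined correlations) are
  skipped with the denominator adjusted. Support categories are `<50`,
  `50–70`, `70–90`, `>90`, left-closed, with exactly 90 in `70–90`.
* **Clustering** is average linkage on 1 − Pearson; **PCA** is on the
  feature-centered matrix without scaling.

## PVCA

Per retained principal component, scores are decomposed by a REML
random-intercept model with one term per factor (altitude, species,
tissue; pairwise interactions optional and off by default — with few
replicates per cell they are rarely estimable and fold into the residual).
Negative variance estimates are truncated at zero by construction.
Components are retained up to a cumulative variance threshold of 0.6
(configurable). Each retained component's factor proportions are weighted
by that component's share of the **total** variance, and the variance in
the discarded trailing components — unexplained by construction — is
credited to the residual before the final renormalization. The alternative
(normalizing weights within the retained set) provably drives the residual
share toward zero whenever the leading components are nearly pure factor
axes, as happens in clean low-rank data, and would make the reported
shares depend strongly on the retention threshold. With the chosen
weighting, a single factor simulated at three times the residual variance
is recovered at a share of about 0.75, as it should be. Factors with one
level get share zero; factors inducing identical sample partitions are
rejected as confounded.

## The simulator: what it emulates, and what it does not

The generator reproduces the study design shape: species pairs sharing
single-copy orthologous genes, six tissues × two altitudes × replicate
individuals (defaults 5 × 6 × 2 × 3 = 180 samples), with expression
variation dominated by tissue and splicing variation dominated by species.

* **Genomes.** One chromosome per species, derived from a common ancestor
  by independent per-site substitutions (star phylogeny, default 0.02 per
  branch). Exon/intron structure is drawn once for the ancestor and
  preserved, so exon orthology holds by construction. Genes alternate
  strands; default 5 exons of 90–240 nt separated by introns of 60–200 nt,
  with the middle exon designated as the cassette in half the genes
  (defaults 200 genes / 100 cassette exons — large enough for stable
  correlation and variance estimates, small enough for laptop-scale runs).
* **Truth.** log2 expression is `gene mean + tissue + species + altitude +
  noise`, with per-(gene, level) effects drawn at the configured variances
  (defaults 1.5/0.5/0.05/0.2); logit(PSI/100) likewise with
  species-dominant defaults (1.5/0.4/0.05/0.2). Additivity on these scales
  is a modelling choice made for interpretability and recoverability.
* **Reads.** Single-end, fixed length (default 76 nt), uniform start
  positions, per-base substitution errors (default 1e-3), constant phred
  35 (+33 encoding). Per gene and sample, read counts are Poisson with
  mean proportional to `2^expression`. For cassette genes the isoform of
  each read is drawn with probability equal to the *molar* PSI weighted by
  the isoform's number of read start positions — PSI is a fraction of
  transcripts, while uniform fragment sampling yields reads in proportion
  to length × molar abundance; ignoring the length weight would bias
  junction-ratio PSI estimates low by several units for mid-range PSI.
* **Determinism.** One master seed; per-stage and per-sample substreams
  are derived arithmetically from it, so identical designs give
  byte-identical FASTA/GTF/FASTQ outputs.

Not emulated: paired ends, GC and positional bias, indels (in sequencing
or evolution), multi-copy gene families, overlapping transcripts,
non-cassette event types, and expression-splicing coupling. Passing tests
on this generator therefore demonstrate correctness of the computation —
formulas, filters, uniqueness contracts, variance partitioning — not
robustness to every artefact of real libraries.

## Problem sizes and tolerances in the test suite

The suite runs everything at desk scale, chosen to keep a full run within
a few minutes while leaving no code path untested: oracle equivalence for
mappability on toy genomes of a few tens of kb with k ≤ 50 (exhaustive
enumeration is exact there); junction-count equivalence on 10,000
simulated reads; PSI accuracy at deep (≥ 100×) error-free junction
coverage with a ±2-unit tolerance on mean absolute error, the binomial
sampling bound at that depth; variance-structure recovery over 20 seeds of
a 2-species × 3-tissue × 2-altitude × 2-individual truth simulation with
200 genes, requiring the dominant factor to rank first and clustering to
match the dominant partition in at least 16 of 20 seeds. The
variance-recovery loop runs on the generator's truth matrices: the claim
under test is the statistical layer's recovery of variance structure,
while the read-level estimation path is exercised separately by the
counting-oracle, PSI-accuracy, and end-to-end pipeline tests.

## Known limitations

* The FPKM quantifier ignores coverage non-uniformity and multi-mapping
  structure; absolute values are not comparable to full-model quantifiers.
* Junctions whose short exons bound `L − k + 1 < k − 15` are up-scaled
  beyond their own placement count by the stated normalization.
* Reads containing N never align; at the default QC thresholds this only
  affects reads that would mostly be discarded anyway.
* PVCA shares for strongly non-dominant factors are conservative (close to
  zero) on clean low-rank data, because those factors barely enter the
  retained leading subspace.
* The pipeline's stage-skipping is a whole-run check (provenance hash),
  not per-stage freshness tracking.
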