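# altisplice

Comparative transcriptomics of multi-species, multi-tissue RNA-seq designs,
built around junction-based quantification of cassette-exon splicing.
The motivating setting is a panel of species pairs — a high-altitude
population and its low-altitude relative — sampled across several tissues,
where the questions are how much of the transcriptome's variation is
attributable to tissue, species, and altitude, and whether that answer
differs between gene *expression* and alternative *splicing*.

## What the package computes

**Splicing (PSI).** Every internal exon A of every transcript is treated as
a cassette exon flanked by C1 (upstream) and C2 (downstream). For read
length *k*, junction sequences are built by concatenating the terminal
*k* − 8 nt of each partner exon (the whole exon when shorter), so a mapped
read overlaps each exon by at least 8 nt. Reads that fail to align to the
genome (≤ 2 mismatches, both strands) are matched against the nonredundant
junction set; only reads hitting exactly one junction position are counted.
Counts are corrected for mappability: each junction's count is multiplied
by (*k* − 15) / *effective positions*, where the effective positions are
the junction's *L* − *k* + 1 k-mers that neither align to the genome within
2 mismatches nor occur anywhere else in the junction set. Percent spliced
in is then

    PSI = 100 · mean(#C1A, #AC2) / (#C1C2 + mean(#C1A, #AC2))

An exon is *alternative* in a sample if 5 ≤ PSI ≤ 95, and *high-confidence*
if `max(min(#C1A,#AC2), #C1C2) ≥ 5` and `min(#C1A,#AC2) + #C1C2 ≥ 10`, and
additionally `|log2(#C1A/#AC2)| ≤ 1` or `max(#C1A,#AC2) < #C1C2`. The
cross-species PSI matrix keeps exon groups with single-copy orthologues in
all species, defined PSI in all samples, and a confident alternative call
in at least one sample.

**Expression.** A deliberately simple union-exon FPKM from uniquely mapped
reads; genes with FPKM > 0.5 in more than 80% of samples are analysed as
log2(FPKM + 1).

**Comparative layer.** Pairwise correlations stratified by the design
(across altitudes, species, tissues); neighbor-joining trees on
1 − Spearman distances with gene bootstrap (100 resamples, support as the
fraction of replicate trees containing each bipartition); average-linkage
hierarchical clustering on 1 − Pearson; PCA; and principal variance
component analysis (PVCA: per retained principal component, a
random-effects decomposition of the scores into altitude, species, tissue
and residual variance, aggregated with eigenvalue weights).

**Simulator.** A deterministic generator of orthologous genomes (FASTA),
annotations (GTF), orthology tables, true expression/PSI matrices with
configurable variance components, and single-end FASTQ reads — so the
entire pipeline is testable end to end without any downloads.

## Worked example

```r
library(altisplice)

design <- simulation_design(
  n_species_pairs = 2, tissues = c("heart", "liver", "lung"),
  n_individuals = 2, n_genes = 150, n_cassette_exons = 75, seed = 42)

truth <- simulate_truth(design)
pvca(truth$expression, truth$samples)
#> <pvca_fit> 2 PC(s) retained (threshold 0.6)
#>   altitude   0.001
#>   species    0.009
#>   tissue     0.701
#>   residual   0.289

tidy(pvca(truth$psi, truth$samples))
#> # A tibble: 4 x 2
#>   factor   proportion
#> 1 altitude    0.00268
#> 2 species     0.584
#> 3 tissue      0.124
#> 4 residual    0.290

correlation_summary(pairwise_correlations(truth$expression, truth$samples))
#> # A tibble: 3 x 3
#>   comparison mean_r n_pairs
#> 1 altitude    0.946      24
#> 2 species     0.849      48
#> 3 tissue      0.618      96
```

Read this as the study's signature: expression variance is dominated by
tissue (PVCA tissue share 0.70; samples from the same tissue correlate far
better across species than samples from different tissues), while splicing
variance is dominated by species (PVCA species share 0.58). The
read-level path — `simulate_reads()`, `filter_reads()`,
`build_junction_catalog()`, `compute_effective_mappability()`,
`align_reads()`, `count_junction_reads()`, `normalize_counts()`,
`psi_table()`, `assemble_psi_matrix()`, `quantify_fpkm()` — is chained by
`run_pipeline(design, out_dir)`, which writes all stage outputs (TSV,
Newick, JSON provenance) under one directory, reproducibly for a given
seed.

See `vignettes/altisplice-methods.Rmd` for the model, parameter and design
discussion.

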