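# histocc

Genome-wide co-occupancy analysis of a chromatin protein with histone
marks, nucleosomes and DNA methylation — with spike-in (ChIP-Rx)
normalization, locus classification, permutation association testing,
multi-layer SOM clustering and a synthetic-data generator that plants
recoverable ground truth for every stage.

## Who this is for

Epigenomics analysts asking questions of the form *"does protein X
co-occupy chromatin with mark Y, and does its binding follow that mark
when the mark is perturbed?"* — the analysis pattern behind studies of
MeCP2/H3K27me3 co-occupancy, but applicable to any protein/mark pair.
The package consumes plain-text genomics formats (BED, bedGraph,
TSV) and stays upstream-agnostic: alignment, peak calling and nucleosome
calling happen elsewhere.

## What is implemented

| Stage | Functions |
|---|---|
| Genome model & I/O | `genome_layout`, `region_set`, `read_regions`, `read_bedgraph`, `coverage_track`, `overlap_pairs`, `merge_overlapping` |
| Normalization & profiles | `rpm_factor`, `rrpm_factor`, `scale_track`, `input_normalize`, `z_transform`, `binned_correlation`, `aggregate_profile`, `region_mean`, `derive_gene_regions` |
| Occupancy classification | `classify_occupancy`, `overlap_percentages`, `sample_loci`, `locus_methylation`, `compare_groups` |
| Differential enrichment | `difference_classes`, `paired_difference_test`, `compare_region_sets`, `window_dmrs`, `select_de_genes` |
| Clustering & association | `build_signal_matrix`, `supersom_cluster`, `cluster_expression`, `gsea_score`, `region_association_z`, `derive_enhancers` |
| Synthetic data | `sim_config`, `simulate_occupancy`, `simulate_tracks`, `simulate_spikein_experiment`, `simulate_methylation`, `simulate_genes_expression`, `write_simulation` |

The statistical core, in standard notation:

* **RPM**: scale factor `1e6 / N` with `N` the target-genome mapped reads.
  **RRPM** (reference-adjusted RPM, for ChIP-Rx): `1e6 / Nx` with `Nx`
  the reads mapped to the exogenous spike-in genome — this preserves
  genuine genome-wide enrichment shifts that RPM cancels.
* **Occupancy groups**: nucleosome loci without (group1) / with (group2)
  an overlapping protein peak, and nucleosome-free protein peaks
  (group3); a half-open, 0-based interval model throughout.
* **Rank tests**: Mann-Whitney U and Wilcoxon signed-rank, exact by
  enumeration at small n, tie-corrected normal approximation otherwise.
* **SuperSOM**: an online self-organizing map trained jointly on several
  mark layers (shared best-matching unit; distance = sum of per-layer
  squared Euclidean distances), codebook units merged to k clusters by
  Ward linkage.
* **GSEA**: weighted Kolmogorov-Smirnov-style running sum; ES = signed
  maximum deviation; NES and p from gene-label permutation.
* **Permutation z**: observed annotation overlap vs uniform
  within-chromosome re-placement of query intervals,
  `z = (obs - mean(null)) / sd(null)`.

## Worked example

Simulate a study-shaped dataset with planted truth, classify occupancy,
and recover the planted structure:

```r
library(histocc)

cfg   <- sim_config(seed = 42)          # 2 x 5 Mb toy genome, 200 bp bins
truth <- simulate_occupancy(cfg)        # plants 31% shared / 44% free peaks

groups <- classify_occupancy(truth$nucleosomes, truth$mecp2_peaks)
overlap_percentages(groups$summary)
#>   pct_a_only pct_a_shared   pct_b_only
#>           69           31           44

sim <- simulate_tracks(cfg)             # plants count-level r = 0.74 / 0.27
binned_correlation(sim$tracks)
#> <correlation_matrix> 50000 bins of 200 bp
#>          MeCP2 H3K27me3 H3K9ac
#> MeCP2    1.000    0.738  0.269
#> H3K27me3 0.738    1.000  0.195
#> H3K9ac   0.269    0.195  1.000

meth <- simulate_methylation(cfg, truth)
cpg  <- lapply(meth$loci, function(l) locus_methylation(meth$table, l, "CpG"))
round(sapply(cpg, median, na.rm = TRUE), 1)
#> group1 group2 group3
#>   50.5   76.1   74.7
compare_groups(lapply(cpg, function(v) v[!is.na(v)]))[, c("group_a", "group_b", "p_adjusted")]
#>   group_a group_b    p_adjusted
#> 1  group1  group2 4.470435e-306
#> 2  group1  group3 6.299757e-300
#> 3  group2  group3  9.048673e-06
```

Reading the output: 31% of planted nucleosomes are protein-occupied and
44% of peaks are nucleosome-free (the planted Venn structure, recovered
exactly); the genome-wide binned Pearson correlation between the protein
and the repressive mark comes back at 0.738 against a planted 0.74; and
protein-bound locus groups (group2/group3) are far more CpG-methylated
than unbound nucleosomes (medians ~76%/75% vs ~50%), with Bonferroni-
corrected Mann-Whitney p-values resolving all three pairs.

## Documentation

The methods vignette (`vignettes/chromatin-cooccupancy.Rmd`) describes
the model and its assumptions, every tunable parameter with units and
defaults, what the synthetic-data generator does and does not emulate,
and the numerical choices (tolerances, tie-breaking, degenerate inputs).
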