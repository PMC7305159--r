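---
title: "Methods: chromatin co-occupancy analysis with spike-in normalization"
author: "histocc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin co-occupancy analysis with spike-in normalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histocc)
```

# The scientific problem

A recurring question in regulatory genomics is whether a chromatin protein
(here the running example is MeCP2, a methyl-CpG-binding protein central to
Rett syndrome) co-occupies the genome with particular nucleosomal features:
nucleosome positions mapped by MNase-seq, repressive (H3K27me3) and active
(H3K9ac) histone modifications, DNA methylation in CpG and non-CpG (CAG,
CAH) contexts, and regulatory elements such as enhancers. Answering it from
sequencing data requires a chain of quantitative steps, each with
well-known pitfalls:

1. **Normalization.** Reads-per-million (RPM) scaling makes libraries of
   different depth comparable but, by construction, erases genuine
   genome-wide shifts in total enrichment — exactly the signal of interest
   when a treatment (e.g. an EZH2 inhibitor) globally depletes a mark.
   Spike-in (ChIP-Rx) designs add exogenous chromatin at a fixed cell
   ratio; scaling by reads mapped to the exogenous genome
   (reference-adjusted RPM, RRPM) preserves global shifts.
2. **Co-occupancy classification.** Counting which nucleosome loci carry
   protein peaks (and which peaks sit in nucleosome-free sequence)
   partitions the genome into interpretable locus classes.
3. **Comparative statistics.** Rank tests (Mann-Whitney, Wilcoxon
   signed-rank) on per-locus summaries, permutation tests for
   region-annotation association, and enrichment scores for expression
   changes.
4. **Pattern discovery.** Multi-layer self-organizing maps (SuperSOM) to
   cluster genes by the joint spatial pattern of several marks around the
   TSS.

`histocc` implements this chain end-to-end with a synthetic-data generator
that *plants* known truth at every stage, so each analysis step is
verifiable by recovery rather than by inspection.

# Data model and coordinate conventions

All coordinates are **0-based, half-open** (`[start, end)`), i.e. native
BED semantics; any 1-based display would be formatting only. Two intervals
that merely touch (`end == start`) do **not** overlap. Unknown chromosomes
in any input are an error, never silently dropped: a chromosome-name
mismatch (genome-build confusion) is the most common silent failure in
this class of pipeline and must surface immediately.

Signal lives in `binned_track` objects: one value per fixed-width bin per
chromosome. The terminal partial bin stores the mean over its covered
bases only, so edge bins are not systematically deflated in correlations.
Fragment coverage (`coverage_track`) extends reads 3'-ward to a fixed
fragment length (e.g. 200 bp for sonicated ChIP fragments, 146 bp cap for
MNase fragments), clips at chromosome ends, and conserves total fragment
bases.

Interval overlap queries are delegated to the IRanges interval engine;
the package's own tests verify it against brute-force all-pairs scans on
hundreds of random instances.

# Normalization

For a library with `N` mapped target-genome reads, the RPM factor is
`1e6 / N`. For a ChIP-Rx library with `Nx` reads mapped to the exogenous
genome, the RRPM factor is `1e6 / Nx` — the target-genome count plays no
role, which is the entire point: if a treatment halves the genome-wide
mark level, target reads halve but spike-in recovery does not, so RRPM
tracks preserve the 2-fold loss that RPM tracks cancel.

Z-transformation of profile curves uses the **population** SD (dividing by
`n`, not `n - 1`) so the transform is an exact idempotent standardization;
constant input returns zeros with a warning rather than NaN.

Genome-wide correlation (`binned_correlation`) mean-aggregates tracks to a
common bin size and computes Pearson correlations over all bins. By
default *all* bins are used; the published analyses this emulates do not
state a bin filter, so filtering (`drop_all_zero`) is opt-in.

Where a figure is described as "input normalized" without a formula, the
package takes the ratio interpretation:
`log2((IP + 1) / (input + 1))` (`input_normalize`). A ratio is
scale-equivariant under the normalization factors applied upstream, which
a subtraction is not; this is an interpretation, and it is flagged as such
here.

# Occupancy classification and methylation comparison

`classify_occupancy` partitions loci into the three canonical groups:
nucleosome-only (group1), nucleosome co-occupied by a protein peak
(group2), and nucleosome-free protein peaks (group3). Decisions taken
where the source analyses are silent:

* The nucleosome-side overlap gate defaults to `min_overlap_bp = 1` (any
  overlap) and is exposed as a parameter, since the original intersection
  rule is unstated.
* A protein peak that overlaps *any* nucleosome is excluded from group3
  even if it also spans nucleosome-free sequence: classification is at
  the peak level, which is what a Venn of peak counts implies.
* Per-locus methylation (`locus_methylation`) is **coverage-weighted**
  (pooled methylated reads over pooled total reads of all covered sites
  in the locus) rather than a mean of per-site levels; with uneven
  bisulfite coverage the pooled estimator has lower variance. Loci
  without covered sites are `NA` and excluded from statistics.

Group comparisons use a two-tailed Mann-Whitney U test with Bonferroni
correction. For per-group sizes up to 8 the null distribution of U is
enumerated exhaustively over all group assignments of the pooled values
(ties handled exactly); beyond that the tie-corrected normal
approximation with continuity correction is used, appropriate for the
10^4-scale locus samples this pipeline feeds it. The paired analyses use
the Wilcoxon signed-rank test with the same exact/approximate split at 15
non-zero pairs; zero differences are dropped, and an all-zero input is
defined as `p = 1` with a warning.

Reported percentages are rounded half-to-even at the requested number of
decimals. (One published figure, 68.9%, is consistent with truncation of
68.965 rather than rounding; the package does not chase that formatting
artifact.)

# Differential enrichment

`difference_classes` computes, per locus, the mean of the two normalized
tracks and their difference `delta = treated - control`, then labels loci
`severe` (`delta <= t_severe`), `moderate` (`t_severe < delta <=
t_moderate`) or `unchanged`. The source analyses never print their
thresholds, so:

* fixed defaults are `t_moderate = -1`, `t_severe = -3` in normalized
  signal units, on the scale where typical RRPM bin values are O(1)
  (see the generator's scale choice below);
* a quantile mode derives thresholds from the observed delta
  distribution, defaulting to the lowest 0.2% (severe) and next 4.7%
  (moderate) — the proportions implied by the published class sizes
  (691 / 16,434 / 333,212);
* classes are depletion-only by default because the motivating design is
  an inhibitor experiment in which every non-unchanged class is a loss; a
  symmetric `gain` mode classifies `|delta|` instead.

The windowed DMR caller is declared plumbing: the upstream publication
reports a DMR count but not a method, so `window_dmrs` implements a
transparent tiled-window rule (window 500 bp, >= 3 CpG sites with
coverage >= 4 in both samples, absolute level difference >= 0.25,
adjacent candidate windows merged) and makes no claim of reproducing any
published DMR count.

DE-gene selection applies strict inequalities (`fdr < 0.05`,
`|fold change| > 1.3` by default) to a signed-fold-change table, the
thresholds used by the expression analyses this feeds.

# Clustering and association

`build_signal_matrix` samples each mark track at fixed strand-aware
offsets (default -1 kb .. +5 kb, the published window) around every TSS;
minus-strand windows are flipped so positive offsets always run into the
gene body. Each layer is z-scaled globally (one mean/SD per layer). The
source does not state whether its layers were scaled; scaling was chosen
because without it the layer with the largest dynamic range silently
dominates the joint distance.

`supersom_cluster` trains a single online SOM jointly over all layers:
the best-matching unit minimizes the *sum* of per-layer squared
Euclidean distances (equal layer weights), and all layers update
together. Defaults: 6 x 6 hexagonal grid, 100 epochs, learning rate
decaying linearly 0.05 to 0.01, Gaussian neighborhood with radius
decaying from half the grid diameter to 1. No hyperparameters were
published for the clustering this emulates; these are conventional SOM
settings and all are exposed. Trained units are merged into `k` clusters
(default `k = 3`, the published cluster count) by Ward agglomeration on
the concatenated codebooks. The presentation order and initialization are
drawn from the caller's seed and the C++ core is order-deterministic, so
identical seed and data give identical assignments on any platform.
Cluster ids are relabeled in decreasing order of mean member signal to
make labels themselves reproducible.

`gsea_score` implements the classical weighted running-sum enrichment
statistic (hit increments proportional to `|stat|^p` normalized to 1,
miss decrement `1/(N - Nh)`, ES = signed maximum deviation), with ties in
the ranking broken by gene id so the ranking is a total order. The null
is **gene-label permutation** (random sets of the same size), not
phenotype permutation: with three replicates per genotype, phenotype
permutation admits only 10 distinct relabelings and is degenerate. NES
divides ES by the mean |ES| of same-sign null scores, and the p-value is
the add-one-smoothed same-sign exceedance fraction. When the gene set
spans the whole ranking the miss term vanishes and ES is 1 by convention.

`region_association_z` measures how many query intervals overlap an
annotation and compares against a null in which every query interval is
re-placed uniformly at random **on its own chromosome**, lengths
preserved, placed intervals allowed to overlap each other. This simple
randomization (as opposed to mask- or gap-aware schemes) was chosen
because it is exactly the scheme under which the generator's null is
calibrated; masks would be a future extension. Enhancers are derived as
DHS intervals overlapping both H3K4me1 and H3K27ac intervals, with
midpoints exposed for +/- 3 kb profiling.

# What the synthetic-data generator emulates

The generator reproduces the *statistical structure* of the motivating
study's deposited data so that every analysis stage has recoverable
truth:

* **Toy genome**: 2 chromosomes x 5 Mb, 200 bp bins = 50,000 bins
  genome-wide. This matches the published binning range (150-1,000 bp)
  while keeping every test under a minute.
* **Correlated mark intensities**: per-bin log-intensities are a latent
  Gaussian field; counts are Poisson draws of the exponentiated field
  (a log-normal/Poisson copula), preserving non-negativity and
  overdispersion. The latent correlation is calibrated in closed form so
  that the **planted value is the expected Pearson correlation of the
  counts**: first invert the log-normal moment identity
  `corr(intensity) = (exp(rho * sigma^2) - 1) / (exp(sigma^2) - 1)`,
  then divide out each track's Poisson attenuation
  `sqrt(Var(lambda) / (Var(lambda) + E[lambda]))`. Defaults plant the
  published genome-wide correlations (protein vs repressive mark 0.74,
  vs acetylation 0.27).
* **Occupancy truth**: 147 bp nucleosomes and 150-600 bp peaks are
  placed on a fixed slot pitch so nothing collides by accident; 31.0% of
  nucleosomes receive an overlapping peak and nucleosome-free peaks are
  added to make up 44% of all peaks — the published Venn percentages —
  so classification recovery is exact by construction up to rounding.
* **Spike-in design**: treated intensity is the control field times a
  global factor before Poisson sampling; spike-in reads are drawn
  independently of that factor. The default spike-in depth (2e7) is
  deliberately larger than the target depth (2e6) so RRPM bin values are
  O(1) — the scale on which the fixed difference-class thresholds are
  meaningful. Spike-in reads are simulated as a scalar count, not a
  second genome, because the RRPM formula consumes only the count.
* **Methylation**: per-site levels are Beta draws parameterized per
  (group, context) with counts Binomial(coverage, level), coverage >= 1
  enforced; CpG sites are denser than CAG/CAH. Group means (CpG
  0.50 / 0.762 / 0.739; non-CpG near zero) are the published group
  medians.
* **Genes and expression**: genes on a 14 kb pitch receive one of three
  planted TSS-proximal template profiles (broad protein+repressive body
  signal; the same plus a TSS acetylation peak; all-TSS-confined), in
  the published cluster proportions, with expression medians (log10 RPKM
  0.26 / 0.97 / 1.11) taken from the published cluster summaries.
  Knockout replicates up-shift a planted per-cluster gene fraction
  2-fold. Replicate noise defaults to 0.02 log10 units — a deliberately
  clean testbed in which threshold-based DE selection should recover
  planted shifts almost perfectly, so that failures indicate pipeline
  defects rather than power limits.

**What it does not emulate** (and what passing tests therefore cannot
show about real data): mappability and GC bias, read-level artifacts
(duplicates, multi-mappers), realistic peak-width/depth distributions
(none were published), chromatin input structure, linkage between
methylation and mark intensity beyond group labels, and biological
replicate variability beyond simple log-normal noise. Published
NES values for the knockout expression analyses are not reproduction
targets: they depend on the deposited expression data, which the package
does not ship.

# Numerical choices

* Rank tests switch from exact enumeration to tie-corrected normal
  approximation at n = 8 (Mann-Whitney, per group) and n = 15 (signed
  rank); both regimes are exhaustively verified against independent
  enumeration oracles in the test suite.
* Two-tailed exact p-values are `2 * min(P(T <= t), P(T >= t))` capped
  at 1, with a 1e-9 tolerance when comparing tied rank sums.
* The SOM neighborhood update skips units with Gaussian weight below
  1e-7; with the default learning rates this is far below any update
  that could change a best-matching unit.
* Percentages round half-to-even (R's `round`); pseudocounts default to
  1 for log2 ratios of count tracks.
* Empirical permutation p-values use add-one smoothing,
  `(1 + exceedances) / (1 + permutations)`.

# Problem sizes used by the tests

The test suite and the acceptance script run entirely on generated data:
50,000-bin genomes for normalization and correlation recovery; 4,000
nucleosomes / ~2,200 peaks for classification; 1,000 loci per group for
methylation; 1,500 genes for SOM and DE recovery; 200 replicate datasets
of 100 query vs 200 annotation intervals at 150 permutations each for
permutation-z calibration; 100 repeats of 1,000 permutations for GSEA
null calibration. These sizes were chosen so each stage's recovery
tolerance (for example +/- 0.05 on a planted correlation at 50,000 bins,
or +/- 2 percentage points on planted overlap fractions) is several
standard errors wide under the generator's randomness.

# Known limitations

* No BAM/bigWig I/O: the package consumes BED, bedGraph and TSV, the
  plain-text interchange formats; alignment and peak calling are
  upstream concerns.
* The DMR caller is a transparent stand-in, not a published method.
* The permutation null ignores mappability masks.
* SOM results depend on the seed through initialization and presentation
  order; determinism is guaranteed per seed, global optimality is not.
* The toy genome uses equal-length chromosomes; nothing in the code
  requires this, but the generator does not exercise unequal layouts.
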