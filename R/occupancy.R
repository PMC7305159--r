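#' Three-way nucleosome / binding-protein occupancy classification
#'
#' Partitions nucleosome calls and protein binding peaks into the three
#' classical co-occupancy groups:
#' \describe{
#'   \item{group1}{nucleosome loci with no protein peak overlap.}
#'   \item{group2}{nucleosome loci overlapping at least one protein peak by
#'     `>= min_overlap_bp`.}
#'   \item{group3}{protein peaks overlapping no nucleosome locus at all
#'     (nucleosome-free binding). A peak with any nucleosome overlap is
#'     excluded from group3 even if it also spans nucleosome-free sequence:
#'     classification is at the peak level, matching a Venn of peak counts.}
#' }
#' groups 1 and 2 always partition the nucleosome set.
#'
#' @param nucleosomes a `region_set` of nucleosome calls.
#' @param mecp2 a `region_set` of protein (e.g. MeCP2) binding peaks.
#' @param min_overlap_bp minimum overlap (bp, >= 1) for a nucleosome to
#'   count as protein-occupied.
#' @return An object of class `occupancy_groups` with fields `group1`,
#'   `group2`, `group3` (region_sets) and `summary` (an `overlap_summary`).
#' @export
classify_occupancy <- function(nucleosomes, mecp2, min_overlap_bp = 1) {
  if (min_overlap_bp < 1) stop("min_overlap_bp must be >= 1")
  if (!nrow(nucleosomes) && !nrow(mecp2))
    stop("both input sets are empty")
  hits <- overlap_pairs(nucleosomes, mecp2)
  hits <- hits[hits$overlap_bp >= min_overlap_bp, , drop = FALSE]
  occupied <- unique(hits$a_idx)
  # group3 uses ANY overlap (>= 1 bp), not the min_overlap_bp gate: a peak
  # touching a nucleosome is not nucleosome-free
  any_hits <- overlap_pairs(mecp2, nucleosomes)
  free_peaks <- setdiff(seq_len(nrow(mecp2)), unique(any_hits$a_idx))
  g1 <- region_subset(nucleosomes, setdiff(seq_len(nrow(nucleosomes)),
                                           occupied))
  g2 <- region_subset(nucleosomes, sort(occupied))
  g3 <- region_subset(mecp2, sort(free_peaks))
  summary <- overlap_summary(
    n_a = nrow(nucleosomes), n_b = nrow(mecp2),
    n_a_shared = length(occupied), n_b_only = length(free_peaks))
  structure(list(group1 = set_label(g1, "group1"),
                 group2 = set_label(g2, "group2"),
                 group3 = set_label(g3, "group3"),
                 summary = summary, min_overlap_bp = min_overlap_bp),
            class = "occupancy_groups")
}

#' @export
print.occupancy_groups <- function(x, ...) {
  s <- x$summary
  cat("<occupancy_groups>\n",
      "  group1 (nucleosome only):   ", nrow(x$group1), "\n",
      "  group2 (shared):            ", nrow(x$group2), "\n",
      "  group3 (peak only):         ", nrow(x$group3), "\n",
      "  of ", s$n_a, " nucleosomes / ", s$n_b, " peaks\n", sep = "")
  invisible(x)
}

#' Overlap summary between two region sets
#'
#' Plain count container backing Venn-style comparisons.
#'
#' @param n_a,n_b total interval counts of the two sets.
#' @param n_a_shared `a` intervals overlapping at least one `b` interval.
#' @param n_b_only `b` intervals overlapping no `a` interval.
#' @return An object of class `overlap_summary` with the additional derived
#'   field `n_a_only = n_a - n_a_shared`.
#' @export
overlap_summary <- function(n_a, n_b, n_a_shared, n_b_only) {
  if (n_a_shared > n_a || n_b_only > n_b) stop("inconsistent counts")
  structure(list(n_a = n_a, n_b = n_b, n_a_only = n_a - n_a_shared,
                 n_a_shared = n_a_shared, n_b_only = n_b_only),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("<overlap_summary> a: ", x$n_a, " (", x$n_a_only, " only, ",
      x$n_a_shared, " shared); b: ", x$n_b, " (", x$n_b_only, " only)\n",
      sep = "")
  invisible(x)
}

#' Venn percentages from an overlap summary
#'
#' Converts the counts of an [overlap_summary()] into the percentages
#' conventionally printed next to Venn diagrams, rounded half-to-even.
#'
#' @param s an `overlap_summary`.
#' @param decimals decimal places to round to (default 1).
#' @return Named numeric vector with `pct_a_only`, `pct_a_shared`
#'   (percentages of `n_a`) and `pct_b_only` (percentage of `n_b`).
#' @examples
#' s <- overlap_summary(n_a = 7672, n_b = 4257, n_a_shared = 2382,
#'                      n_b_only = 1876)
#' overlap_percentages(s) # pct_a_shared = 31.0
#' @export
overlap_percentages <- function(s, decimals = 1) {
  if (!inherits(s, "overlap_summary")) stop("s must be an overlap_summary")
  if (s$n_a <= 0 || s$n_b <= 0) stop("zero denominator")
  c(pct_a_only = round(100 * s$n_a_only / s$n_a, decimals),
    pct_a_shared = round(100 * s$n_a_shared / s$n_a, decimals),
    pct_b_only = round(100 * s$n_b_only / s$n_b, decimals))
}

#' Random subsample of loci
#'
#' Uniform sampling without replacement, deterministic under the given
#' seed; the caller's RNG stream is left untouched.
#'
#' @param rs a `region_set`.
#' @param n number of loci to draw.
#' @param seed RNG seed (required).
#' @param allow_all if `TRUE`, `n > nrow(rs)` returns the whole set instead
#'   of erroring.
#' @return A `region_set` of `n` loci.
#' @export
sample_loci <- function(rs, n, seed, allow_all = FALSE) {
  if (n > nrow(rs)) {
    if (!allow_all) stop("requested ", n, " loci from a set of ", nrow(rs))
    n <- nrow(rs)
  }
  idx <- with_seed(seed, sample.int(nrow(rs), n))
  region_subset(rs, idx)
}

#' Per-locus methylation percentage
#'
#' For each locus, pools the methylated and total read counts of all
#' covered cytosines of the requested context inside the locus
#' (coverage-weighted aggregation) and reports
#' `100 * sum(methylated) / sum(total)`. Loci containing no covered site of
#' that context get `NA` and are meant to be excluded from downstream
#' statistics.
#'
#' @param mt a `methylation_table`.
#' @param loci a `region_set`.
#' @param context one of `"CpG"`, `"CAG"`, `"CAH"`.
#' @return Numeric vector of per-locus methylation percentages (0-100),
#'   `NA` where no site is covered.
#' @export
locus_methylation <- function(mt, loci, context = c("CpG", "CAG", "CAH")) {
  context <- match.arg(context)
  mt <- mt[mt$context == context, , drop = FALSE]
  meth <- numeric(nrow(loci)); tot <- numeric(nrow(loci))
  for (ch in unique(loci$chrom)) {
    li <- which(loci$chrom == ch)
    si <- which(mt$chrom == ch)
    if (!length(si)) next
    ir_loci <- IRanges::IRanges(loci$start[li] + 1, loci$end[li])
    ir_sites <- IRanges::IRanges(mt$pos[si] + 1, width = 1)
    hits <- IRanges::findOverlaps(ir_sites, ir_loci)
    if (!length(hits)) next
    sh <- si[S4Vectors::queryHits(hits)]
    lh <- li[S4Vectors::subjectHits(hits)]
    meth[li] <- meth[li] +
      as.numeric(tapply(mt$methylated[sh], factor(lh, levels = li), sum,
                        default = 0))
    tot[li] <- tot[li] +
      as.numeric(tapply(mt$total[sh], factor(lh, levels = li), sum,
                        default = 0))
  }
  ifelse(tot > 0, 100 * meth / tot, NA_real_)
}
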