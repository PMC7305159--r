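#' Permutation z-score for region-annotation association
#'
#' Tests whether a query region set overlaps an annotation more often than
#' expected by chance. The observed statistic is the number of query
#' intervals overlapping the annotation by at least 1 bp. Each permutation
#' re-places every query interval uniformly at random on its own
#' chromosome (lengths preserved; placed intervals may overlap each
#' other), and the overlap count is recomputed. The z-score is
#' `(observed - mean(null)) / sd(null)`; the empirical p-value is the
#' add-one-smoothed fraction of permutations with at least the observed
#' overlap (enrichment direction).
#'
#' @param query,annotation `region_set`s on `layout`; the annotation must
#'   be non-empty.
#' @param layout a `genome_layout`.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed (required).
#' @return An object of class `permutation_result` with
#'   `observed_overlap`, `perm_mean`, `perm_sd`, `z`, `p_empirical`,
#'   `n_perm`, `seed`.
#' @export
region_association_z <- function(query, annotation, layout, n_perm = 1000,
                                 seed) {
  check_layout(layout)
  if (!nrow(annotation)) stop("annotation is empty")
  if (n_perm < 100) stop("n_perm must be >= 100")
  validate_region_df(query, layout)
  validate_region_df(annotation, layout)
  ann <- merge_overlapping(annotation, gap = 0)
  ann_idx <- lapply(split(seq_len(nrow(ann)), ann$chrom), function(i)
    list(starts = ann$start[i], ends = ann$end[i]))
  q_by_chrom <- split(data.frame(start = query$start,
                                 len = query$end - query$start),
                      query$chrom)
  count_overlap <- function(starts_by_chrom) {
    total <- 0L
    for (ch in names(starts_by_chrom)) {
      a <- ann_idx[[ch]]
      if (is.null(a)) next
      s <- starts_by_chrom[[ch]]$start
      e <- s + starts_by_chrom[[ch]]$len
      i <- findInterval(s, a$starts)
      hit <- (i >= 1 & a$ends[pmax(i, 1)] > s) |
        (i < length(a$starts) & a$starts[pmin(i + 1, length(a$starts))] < e)
      total <- total + sum(hit)
    }
    total
  }
  observed <- count_overlap(q_by_chrom)
  max_start <- lapply(names(q_by_chrom), function(ch)
    chrom_length(layout, ch) - q_by_chrom[[ch]]$len)
  names(max_start) <- names(q_by_chrom)
  null_counts <- with_seed(seed, vapply(seq_len(n_perm), function(p) {
    placed <- lapply(names(q_by_chrom), function(ch) {
      m <- max_start[[ch]]
      data.frame(start = floor(stats::runif(length(m), 0, m + 1)),
                 len = q_by_chrom[[ch]]$len)
    })
    names(placed) <- names(q_by_chrom)
    count_overlap(placed)
  }, 1.0))
  mu <- mean(null_counts)
  sdv <- stats::sd(null_counts)
  structure(list(observed_overlap = observed, perm_mean = mu,
                 perm_sd = sdv,
                 z = if (sdv > 0) (observed - mu) / sdv else NA_real_,
                 p_empirical = (1 + sum(null_counts >= observed)) /
                   (1 + n_perm),
                 n_perm = n_perm, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result> observed = ", x$observed_overlap,
      ", null = ", signif(x$perm_mean, 4), " +/- ", signif(x$perm_sd, 4),
      ", z = ", signif(x$z, 4), ", p = ", signif(x$p_empirical, 4), "\n",
      sep = "")
  invisible(x)
}

#' Derive enhancer loci by three-way co-enrichment
#'
#' Enhancers are defined as DNase I hypersensitive sites co-enriched with
#' both H3K4me1 and H3K27ac: every DHS interval overlapping (by >= 1 bp)
#' at least one interval of each mark is retained. Midpoints for
#' profiling are available through [region_midpoints()].
#'
#' @param dhs,h3k4me1,h3k27ac `region_set`s on the same genome.
#' @return A `region_set` of qualifying DHS intervals, labelled
#'   `"enhancers"`.
#' @export
derive_enhancers <- function(dhs, h3k4me1, h3k27ac) {
  if (!nrow(dhs)) return(set_label(dhs, "enhancers"))
  in_k4 <- unique(overlap_pairs(dhs, h3k4me1)$a_idx)
  in_k27 <- unique(overlap_pairs(dhs, h3k27ac)$a_idx)
  set_label(region_subset(dhs, sort(intersect(in_k4, in_k27))), "enhancers")
}

#' Midpoint anchors of a region set
#'
#' Integer midpoints suitable as `anchors` for [aggregate_profile()]
#' (e.g. enhancer midpoints profiled +/- 3 kb).
#'
#' @param rs a `region_set`.
#' @return A data frame with columns `chrom`, `pos`, `strand`.
#' @export
region_midpoints <- function(rs) {
  data.frame(chrom = rs$chrom,
             pos = floor((rs$start + rs$end) / 2),
             strand = rs$strand,
             stringsAsFactors = FALSE)
}
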