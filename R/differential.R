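#' Classify loci by between-condition enrichment difference
#'
#' For each locus computes the mean signal of the two (spike-in normalized)
#' tracks and the difference `delta = treated - control`, then assigns one
#' of three depletion classes: `severe` when `delta <= t_severe`,
#' `moderate` when `t_severe < delta <= t_moderate`, else `unchanged`.
#' Thresholds can be given directly (`mode = "fixed"`) or derived from the
#' observed delta distribution (`mode = "quantile"`: severe = lowest
#' `q_severe` fraction, moderate = next fraction up to `q_moderate`).
#' A symmetric gain mode (`gain = TRUE`) classifies `|delta|` instead, for
#' designs where enrichment may move in either direction.
#'
#' @param control,treated `binned_track`s on the same layout, already
#'   normalized to comparable units (e.g. RRPM).
#' @param loci a `region_set` of loci to classify.
#' @param t_moderate,t_severe depletion thresholds (negative,
#'   `t_severe < t_moderate < 0`) used when `mode = "fixed"`.
#' @param mode `"fixed"` or `"quantile"`.
#' @param q_severe,q_moderate lower-tail fractions for quantile mode
#'   (defaults 0.002 and 0.049).
#' @param gain classify on `-|delta|` so both gains and losses leave
#'   `unchanged`.
#' @return An object of class `difference_classes`: a data frame with
#'   per-locus `mean_signal`, `delta`, `label`, plus attributes
#'   `thresholds` and `counts`.
#' @export
difference_classes <- function(control, treated, loci,
                               t_moderate = -1, t_severe = -3,
                               mode = c("fixed", "quantile"),
                               q_severe = 0.002, q_moderate = 0.049,
                               gain = FALSE) {
  mode <- match.arg(mode)
  if (!same_layout(control, treated)) stop("tracks must share a layout")
  if (!nrow(loci)) stop("no loci supplied")
  mc <- region_mean(control, loci)
  mt <- region_mean(treated, loci)
  delta <- mt - mc
  crit <- if (gain) -abs(delta) else delta
  if (mode == "quantile") {
    t_severe <- stats::quantile(crit, q_severe, names = FALSE)
    t_moderate <- stats::quantile(crit, q_moderate, names = FALSE)
  }
  if (!(t_severe < t_moderate))
    stop("thresholds out of order: need t_severe < t_moderate")
  if (mode == "fixed" && t_moderate >= 0)
    stop("depletion thresholds must be negative")
  label <- ifelse(crit <= t_severe, "severe",
                  ifelse(crit <= t_moderate, "moderate", "unchanged"))
  out <- data.frame(mean_signal = (mc + mt) / 2, delta = delta,
                    label = factor(label, c("unchanged", "moderate",
                                            "severe")),
                    stringsAsFactors = FALSE)
  structure(out,
            thresholds = c(t_moderate = t_moderate, t_severe = t_severe),
            counts = table(out$label),
            class = c("difference_classes", "data.frame"))
}

#' Paired difference test on per-locus signal
#'
#' Two-tailed Wilcoxon signed-rank test of treated vs control per-locus
#' values ([wilcoxon_signed_rank_test()]); zero differences are dropped and
#' the number of informative pairs is reported.
#'
#' @param x_control,x_treated equal-length numeric vectors of per-locus
#'   signal.
#' @return A list with `n_pairs`, `statistic`, `p_two_tailed`,
#'   `median_difference`.
#' @export
paired_difference_test <- function(x_control, x_treated) {
  if (length(x_control) != length(x_treated))
    stop("paired vectors must have equal length")
  if (!length(x_control)) stop("no loci supplied")
  w <- wilcoxon_signed_rank_test(x_treated, x_control)
  w$median_difference <- stats::median(x_treated - x_control)
  w
}

#' Interval-level comparison of two peak sets
#'
#' Counts, for a Venn-style comparison, how many `a` intervals overlap at
#' least one `b` interval by `>= min_overlap_bp` (and vice versa). Because
#' counting is at the interval level the two shared counts need not agree;
#' both perspectives are retained in the summary.
#'
#' @param a,b `region_set`s on the same genome.
#' @param min_overlap_bp minimum overlap in bp (default 1).
#' @return An `overlap_summary` (`n_a_shared` counts `a` intervals with a
#'   match; `n_b_only` counts unmatched `b` intervals).
#' @export
compare_region_sets <- function(a, b, min_overlap_bp = 1) {
  hits <- overlap_pairs(a, b)
  hits <- hits[hits$overlap_bp >= min_overlap_bp, , drop = FALSE]
  a_shared <- length(unique(hits$a_idx))
  b_shared <- length(unique(hits$b_idx))
  overlap_summary(n_a = nrow(a), n_b = nrow(b),
                  n_a_shared = a_shared, n_b_only = nrow(b) - b_shared)
}

#' Sliding-window differentially methylated regions
#'
#' A deliberately simple windowed DMR caller: the genome is tiled into
#' fixed windows; a window is a DMR candidate when both samples contain at
#' least `min_sites` CpG sites with coverage `>= min_cov` in the window and
#' the absolute difference of the coverage-weighted mean methylation levels
#' is `>= min_delta`. Adjacent candidate windows are merged.
#'
#' @param meth_a,meth_b `methylation_table`s for the two samples.
#' @param layout a `genome_layout`.
#' @param window_bp window size (>= 100 bp).
#' @param min_sites minimum qualifying CpG sites per window per sample.
#' @param min_cov minimum per-site coverage.
#' @param min_delta minimum absolute methylation-level difference (0-1).
#' @return A `region_set` of merged DMRs; the `score` column holds the
#'   mean level difference (`b - a`) of each merged region's windows.
#' @export
window_dmrs <- function(meth_a, meth_b, layout, window_bp = 500,
                        min_sites = 3, min_cov = 4, min_delta = 0.25) {
  check_layout(layout)
  if (window_bp < 100) stop("window_bp must be >= 100")
  if (min_sites < 1 || min_cov < 1 || min_delta <= 0)
    stop("parameters must be positive")
  window_stats <- function(mt, ch, nwin) {
    mt <- mt[mt$chrom == ch & mt$context == "CpG" & mt$total >= min_cov, ,
             drop = FALSE]
    win <- floor(mt$pos / window_bp) + 1
    f <- factor(win, levels = seq_len(nwin))
    list(n = as.integer(tapply(rep(1, nrow(mt)), f, sum, default = 0)),
         level = as.numeric(tapply(mt$methylated, f, sum, default = 0)) /
           pmax(1e-12, as.numeric(tapply(mt$total, f, sum, default = 0))))
  }
  chrom <- character(); start <- numeric(); end <- numeric()
  score <- numeric()
  for (ch in layout$chrom_names) {
    nwin <- ceiling(chrom_length(layout, ch) / window_bp)
    sa <- window_stats(meth_a, ch, nwin)
    sb <- window_stats(meth_b, ch, nwin)
    dd <- sb$level - sa$level
    cand <- sa$n >= min_sites & sb$n >= min_sites & abs(dd) >= min_delta
    if (!any(cand)) next
    r <- rle(cand)
    ends_r <- cumsum(r$lengths)
    starts_r <- ends_r - r$lengths + 1
    keep <- which(r$values)
    for (k in keep) {
      w0 <- starts_r[k]; w1 <- ends_r[k]
      chrom <- c(chrom, ch)
      start <- c(start, (w0 - 1) * window_bp)
      end <- c(end, min(w1 * window_bp, chrom_length(layout, ch)))
      score <- c(score, mean(dd[w0:w1]))
    }
  }
  region_set(chrom, start, end, score = score, label = "dmrs",
             layout = layout)
}

#' Select differentially expressed genes by FDR and fold-change thresholds
#'
#' Applies strict thresholds to a differential-expression statistics table:
#' up-regulated genes satisfy `fdr < fdr_max` and `fold_change > fc_min`;
#' down-regulated genes satisfy `fdr < fdr_max` and
#' `fold_change < -fc_min`. Fold changes are signed (negative = down);
#' boundary values are excluded.
#'
#' @param stats a data frame with columns `gene`, `fold_change`, `fdr`.
#' @param fdr_max FDR threshold (default 0.05).
#' @param fc_min fold-change magnitude threshold (default 1.3).
#' @return A list of class `de_gene_selection` with character vectors `up`
#'   and `down` (disjoint) and the `thresholds` used.
#' @export
select_de_genes <- function(stats, fdr_max = 0.05, fc_min = 1.3) {
  need <- c("gene", "fold_change", "fdr")
  if (!all(need %in% names(stats)))
    stop("stats must have columns: ", paste(need, collapse = ", "))
  if (any(stats$fdr < 0 | stats$fdr > 1, na.rm = TRUE))
    stop("fdr values must lie in [0, 1]")
  sig <- !is.na(stats$fdr) & stats$fdr < fdr_max
  up <- stats$gene[sig & stats$fold_change > fc_min]
  down <- stats$gene[sig & stats$fold_change < -fc_min]
  structure(list(up = up, down = down,
                 thresholds = c(fdr_max = fdr_max, fc_min = fc_min)),
            class = "de_gene_selection")
}

#' @export
print.de_gene_selection <- function(x, ...) {
  cat("<de_gene_selection> ", length(x$up), " up, ", length(x$down),
      " down (FDR < ", x$thresholds["fdr_max"], ", |fc| > ",
      x$thresholds["fc_min"], ")\n", sep = "")
  invisible(x)
}
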