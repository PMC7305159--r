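#' RPM normalization factor
#'
#' Reads-per-million scaling: the factor is `1e6 / mapped_reads`, where
#' `mapped_reads` counts reads aligned to the target genome. Multiplying a
#' raw count track by this factor expresses it in reads per million.
#'
#' @param target_mapped_reads number of reads mapped to the target genome.
#' @return An object of class `normalization_factor` with fields `kind`
#'   (`"RPM"`), `source_reads` and `factor`.
#' @examples
#' rpm_factor(2e6)$factor # 0.5
#' @export
rpm_factor <- function(target_mapped_reads) {
  new_norm_factor("RPM", target_mapped_reads)
}

#' RRPM (reference-adjusted RPM) spike-in normalization factor
#'
#' In a ChIP-Rx design a fixed ratio of exogenous (spike-in) cells is added
#' to every sample, so the number of reads mapping to the exogenous genome
#' measures the per-cell recovery of the experiment. The RRPM factor is
#' `1e6 / spikein_mapped_reads`; the target-genome read count plays no role.
#' Scaling target-genome tracks by this factor makes genuinely global
#' enrichment shifts between conditions visible, which plain RPM scaling
#' cancels out.
#'
#' @param spikein_mapped_reads number of reads mapped to the exogenous
#'   (spike-in) genome.
#' @return An object of class `normalization_factor` with `kind = "RRPM"`.
#' @examples
#' rrpm_factor(5e5)$factor # 2
#' @export
rrpm_factor <- function(spikein_mapped_reads) {
  new_norm_factor("RRPM", spikein_mapped_reads)
}

new_norm_factor <- function(kind, reads) {
  reads <- as.numeric(reads)
  if (!is.finite(reads) || reads <= 0)
    stop("mapped-read count must be > 0")
  structure(list(kind = kind, source_reads = reads, factor = 1e6 / reads),
            class = "normalization_factor")
}

#' @export
print.normalization_factor <- function(x, ...) {
  cat("<normalization_factor ", x$kind, "> ",
      format(x$source_reads, big.mark = ","), " reads, factor = ",
      signif(x$factor, 6), "\n", sep = "")
  invisible(x)
}

#' Scale a binned track by a normalization factor
#'
#' @param track a `binned_track` of raw counts.
#' @param nf a `normalization_factor` from [rpm_factor()] or
#'   [rrpm_factor()].
#' @return The scaled `binned_track`.
#' @export
scale_track <- function(track, nf) {
  if (!inherits(nf, "normalization_factor"))
    stop("nf must be a normalization_factor")
  track_map(track, function(v) v * nf$factor)
}

#' Z-transform a numeric vector
#'
#' Centres and scales by the population (not sample) standard deviation, so
#' the output has mean 0 and population SD 1. A constant input maps to all
#' zeros with a warning rather than propagating NaN.
#'
#' @param values numeric vector, length >= 2.
#' @return The z-transformed vector.
#' @examples
#' z_transform(c(1, 2, 3))
#' @export
z_transform <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  if (s == 0) {
    warning("constant input; returning zeros")
    return(rep(0, length(values)))
  }
  (values - m) / s
}

#' Genome-wide binned Pearson correlation between tracks
#'
#' Computes all pairwise Pearson correlations over genome-wide bins.
#' Tracks with a finer bin size are mean-aggregated up to `bin_size` first.
#' By default every bin is used; `drop_all_zero = TRUE` excludes bins that
#' are zero in all tracks.
#'
#' @param tracks a named list of `binned_track`s on the same layout.
#' @param bin_size correlation bin size in bp (default: the tracks' common
#'   bin size).
#' @param drop_all_zero drop bins zero in every track before correlating.
#' @return An object of class `correlation_matrix` with fields
#'   `track_labels`, `r` (symmetric matrix), `bin_size`, `n_bins_used`.
#' @export
binned_correlation <- function(tracks, bin_size = NULL,
                               drop_all_zero = FALSE) {
  if (length(tracks) < 2) stop("need at least two tracks")
  if (is.null(names(tracks)) || any(!nzchar(names(tracks))))
    names(tracks) <- vapply(tracks, function(t) t$label, "")
  for (t in tracks[-1])
    if (!same_layout(tracks[[1]], t)) stop("tracks must share a layout")
  if (is.null(bin_size)) {
    bs <- unique(vapply(tracks, function(t) t$bin_size, 1))
    if (length(bs) > 1)
      stop("tracks have mixed bin sizes; pass an explicit bin_size")
    bin_size <- bs
  }
  mat <- vapply(tracks, function(t) track_concat(rebin_track(t, bin_size)),
                numeric(sum(n_bins(tracks[[1]]$layout, bin_size))))
  if (drop_all_zero) mat <- mat[rowSums(mat != 0) > 0, , drop = FALSE]
  if (nrow(mat) < 2) stop("fewer than 2 usable bins")
  r <- stats::cor(mat)
  structure(list(track_labels = names(tracks), r = r, bin_size = bin_size,
                 n_bins_used = nrow(mat)),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("<correlation_matrix> ", x$n_bins_used, " bins of ", x$bin_size,
      " bp\n", sep = "")
  print(round(x$r, 3))
  invisible(x)
}

#' Strand-aware aggregate (metagene) profile around anchors
#'
#' Averages track signal at fixed offsets around a set of anchor positions
#' (TSSs, enhancer midpoints, ...). Minus-strand anchor windows are
#' orientation-flipped before averaging so that positive offsets always
#' point downstream. Anchors whose window leaves the chromosome are
#' dropped. Offsets run from `-upstream` to `+downstream` in steps of
#' `step` bp; the value at an offset is the track bin containing that base.
#'
#' @param track a `binned_track`.
#' @param anchors a data frame with columns `chrom`, `pos` and optionally
#'   `strand` (`"+"`/`"-"`/`"."`; default `"+"` orientation).
#' @param upstream,downstream window extent in bp.
#' @param step offset spacing in bp (default: the track bin size).
#' @param z if `TRUE`, z-transform the mean curve ([z_transform()]).
#' @return An object of class `aggregate_profile` with fields `offsets`,
#'   `mean`, `sd` (per-offset SD across anchors) and `n_anchors`.
#' @export
aggregate_profile <- function(track, anchors, upstream, downstream,
                              step = NULL, z = FALSE) {
  if (is.null(step)) step <- track$bin_size
  if (!all(c("chrom", "pos") %in% names(anchors)))
    stop("anchors need columns chrom and pos")
  strand <- if ("strand" %in% names(anchors)) anchors$strand else "+"
  strand <- rep_len(strand, nrow(anchors))
  offsets <- seq(-upstream, downstream, by = step)
  len <- chrom_length(track$layout, anchors$chrom)
  minus <- strand == "-"
  lo <- ifelse(minus, anchors$pos - downstream, anchors$pos - upstream)
  hi <- ifelse(minus, anchors$pos + upstream, anchors$pos + downstream)
  keep <- lo >= 0 & hi < len
  if (!any(keep)) stop("no usable anchors: all windows leave the chromosome")
  anchors <- anchors[keep, , drop = FALSE]
  minus <- minus[keep]
  m <- matrix(NA_real_, nrow(anchors), length(offsets))
  for (ch in unique(anchors$chrom)) {
    idx <- which(anchors$chrom == ch)
    for (i in idx) {
      off <- if (minus[i]) -offsets else offsets
      m[i, ] <- track_value_at(track, ch, anchors$pos[i] + off)
    }
  }
  mu <- colMeans(m)
  sd <- apply(m, 2, stats::sd)
  if (nrow(m) == 1) sd <- rep(0, length(offsets))
  if (z) mu <- z_transform(mu)
  structure(list(offsets = offsets, mean = mu, sd = sd,
                 n_anchors = nrow(m), z = z, label = track$label),
            class = "aggregate_profile")
}

#' @export
print.aggregate_profile <- function(x, ...) {
  cat("<aggregate_profile '", x$label, "'> ", length(x$offsets),
      " offsets [", min(x$offsets), ", ", max(x$offsets), "] bp over ",
      x$n_anchors, " anchors\n", sep = "")
  invisible(x)
}

#' Plot an aggregate profile
#'
#' Mean curve with a +/- SD shaded band.
#'
#' @param x an `aggregate_profile`.
#' @param ... further arguments to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.aggregate_profile <- function(x, ...) {
  ylim <- range(x$mean - x$sd, x$mean + x$sd)
  graphics::plot(x$offsets, x$mean, type = "n", ylim = ylim,
                 xlab = "offset from anchor (bp)",
                 ylab = if (x$z) "z-scaled mean signal" else "mean signal",
                 ...)
  graphics::polygon(c(x$offsets, rev(x$offsets)),
                    c(x$mean - x$sd, rev(x$mean + x$sd)),
                    border = NA, col = grDevices::adjustcolor("grey", 0.5))
  graphics::lines(x$offsets, x$mean, lwd = 2)
  invisible(x)
}

#' Per-region mean signal
#'
#' Base-weighted mean of the track over each region, optionally on a log2
#' scale with a pseudocount.
#'
#' @param track a `binned_track`.
#' @param regions a `region_set` within the track layout.
#' @param log2 return `log2(mean + pseudocount)`.
#' @param pseudocount added before the log (default 1, preventing
#'   `-Inf` on empty regions of count tracks).
#' @return Numeric vector, one value per region (empty input gives an empty
#'   vector).
#' @export
region_mean <- function(track, regions, log2 = FALSE, pseudocount = 1) {
  if (!nrow(regions)) return(numeric())
  m <- track_region_means(track, regions)
  if (log2) base::log2(m + pseudocount) else m
}

#' Input-normalize an IP track
#'
#' Expresses an immunoprecipitation (IP) track relative to its chromatin
#' input as `log2((IP + pseudocount) / (input + pseudocount))` per bin.
#' A ratio (rather than subtraction) is used because it is
#' scale-equivariant under the RPM/RRPM factors applied upstream; the
#' pseudocount keeps empty bins finite.
#'
#' @param ip,input `binned_track`s on the same layout and bin size.
#' @param pseudocount added to both tracks before the ratio (default 1).
#' @return A `binned_track` of log2 ratios.
#' @export
input_normalize <- function(ip, input, pseudocount = 1) {
  if (!same_layout(ip, input) || ip$bin_size != input$bin_size)
    stop("tracks must share layout and bin size")
  vals <- mapply(function(a, b) base::log2((a + pseudocount) /
                                             (b + pseudocount)),
                 ip$values, input$values, SIMPLIFY = FALSE)
  binned_track(ip$layout, ip$bin_size, vals,
               label = paste0(ip$label, "_over_input"))
}

#' Derive standard gene-anchored region sets
#'
#' Builds the region grammar used for relative-enrichment summaries, all
#' strand-aware ("upstream" follows the gene's direction of transcription):
#' \describe{
#'   \item{`tss`}{TSS -1 kb .. +1 kb.}
#'   \item{`body`}{TSS +1 kb .. +10 kb into the gene.}
#'   \item{`proximal`}{the flanking baseline: TSS -6 kb .. -1 kb plus
#'     TES .. TES +5 kb (two intervals per gene, sharing the gene's name).}
#' }
#' Intervals are clipped to chromosome bounds; genes whose clipped interval
#' vanishes are dropped.
#'
#' @param genes a `gene_model`.
#' @param scheme one of `"tss"`, `"body"`, `"proximal"`.
#' @param layout a `genome_layout` used for clipping.
#' @return A `region_set` with `name` = gene id.
#' @export
derive_gene_regions <- function(genes, scheme = c("tss", "body", "proximal"),
                                layout) {
  scheme <- match.arg(scheme)
  check_layout(layout)
  plus <- genes$strand == "+"
  dir <- ifelse(plus, 1, -1)
  win <- switch(scheme,
    tss = list(cbind(genes$tss - 1000 * dir, genes$tss + 1000 * dir)),
    body = list(cbind(genes$tss + 1000 * dir, genes$tss + 10000 * dir)),
    proximal = list(cbind(genes$tss - 6000 * dir, genes$tss - 1000 * dir),
                    cbind(genes$tes, genes$tes + 5000 * dir)))
  chrom <- character(); start <- numeric(); end <- numeric(); nm <- character()
  for (w in win) {
    s <- pmin(w[, 1], w[, 2]); e <- pmax(w[, 1], w[, 2])
    len <- chrom_length(layout, genes$chrom)
    s <- pmax(s, 0); e <- pmin(e, len)
    keep <- s < e
    chrom <- c(chrom, genes$chrom[keep])
    start <- c(start, s[keep]); end <- c(end, e[keep])
    nm <- c(nm, genes$gene_id[keep])
  }
  region_set(chrom, start, end, name = nm, label = scheme, layout = layout)
}
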