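#' Define a genome layout
#'
#' A genome layout names the chromosomes and fixes their lengths. Every
#' interval, track and anchor handled by the package is validated against a
#' layout: coordinates are 0-based, half-open, and must lie within
#' `[0, chrom_length)`. Unknown chromosomes in input data are always an
#' error, never silently dropped, because a chromosome-name mismatch is the
#' most common silent failure when mixing genome builds.
#'
#' @param chrom_names character vector of unique chromosome names.
#' @param chrom_lengths positive integer vector of chromosome lengths (bp),
#'   parallel to `chrom_names`.
#' @return An object of class `genome_layout`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(5e6, 5e6))
#' @export
genome_layout <- function(chrom_names, chrom_lengths) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_names) != length(chrom_lengths))
    stop("chrom_names and chrom_lengths must have the same length")
  if (anyDuplicated(chrom_names))
    stop("chromosome names must be unique")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("chromosome lengths must be positive")
  structure(
    list(chrom_names = chrom_names,
         chrom_lengths = stats::setNames(chrom_lengths, chrom_names)),
    class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", length(x$chrom_names), " chromosomes, ",
      format(sum(x$chrom_lengths), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

chrom_length <- function(layout, chrom) {
  len <- layout$chrom_lengths[chrom]
  if (anyNA(len))
    stop("unknown chromosome(s): ",
         paste(unique(chrom[is.na(len)]), collapse = ", "))
  unname(len)
}

check_layout <- function(layout) {
  if (!inherits(layout, "genome_layout"))
    stop("`layout` must be a genome_layout object")
  layout
}

#' Construct a set of genomic regions
#'
#' A `region_set` is an ordered collection of 0-based half-open genomic
#' intervals (peaks, nucleosome calls, annotations ...) with optional names,
#' scores and strands. Intervals are sorted by (chrom, start, end) on
#' construction; this ordering is an invariant relied on throughout the
#' package.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end 0-based half-open coordinates; `start < end` required.
#' @param name optional interval names.
#' @param score optional numeric scores (no NaN permitted).
#' @param strand strand per interval, one of `"+"`, `"-"`, `"."`.
#' @param label a label for the whole set (e.g. `"mecp2_peaks"`).
#' @param layout optional `genome_layout`; if given, intervals are validated
#'   to lie within their chromosomes.
#' @return A data frame of class `region_set` with columns
#'   `chrom, start, end, name, score, strand` and attribute `label`.
#' @examples
#' region_set("chr1", c(100, 0), c(250, 50), label = "demo")
#' @export
region_set <- function(chrom, start, end, name = NA_character_,
                       score = NA_real_, strand = ".",
                       label = "regions", layout = NULL) {
  n <- length(start)
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = as.numeric(start),
    end = as.numeric(end),
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE)
  validate_region_df(df, layout)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, label = label, class = c("region_set", "data.frame"))
}

validate_region_df <- function(df, layout = NULL) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(!is.finite(df$start)) || any(!is.finite(df$end)))
    stop("non-finite interval coordinates")
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop("start >= end for interval(s) at row ", bad[1])
  if (any(df$start < 0))
    stop("negative start coordinate")
  if (!all(df$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  if (any(is.nan(df$score)))
    stop("NaN scores are not permitted")
  if (!is.null(layout)) {
    len <- chrom_length(check_layout(layout), df$chrom)
    if (any(df$end > len))
      stop("interval extends beyond chromosome end (row ",
           which(df$end > len)[1], ")")
  }
  invisible(df)
}

#' @export
print.region_set <- function(x, ...) {
  cat("<region_set '", attr(x, "label"), "'> ", nrow(x), " intervals on ",
      length(unique(x$chrom)), " chromosome(s)\n", sep = "")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ... ", nrow(x) - 6, " more\n", sep = "")
  invisible(x)
}

set_label <- function(rs, label) {
  attr(rs, "label") <- label
  rs
}

region_label <- function(rs) attr(rs, "label")

n_regions <- function(rs) nrow(rs)

region_widths <- function(rs) rs$end - rs$start

as_region_set <- function(df, label = "regions", layout = NULL) {
  region_set(df$chrom, df$start, df$end,
             name = if ("name" %in% names(df)) df$name else NA_character_,
             score = if ("score" %in% names(df)) df$score else NA_real_,
             strand = if ("strand" %in% names(df)) df$strand else ".",
             label = label, layout = layout)
}

# subset that preserves class + label
region_subset <- function(rs, idx) {
  out <- as.data.frame(rs)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, label = attr(rs, "label"),
            class = c("region_set", "data.frame"))
}

# split a region_set into per-chromosome IRanges (1-based closed, as IRanges
# expects); used by the overlap engine.
regions_to_iranges <- function(rs) {
  lapply(split(seq_len(nrow(rs)), rs$chrom), function(idx) {
    list(idx = idx,
         ir = IRanges::IRanges(start = rs$start[idx] + 1, end = rs$end[idx]))
  })
}

#' Construct a gene model table
#'
#' Genes are represented by their transcription start (TSS) and end (TES)
#' sites in genomic coordinates together with a strand. For a `+` gene
#' `tss < tes`; for a `-` gene `tss > tes`.
#'
#' @param gene_id character gene identifiers (unique).
#' @param chrom chromosome per gene.
#' @param strand `"+"` or `"-"`.
#' @param tss,tes transcription start / end site (0-based bp).
#' @param layout optional `genome_layout` for bounds checking.
#' @return A data frame of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, tss, tes, layout = NULL) {
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   strand = as.character(strand),
                   tss = as.numeric(tss), tes = as.numeric(tes),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene_id)) stop("gene ids must be unique")
  if (!all(df$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  bad <- ifelse(df$strand == "+", df$tss >= df$tes, df$tss <= df$tes)
  if (any(bad))
    stop("tss/tes inconsistent with strand at row ", which(bad)[1])
  if (!is.null(layout)) {
    len <- chrom_length(check_layout(layout), df$chrom)
    if (any(pmax(df$tss, df$tes) > len) || any(pmin(df$tss, df$tes) < 0))
      stop("gene coordinates outside chromosome bounds")
  }
  structure(df, class = c("gene_model", "data.frame"))
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", nrow(x), " genes\n", sep = "")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

# run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards
with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) stop("a seed is required")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
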