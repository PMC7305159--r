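#' Read genomic regions from a BED file
#'
#' Parses BED3/BED6 with the standard conventions: 0-based half-open
#' coordinates, column 4 = name, column 5 = score, column 6 = strand.
#' Output is sorted by (chrom, start, end). Malformed lines raise an error
#' naming the offending line number; `start >= end` is a validation error.
#'
#' @param path path to a tab-separated BED file.
#' @param layout optional `genome_layout`; when given, intervals beyond
#'   chromosome ends or on unknown chromosomes are an error.
#' @param label label for the resulting set (default: file base name).
#' @return A `region_set`.
#' @export
read_regions <- function(path, layout = NULL, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(region_set(character(), numeric(), numeric(), label = label))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 fields")
  get <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, "")
  }
  start <- suppressWarnings(as.numeric(get(2, NA_character_)))
  end <- suppressWarnings(as.numeric(get(3, NA_character_)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", bad[1], ": non-numeric coordinates")
  score <- suppressWarnings(as.numeric(get(5, NA_character_)))
  region_set(chrom = get(1, NA_character_), start = start, end = end,
             name = ifelse(nf >= 4, get(4, NA_character_), NA),
             score = score,
             strand = ifelse(nf >= 6, get(6, "."), "."),
             label = label, layout = layout)
}

#' Write genomic regions to a BED file
#'
#' Inverse of [read_regions()]: `read_regions(write_regions(rs, f))`
#' reproduces `rs`. Columns beyond the third are emitted only as far as
#' needed (BED3 when no name/score/strand is set).
#'
#' @param rs a `region_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(rs, path) {
  validate_region_df(rs)
  ncol_out <- if (all(rs$strand == ".") && all(is.na(rs$score)) &&
                  all(is.na(rs$name))) 3L else 6L
  if (nrow(rs) == 0) {
    cat("", file = path)
    return(invisible(path))
  }
  df <- data.frame(rs$chrom, format_bp(rs$start), format_bp(rs$end))
  if (ncol_out == 6L)
    df <- cbind(df, ifelse(is.na(rs$name), ".", rs$name),
                ifelse(is.na(rs$score), "0", as.character(rs$score)),
                rs$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a bedGraph file into a binned track
#'
#' Each bin receives the coverage-weighted mean of the bedGraph records
#' overlapping it, with uncovered bases contributing zero; the terminal
#' partial bin averages over its in-chromosome bases only. Records beyond a
#' chromosome end (or on unknown chromosomes) are an error.
#'
#' @param path path to a 4-column tab-separated bedGraph file.
#' @param layout a `genome_layout`.
#' @param bin_size bin width in bp.
#' @param label track label.
#' @return A `binned_track`.
#' @export
read_bedgraph <- function(path, layout, bin_size, label = NULL) {
  check_layout(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  track <- binned_track(layout, bin_size, label = label)
  if (!length(lines)) return(track)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4))
    stop("malformed bedGraph line ", which(nf < 4)[1], ": fewer than 4 fields")
  chrom <- vapply(fields, `[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3)))
  val <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 4)))
  bad <- which(is.na(start) | is.na(end) | is.na(val))
  if (length(bad))
    stop("malformed bedGraph line ", bad[1], ": non-numeric field")
  len <- chrom_length(layout, chrom)
  if (any(end > len))
    stop("bedGraph record beyond chromosome end (line ",
         which(end > len)[1], ")")
  if (any(start < 0) || any(start >= end))
    stop("invalid bedGraph interval (line ",
         which(start < 0 | start >= end)[1], ")")
  # accumulate value*bp per bin, then divide by covered bin width
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    nb <- length(track$values[[ch]])
    acc <- numeric(nb)
    for (i in idx) {
      s <- start[i]; e <- end[i]
      b0 <- floor(s / bin_size); b1 <- floor((e - 1) / bin_size)
      bins <- b0:b1
      lo <- pmax(bins * bin_size, s)
      hi <- pmin((bins + 1) * bin_size, e)
      acc[bins + 1] <- acc[bins + 1] + val[i] * (hi - lo)
    }
    width <- pmin((seq_len(nb)) * bin_size, chrom_length(layout, ch)) -
      (seq_len(nb) - 1) * bin_size
    track$values[[ch]] <- acc / width
  }
  track
}

#' Write a binned track as bedGraph
#'
#' Emits one record per bin (zero bins included), so that
#' `read_bedgraph(write_bedgraph(t, f), layout, bin_size)` reproduces `t`.
#'
#' @param track a `binned_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in track$layout$chrom_names) {
    v <- track$values[[ch]]
    if (!length(v)) next
    s <- (seq_along(v) - 1) * track$bin_size
    e <- pmin(s + track$bin_size, chrom_length(track$layout, ch))
    utils::write.table(
      data.frame(ch, format_bp(s), format_bp(e),
                 format(v, scientific = FALSE, trim = TRUE)),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a per-cytosine methylation table
#'
#' Expects a tab-separated file with header columns
#' `chrom, pos, context, methylated, total` (context in CpG/CAG/CAH).
#'
#' @param path input path.
#' @return A data frame of class `methylation_table`.
#' @export
read_methylation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  methylation_table(df$chrom, df$pos, df$context, df$methylated, df$total)
}

#' Construct a per-cytosine methylation table
#'
#' @param chrom,pos site coordinates (0-based).
#' @param context sequence context, one of `"CpG"`, `"CAG"`, `"CAH"`.
#' @param methylated,total methylated and total read counts;
#'   `0 <= methylated <= total`, `total >= 1`.
#' @return A data frame of class `methylation_table`.
#' @export
methylation_table <- function(chrom, pos, context, methylated, total) {
  df <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   context = as.character(context),
                   methylated = as.numeric(methylated),
                   total = as.numeric(total), stringsAsFactors = FALSE)
  if (!all(df$context %in% c("CpG", "CAG", "CAH")))
    stop("context must be one of CpG, CAG, CAH")
  if (any(df$total < 1)) stop("total coverage must be >= 1 at every site")
  if (any(df$methylated < 0 | df$methylated > df$total))
    stop("methylated count must lie in [0, total]")
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("methylation_table", "data.frame"))
}

#' Write a methylation table as TSV
#' @param mt a `methylation_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_methylation <- function(mt, path) {
  utils::write.table(as.data.frame(mt), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Fragment-extended coverage track from mapped reads
#'
#' Each read is extended 3'-ward (rightward for `+`, leftward for `-`) to
#' `extend_to` bp, clipped at the chromosome ends, and per-bin fragment
#' coverage is accumulated: a bin's value is the number of fragment-bases
#' falling in it, so the genome-wide total equals the summed (clipped)
#' fragment lengths.
#'
#' @param reads a stranded `region_set` of mapped reads.
#' @param layout a `genome_layout`.
#' @param bin_size bin width in bp.
#' @param extend_to target fragment length in bp; `0` disables extension.
#'   Reads already longer than `extend_to` are left unextended.
#' @return A `binned_track` of fragment-base counts.
#' @export
coverage_track <- function(reads, layout, bin_size, extend_to = 0) {
  check_layout(layout)
  if (extend_to < 0) stop("extend_to must be >= 0")
  track <- binned_track(layout, bin_size, label = region_label(reads))
  if (!nrow(reads)) return(track)
  len <- chrom_length(layout, reads$chrom)
  s <- reads$start; e <- reads$end
  if (extend_to > 0) {
    w <- pmax(e - s, extend_to)
    plus <- reads$strand != "-"
    s <- ifelse(plus, s, e - w)
    e <- ifelse(plus, s + w, e)
  }
  s <- pmax(s, 0)
  e <- pmin(e, len)
  for (ch in unique(reads$chrom)) {
    idx <- which(reads$chrom == ch)
    v <- track$values[[ch]]
    for (i in idx) {
      b0 <- floor(s[i] / bin_size); b1 <- floor((e[i] - 1) / bin_size)
      bins <- b0:b1
      lo <- pmax(bins * bin_size, s[i])
      hi <- pmin((bins + 1) * bin_size, e[i])
      v[bins + 1] <- v[bins + 1] + (hi - lo)
    }
    track$values[[ch]] <- v
  }
  track
}

#' All overlapping interval pairs between two region sets
#'
#' Half-open semantics: intervals sharing only a boundary do not overlap.
#' A pair is reported when the overlap is at least 1 bp and covers at least
#' `min_frac` of the `a` interval.
#'
#' @param a,b `region_set`s on the same genome.
#' @param min_frac minimum overlap as a fraction of the `a` interval width
#'   (in `[0, 1]`).
#' @return A data frame with columns `a_idx`, `b_idx`, `overlap_bp`, indices
#'   referring to row numbers of the (sorted) inputs.
#' @export
overlap_pairs <- function(a, b, min_frac = 0) {
  if (min_frac < 0 || min_frac > 1) stop("min_frac must be in [0, 1]")
  out <- list()
  ir_a <- regions_to_iranges(a)
  ir_b <- regions_to_iranges(b)
  for (ch in intersect(names(ir_a), names(ir_b))) {
    ha <- ir_a[[ch]]; hb <- ir_b[[ch]]
    hits <- IRanges::findOverlaps(ha$ir, hb$ir, minoverlap = 1L)
    if (!length(hits)) next
    qa <- S4Vectors::queryHits(hits); qb <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(ha$ir[qa], hb$ir[qb]))
    keep <- ov / IRanges::width(ha$ir[qa]) >= min_frac
    out[[ch]] <- data.frame(a_idx = ha$idx[qa][keep],
                            b_idx = hb$idx[qb][keep],
                            overlap_bp = ov[keep])
  }
  if (!length(out))
    return(data.frame(a_idx = integer(), b_idx = integer(),
                      overlap_bp = integer()))
  res <- do.call(rbind, out)
  res <- res[order(res$a_idx, res$b_idx), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Merge nearby intervals
#'
#' Intervals separated by at most `gap` bp are merged (`gap = 0` merges
#' overlapping and touching intervals, yielding a disjoint set).
#'
#' @param rs a `region_set`.
#' @param gap maximum separation (bp) at which two intervals are still
#'   merged; must be `>= 0`.
#' @return A `region_set` of merged intervals (name/score dropped).
#' @export
merge_overlapping <- function(rs, gap = 0) {
  if (gap < 0) stop("gap must be >= 0")
  if (!nrow(rs)) return(rs)
  parts <- lapply(regions_to_iranges(rs), function(h)
    IRanges::reduce(h$ir, min.gapwidth = gap + 1))
  chrom <- rep(names(parts), vapply(parts, length, 1L))
  starts <- unlist(lapply(parts, IRanges::start), use.names = FALSE) - 1
  ends <- unlist(lapply(parts, IRanges::end), use.names = FALSE)
  region_set(chrom, starts, ends, label = region_label(rs))
}
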