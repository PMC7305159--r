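#' Construct a binned signal track
#'
#' A `binned_track` stores one numeric vector per chromosome, with one value
#' per fixed-size bin (`ceiling(chrom_length / bin_size)` bins; the terminal
#' bin may cover fewer bases). It is the unit every normalization,
#' correlation and profiling operation acts on.
#'
#' @param layout a `genome_layout`.
#' @param bin_size bin width in bp (positive integer).
#' @param values optional named list (one numeric vector per chromosome) of
#'   initial values; defaults to all-zero.
#' @param label optional track label.
#' @return An object of class `binned_track`.
#' @export
binned_track <- function(layout, bin_size, values = NULL, label = "track") {
  check_layout(layout)
  bin_size <- as.numeric(bin_size)
  if (!is.finite(bin_size) || bin_size < 1) stop("bin_size must be >= 1")
  nb <- n_bins(layout, bin_size)
  if (is.null(values)) {
    values <- lapply(nb, function(n) numeric(n))
  } else {
    if (!setequal(names(values), layout$chrom_names))
      stop("values must be a named list covering every chromosome")
    values <- values[layout$chrom_names]
    ok <- mapply(function(v, n) length(v) == n, values, nb[names(values)])
    if (!all(ok)) stop("value vector length does not match bin count")
  }
  structure(list(layout = layout, bin_size = bin_size,
                 values = values, label = label),
            class = "binned_track")
}

n_bins <- function(layout, bin_size) {
  stats::setNames(as.integer(ceiling(layout$chrom_lengths / bin_size)),
                  layout$chrom_names)
}

#' @export
print.binned_track <- function(x, ...) {
  tot <- sum(vapply(x$values, length, 1L))
  cat("<binned_track '", x$label, "'> bin ", x$bin_size, " bp, ",
      format(tot, big.mark = ","), " bins over ",
      length(x$values), " chromosome(s)\n", sep = "")
  invisible(x)
}

# concatenated genome-wide bin vector (chromosomes in layout order)
track_concat <- function(track) {
  unlist(track$values[track$layout$chrom_names], use.names = FALSE)
}

track_total <- function(track) sum(track_concat(track))

same_layout <- function(a, b) {
  identical(a$layout$chrom_names, b$layout$chrom_names) &&
    identical(unname(a$layout$chrom_lengths), unname(b$layout$chrom_lengths))
}

# value of the bin containing each base position (vectorised within one
# chromosome)
track_value_at <- function(track, chrom, pos) {
  v <- track$values[[chrom]]
  if (is.null(v)) stop("unknown chromosome: ", chrom)
  idx <- floor(pos / track$bin_size) + 1
  if (any(idx < 1 | idx > length(v))) stop("position outside chromosome")
  v[idx]
}

# map a track onto wider bins by mean aggregation (used by
# binned_correlation when tracks disagree with the requested bin size)
rebin_track <- function(track, new_bin) {
  if (new_bin == track$bin_size) return(track)
  if (new_bin < track$bin_size || new_bin %% track$bin_size != 0)
    stop("new bin size must be a multiple of the track bin size")
  k <- new_bin / track$bin_size
  vals <- lapply(track$layout$chrom_names, function(ch) {
    v <- track$values[[ch]]
    grp <- rep(seq_len(ceiling(length(v) / k)), each = k)[seq_along(v)]
    as.numeric(tapply(v, grp, mean))
  })
  names(vals) <- track$layout$chrom_names
  binned_track(track$layout, new_bin, vals, label = track$label)
}

# apply a function bin-wise, keeping layout/bin structure
track_map <- function(track, f, label = track$label) {
  binned_track(track$layout, track$bin_size, lapply(track$values, f),
               label = label)
}

# For each region (0-based half-open), the base-weighted mean of the bin
# values it covers. Shared by region_mean and difference_classes.
track_region_means <- function(track, regions) {
  bs <- track$bin_size
  out <- numeric(nrow(regions))
  for (ch in unique(regions$chrom)) {
    v <- track$values[[ch]]
    if (is.null(v)) stop("unknown chromosome: ", ch)
    ridx <- which(regions$chrom == ch)
    for (i in ridx) {
      s <- regions$start[i]; e <- regions$end[i]
      b0 <- floor(s / bs); b1 <- floor((e - 1) / bs)
      if (b1 >= length(v)) stop("region extends beyond chromosome end")
      bins <- b0:b1
      # bp of the region inside each covered bin
      lo <- pmax(bins * bs, s)
      hi <- pmin((bins + 1) * bs, e)
      w <- hi - lo
      out[i] <- sum(v[bins + 1] * w) / (e - s)
    }
  }
  out
}
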