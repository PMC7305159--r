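# Independent brute-force oracles and small fixture builders. These
# deliberately avoid the package's own code paths (IRanges, rank-based
# statistics) so that agreement is evidence, not tautology.

tiny_layout <- function(len = 10000, n_chrom = 2) {
  genome_layout(paste0("chr", seq_len(n_chrom)), rep(len, n_chrom))
}

random_regions <- function(n, layout, max_width = 400, label = "rand") {
  chrom <- sample(layout$chrom_names, n, replace = TRUE)
  len <- layout$chrom_lengths[chrom]
  width <- sample.int(max_width, n, replace = TRUE)
  start <- floor(runif(n, 0, len - width))
  region_set(chrom, start, start + width, label = label, layout = layout)
}

# O(n*m) all-pairs overlap scan on the sorted region data frames
brute_overlap_pairs <- function(a, b, min_frac = 0) {
  out <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (ov >= 1 && ov / (a$end[i] - a$start[i]) >= min_frac)
      out <- rbind(out, c(i, j, ov))
  }
  if (is.null(out))
    return(data.frame(a_idx = integer(), b_idx = integer(),
                      overlap_bp = integer()))
  out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
  data.frame(a_idx = out[, 1], b_idx = out[, 2], overlap_bp = out[, 3])
}

# per-base pileup oracle for coverage and bedGraph binning
per_base_bins <- function(base_values, bin_size, agg = mean) {
  grp <- rep(seq_len(ceiling(length(base_values) / bin_size)),
             each = bin_size)[seq_along(base_values)]
  as.numeric(tapply(base_values, grp, agg))
}

# Exact two-tailed Mann-Whitney p by enumerating group assignments and
# counting pairwise wins directly (no ranks).
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_of(x, y)
  combs <- utils::combn(length(pooled), n1)
  u_null <- apply(combs, 2, function(idx)
    u_of(pooled[idx], pooled[-idx]))
  eps <- 1e-9
  min(1, 2 * min(mean(u_null <= u_obs + eps),
                 mean(u_null >= u_obs - eps)))
}

# Exact two-tailed Wilcoxon signed-rank p by sign-pattern enumeration,
# computing W+ from scratch per pattern.
oracle_wsr_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  w_null <- apply(signs, 1, function(s) sum(rk[s > 0]))
  eps <- 1e-9
  min(1, 2 * min(mean(w_null <= w_obs + eps),
                 mean(w_null >= w_obs - eps)))
}

track_total_test <- function(tr) sum(unlist(tr$values))

track_concat_test <- function(tr) unlist(tr$values, use.names = FALSE)

# direct per-interval labeling for the three-way occupancy classification
brute_classify <- function(nuc, peaks, min_overlap_bp = 1) {
  ov <- function(i, rs) {
    same <- rs$chrom == nuc$chrom[i]
    pmin(rs$end, nuc$end[i]) - pmax(rs$start, nuc$start[i]) >= min_overlap_bp & same
  }
  nuc_lab <- vapply(seq_len(nrow(nuc)), function(i)
    if (any(ov(i, peaks))) "group2" else "group1", "")
  peak_free <- vapply(seq_len(nrow(peaks)), function(j) {
    same <- nuc$chrom == peaks$chrom[j]
    !any(pmin(nuc$end, peaks$end[j]) - pmax(nuc$start, peaks$start[j]) >= 1 &
           same)
  }, TRUE)
  list(nuc_lab = nuc_lab, peak_free = peak_free)
}
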