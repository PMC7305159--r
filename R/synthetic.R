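#' Simulation configuration with planted ground truth parameters
#'
#' Central parameter object for the synthetic-data generators. Defaults
#' define a toy genome of 2 chromosomes x 5 Mb with 200 bp bins (50,000
#' bins genome-wide) and plant the headline quantities of the study
#' design the generators emulate: 31.0% of nucleosomes protein-occupied /
#' 68.9% free, 44% of protein peaks nucleosome-free, a 0.74 count-level
#' Pearson correlation between the protein and the repressive mark,
#' CpG methylation centred at 0.50 / 0.762 / 0.739 for groups 1-3 with
#' near-zero CAG/CAH methylation, three TSS-proximal signal clusters with
#' expression medians ordered cluster3 > cluster2 > cluster1, and a
#' spike-in design with a condition-level global scaling factor.
#'
#' @param seed RNG seed (mandatory; all generators derive their
#'   deterministic streams from it).
#' @param n_chrom,chrom_length,bin_size toy genome geometry.
#' @param marks mark names simulated by [simulate_tracks()].
#' @param rho target count-level Pearson correlation matrix between marks
#'   (entries in `[-1, 1]`).
#' @param depth expected mapped reads per mark track.
#' @param sigma_log SD of the latent log-normal intensity field.
#' @param spikein_depth expected spike-in (exogenous genome) reads per
#'   sample.
#' @param global_factor condition-level true enrichment ratio
#'   (treated / control) planted by [simulate_spikein_experiment()].
#' @param n_nucleosomes number of 147 bp nucleosome loci to place.
#' @param frac_nuc_shared fraction of nucleosomes overlapped by a protein
#'   peak (group2 truth).
#' @param frac_peak_free fraction of protein peaks placed nucleosome-free
#'   (group3 truth).
#' @param peak_width_range protein peak width range in bp.
#' @param meth_beta per-group, per-context Beta means and the shared
#'   concentration used by [simulate_methylation()].
#' @param meth_sites_per_locus expected CpG / CAG / CAH sites per locus.
#' @param meth_coverage expected per-site read coverage.
#' @param n_genes,cluster_props,cluster_expr_log10,expr_sd_log10,
#'   rep_sd_log10,ko_up_frac,ko_effect gene/cluster/expression parameters
#'   for [simulate_genes_expression()].
#' @param template_amplitude planted TSS-proximal signal amplitude
#'   (in track units) and `template_noise` the per-bin noise SD.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_chrom = 2,
                       chrom_length = 5e6,
                       bin_size = 200,
                       marks = c("MeCP2", "H3K27me3", "H3K9ac"),
                       rho = NULL,
                       depth = 2e6,
                       sigma_log = 0.5,
                       spikein_depth = 2e7,
                       global_factor = 1,
                       n_nucleosomes = 4000,
                       frac_nuc_shared = 0.310,
                       frac_peak_free = 0.44,
                       peak_width_range = c(150, 600),
                       meth_beta = list(
                         CpG = c(group1 = 0.50, group2 = 0.762,
                                 group3 = 0.739),
                         CAG = c(group1 = 1e-5, group2 = 1.1e-4,
                                 group3 = 9e-5),
                         CAH = c(group1 = 1e-5, group2 = 4e-5,
                                 group3 = 6e-5)),
                       meth_concentration = 20,
                       meth_sites_per_locus = c(CpG = 5, CAG = 2, CAH = 2),
                       meth_coverage = 10,
                       n_genes = 1500,
                       cluster_props = c(0.626, 0.100, 0.274),
                       cluster_expr_log10 = c(0.26, 0.97, 1.11),
                       expr_sd_log10 = 0.4,
                       rep_sd_log10 = 0.02,
                       ko_up_frac = c(0.05, 0.25, 0.40),
                       ko_effect = 2,
                       template_amplitude = 3,
                       template_noise = 0.3) {
  if (missing(seed)) stop("a seed is mandatory")
  if (is.null(rho)) {
    rho <- diag(length(marks))
    dimnames(rho) <- list(marks, marks)
    if (all(c("MeCP2", "H3K27me3") %in% marks))
      rho["MeCP2", "H3K27me3"] <- rho["H3K27me3", "MeCP2"] <- 0.74
    if (all(c("MeCP2", "H3K9ac") %in% marks))
      rho["MeCP2", "H3K9ac"] <- rho["H3K9ac", "MeCP2"] <- 0.27
    if (all(c("H3K27me3", "H3K9ac") %in% marks))
      rho["H3K27me3", "H3K9ac"] <- rho["H3K9ac", "H3K27me3"] <- 0.20
  }
  if (any(abs(rho) > 1)) stop("correlations must lie in [-1, 1]")
  if (depth <= 0 || spikein_depth <= 0) stop("depths must be positive")
  if (global_factor <= 0) stop("global_factor must be positive")
  if (frac_nuc_shared < 0 || frac_nuc_shared > 1 ||
      frac_peak_free < 0 || frac_peak_free > 1)
    stop("planted fractions must lie in [0, 1]")
  layout <- genome_layout(paste0("chr", seq_len(n_chrom)),
                          rep(chrom_length, n_chrom))
  structure(list(seed = seed, layout = layout, bin_size = bin_size,
                 marks = marks, rho = rho, depth = depth,
                 sigma_log = sigma_log, spikein_depth = spikein_depth,
                 global_factor = global_factor,
                 n_nucleosomes = n_nucleosomes,
                 frac_nuc_shared = frac_nuc_shared,
                 frac_peak_free = frac_peak_free,
                 peak_width_range = peak_width_range,
                 meth_beta = meth_beta,
                 meth_concentration = meth_concentration,
                 meth_sites_per_locus = meth_sites_per_locus,
                 meth_coverage = meth_coverage,
                 n_genes = n_genes, cluster_props = cluster_props,
                 cluster_expr_log10 = cluster_expr_log10,
                 expr_sd_log10 = expr_sd_log10,
                 rep_sd_log10 = rep_sd_log10,
                 ko_up_frac = ko_up_frac, ko_effect = ko_effect,
                 template_amplitude = template_amplitude,
                 template_noise = template_noise),
            class = "sim_config")
}

#' Simulate nucleosome and protein-peak placements with known truth
#'
#' Places non-overlapping 147 bp nucleosome loci and variable-width
#' protein peaks on the toy genome so that the planted overlap structure
#' holds exactly by construction: a fraction `frac_nuc_shared` of
#' nucleosomes receives an overlapping peak (group2), the remainder stays
#' protein-free (group1), and additional peaks are placed on
#' nucleosome-free sequence (group3) so that they make up
#' `frac_peak_free` of all peaks. True labels are recorded per locus.
#'
#' @param cfg a `sim_config`.
#' @return A list of class `occupancy_truth` with `nucleosomes`,
#'   `mecp2_peaks` (region_sets; peak names carry the truth labels),
#'   `true_group` (per-locus label vector, loci = nucleosomes then
#'   nucleosome-free peaks).
#' @export
simulate_occupancy <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 1L, {
    n_nuc <- cfg$n_nucleosomes
    n_shared <- round(n_nuc * cfg$frac_nuc_shared)
    # peaks: shared peaks sit on group2 nucleosomes; free peaks make up
    # frac_peak_free of the total peak count
    n_free <- round(n_shared * cfg$frac_peak_free /
                      (1 - cfg$frac_peak_free))
    # lay out candidate slots on a fixed pitch so nothing collides; slot
    # pitch leaves room for the widest peak plus clearance
    pitch <- max(cfg$peak_width_range) + 300
    slots_per_chrom <- floor((cfg$layout$chrom_lengths[1] - pitch) / pitch)
    total_slots <- slots_per_chrom * length(cfg$layout$chrom_names)
    if (n_nuc + n_free > total_slots)
      stop("genome too small for requested locus counts")
    slot_id <- sample.int(total_slots, n_nuc + n_free)
    slot_chrom <- cfg$layout$chrom_names[(slot_id - 1) %/% slots_per_chrom
                                         + 1]
    slot_pos <- ((slot_id - 1) %% slots_per_chrom) * pitch + 150
    # first n_nuc slots hold nucleosomes; of those the first n_shared are
    # group2; remaining slots hold nucleosome-free peaks (group3)
    nuc_start <- slot_pos[seq_len(n_nuc)]
    nucleosomes <- region_set(slot_chrom[seq_len(n_nuc)], nuc_start,
                              nuc_start + 147, label = "nucleosomes",
                              layout = cfg$layout)
    # region_set sorts; recover which sorted rows are the shared ones
    ord <- order(slot_chrom[seq_len(n_nuc)], nuc_start, nuc_start + 147)
    shared_sorted <- which(ord %in% seq_len(n_shared))
    peak_w <- function(k) round(stats::runif(k, cfg$peak_width_range[1],
                                             cfg$peak_width_range[2]))
    # shared peaks overlap their nucleosome by at least ~half the peak
    w_sh <- peak_w(n_shared)
    sh_start <- pmax(0, slot_pos[seq_len(n_shared)] + 74 - round(w_sh / 2))
    w_fr <- peak_w(n_free)
    fr_slot <- seq(n_nuc + 1, length.out = n_free)
    fr_start <- pmax(0, slot_pos[fr_slot] - round(w_fr / 2) + 74)
    peaks <- region_set(
      c(slot_chrom[seq_len(n_shared)], slot_chrom[fr_slot]),
      c(sh_start, fr_start),
      c(sh_start + w_sh, fr_start + w_fr),
      name = c(rep("shared", n_shared), rep("free", n_free)),
      label = "mecp2_peaks", layout = cfg$layout)
    true_group <- rep("group1", n_nuc)
    true_group[shared_sorted] <- "group2"
    structure(list(nucleosomes = nucleosomes, mecp2_peaks = peaks,
                   true_group = c(true_group,
                                  rep("group3",
                                      sum(peaks$name == "free"))),
                   n_shared = n_shared, n_free = n_free),
              class = "occupancy_truth")
  })
}

#' @export
print.occupancy_truth <- function(x, ...) {
  cat("<occupancy_truth> ", nrow(x$nucleosomes), " nucleosomes (",
      x$n_shared, " shared), ", nrow(x$mecp2_peaks), " peaks (",
      x$n_free, " free)\n", sep = "")
  invisible(x)
}

# Closed-form calibration of the latent-Gaussian copula: choose the latent
# normal correlation so that the PLANTED value is the expected Pearson r on
# the Poisson counts. Two exact steps: (i) invert the log-normal moment
# identity corr(lambda_i, lambda_j) = (exp(rho_lat sigma^2) - 1) /
# (exp(sigma^2) - 1); (ii) divide out the Poisson attenuation
# a = sqrt(Var(lambda) / (Var(lambda) + E lambda)) of each track.
latent_rho <- function(r_target, sigma, mu_count) {
  if (r_target == 0) return(0)
  ev2 <- exp(sigma^2) - 1
  v <- mu_count^2 * ev2
  a <- sqrt(v / (v + mu_count))
  r_int <- r_target / (a * a)
  if (abs(r_int) > 1)
    stop("target correlation unreachable at this depth/sigma; ",
         "increase depth or sigma_log")
  rho <- log(1 + r_int * ev2) / sigma^2
  if (abs(rho) > 1)
    stop("target correlation unreachable: latent rho out of [-1, 1]")
  rho
}

#' Simulate correlated mark count tracks
#'
#' Per-bin log-intensities are a shared latent Gaussian field whose
#' correlation is calibrated in closed form so the *counts* carry the
#' configured Pearson correlations; counts are then drawn
#' Poisson(depth-scaled intensity). When an `occupancy_truth` is supplied,
#' protein-peak bins receive a log-intensity boost in the protein layer
#' (planted peak signal on top of the correlated background).
#'
#' @param cfg a `sim_config`.
#' @param truth optional `occupancy_truth` from [simulate_occupancy()].
#' @param boost log-intensity increment added at peak bins when `truth` is
#'   given (default 1).
#' @return A list with `tracks` (named list of count `binned_track`s) and
#'   `mapped_reads` (named total counts per mark).
#' @export
simulate_tracks <- function(cfg, truth = NULL, boost = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  nb <- n_bins(cfg$layout, cfg$bin_size)
  total_bins <- sum(nb)
  mu_count <- cfg$depth / total_bins
  k <- length(cfg$marks)
  rho_lat <- diag(k)
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
    rho_lat[i, j] <- latent_rho(cfg$rho[i, j], cfg$sigma_log, mu_count)
  ch <- tryCatch(chol(rho_lat), error = function(e)
    stop("calibrated latent correlation matrix is not positive definite"))
  with_seed(cfg$seed + 2L, {
    zmat <- matrix(stats::rnorm(total_bins * k), total_bins, k) %*% ch
    tracks <- list()
    reads <- numeric(k)
    for (m in seq_len(k)) {
      logint <- cfg$sigma_log * zmat[, m] - cfg$sigma_log^2 / 2
      if (!is.null(truth) && cfg$marks[m] == "MeCP2")
        logint <- logint + boost * peak_bin_indicator(cfg, truth)
      lambda <- mu_count * exp(logint)
      counts <- stats::rpois(total_bins, lambda)
      vals <- split(counts, rep(seq_along(nb), nb))
      names(vals) <- cfg$layout$chrom_names
      tracks[[cfg$marks[m]]] <- binned_track(cfg$layout, cfg$bin_size,
                                             vals, label = cfg$marks[m])
      reads[m] <- sum(counts)
    }
    list(tracks = tracks,
         mapped_reads = stats::setNames(reads, cfg$marks))
  })
}

# 0/1 genome-wide bin vector marking protein-peak bins
peak_bin_indicator <- function(cfg, truth) {
  nb <- n_bins(cfg$layout, cfg$bin_size)
  ind <- numeric(sum(nb))
  offset <- c(0, cumsum(nb))[seq_along(nb)]
  names(offset) <- names(nb)
  pk <- truth$mecp2_peaks
  for (i in seq_len(nrow(pk))) {
    b0 <- floor(pk$start[i] / cfg$bin_size)
    b1 <- floor((pk$end[i] - 1) / cfg$bin_size)
    ind[offset[pk$chrom[i]] + (b0:b1) + 1] <- 1
  }
  ind
}

#' Simulate a spike-in (ChIP-Rx) two-condition experiment
#'
#' Control and treated share one latent intensity field; the treated
#' intensity is globally scaled by `cfg$global_factor` before Poisson
#' sampling, emulating a genuine genome-wide enrichment shift. Spike-in
#' reads are drawn independently of the target-genome scaling (the
#' exogenous material is added per cell, so its recovery does not follow
#' the target shift). Consequently RRPM normalization recovers the true
#' ratio while plain RPM cancels it.
#'
#' @param cfg a `sim_config` (set `global_factor` to the planted ratio).
#' @param truth optional `occupancy_truth`; when given, peak bins carry a
#'   log-intensity `boost` in both conditions (planted enriched loci).
#' @param boost log-intensity increment at peak bins (default 1).
#' @return A list of per-condition lists (`control`, `treated`), each with
#'   `track` (count `binned_track`), `target_reads`, `spikein_reads`.
#' @export
simulate_spikein_experiment <- function(cfg, truth = NULL, boost = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  nb <- n_bins(cfg$layout, cfg$bin_size)
  total_bins <- sum(nb)
  mu_count <- cfg$depth / total_bins
  with_seed(cfg$seed + 3L, {
    z <- stats::rnorm(total_bins)
    logint <- cfg$sigma_log * z - cfg$sigma_log^2 / 2
    if (!is.null(truth))
      logint <- logint + boost * peak_bin_indicator(cfg, truth)
    lambda <- mu_count * exp(logint)
    make <- function(scale, label) {
      counts <- stats::rpois(total_bins, lambda * scale)
      vals <- split(counts, rep(seq_along(nb), nb))
      names(vals) <- cfg$layout$chrom_names
      list(track = binned_track(cfg$layout, cfg$bin_size, vals,
                                label = label),
           target_reads = sum(counts),
           spikein_reads = stats::rpois(1, cfg$spikein_depth))
    }
    list(control = make(1, "control"),
         treated = make(cfg$global_factor, "treated"))
  })
}

#' Simulate a per-cytosine methylation table over occupancy loci
#'
#' Scatters cytosine sites in the truth loci (CpG denser than CAG/CAH by
#' configuration), draws per-site methylation levels from
#' Beta(mean, concentration) parameterised per (group, context), and
#' methylated counts Binomial(coverage, level) with coverage >= 1
#' enforced.
#'
#' @param cfg a `sim_config`.
#' @param truth an `occupancy_truth`.
#' @param loci_per_group number of loci sampled per group (default 1000;
#'   capped at group size).
#' @return A list with `table` (a `methylation_table`) and `loci` (named
#'   list of per-group `region_set`s used).
#' @export
simulate_methylation <- function(cfg, truth, loci_per_group = 1000) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "occupancy_truth"))
  groups <- list(
    group1 = region_subset(truth$nucleosomes,
                           which(truth$true_group[
                             seq_len(nrow(truth$nucleosomes))] == "group1")),
    group2 = region_subset(truth$nucleosomes,
                           which(truth$true_group[
                             seq_len(nrow(truth$nucleosomes))] == "group2")),
    group3 = region_subset(truth$mecp2_peaks,
                           which(truth$mecp2_peaks$name == "free")))
  with_seed(cfg$seed + 4L, {
    rows <- list()
    loci <- list()
    for (g in names(groups)) {
      rs <- groups[[g]]
      n_take <- min(loci_per_group, nrow(rs))
      rs <- region_subset(rs, sample.int(nrow(rs), n_take))
      loci[[g]] <- set_label(rs, g)
      for (ctx in names(cfg$meth_sites_per_locus)) {
        n_sites <- stats::rpois(n_take, cfg$meth_sites_per_locus[ctx]) + 1
        locus_idx <- rep(seq_len(n_take), n_sites)
        pos <- floor(rs$start[locus_idx] +
                       stats::runif(length(locus_idx)) *
                       (rs$end[locus_idx] - rs$start[locus_idx]))
        m0 <- cfg$meth_beta[[ctx]][g]
        conc <- cfg$meth_concentration
        level <- stats::rbeta(length(pos), m0 * conc, (1 - m0) * conc)
        coverage <- 1 + stats::rpois(length(pos),
                                     cfg$meth_coverage - 1)
        rows[[paste(g, ctx)]] <- data.frame(
          chrom = rs$chrom[locus_idx], pos = pos, context = ctx,
          methylated = stats::rbinom(length(pos), coverage, level),
          total = coverage, stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    # distinct site positions per chromosome/context (duplicates pooled)
    df <- df[!duplicated(df[, c("chrom", "pos", "context")]), ]
    list(table = methylation_table(df$chrom, df$pos, df$context,
                                   df$methylated, df$total),
         loci = loci)
  })
}

# smooth cluster templates over the TSS window; values in [0, 1] units of
# template_amplitude. Shapes: cluster 1 = protein+repressive mark across
# TSS and gene body, no acetylation; cluster 2 = same plus acetylation
# peak at the TSS; cluster 3 = all three marks confined to the TSS.
cluster_templates <- function(offsets) {
  tss_peak <- exp(-(offsets)^2 / (2 * 500^2))
  body <- 1 / (1 + exp(-(offsets + 200) / 200)) # ramps up into the body
  list(
    MeCP2 = rbind(cluster1 = body, cluster2 = body, cluster3 = tss_peak),
    H3K27me3 = rbind(cluster1 = body, cluster2 = body,
                     cluster3 = tss_peak),
    H3K9ac = rbind(cluster1 = 0 * offsets, cluster2 = tss_peak,
                   cluster3 = tss_peak))
}

#' Simulate genes, cluster-structured TSS signal and expression
#'
#' Places genes on the toy genome, assigns each a planted cluster, writes
#' cluster-specific mark templates (plus log-normal noise) into
#' per-mark tracks around each TSS, and draws replicate expression values
#' whose cluster medians are ordered cluster3 > cluster2 > cluster1.
#' Knockout (KO) replicates up-shift a planted per-cluster fraction of
#' genes by `ko_effect`. A differential-expression table (signed fold
#' change + Welch-test BH FDR across replicates) is derived from the
#' simulated replicates.
#'
#' @param cfg a `sim_config`. The gene tracks use a 100 bp bin size and a
#'   genome layout stretched to fit `n_genes` (returned in the result).
#' @return A list of class `genes_sim` with `genes` (a `gene_model`),
#'   `true_cluster`, `tracks` (named list of mark `binned_track`s),
#'   `expression` (gene x replicate RPKM data frame), `de_stats`
#'   (gene, fold_change, fdr), `true_ko_up` (planted up-shifted genes),
#'   `layout`.
#' @export
simulate_genes_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  bin <- 100
  spacing <- 14000
  n <- cfg$n_genes
  per_chrom <- ceiling(n / 2)
  chrom_len <- (per_chrom + 1) * spacing + 20000
  layout <- genome_layout(c("chr1", "chr2"), rep(chrom_len, 2))
  with_seed(cfg$seed + 5L, {
    idx <- seq_len(n)
    chrom <- ifelse(idx <= per_chrom, "chr1", "chr2")
    slot <- ifelse(idx <= per_chrom, idx, idx - per_chrom)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    tss <- slot * spacing
    glen <- round(stats::runif(n, 2000, 8000))
    tes <- ifelse(strand == "+", tss + glen, tss - glen)
    genes <- gene_model(sprintf("gene%04d", idx), chrom, strand, tss, tes,
                        layout = layout)
    truec <- sample.int(3, n, replace = TRUE, prob = cfg$cluster_props)
    names(truec) <- genes$gene_id
    offsets <- seq(-1000, 5000, by = bin)
    tmpl <- cluster_templates(offsets)
    tracks <- list()
    for (mk in names(tmpl)) {
      tr <- binned_track(layout, bin, label = mk)
      for (i in seq_len(n)) {
        shape <- tmpl[[mk]][truec[i], ]
        noise <- stats::rnorm(length(offsets), 0, cfg$template_noise)
        vals <- pmax(0, cfg$template_amplitude * shape + noise)
        off <- if (strand[i] == "-") -offsets else offsets
        b <- floor((tss[i] + off) / bin) + 1
        v <- tr$values[[chrom[i]]]
        v[b] <- v[b] + vals
        tr$values[[chrom[i]]] <- v
      }
      # low uniform background noise everywhere
      tr$values <- lapply(tr$values, function(v)
        v + abs(stats::rnorm(length(v), 0, cfg$template_noise / 3)))
      tracks[[mk]] <- tr
    }
    base_log10 <- cfg$cluster_expr_log10[truec] +
      stats::rnorm(n, 0, cfg$expr_sd_log10)
    ko_up <- unlist(lapply(1:3, function(cl) {
      members <- which(truec == cl)
      sample(members, round(length(members) * cfg$ko_up_frac[cl]))
    }))
    shift <- rep(0, n)
    shift[ko_up] <- log10(cfg$ko_effect)
    reps <- function(center) vapply(1:3, function(r)
      10^(center + stats::rnorm(n, 0, cfg$rep_sd_log10)), numeric(n))
    wt <- reps(base_log10)
    ko <- reps(base_log10 + shift)
    expression <- data.frame(gene = genes$gene_id,
                             wt1 = wt[, 1], wt2 = wt[, 2], wt3 = wt[, 3],
                             ko1 = ko[, 1], ko2 = ko[, 2], ko3 = ko[, 3],
                             stringsAsFactors = FALSE)
    lwt <- log2(wt); lko <- log2(ko)
    pvals <- vapply(seq_len(n), function(i)
      stats::t.test(lko[i, ], lwt[i, ])$p.value, 1.0)
    lfc <- rowMeans(lko) - rowMeans(lwt)
    ratio <- 2^lfc
    de_stats <- data.frame(
      gene = genes$gene_id,
      fold_change = ifelse(ratio >= 1, ratio, -1 / ratio),
      fdr = stats::p.adjust(pvals, "BH"), stringsAsFactors = FALSE)
    structure(list(genes = genes, true_cluster = truec, tracks = tracks,
                   expression = expression, de_stats = de_stats,
                   true_ko_up = genes$gene_id[sort(ko_up)],
                   layout = layout),
              class = "genes_sim")
  })
}

#' Write a full synthetic fixture set to a directory
#'
#' Emits every simulated artifact in the plain-text formats the readers of
#' this package consume (BED, bedGraph, TSV) plus a truth manifest, so a
#' complete downstream run can start from files alone.
#'
#' @param cfg a `sim_config`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  truth <- simulate_occupancy(cfg)
  write_regions(truth$nucleosomes, file.path(outdir, "nucleosomes.bed"))
  write_regions(truth$mecp2_peaks, file.path(outdir, "mecp2_peaks.bed"))
  sim <- simulate_tracks(cfg, truth)
  for (mk in names(sim$tracks))
    write_bedgraph(sim$tracks[[mk]],
                   file.path(outdir, paste0(mk, ".bedGraph")))
  utils::write.table(
    data.frame(sample = names(sim$mapped_reads),
               mapped_reads = as.numeric(sim$mapped_reads)),
    file.path(outdir, "read_counts.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  meth <- simulate_methylation(cfg, truth)
  write_methylation(meth$table, file.path(outdir, "methylation.tsv"))
  utils::write.table(
    data.frame(locus = seq_along(truth$true_group),
               group = truth$true_group),
    file.path(outdir, "truth_groups.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(outdir)
}
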