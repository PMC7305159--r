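make_pair_tracks <- function(control_vals, treated_vals, bin = 100) {
  layout <- genome_layout("chr1", length(control_vals) * bin)
  list(control = binned_track(layout, bin,
                              values = list(chr1 = control_vals)),
       treated = binned_track(layout, bin,
                              values = list(chr1 = treated_vals)),
       layout = layout)
}

test_that("difference classes follow the threshold arithmetic", {
  ctrl <- rep(5, 30)
  trt <- ctrl + c(rep(-0.5, 10), rep(-2, 10), rep(-4, 10))
  tr <- make_pair_tracks(ctrl, trt)
  loci <- region_set("chr1", (0:29) * 100, (0:29) * 100 + 100)
  dc <- difference_classes(tr$control, tr$treated, loci,
                           t_moderate = -1, t_severe = -3)
  expect_equal(as.character(dc$label),
               rep(c("unchanged", "moderate", "severe"), each = 10))
  expect_equal(sum(table(dc$label)), 30)
  expect_error(difference_classes(tr$control, tr$treated, loci,
                                  t_moderate = -3, t_severe = -1),
               "out of order")
})

test_that("difference classes are invariant to a shared constant offset", {
  set.seed(61)
  ctrl <- rpois(50, 10)
  trt <- pmax(0, ctrl + rnorm(50, -1))
  tr <- make_pair_tracks(ctrl, trt)
  tr2 <- make_pair_tracks(ctrl + 100, trt + 100)
  loci <- region_set("chr1", (0:49) * 100, (0:49) * 100 + 100)
  d1 <- difference_classes(tr$control, tr$treated, loci)
  d2 <- difference_classes(tr2$control, tr2$treated, loci)
  expect_equal(d1$delta, d2$delta, tolerance = 1e-12)
  expect_equal(d1$label, d2$label)
})

test_that("quantile mode reproduces the configured class proportions", {
  set.seed(67)
  ctrl <- rpois(2000, 20)
  trt <- rpois(2000, 20) - seq(0, 10, length.out = 2000)
  tr <- make_pair_tracks(ctrl, trt)
  loci <- region_set("chr1", (0:1999) * 100, (0:1999) * 100 + 100)
  dc <- difference_classes(tr$control, tr$treated, loci, mode = "quantile",
                           q_severe = 0.002, q_moderate = 0.049)
  counts <- table(dc$label)
  expect_equal(unname(counts["severe"]), 4, tolerance = 1)
  expect_lte(abs(unname(counts["moderate"]) - (0.049 - 0.002) * 2000), 5)
})

test_that("null spike-in data stays almost entirely 'unchanged'", {
  cfg <- sim_config(seed = 71, global_factor = 1)
  sp <- simulate_spikein_experiment(cfg)
  rr_c <- scale_track(sp$control$track,
                      rrpm_factor(sp$control$spikein_reads))
  rr_t <- scale_track(sp$treated$track,
                      rrpm_factor(sp$treated$spikein_reads))
  set.seed(1)
  loci <- random_regions(500, cfg$layout, max_width = 2000)
  loci <- loci[region_widths(loci) >= 1000, , drop = FALSE]
  dc <- difference_classes(rr_c, rr_t, loci)
  frac_changed <- mean(dc$label != "unchanged")
  expect_lte(frac_changed, 0.05)
})

test_that("depleted high-signal loci fall in moderate/severe classes", {
  cfg <- sim_config(seed = 73, global_factor = 0.4)
  truth <- simulate_occupancy(cfg)
  sp <- simulate_spikein_experiment(cfg, truth = truth, boost = 1.5)
  rr_c <- scale_track(sp$control$track,
                      rrpm_factor(sp$control$spikein_reads))
  rr_t <- scale_track(sp$treated$track,
                      rrpm_factor(sp$treated$spikein_reads))
  peaks <- truth$mecp2_peaks
  set.seed(2)
  bg <- random_regions(1000, cfg$layout, max_width = 500)
  loci <- region_set(c(peaks$chrom, bg$chrom), c(peaks$start, bg$start),
                     c(peaks$end, bg$end), layout = cfg$layout)
  dc <- difference_classes(rr_c, rr_t, loci)
  changed <- dc$label != "unchanged"
  expect_gt(sum(changed), 0)
  # depletion scales with signal, so changed loci have higher mean signal
  expect_gt(suppressWarnings(
    cor(dc$mean_signal, as.integer(changed), method = "spearman")), 0)
  # and the paired test detects genome-wide depletion decisively
  pt <- paired_difference_test(region_mean(rr_c, loci),
                               region_mean(rr_t, loci))
  expect_lt(pt$p_two_tailed, 1e-6)
  expect_lt(pt$median_difference, 0)
})

test_that("paired difference test handles hand-checkable cases", {
  expect_equal(paired_difference_test(c(1, 2, 3),
                                      c(2, 4, 6))$p_two_tailed, 0.25)
  expect_warning(res <- paired_difference_test(c(1, 1), c(1, 1)), "zero")
  expect_equal(res$p_two_tailed, 1)
  expect_error(paired_difference_test(1:3, 1:4), "equal length")
})

test_that("interval-level Venn comparison counts both perspectives", {
  a <- region_set("chr1", c(0, 1000), c(500, 1500))
  b <- region_set("chr1", c(2000, 3000), c(2500, 3500))
  s <- compare_region_sets(a, b)
  expect_equal(s$n_a_shared, 0)
  expect_equal(s$n_b_only, 2)
  # b nested in a: no unique b
  b2 <- region_set("chr1", c(100, 1100), c(200, 1200))
  s2 <- compare_region_sets(a, b2)
  expect_equal(s2$n_b_only, 0)
  expect_equal(s2$n_a_shared, 2)
  # one a interval can absorb several b intervals: shared counts differ
  a3 <- region_set("chr1", 0, 1000)
  b3 <- region_set("chr1", c(10, 500), c(20, 600))
  s3 <- compare_region_sets(a3, b3)
  expect_equal(s3$n_a_shared, 1)
  expect_equal(s3$n_b_only, 0)
})

test_that("windowed DMR calling finds planted differences only", {
  layout <- genome_layout("chr1", 10000)
  mk <- function(pos, meth, tot) {
    methylation_table(rep("chr1", length(pos)), pos,
                      rep("CpG", length(pos)), meth, tot)
  }
  pos <- c(100, 200, 300, 400, 450, 5100, 5200, 5300, 5350, 5400)
  a <- mk(pos, meth = rep(8, 10), tot = rep(10, 10))
  expect_equal(nrow(window_dmrs(a, a, layout)), 0)
  # plant an 80% drop in the second window only
  b <- mk(pos, meth = c(rep(8, 5), rep(0, 5)), tot = rep(10, 10))
  dmrs <- window_dmrs(a, b, layout, window_bp = 500, min_sites = 3,
                      min_cov = 4, min_delta = 0.25)
  expect_equal(nrow(dmrs), 1)
  expect_equal(dmrs$start, 5000)
  expect_equal(dmrs$end, 5500)
  expect_equal(dmrs$score, -0.8, tolerance = 1e-12)
  # low-coverage sites are ignored
  c_tab <- mk(pos, meth = c(rep(8, 5), rep(0, 5)),
              tot = c(rep(10, 5), rep(2, 5)))
  expect_equal(nrow(window_dmrs(a, c_tab, layout)), 0)
})

test_that("planted methylation reductions are recovered across windows", {
  set.seed(79)
  layout <- genome_layout("chr1", 100000)
  win_starts <- seq(0, 49) * 2000 # one planted site cluster every 2 kb
  pos <- unlist(lapply(win_starts, function(s) s + c(50, 150, 250, 350)))
  tot <- rep(10, length(pos))
  base_level <- 0.8
  a <- methylation_table(rep("chr1", length(pos)), pos,
                         rep("CpG", length(pos)),
                         rbinom(length(pos), 10, base_level), tot)
  # 81% relative reduction in methylation
  b <- methylation_table(rep("chr1", length(pos)), pos,
                         rep("CpG", length(pos)),
                         rbinom(length(pos), 10, base_level * 0.19), tot)
  dmrs <- window_dmrs(a, b, layout, window_bp = 500, min_sites = 3,
                      min_cov = 4, min_delta = 0.25)
  # each planted 400 bp cluster sits in one 500 bp window
  expect_gte(nrow(dmrs), 45)
  expect_true(all(dmrs$score < 0))
})

test_that("DE gene selection applies strict thresholds", {
  stats <- data.frame(
    gene = paste0("g", 1:5),
    fold_change = c(1.5, -1.4, -1.31, 1.3, 2),
    fdr = c(0.01, 0.2, 0.049, 0.01, 0.05))
  sel <- select_de_genes(stats)
  expect_equal(sel$up, "g1")     # g4 fails fc > 1.3 strictly
  expect_equal(sel$down, "g3")   # g2 fails fdr, g5 fails fdr strictly
  expect_length(intersect(sel$up, sel$down), 0)
  expect_error(select_de_genes(data.frame(gene = "a")), "columns")
})
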