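sim_genes_fixture <- function(seed = 11, ...) {
  simulate_genes_expression(sim_config(seed = seed, ...))
}

test_that("signal matrix rows reproduce the underlying windows", {
  layout <- genome_layout("chr1", 100000)
  const <- binned_track(layout, 100,
                        values = list(chr1 = rep(3, 1000)), label = "m")
  genes <- gene_model(c("g1", "g2"), "chr1", c("+", "-"),
                      tss = c(20000, 60000), tes = c(30000, 50000),
                      layout = layout)
  m <- build_signal_matrix(list(m = const), genes, scale_layers = FALSE)
  expect_equal(dim(m$layers$m), c(2, 61))
  expect_true(all(m$layers$m == 3))
  # single gene: matrix equals its (strand-flipped) window
  v <- numeric(1000); v[591:600] <- 10 # 59000-60000, upstream of g2's TSS
  tr <- binned_track(layout, 100, values = list(chr1 = v), label = "m")
  m2 <- build_signal_matrix(list(m = tr), genes[2, ], scale_layers = FALSE)
  # for the minus-strand gene those bases are DOWNSTREAM (positive offsets)
  expect_true(all(m2$layers$m[1, m2$offsets > 0 & m2$offsets <= 1000] == 10))
  expect_true(all(m2$layers$m[1, m2$offsets < 0] == 0))
})

test_that("out-of-bounds genes are dropped with a message", {
  layout <- genome_layout("chr1", 100000)
  tr <- binned_track(layout, 100, values = list(chr1 = rep(1, 1000)))
  genes <- gene_model(c("ok", "edge"), "chr1", c("+", "+"),
                      tss = c(50000, 500), tes = c(60000, 6000),
                      layout = layout)
  expect_message(m <- build_signal_matrix(list(m = tr), genes), "dropping")
  expect_equal(m$gene_ids, "ok")
  bad <- gene_model("b", "chr1", "+", tss = 200, tes = 5000,
                    layout = layout)
  expect_error(build_signal_matrix(list(m = tr), bad), "no usable genes")
})

test_that("SuperSOM is deterministic and respects k", {
  gs <- sim_genes_fixture(seed = 83, n_genes = 300)
  m <- build_signal_matrix(gs$tracks, gs$genes)
  ca1 <- supersom_cluster(m, epochs = 20, seed = 4)
  ca2 <- supersom_cluster(m, epochs = 20, seed = 4)
  expect_identical(ca1$cluster, ca2$cluster)
  expect_identical(ca1$codebooks, ca2$codebooks)
  one <- supersom_cluster(m, k = 1, epochs = 5, seed = 4)
  expect_true(all(one$cluster == 1))
  expect_error(supersom_cluster(m, k = 99, seed = 1), "k must")
})

test_that("SuperSOM recovers planted clusters (noisy and near-noiseless)", {
  skip_if_not_installed("mclust")
  gs <- sim_genes_fixture(seed = 11) # default noise, 1500 genes
  m <- build_signal_matrix(gs$tracks, gs$genes)
  ca <- supersom_cluster(m, seed = 5)
  ari <- mclust::adjustedRandIndex(ca$cluster,
                                   gs$true_cluster[names(ca$cluster)])
  expect_gte(ari, 0.9)
  # near-zero template noise: recovery is exact
  gs0 <- sim_genes_fixture(seed = 13, n_genes = 300,
                           template_noise = 1e-6)
  m0 <- build_signal_matrix(gs0$tracks, gs0$genes)
  ca0 <- supersom_cluster(m0, epochs = 30, seed = 5)
  expect_equal(mclust::adjustedRandIndex(
    ca0$cluster, gs0$true_cluster[names(ca0$cluster)]), 1.0)
})

test_that("cluster expression recovers the planted ordering", {
  gs <- sim_genes_fixture(seed = 17, n_genes = 600)
  m <- build_signal_matrix(gs$tracks, gs$genes)
  ca <- supersom_cluster(m, epochs = 30, seed = 6)
  ce <- cluster_expression(gs$expression[, c("gene", "wt1", "wt2", "wt3")],
                           ca)
  expect_equal(length(ce$values), 3)
  expect_true(all(ce$comparisons$p_adjusted <= 1))
  # identical expression everywhere gives p = 1 on every pair
  flat <- gs$expression
  flat[, 2:7] <- 1
  ce_flat <- cluster_expression(flat, ca)
  expect_true(all(ce_flat$comparisons$p_two_tailed == 1))
})

test_that("cluster expression orders medians like the planted truth", {
  gs <- sim_genes_fixture(seed = 19)
  lv <- log10(rowMeans(gs$expression[, c("wt1", "wt2", "wt3")]))
  by_true <- split(lv, gs$true_cluster)
  expect_lt(median(by_true[[1]]), median(by_true[[2]]))
  expect_lt(median(by_true[[2]]), median(by_true[[3]]))
  cmp <- compare_groups(by_true)
  # the low-expression cluster separates decisively from the other two;
  # clusters 2 and 3 are planted much closer and only the direction is
  # asserted above
  expect_lt(max(cmp$p_adjusted[cmp$group_a == "1"]), 1e-6)
})

test_that("GSEA matches the hand-computed running sum", {
  stats <- c(a = 5, b = 4, c = 3, d = 2, e = 1)
  # top-2 set, unweighted: +1/2, +1 then only misses -> ES = 1
  expect_equal(gsea_score(stats, c("a", "b"), weight_p = 0,
                          n_perm = 0)$es, 1)
  # bottom-2 set, unweighted: running sum dips to -1 at position 3
  expect_equal(gsea_score(stats, c("d", "e"), weight_p = 0,
                          n_perm = 0)$es, -1)
  # whole-list set: ES = 1 by convention
  expect_equal(gsea_score(stats, names(stats), n_perm = 0)$es, 1)
  # weighted case, hand-derived: hits a (w 5/8) and c (w 3/8)
  es <- gsea_score(stats, c("a", "c"), weight_p = 1, n_perm = 0)$es
  expect_equal(es, 5 / 8 - 1 / 3 + 3 / 8) # peak after the hit at rank 3
  expect_error(gsea_score(stats, character()), "empty")
  expect_error(gsea_score(stats, "zzz"), "absent")
})

test_that("GSEA ES is invariant to positive rescaling when unweighted", {
  set.seed(89)
  stats <- setNames(rnorm(100), paste0("g", 1:100))
  set <- sample(names(stats), 15)
  e1 <- gsea_score(stats, set, weight_p = 0, n_perm = 0)$es
  e2 <- gsea_score(stats * 37.5, set, weight_p = 0, n_perm = 0)$es
  expect_equal(e1, e2)
})

test_that("GSEA null p-values are uniform for random sets", {
  set.seed(97)
  ps <- replicate(100, {
    stats <- setNames(rnorm(200), sprintf("g%03d", 1:200))
    gene_set <- sample(names(stats), 10)
    gsea_score(stats, gene_set, weight_p = 1, n_perm = 200,
               seed = sample.int(1e6, 1))$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("GSEA detects a planted shifted set with high NES", {
  set.seed(101)
  stats <- setNames(rnorm(300), sprintf("g%03d", 1:300))
  hot <- sample(names(stats), 20)
  stats[hot] <- stats[hot] + 2.5
  res <- gsea_score(stats, hot, weight_p = 1, n_perm = 500, seed = 7)
  expect_gt(res$es, 0.5)
  expect_gt(res$nes, 1.5)
  expect_lt(res$p, 0.01)
  expect_equal(res$direction, "up")
})

test_that("permutation association is deterministic and calibrated", {
  layout <- tiny_layout(5e5, 2)
  set.seed(103)
  ann <- random_regions(300, layout, max_width = 1000)
  q <- random_regions(150, layout, max_width = 500)
  r1 <- region_association_z(q, ann, layout, n_perm = 200, seed = 11)
  r2 <- region_association_z(q, ann, layout, n_perm = 200, seed = 11)
  expect_identical(r1$z, r2$z)
  expect_equal(r1$observed_overlap,
               length(unique(overlap_pairs(q, ann)$a_idx)))
  # strong planted association: query equals annotation
  self <- region_association_z(ann, ann, layout, n_perm = 200, seed = 12)
  expect_gt(self$z, 10)
  expect_lt(self$p_empirical, 0.01)
  expect_error(region_association_z(q, ann, layout, n_perm = 10, seed = 1),
               ">= 100")
})

test_that("permutation z is null-calibrated over replicate datasets", {
  layout <- tiny_layout(2e5, 2)
  set.seed(107)
  zs <- replicate(60, {
    ann <- random_regions(200, layout, max_width = 800)
    q <- random_regions(100, layout, max_width = 400)
    region_association_z(q, ann, layout, n_perm = 120,
                         seed = sample.int(1e6, 1))$z
  })
  expect_lt(abs(mean(zs)), 0.35) # ~2.7 SE of the replicate mean
  expect_gt(sd(zs), 0.8)
  expect_lt(sd(zs), 1.2)
})

test_that("enhancer derivation is a three-way intersection", {
  layout <- tiny_layout(50000, 1)
  dhs <- region_set("chr1", c(1000, 10000, 20000),
                    c(1500, 10500, 20500), label = "dhs")
  k4 <- region_set("chr1", c(1200, 20100), c(1600, 20200))
  k27 <- region_set("chr1", c(900, 10100), c(1100, 10600))
  enh <- derive_enhancers(dhs, k4, k27)
  expect_equal(enh$start, 1000) # only the first DHS has both marks
  # identical inputs: everything qualifies
  expect_equal(nrow(derive_enhancers(dhs, dhs, dhs)), 3)
  # disjoint marks: nothing qualifies
  far <- region_set("chr1", 40000, 41000)
  expect_equal(nrow(derive_enhancers(dhs, far, far)), 0)
  mids <- region_midpoints(enh)
  expect_equal(mids$pos, 1250)
})

test_that("enhancer derivation equals a brute-force triple scan", {
  set.seed(109)
  layout <- tiny_layout(20000, 2)
  dhs <- random_regions(80, layout, max_width = 400)
  k4 <- random_regions(120, layout, max_width = 600)
  k27 <- random_regions(120, layout, max_width = 600)
  got <- derive_enhancers(dhs, k4, k27)
  keep <- vapply(seq_len(nrow(dhs)), function(i) {
    hit <- function(rs) any(rs$chrom == dhs$chrom[i] &
                              pmin(rs$end, dhs$end[i]) -
                              pmax(rs$start, dhs$start[i]) >= 1)
    hit(k4) && hit(k27)
  }, TRUE)
  expect_equal(as.data.frame(got)[c("start", "end")],
               as.data.frame(dhs[keep, , drop = FALSE])[c("start", "end")],
               ignore_attr = TRUE)
})
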