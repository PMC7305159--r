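test_that("RPM and RRPM factors follow the 1e6/reads definition", {
  expect_equal(rpm_factor(1e6)$factor, 1)
  expect_equal(rpm_factor(2e6)$factor, 0.5)
  f <- rpm_factor(38456123)
  expect_equal(f$factor * f$source_reads, 1e6)
  expect_equal(f$kind, "RPM")
  expect_equal(rrpm_factor(1e6)$factor, 1)
  expect_equal(rrpm_factor(5e5)$factor, 2)
  expect_error(rpm_factor(0), "> 0")
  expect_error(rrpm_factor(-5), "> 0")
})

test_that("RRPM scaling depends only on spike-in reads", {
  layout <- tiny_layout(1000, 1)
  tr <- binned_track(layout, 100, values = list(chr1 = rep(4, 10)))
  a <- scale_track(tr, rrpm_factor(1e6))
  b <- scale_track(tr, rrpm_factor(2e6))
  expect_equal(b$values$chr1, a$values$chr1 / 2)
})

test_that("scale_track is multiplicative and invertible", {
  layout <- tiny_layout(1000, 1)
  set.seed(2)
  tr <- binned_track(layout, 100, values = list(chr1 = rpois(10, 5)))
  expect_equal(scale_track(tr, rpm_factor(1e6))$values, tr$values)
  half <- scale_track(tr, rpm_factor(2e6))
  expect_equal(half$values$chr1, tr$values$chr1 * 0.5)
  back <- scale_track(half, rrpm_factor(5e5))
  expect_equal(back$values$chr1, tr$values$chr1, tolerance = 1e-12)
})

test_that("z-transform uses the population SD and handles constants", {
  expect_equal(z_transform(c(1, 2, 3)),
               c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
  expect_warning(z <- z_transform(c(5, 5, 5)), "constant")
  expect_equal(z, c(0, 0, 0))
  set.seed(3)
  x <- rnorm(100)
  expect_lt(abs(mean(z_transform(x))), 1e-12)
  expect_equal(sqrt(mean(z_transform(x)^2)), 1, tolerance = 1e-12)
  expect_error(z_transform(1), "at least 2")
})

test_that("binned correlation has unit diagonal and detects sign", {
  layout <- tiny_layout(10000, 1)
  set.seed(5)
  v <- rpois(100, 20)
  t1 <- binned_track(layout, 100, values = list(chr1 = v), label = "a")
  t2 <- binned_track(layout, 100, values = list(chr1 = max(v) - v),
                     label = "b")
  cm <- binned_correlation(list(a = t1, b = t2))
  expect_equal(diag(cm$r), c(a = 1, b = 1))
  expect_equal(cm$r["a", "b"], -1)
  expect_equal(cm$r, t(cm$r))
  # invariance to positive rescaling of one track
  cm2 <- binned_correlation(list(a = scale_track(t1, rpm_factor(3e6)),
                                 b = t2))
  expect_equal(cm2$r["a", "b"], cm$r["a", "b"], tolerance = 1e-12)
})

test_that("correlation rebinning mean-aggregates finer tracks", {
  layout <- tiny_layout(1000, 1)
  set.seed(6)
  fine <- binned_track(layout, 100, values = list(chr1 = rnorm(10, 10)),
                       label = "fine")
  agg <- histocc:::rebin_track(fine, 200)
  expect_equal(agg$values$chr1,
               colMeans(matrix(fine$values$chr1, nrow = 2)))
  cm <- binned_correlation(list(a = fine, b = fine), bin_size = 200)
  expect_equal(cm$n_bins_used, 5)
})

test_that("aggregate profiles are strand-aware with per-offset SD", {
  layout <- tiny_layout(10000, 1)
  const <- binned_track(layout, 100,
                        values = list(chr1 = rep(7, 100)))
  anchors <- data.frame(chrom = "chr1", pos = c(2000, 5000))
  pr <- aggregate_profile(const, anchors, upstream = 500, downstream = 500)
  expect_true(all(pr$mean == 7))
  expect_true(all(pr$sd == 0))
  # single anchor reproduces its window
  v <- numeric(100); v[21:30] <- 1:10
  tr <- binned_track(layout, 100, values = list(chr1 = v))
  one <- aggregate_profile(tr, data.frame(chrom = "chr1", pos = 2500),
                           upstream = 400, downstream = 400)
  expect_equal(one$mean, v[22:30])
  expect_true(all(one$sd == 0))
  # minus-strand windows are flipped: offset +400 reads 400 bp to the LEFT
  # of a minus-strand anchor
  minus <- aggregate_profile(tr, data.frame(chrom = "chr1", pos = 2900,
                                            strand = "-"),
                             upstream = 400, downstream = 400)
  expect_equal(minus$mean, rev(v[26:34]))
})

test_that("aggregate profile drops out-of-bounds anchors and errors on none", {
  layout <- tiny_layout(10000, 1)
  tr <- binned_track(layout, 100, values = list(chr1 = rep(1, 100)))
  pr <- aggregate_profile(tr, data.frame(chrom = "chr1", pos = c(50, 5000)),
                          upstream = 1000, downstream = 1000)
  expect_equal(pr$n_anchors, 1)
  expect_error(
    aggregate_profile(tr, data.frame(chrom = "chr1", pos = 50),
                      upstream = 1000, downstream = 1000), "anchors")
})

test_that("aggregate profile peaks at the anchor for planted signal", {
  layout <- tiny_layout(50000, 1)
  set.seed(8)
  v <- rnorm(500, 1, 0.05)
  anchors_pos <- c(10000, 20000, 30000, 40000)
  for (p in anchors_pos) {
    b <- p / 100 + 1
    v[(b - 3):(b + 3)] <- v[(b - 3):(b + 3)] + dnorm(-3:3, 0, 1.5) * 10
  }
  tr <- binned_track(layout, 100, values = list(chr1 = v))
  pr <- aggregate_profile(tr, data.frame(chrom = "chr1", pos = anchors_pos),
                          upstream = 2000, downstream = 2000)
  expect_lte(abs(pr$offsets[which.max(pr$mean)]), 100)
  # z-transformed profile has mean ~0
  prz <- aggregate_profile(tr, data.frame(chrom = "chr1",
                                          pos = anchors_pos),
                           upstream = 2000, downstream = 2000, z = TRUE)
  expect_lt(abs(mean(prz$mean)), 1e-10)
})

test_that("region means are base-weighted and match a per-base oracle", {
  layout <- tiny_layout(1000, 1)
  uni <- binned_track(layout, 100, values = list(chr1 = rep(4, 10)))
  rs <- region_set("chr1", c(0, 300), c(100, 450))
  expect_equal(region_mean(uni, rs), c(4, 4))
  expect_equal(region_mean(uni, rs, log2 = TRUE, pseudocount = 0), c(2, 2))
  two <- binned_track(layout, 100,
                      values = list(chr1 = c(3, 5, rep(0, 8))))
  expect_equal(region_mean(two, region_set("chr1", 50, 150)), 4)
  # random oracle
  set.seed(9)
  v <- rpois(10, 6)
  tr <- binned_track(layout, 100, values = list(chr1 = v))
  base <- rep(v, each = 100)
  rr <- random_regions(20, layout, max_width = 300)
  expected <- vapply(seq_len(nrow(rr)), function(i)
    mean(base[(rr$start[i] + 1):rr$end[i]]), 1.0)
  expect_equal(region_mean(tr, rr), expected, tolerance = 1e-12)
  expect_equal(region_mean(tr, region_set(character(), numeric(),
                                          numeric())), numeric())
})

test_that("input normalization is a pseudocounted log2 ratio", {
  layout <- tiny_layout(1000, 1)
  ip <- binned_track(layout, 100, values = list(chr1 = c(7, 0, rep(1, 8))))
  input <- binned_track(layout, 100,
                        values = list(chr1 = c(3, 0, rep(1, 8))))
  ln <- input_normalize(ip, input, pseudocount = 1)
  expect_equal(ln$values$chr1[1], 1) # log2(8/4)
  expect_equal(ln$values$chr1[2], 0) # empty bins stay finite at 0
  expect_error(input_normalize(ip, binned_track(layout, 50)), "bin size")
})

test_that("gene-anchored region schemes honor strand", {
  layout <- tiny_layout(100000, 1)
  genes <- gene_model(c("gp", "gm"), "chr1", c("+", "-"),
                      tss = c(20000, 50000), tes = c(28000, 42000),
                      layout = layout)
  tss <- derive_gene_regions(genes, "tss", layout)
  expect_equal(tss$start[tss$name == "gp"], 19000)
  expect_equal(tss$end[tss$name == "gp"], 21000)
  expect_equal(tss$start[tss$name == "gm"], 49000)
  body <- derive_gene_regions(genes, "body", layout)
  expect_equal(body$start[body$name == "gp"], 21000)
  expect_equal(body$end[body$name == "gp"], 30000)
  expect_equal(body$start[body$name == "gm"], 40000) # runs 3'-ward
  expect_equal(body$end[body$name == "gm"], 49000)
  prox <- derive_gene_regions(genes, "proximal", layout)
  expect_equal(nrow(prox), 4) # two flanks per gene
  gp <- prox[prox$name == "gp", ]
  expect_equal(gp$start, c(14000, 28000))
  expect_equal(gp$end, c(19000, 33000))
})
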