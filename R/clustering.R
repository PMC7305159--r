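#' Build a TSS-proximal multi-mark signal matrix
#'
#' For every gene and every offset in `[-upstream, +downstream]` (step
#' `step` bp, strand-aware so positive offsets run into the gene body),
#' records the signal of each mark track at that position, yielding one
#' genes x offsets matrix per mark layer. Genes whose window leaves the
#' chromosome are dropped with a message. Layers are optionally z-scaled
#' (global mean/SD per layer) so that marks with different dynamic ranges
#' contribute comparably to downstream clustering.
#'
#' @param tracks a named list of `binned_track`s (one per mark).
#' @param genes a `gene_model`.
#' @param upstream,downstream window extent in bp (defaults 1000 / 5000).
#' @param step offset spacing in bp (default: common track bin size).
#' @param scale_layers z-scale each layer (default `TRUE`).
#' @return An object of class `signal_matrix` with fields `gene_ids`,
#'   `offsets`, `layers` (named list of matrices), `layer_labels`.
#' @export
build_signal_matrix <- function(tracks, genes, upstream = 1000,
                                downstream = 5000, step = NULL,
                                scale_layers = TRUE) {
  if (!length(tracks)) stop("no tracks supplied")
  if (is.null(names(tracks)) || any(!nzchar(names(tracks))))
    names(tracks) <- vapply(tracks, function(t) t$label, "")
  t1 <- tracks[[1]]
  if (is.null(step)) step <- t1$bin_size
  offsets <- seq(-upstream, downstream, by = step)
  len <- chrom_length(t1$layout, genes$chrom)
  minus <- genes$strand == "-"
  lo <- ifelse(minus, genes$tss - downstream, genes$tss - upstream)
  hi <- ifelse(minus, genes$tss + upstream, genes$tss + downstream)
  keep <- lo >= 0 & hi < len
  if (!any(keep)) stop("no usable genes: all windows leave the chromosome")
  if (any(!keep))
    message("dropping ", sum(!keep), " gene(s) with out-of-bounds windows")
  genes <- genes[keep, , drop = FALSE]
  minus <- minus[keep]
  layers <- lapply(tracks, function(track) {
    m <- matrix(NA_real_, nrow(genes), length(offsets))
    for (i in seq_len(nrow(genes))) {
      off <- if (minus[i]) -offsets else offsets
      m[i, ] <- track_value_at(track, genes$chrom[i], genes$tss[i] + off)
    }
    rownames(m) <- genes$gene_id
    m
  })
  if (scale_layers)
    layers <- lapply(layers, function(m) {
      s <- stats::sd(as.vector(m))
      if (s == 0) m - mean(m) else (m - mean(m)) / s
    })
  structure(list(gene_ids = genes$gene_id, offsets = offsets,
                 layers = layers, layer_labels = names(tracks)),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("<signal_matrix> ", length(x$gene_ids), " genes x ",
      length(x$offsets), " offsets, layers: ",
      paste(x$layer_labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Multi-layer self-organizing-map (SuperSOM) clustering
#'
#' Trains a single SOM jointly on all mark layers: each sample's
#' best-matching unit minimises the *sum* of per-layer squared Euclidean
#' distances (equal layer weights), and all layers of a unit are updated
#' together. Training is online with linearly decaying learning rate and
#' Gaussian neighbourhood on a hexagonal grid. The trained codebook units
#' are then merged into `k` clusters by Ward agglomeration on the
#' concatenated codebook vectors, and each gene inherits its unit's
#' cluster. Cluster ids are relabelled in decreasing order of mean member
#' signal so that cluster 1 is the strongest, making labels deterministic.
#' The whole procedure is deterministic under `seed`.
#'
#' @param m a `signal_matrix`.
#' @param grid_w,grid_h SOM grid dimensions (default 6 x 6).
#' @param k number of final clusters (default 3; `k <= grid_w * grid_h`).
#' @param epochs training epochs (default 100).
#' @param seed RNG seed (required).
#' @param alpha learning-rate range, length 2 (default `c(0.05, 0.01)`).
#' @return An object of class `cluster_assignment` with fields `cluster`
#'   (named integer vector gene -> cluster), `unit` (gene -> BMU),
#'   `codebooks`, `unit_cluster`, and training metadata.
#' @export
supersom_cluster <- function(m, grid_w = 6, grid_h = 6, k = 3,
                             epochs = 100, seed, alpha = c(0.05, 0.01)) {
  if (!inherits(m, "signal_matrix")) stop("m must be a signal_matrix")
  units <- grid_w * grid_h
  if (k < 1 || k > units) stop("k must lie in [1, grid_w * grid_h]")
  if (any(!vapply(m$layers, nrow, 1L))) stop("empty layer")
  n <- length(m$gene_ids)
  # hexagonal grid coordinates
  row <- rep(seq_len(grid_h), each = grid_w) - 1
  col <- rep(seq_len(grid_w), grid_h) - 1
  gx <- col + 0.5 * (row %% 2)
  gy <- row * sqrt(3) / 2
  grid_d2 <- outer(gx, gx, "-")^2 + outer(gy, gy, "-")^2
  r0 <- max(sqrt(grid_d2)) / 2
  init <- with_seed(seed, {
    rows <- sample.int(n, units, replace = units > n)
    ord <- vapply(seq_len(epochs), function(e) sample.int(n), integer(n))
    list(rows = rows, ord = ord)
  })
  layers_t <- lapply(m$layers, t) # samples as columns for the C++ core
  codebooks0 <- lapply(layers_t, function(x) x[, init$rows, drop = FALSE])
  trained <- som_train_cpp(unname(layers_t), unname(codebooks0), grid_d2,
                           init$ord, alpha[1], alpha[2], r0, 1)
  bmu <- som_assign_cpp(unname(layers_t), trained)
  flat <- do.call(cbind, lapply(trained, t))
  hc <- stats::hclust(stats::dist(flat), method = "ward.D2")
  unit_cluster <- stats::cutree(hc, k = k)
  cluster <- unit_cluster[bmu]
  # relabel clusters by decreasing mean member signal (deterministic)
  tot <- rowSums(do.call(cbind, m$layers))
  means <- tapply(tot, factor(cluster, levels = seq_len(k)), mean)
  means[is.na(means)] <- -Inf # clusters with no member genes rank last
  relabel <- integer(k)
  relabel[order(-means)] <- seq_len(k)
  cluster <- relabel[cluster]
  unit_cluster <- relabel[unit_cluster]
  names(cluster) <- m$gene_ids
  codebooks <- lapply(trained, t) # back to units x offsets
  names(codebooks) <- m$layer_labels
  structure(list(cluster = cluster,
                 unit = stats::setNames(bmu, m$gene_ids),
                 codebooks = codebooks, unit_cluster = unit_cluster,
                 k = k, grid = c(grid_w, grid_h), epochs = epochs,
                 seed = seed),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment> ", length(x$cluster), " genes, k = ", x$k,
      " (grid ", x$grid[1], "x", x$grid[2], ", ", x$epochs,
      " epochs, seed ", x$seed, ")\n", sep = "")
  print(table(cluster = x$cluster))
  invisible(x)
}

#' Cluster-wise expression comparison
#'
#' Summarises gene expression per cluster (replicate-mean per gene,
#' optionally log10 with a pseudocount) and compares all cluster pairs
#' with two-tailed Mann-Whitney tests under Bonferroni correction
#' ([compare_groups()]). Clusters without any expressed gene are excluded
#' with a warning.
#'
#' @param expr a data frame with a `gene` column and one numeric column
#'   per replicate.
#' @param ca a `cluster_assignment`.
#' @param log10 report `log10(mean + pseudocount)` (default `TRUE`).
#' @param pseudocount added before the log (default 0.01).
#' @return A list with `values` (named list of per-cluster expression
#'   vectors) and `comparisons` (a `group_comparison` data frame).
#' @export
cluster_expression <- function(expr, ca, log10 = TRUE, pseudocount = 0.01) {
  if (!"gene" %in% names(expr)) stop("expr needs a 'gene' column")
  reps <- expr[, setdiff(names(expr), "gene"), drop = FALSE]
  if (!ncol(reps)) stop("expr needs at least one replicate column")
  level <- rowMeans(as.matrix(reps))
  if (log10) level <- base::log10(level + pseudocount)
  names(level) <- expr$gene
  common <- intersect(names(ca$cluster), expr$gene)
  values <- split(level[common], paste0("cluster", ca$cluster[common]))
  empty <- setdiff(paste0("cluster", seq_len(ca$k)), names(values))
  if (length(empty))
    warning("cluster(s) without expressed genes excluded: ",
            paste(empty, collapse = ", "))
  if (length(values) < 2)
    stop("need expressed genes in at least two clusters")
  list(values = values, comparisons = compare_groups(values))
}
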