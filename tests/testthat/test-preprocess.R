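test_that("delimited tables round-trip with cell x gene orientation", {
  x <- matrix(c(1, 0, 2, 3, 4, 5), 3, 2)
  path <- write_delim_counts(x, c("a", "b", "c"), c("g1", "g2"))
  em <- load_expression(path)
  expect_s3_class(em, "expression_matrix")
  expect_equal(dim(em$counts), c(3L, 2L))
  expect_equal(em$cell_ids, c("a", "b", "c"))
  expect_equal(em$gene_ids, c("g1", "g2"))
  expect_equal(unname(as.matrix(em$counts)), x)
  # tab-separated dialect is auto-detected
  path2 <- write_delim_counts(x, c("a", "b", "c"), c("g1", "g2"), sep = "\t")
  expect_equal(as.matrix(load_expression(path2)$counts),
               as.matrix(em$counts))
})

test_that("MTX directories load transposed and conserve nonzeros", {
  cg <- matrix(0, 4, 3)
  cg[cbind(c(1, 2, 2, 3, 4), c(1, 1, 3, 2, 3))] <- c(5, 1, 2, 7, 4)
  dir <- write_mtx_dir(cg, sprintf("bc%d", 1:4), sprintf("g%d", 1:3))
  em <- load_expression(dir)
  expect_equal(dim(em$counts), c(4L, 3L))
  expect_equal(sum(em$counts != 0), 5)
  expect_equal(unname(as.matrix(em$counts)), cg)
})

test_that("duplicate cell ids and dimension mismatches are consistency errors", {
  x <- matrix(1:4, 2, 2)
  path <- write_delim_counts(x, c("a", "a"), c("g1", "g2"))
  expect_error(load_expression(path), "consistency error")
  dir <- write_mtx_dir(x, c("b1", "b2"), c("g1", "g2"))
  writeLines(c("g1", "g2", "g3"), file.path(dir, "genes.tsv"))
  expect_error(load_expression(dir), "consistency error")
})

test_that("qc_filter removes sparse genes, libsize outliers and mito-heavy cells", {
  fx <- make_counts(n_cells = 100, seed = 3)
  # one gene nonzero in a single cell
  fx$counts[, 12] <- 0
  fx$counts[7, 12] <- 9
  em <- expression_matrix(fx$counts, fx$cell_ids, fx$gene_ids)
  out <- qc_filter(em, qc_config(min_cells_per_gene = 3))
  expect_false(fx$gene_ids[12] %in% out$gene_ids)

  # five cells with 100x library size are outside median +/- 3 MAD
  fx2 <- make_counts(n_cells = 100, seed = 4)
  big <- c(10, 20, 30, 40, 50)
  fx2$counts[big, ] <- fx2$counts[big, ] * 100
  em2 <- expression_matrix(fx2$counts, fx2$cell_ids, fx2$gene_ids)
  libsize <- rowSums(fx2$counts)
  expect_true(all(abs(libsize[big] - median(libsize)) > 3 * mad(libsize)))
  out2 <- qc_filter(em2, qc_config())
  expect_true(all(!fx2$cell_ids[big] %in% out2$cell_ids))

  # mito-heavy cells are dropped; without mito genes the filter is vacuous
  fx3 <- make_counts(n_cells = 50, seed = 5)
  fx3$counts[3, 1:3] <- 500  # ~70% mito
  em3 <- expression_matrix(fx3$counts, fx3$cell_ids, fx3$gene_ids)
  out3 <- qc_filter(em3, qc_config(libsize_mad_window = 100))
  expect_false("cell003" %in% out3$cell_ids)
  fx4 <- make_counts(n_cells = 50, n_mito = 0, seed = 6)
  em4 <- expression_matrix(fx4$counts, fx4$cell_ids, fx4$gene_ids)
  out4 <- qc_filter(em4, qc_config(libsize_mad_window = 100))
  expect_equal(out4$cell_ids, fx4$cell_ids)
})

test_that("qc_filter is idempotent and preserves ordering", {
  fx <- make_counts(n_cells = 80, seed = 7)
  fx$counts[c(5, 6), ] <- fx$counts[c(5, 6), ] * 50
  em <- expression_matrix(fx$counts, fx$cell_ids, fx$gene_ids)
  once <- qc_filter(em)
  twice <- qc_filter(once)
  expect_identical(as.matrix(once$counts), as.matrix(twice$counts))
  expect_identical(once$cell_ids, twice$cell_ids)
  expect_true(!is.unsorted(match(once$cell_ids, fx$cell_ids)))
})

test_that("normalization equalizes library sizes and PCA output has the right shape", {
  fx <- make_counts(n_cells = 60, n_genes = 50, seed = 8)
  em <- qc_filter(expression_matrix(fx$counts, fx$cell_ids, fx$gene_ids))
  cfg <- qc_config(n_hvg = 30, n_pcs = 10)
  pc <- normalize_and_reduce(em, cfg)
  expect_s3_class(pc, "point_cloud")
  expect_equal(dim(pc), c(length(em$cell_ids), 10L))
  # pre-log totals equal the median library size
  counts <- as.matrix(em$counts)
  libsize <- rowSums(counts)
  norm_totals <- rowSums(counts * (median(libsize) / libsize))
  expect_equal(norm_totals, rep(median(libsize), nrow(counts)),
               tolerance = 1e-6, ignore_attr = TRUE)
  # d is capped at min(n_pcs, n_hvg, n-1)
  small <- expression_matrix(fx$counts[1:5, ], fx$cell_ids[1:5], fx$gene_ids)
  pc_small <- normalize_and_reduce(small, qc_config(n_hvg = 30, n_pcs = 20))
  expect_equal(ncol(pc_small), 4L)
})

test_that("identical cells collapse to identical PCA coordinates and variance never grows", {
  fx <- make_counts(n_cells = 30, n_genes = 40, seed = 9)
  same <- fx$counts[rep(1, 30), ]
  em <- expression_matrix(same, fx$cell_ids, fx$gene_ids)
  pc <- normalize_and_reduce(em, qc_config(n_hvg = 20, n_pcs = 5))
  expect_lt(max(apply(pc, 2, sd)), 1e-10)

  em2 <- expression_matrix(fx$counts, fx$cell_ids, fx$gene_ids)
  cfg <- qc_config(n_hvg = 25, n_pcs = 5)
  pc2 <- normalize_and_reduce(em2, cfg)
  # total variance of the projection cannot exceed that of the source
  counts <- as.matrix(em2$counts)
  libsize <- rowSums(counts)
  logm <- log1p(counts * (median(libsize) / libsize))
  expect_lte(sum(apply(pc2, 2, var)), sum(apply(logm, 2, var)) + 1e-8)
})

test_that("PCA coordinates are gene-permutation invariant up to sign", {
  fx <- make_counts(n_cells = 40, n_genes = 30, seed = 10)
  em <- expression_matrix(fx$counts, fx$cell_ids, fx$gene_ids)
  cfg <- qc_config(n_hvg = 20, n_pcs = 4)
  pc1 <- normalize_and_reduce(em, cfg)
  set.seed(1)
  perm <- sample(ncol(fx$counts))
  em2 <- expression_matrix(fx$counts[, perm], fx$cell_ids, fx$gene_ids[perm])
  pc2 <- normalize_and_reduce(em2, cfg)
  expect_equal(abs(unclass(pc1)), abs(unclass(pc2)), tolerance = 1e-6)
})
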