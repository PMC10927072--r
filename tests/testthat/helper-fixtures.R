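# Programmatic fixtures for the I/O and preprocessing tests.

# Write a small delimited cell x gene table; returns its path.
write_delim_counts <- function(counts, cell_ids, gene_ids, sep = ",",
                               dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "counts.csv")
  header <- paste(c("cell", gene_ids), collapse = sep)
  rows <- vapply(seq_along(cell_ids), function(i)
    paste(c(cell_ids[i], counts[i, ]), collapse = sep), character(1))
  writeLines(c(header, rows), path)
  path
}

# Write a 10x-style MTX directory (gene x cell on disk); returns its path.
write_mtx_dir <- function(counts_cell_by_gene, cell_ids, gene_ids,
                          dir = withr::local_tempdir(.local_envir = parent.frame())) {
  m <- Matrix::Matrix(t(counts_cell_by_gene), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(gene_ids, file.path(dir, "genes.tsv"))
  writeLines(cell_ids, file.path(dir, "barcodes.tsv"))
  dir
}

# A small synthetic count matrix with Poisson noise and a couple of
# structured cell groups; mitochondrial genes get the "MT-" prefix.
make_counts <- function(n_cells = 60, n_genes = 40, n_mito = 3, seed = 1) {
  set.seed(seed)
  base <- matrix(rpois(n_cells * n_genes, lambda = 5), n_cells, n_genes)
  grp <- rep(1:2, length.out = n_cells)
  base[grp == 2, 1:10] <- base[grp == 2, 1:10] + rpois(sum(grp == 2) * 10, 20)
  genes <- c(if (n_mito > 0) paste0("MT-", seq_len(n_mito)),
             sprintf("G%03d", seq_len(n_genes - n_mito)))
  list(counts = base, cell_ids = sprintf("cell%03d", seq_len(n_cells)),
       gene_ids = genes)
}
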