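#' Quality-control and reduction configuration
#'
#' Parameters controlling gene/cell filtering and dimensionality reduction.
#' Defaults follow common single-cell practice: genes must be detected in at
#' least 3 cells; cells are kept when their library size lies within
#' median +/- 3 MAD; cells with more than 20% mitochondrial counts (gene ids
#' starting with `"MT-"`) are removed; the top 2000 genes by dispersion are
#' retained and reduced to 20 principal components.
#'
#' @param min_cells_per_gene Minimum number of cells in which a gene must
#'   have a nonzero count.
#' @param libsize_mad_window Half-width of the library-size window in MADs.
#' @param max_mito_fraction Maximum allowed mitochondrial count fraction.
#' @param mito_prefix Gene-id prefix identifying mitochondrial genes.
#' @param n_hvg Number of highly variable genes to retain.
#' @param n_pcs Number of principal components (>= 2; `n_hvg >= n_pcs`).
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_cells_per_gene = 3L, libsize_mad_window = 3,
                      max_mito_fraction = 0.2, mito_prefix = "MT-",
                      n_hvg = 2000L, n_pcs = 20L) {
  assert_count(min_cells_per_gene, "min_cells_per_gene", min = 0L)
  if (!is.finite(libsize_mad_window) || libsize_mad_window <= 0)
    stop("`libsize_mad_window` must be positive", call. = FALSE)
  assert_fraction(max_mito_fraction, "max_mito_fraction", open = FALSE)
  assert_count(n_pcs, "n_pcs", min = 2L)
  assert_count(n_hvg, "n_hvg", min = 2L)
  if (n_hvg < n_pcs) stop("`n_hvg` must be >= `n_pcs`", call. = FALSE)
  structure(list(min_cells_per_gene = as.integer(min_cells_per_gene),
                 libsize_mad_window = libsize_mad_window,
                 max_mito_fraction = max_mito_fraction,
                 mito_prefix = mito_prefix,
                 n_hvg = as.integer(n_hvg), n_pcs = as.integer(n_pcs)),
            class = "qc_config")
}

expression_matrix <- function(counts, cell_ids, gene_ids) {
  if (nrow(counts) != length(cell_ids) || ncol(counts) != length(gene_ids))
    stop("consistency error: counts dimensions do not match id lists",
         call. = FALSE)
  if (anyDuplicated(cell_ids))
    stop("consistency error: duplicate cell ids", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(list(counts = counts, cell_ids = as.character(cell_ids),
                 gene_ids = as.character(gene_ids)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d cells x %d genes (%.1f%% nonzero)\n",
              length(x$cell_ids), length(x$gene_ids),
              100 * sum(x$counts != 0) / length(x$cell_ids) / length(x$gene_ids)))
  invisible(x)
}

#' Load an expression matrix
#'
#' Reads either a 10x-style Matrix Market directory (`matrix.mtx` stored
#' gene x cell, plus gene and barcode lists; transposed to cell x gene on
#' load) or a delimited cell x gene table whose first row holds gene ids and
#' first column holds cell ids. The delimiter (comma or tab) is auto-detected
#' from the first line.
#'
#' @param path Directory (for `mtx_dir`) or file (for `delimited`).
#' @param format `"mtx_dir"`, `"delimited"`, or `"auto"` (directory implies
#'   `mtx_dir`).
#' @return An `expression_matrix` (list with `counts` in cell x gene
#'   orientation, `cell_ids`, `gene_ids`).
#' @export
load_expression <- function(path, format = c("auto", "mtx_dir", "delimited")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "mtx_dir" else "delimited"
  if (format == "mtx_dir") load_expression_mtx(path) else load_expression_delim(path)
}

load_expression_mtx <- function(path) {
  if (!dir.exists(path)) stop("no such directory: ", path, call. = FALSE)
  find1 <- function(patterns, what) {
    for (p in patterns) {
      hit <- list.files(path, pattern = p, full.names = TRUE)
      if (length(hit)) return(hit[[1L]])
    }
    stop(sprintf("format error: no %s file found in %s", what, path),
         call. = FALSE)
  }
  mtx_file <- find1("\\.mtx$", "Matrix Market (.mtx)")
  gene_file <- find1(c("^features\\.tsv$", "^genes\\.tsv$", "genes", "features"),
                     "gene list")
  bc_file <- find1(c("^barcodes\\.tsv$", "barcodes"), "barcode list")
  m <- tryCatch(Matrix::readMM(mtx_file), error = function(e)
    stop("format error in ", mtx_file, ": ", conditionMessage(e), call. = FALSE))
  genes <- read.table(gene_file, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)[[1L]]
  barcodes <- readLines(bc_file)
  if (nrow(m) != length(genes) || ncol(m) != length(barcodes))
    stop(sprintf(paste0("consistency error: matrix is %d x %d but found ",
                        "%d genes and %d barcodes"),
                 nrow(m), ncol(m), length(genes), length(barcodes)),
         call. = FALSE)
  # on-disk convention is gene x cell; flip to cell x gene
  expression_matrix(Matrix::t(m), cell_ids = barcodes, gene_ids = genes)
}

load_expression_delim <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- tryCatch(
    read.table(path, sep = sep, header = TRUE, check.names = FALSE,
               stringsAsFactors = FALSE),
    error = function(e)
      stop("format error near the header line of ", path, ": ",
           conditionMessage(e), call. = FALSE))
  if (ncol(df) < 2L)
    stop("format error: header line of ", path,
         " defines fewer than two columns", call. = FALSE)
  cell_ids <- as.character(df[[1L]])
  if (anyDuplicated(cell_ids))
    stop("consistency error: duplicate cell ids in ", path, call. = FALSE)
  counts <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(counts) <- "double"
  if (any(!is.finite(counts)))
    stop("format error: non-numeric entries in ", path, call. = FALSE)
  rownames(counts) <- NULL
  expression_matrix(counts, cell_ids = cell_ids, gene_ids = colnames(df)[-1L])
}

#' Quality-control filtering of an expression matrix
#'
#' Removes (i) genes with nonzero counts in fewer than
#' `cfg$min_cells_per_gene` cells, (ii) cells whose library size lies outside
#' median +/- `libsize_mad_window` * MAD of the current library sizes, and
#' (iii) cells whose mitochondrial count fraction (genes whose id starts with
#' `cfg$mito_prefix`) exceeds `cfg$max_mito_fraction`. The three rules are
#' applied jointly and iterated to a fixed point, which makes the operation
#' idempotent; the order of surviving cells and genes is preserved.
#'
#' @param x An `expression_matrix` from [load_expression()].
#' @param cfg A [qc_config()].
#' @return A filtered `expression_matrix`.
#' @export
qc_filter <- function(x, cfg = qc_config()) {
  stopifnot(inherits(x, "expression_matrix"))
  counts <- x$counts
  cell_ids <- x$cell_ids
  gene_ids <- x$gene_ids
  if (length(cell_ids) == 0L || length(gene_ids) == 0L)
    stop("degenerate input: empty expression matrix", call. = FALSE)
  repeat {
    keep_gene <- Matrix::colSums(counts != 0) >= cfg$min_cells_per_gene
    counts2 <- counts[, keep_gene, drop = FALSE]
    gene_ids2 <- gene_ids[keep_gene]
    libsize <- Matrix::rowSums(counts2)
    med <- median(libsize)
    dev <- mad(libsize)
    keep_cell <- abs(libsize - med) <= cfg$libsize_mad_window * dev
    mito <- startsWith(gene_ids2, cfg$mito_prefix)
    if (any(mito)) {
      mito_frac <- Matrix::rowSums(counts2[, mito, drop = FALSE]) /
        pmax(libsize, 1)
      keep_cell <- keep_cell & mito_frac <= cfg$max_mito_fraction
    }
    stable <- all(keep_gene) && all(keep_cell)
    counts <- counts2[keep_cell, , drop = FALSE]
    cell_ids <- cell_ids[keep_cell]
    gene_ids <- gene_ids2
    if (nrow(counts) == 0L)
      stop("degenerate output: all cells removed by QC filtering", call. = FALSE)
    if (stable) break
  }
  expression_matrix(counts, cell_ids, gene_ids)
}

#' Normalize, select highly variable genes, and reduce to a point cloud
#'
#' Counts are library-size normalized (every cell rescaled so its total
#' equals the median library size), log1p-transformed, the top `cfg$n_hvg`
#' genes by dispersion (variance/mean of the log-normalized values) are
#' retained, and PCA (centered, unscaled, no whitening) reduces the matrix to
#' `min(n_pcs, n_hvg, n - 1)` components ordered by explained variance.
#'
#' @inheritParams qc_filter
#' @return A [point_cloud()] with one row per cell and the cell ids as
#'   `point_ids`.
#' @export
normalize_and_reduce <- function(x, cfg = qc_config()) {
  stopifnot(inherits(x, "expression_matrix"))
  n <- length(x$cell_ids)
  if (n < 3L)
    stop("degenerate output: fewer than 3 cells after QC", call. = FALSE)
  counts <- as.matrix(x$counts)
  libsize <- rowSums(counts)
  if (any(libsize == 0))
    stop("degenerate input: cells with zero library size; run qc_filter() first",
         call. = FALSE)
  target <- median(libsize)
  norm <- counts * (target / libsize)  # recycles by row
  logm <- log1p(norm)
  mu <- colMeans(logm)
  v <- apply(logm, 2L, var)
  dispersion <- ifelse(mu > 0, v / mu, 0)
  n_hvg <- min(cfg$n_hvg, ncol(logm))
  hvg <- order(dispersion, decreasing = TRUE)[seq_len(n_hvg)]
  hvg <- sort(hvg)  # keep original gene order among the selected
  reduced <- prcomp(logm[, hvg, drop = FALSE], center = TRUE, scale. = FALSE)
  d <- min(cfg$n_pcs, n_hvg, n - 1L)
  point_cloud(reduced$x[, seq_len(d), drop = FALSE], point_ids = x$cell_ids)
}
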