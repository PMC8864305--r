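#' Expression dataset container
#'
#' Bundles a gene x cell UMI count matrix with per-cell and per-gene metadata.
#' Counts are stored as a sparse [Matrix::dgCMatrix] with gene ids as row
#' names and cell ids as column names; both metadata tables are tibbles whose
#' first columns (`gene_id`, `cell_id`) mirror the matrix dimnames.
#'
#' @param counts non-negative integer gene x cell matrix (dense or sparse)
#'   with unique row and column names.
#' @param cell_meta tibble/data.frame with a `cell_id` column matching
#'   `colnames(counts)`, typically also `condition`, `age`, `replicate`.
#' @param gene_meta tibble/data.frame with a `gene_id` column matching
#'   `rownames(counts)`; a logical `mito` column flags mitochondrial genes.
#'   If absent, `mito` is populated from a "mt-" / "MT-" gene-id prefix.
#'
#' @return An object of class `expr_dataset`.
#' @export
expr_dataset <- function(counts, cell_meta, gene_meta = NULL) {
  counts <- methods::as(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
    "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (nrow(counts) > 0 && is.null(rownames(counts))) {
    abort("`counts` must have gene row names")
  }
  if (ncol(counts) > 0 && is.null(colnames(counts))) {
    abort("`counts` must have cell column names")
  }
  if (anyDuplicated(rownames(counts))) abort("gene ids must be unique")
  if (anyDuplicated(colnames(counts))) abort("cell ids must be unique")
  if (any(counts@x < 0)) abort("`counts` must be non-negative")
  if (any(counts@x != round(counts@x))) abort("`counts` must be integers")

  cell_meta <- tibble::as_tibble(cell_meta)
  if (!"cell_id" %in% names(cell_meta)) abort("`cell_meta` needs a `cell_id` column")
  if (nrow(cell_meta) != ncol(counts)) {
    abort(sprintf(
      "`cell_meta` has %d rows but `counts` has %d cells",
      nrow(cell_meta), ncol(counts)
    ))
  }
  if (ncol(counts) > 0 &&
    !identical(as.character(cell_meta$cell_id), colnames(counts))) {
    abort("`cell_meta$cell_id` must match `colnames(counts)` in order")
  }

  if (is.null(gene_meta)) {
    gene_meta <- tibble::tibble(gene_id = rownames(counts))
  }
  gene_meta <- tibble::as_tibble(gene_meta)
  if (!"gene_id" %in% names(gene_meta)) abort("`gene_meta` needs a `gene_id` column")
  if (nrow(gene_meta) != nrow(counts)) {
    abort(sprintf(
      "`gene_meta` has %d rows but `counts` has %d genes",
      nrow(gene_meta), nrow(counts)
    ))
  }
  if (nrow(counts) > 0 &&
    !identical(as.character(gene_meta$gene_id), rownames(counts))) {
    abort("`gene_meta$gene_id` must match `rownames(counts)` in order")
  }
  if (!"mito" %in% names(gene_meta)) {
    gene_meta$mito <- grepl("^mt-", gene_meta$gene_id, ignore.case = TRUE)
  }

  structure(
    list(counts = counts, cell_meta = cell_meta, gene_meta = gene_meta),
    class = "expr_dataset"
  )
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf(
    "<expr_dataset> %d genes x %d cells\n",
    nrow(x$counts), ncol(x$counts)
  ))
  if ("condition" %in% names(x$cell_meta)) {
    tb <- table(x$cell_meta$condition)
    cat("  conditions:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  cat(sprintf("  mito genes flagged: %d\n", sum(x$gene_meta$mito)))
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$counts)

#' Subset an expression dataset by gene and/or cell
#'
#' @param x an `expr_dataset`.
#' @param genes,cells index vectors (logical, integer or character ids).
#' @return A new `expr_dataset` with metadata subset in step.
#' @export
subset_dataset <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "expr_dataset"))
  gi <- if (is.null(genes)) seq_len(nrow(x$counts)) else genes
  ci <- if (is.null(cells)) seq_len(ncol(x$counts)) else cells
  if (is.character(gi)) gi <- match(gi, rownames(x$counts))
  if (is.character(ci)) ci <- match(ci, colnames(x$counts))
  if (anyNA(gi) || anyNA(ci)) abort("unknown gene or cell ids in subset")
  expr_dataset(
    x$counts[gi, ci, drop = FALSE],
    x$cell_meta[ci, , drop = FALSE],
    x$gene_meta[gi, , drop = FALSE]
  )
}

#' Read an expression dataset from Matrix Market + TSV metadata
#'
#' Expects `mtx_path` (genes x cells sparse counts), a gene metadata TSV with
#' a `gene_id` first column, and a cell metadata TSV with a `cell_id` first
#' column; rows of the TSVs correspond to matrix rows/columns in order.
#'
#' @param mtx_path path to MatrixMarket counts.
#' @param genes_tsv,cells_tsv paths to the metadata tables.
#' @return An `expr_dataset`.
#' @export
read_expression <- function(mtx_path, genes_tsv, cells_tsv) {
  for (p in c(mtx_path, genes_tsv, cells_tsv)) {
    if (!file.exists(p)) abort(sprintf("file not found: %s", p))
  }
  m <- tryCatch(Matrix::readMM(mtx_path), error = function(e) {
    abort(sprintf("malformed MatrixMarket file %s: %s", mtx_path, conditionMessage(e)))
  })
  genes <- readr::read_tsv(genes_tsv, show_col_types = FALSE, progress = FALSE)
  cells <- readr::read_tsv(cells_tsv, show_col_types = FALSE, progress = FALSE)
  if (nrow(genes) != nrow(m)) {
    abort(sprintf(
      "gene metadata has %d rows but matrix has %d rows", nrow(genes), nrow(m)
    ))
  }
  if (nrow(cells) != ncol(m)) {
    abort(sprintf(
      "cell metadata has %d rows but matrix has %d columns", nrow(cells), ncol(m)
    ))
  }
  if (anyDuplicated(genes$gene_id)) abort("duplicate gene ids in gene metadata")
  dimnames(m) <- list(as.character(genes$gene_id), as.character(cells$cell_id))
  expr_dataset(m, cells, genes)
}

#' Write an expression dataset as Matrix Market + TSV metadata
#'
#' @param x an `expr_dataset`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return Invisibly, the three file paths written.
#' @export
write_expression <- function(x, dir, prefix = "expr") {
  stopifnot(inherits(x, "expr_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(prefix, c("_counts.mtx", "_genes.tsv", "_cells.tsv")))
  Matrix::writeMM(x$counts, paths[1])
  readr::write_tsv(x$gene_meta, paths[2], progress = FALSE)
  readr::write_tsv(x$cell_meta, paths[3], progress = FALSE)
  invisible(paths)
}
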