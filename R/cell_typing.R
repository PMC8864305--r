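#' Marker-gene sets for cell-type assignment
#'
#' @param sets named list, category -> character vector of gene ids, in the
#'   maturation order of the categories (e.g. AP < BP < N0 < N1).
#' @return A `marker_sets` object.
#' @export
marker_sets <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || length(sets) < 2L) {
    abort("`sets` must be a named list with >= 2 categories")
  }
  if (any(lengths(sets) == 0L)) abort("marker lists must be non-empty")
  all_genes <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(all_genes)) abort("marker lists must be disjoint")
  structure(lapply(sets, as.character), class = "marker_sets")
}

#' Extract the shipped marker sets of a synthetic dataset
#'
#' @param dataset an [expr_dataset()] whose `gene_meta$marker_set` is set.
#' @return A [marker_sets()] in AP < BP < N0 < N1 order (or the dataset's
#'   own category order for layer data).
#' @export
default_marker_sets <- function(dataset) {
  gm <- dataset$gene_meta
  if (!"marker_set" %in% names(gm) || all(is.na(gm$marker_set))) {
    abort("dataset carries no marker-set annotations")
  }
  cats <- unique(gm$marker_set[!is.na(gm$marker_set)])
  cats <- c(intersect(cell_type_levels, cats), setdiff(cats, cell_type_levels))
  marker_sets(lapply(
    stats::setNames(cats, cats),
    function(ct) gm$gene_id[!is.na(gm$marker_set) & gm$marker_set == ct]
  ))
}

#' Read / write marker sets as a two-column TSV (category, gene_id)
#'
#' @param path TSV file.
#' @return [read_marker_sets()] a [marker_sets()] object.
#' @export
read_marker_sets <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("category", "gene_id") %in% names(df))) {
    abort("marker TSV needs `category` and `gene_id` columns")
  }
  marker_sets(split(df$gene_id, factor(df$category, levels = unique(df$category))))
}

#' @rdname read_marker_sets
#' @param markers a [marker_sets()] object.
#' @export
write_marker_sets <- function(markers, path) {
  df <- tibble::tibble(
    category = rep(names(markers), lengths(markers)),
    gene_id = unlist(markers, use.names = FALSE)
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Select highly variable genes by standardized variance
#'
#' Variance-stabilizing selection: a loess trend of log10 variance on log10
#' mean predicts each gene's expected standard deviation; expression values
#' are standardized against it, clipped at `sqrt(n_cells)`, and genes are
#' ranked by the variance of the clipped z-scores. Constant genes get
#' standardized variance 0 and rank last. Ties break by gene id, so the
#' result is deterministic.
#'
#' @param norm_matrix gene x cell normalized expression matrix with gene
#'   row names.
#' @param n_top number of genes to return.
#' @param loess_span span of the mean-variance trend fit.
#' @return Character vector of `n_top` gene ids, most variable first.
#' @export
select_variable_genes <- function(norm_matrix, n_top = 2000, loess_span = 0.3) {
  norm_matrix <- as.matrix(norm_matrix)
  if (n_top > nrow(norm_matrix)) {
    abort(sprintf(
      "`n_top` (%d) exceeds gene count (%d)", n_top, nrow(norm_matrix)
    ))
  }
  n <- ncol(norm_matrix)
  mu <- rowMeans(norm_matrix)
  v <- apply(norm_matrix, 1, var)
  std_var <- numeric(nrow(norm_matrix))
  ok <- v > 0 & mu > 0
  if (sum(ok) > 10) {
    fit <- loess(log10(v[ok]) ~ log10(mu[ok]), span = loess_span, degree = 2)
    esd <- sqrt(10^predict(fit))
    z <- (norm_matrix[ok, , drop = FALSE] - mu[ok]) / esd
    clip <- sqrt(n)
    z[z > clip] <- clip
    z[z < -clip] <- -clip
    std_var[ok] <- apply(z, 1, var)
  } else {
    std_var[ok] <- v[ok]
  }
  ord <- order(-std_var, rownames(norm_matrix))
  rownames(norm_matrix)[ord[seq_len(n_top)]]
}

#' Assign cell types from marker-gene scores
#'
#' Each gene is z-scored across cells (constant genes get z = 0); a cell's
#' score for a category is the mean z of that category's markers, and the
#' cell is assigned the best-scoring category. Confidence is the margin
#' between best and second-best score; cells whose best score is not above
#' the across-cell average (score <= 0) are flagged ambiguous. Gene order
#' never changes the result.
#'
#' @param norm_matrix gene x cell normalized expression matrix.
#' @param markers a [marker_sets()].
#' @return Tibble with `cell_id`, `cell_type` (ordered factor in marker
#'   order), `confidence`, `ambiguous`, and one score column per category.
#' @export
assign_cell_types <- function(norm_matrix, markers) {
  stopifnot(inherits(markers, "marker_sets"))
  norm_matrix <- as.matrix(norm_matrix)
  present <- lapply(markers, intersect, rownames(norm_matrix))
  if (any(lengths(present) == 0L)) {
    abort("no markers of at least one category found in the matrix")
  }
  mu <- rowMeans(norm_matrix)
  sdv <- apply(norm_matrix, 1, sd)
  z <- (norm_matrix - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  scores <- vapply(
    present,
    function(g) colMeans(z[g, , drop = FALSE]),
    numeric(ncol(norm_matrix))
  )
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  cats <- names(markers)
  best <- apply(scores, 1, which.max)
  sorted <- apply(scores, 1, function(s) sort(s, decreasing = TRUE)[1:2])
  margin <- sorted[1, ] - sorted[2, ]
  out <- tibble::tibble(
    cell_id = colnames(norm_matrix),
    cell_type = factor(cats[best], levels = cats, ordered = TRUE),
    confidence = margin,
    ambiguous = sorted[1, ] <= 0 | margin == 0
  )
  score_df <- tibble::as_tibble(scores)
  names(score_df) <- paste0("score_", gsub("[^A-Za-z0-9]", "", cats))
  dplyr::bind_cols(out, score_df)
}
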