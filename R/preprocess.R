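#' Quality-control thresholds
#'
#' Embryonic single cells are conventionally kept when they express at least
#' 2000 genes, postnatal cells at least 1000, and in both cases at most 15%
#' mitochondrial counts. The exclusion rule is strict: a cell expressing
#' *less than* `min_genes_detected` genes or *more than*
#' `max_mito_fraction` mitochondrial counts is dropped, so cells exactly at
#' either boundary are retained.
#'
#' @param min_genes_detected minimum genes with count > 0.
#' @param max_mito_fraction maximum mitochondrial count fraction.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_genes_detected = 2000, max_mito_fraction = 0.15) {
  stopifnot_scalar_number(min_genes_detected, "min_genes_detected", lower = 0)
  stopifnot_scalar_number(max_mito_fraction, "max_mito_fraction", 0, 1)
  structure(
    list(
      min_genes_detected = min_genes_detected,
      max_mito_fraction = max_mito_fraction
    ),
    class = "qc_thresholds"
  )
}

#' Per-cell QC statistics
#'
#' @param dataset an [expr_dataset()].
#' @return Tibble with `cell_id`, `total_counts`, `genes_detected`,
#'   `mito_fraction` (NA when no mitochondrial gene is flagged).
#' @export
qc_stats <- function(dataset) {
  stopifnot(inherits(dataset, "expr_dataset"))
  cnt <- dataset$counts
  total <- Matrix::colSums(cnt)
  detected <- Matrix::colSums(cnt > 0)
  mito_idx <- which(dataset$gene_meta$mito)
  mito_frac <- if (length(mito_idx)) {
    Matrix::colSums(cnt[mito_idx, , drop = FALSE]) / pmax(total, 1)
  } else {
    rep(NA_real_, ncol(cnt))
  }
  tibble::tibble(
    cell_id = colnames(cnt),
    total_counts = as.numeric(total),
    genes_detected = as.integer(detected),
    mito_fraction = as.numeric(mito_frac)
  )
}

#' Filter cells on detected genes and mitochondrial fraction
#'
#' Retains exactly the cells with `genes_detected >= min_genes_detected` and
#' `mito_fraction <= max_mito_fraction`; the exclusions are strict
#' inequalities, so boundary cells stay. When `use_picture_qc` and the
#' dataset carries a logical `picture_qc` cell column (single healthy cell
#' observed in the well), cells flagged FALSE are excluded too. Filtering is
#' idempotent.
#'
#' @param dataset an [expr_dataset()].
#' @param thresholds a [qc_thresholds()].
#' @param use_picture_qc honor the optional `picture_qc` metadata column.
#' @return List with `dataset` (filtered) and `report`, a per-cell tibble of
#'   QC stats, `kept` flag and `exclusion_reason`.
#' @export
qc_filter <- function(dataset, thresholds = qc_thresholds(),
                      use_picture_qc = TRUE) {
  stopifnot(inherits(dataset, "expr_dataset"))
  if (ncol(dataset$counts) == 0L) abort("empty dataset: no cells to filter")
  st <- qc_stats(dataset)
  no_mito <- all(is.na(st$mito_fraction))
  if (no_mito) {
    warn("no mitochondrial genes flagged; mito-fraction filter skipped")
  }
  fail_genes <- st$genes_detected < thresholds$min_genes_detected
  fail_mito <- if (no_mito) rep(FALSE, nrow(st)) else
    st$mito_fraction > thresholds$max_mito_fraction
  fail_pic <- rep(FALSE, nrow(st))
  if (use_picture_qc && "picture_qc" %in% names(dataset$cell_meta)) {
    fail_pic <- !dataset$cell_meta$picture_qc
  }
  reason <- dplyr::case_when(
    fail_pic ~ "picture_qc",
    fail_genes & fail_mito ~ "low_genes;high_mito",
    fail_genes ~ "low_genes",
    fail_mito ~ "high_mito",
    TRUE ~ NA_character_
  )
  keep <- is.na(reason)
  report <- dplyr::mutate(st,
    kept = keep, exclusion_reason = reason,
    mito_filter_applied = !no_mito
  )
  list(
    dataset = subset_dataset(dataset, cells = which(keep)),
    report = report
  )
}

#' RPM-log normalization
#'
#' Scales each cell to reads per million and log-transforms:
#' `log10(1 + 1e6 * count / cell_total)`. The pseudocount is configurable;
#' the per-cell RPM values sum to 1e6 before the log.
#'
#' @param dataset an [expr_dataset()], or a gene x cell count matrix.
#' @param pseudocount added inside the log (default 1).
#' @return Dense gene x cell matrix of normalized expression.
#' @export
normalize_rpm_log <- function(dataset, pseudocount = 1) {
  cnt <- if (inherits(dataset, "expr_dataset")) dataset$counts else dataset
  if (ncol(cnt) == 0L || nrow(cnt) == 0L) abort("empty expression matrix")
  totals <- Matrix::colSums(cnt)
  if (any(totals <= 0)) {
    bad <- colnames(cnt)[totals <= 0]
    abort(sprintf(
      "zero-total cell(s): %s", paste(head(bad, 5), collapse = ", ")
    ))
  }
  rpm <- sweep(as.matrix(cnt), 2, 1e6 / totals, "*")
  log10(pseudocount + rpm)
}
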