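#' Per-cell-type perturbation scoring (control vs perturbed classifiers)
#'
#' For each cell type independently, trains the full pipeline (all-gene
#' hinge classifier, signed-weight ranking, re-optimization on the best
#' `n_top + n_bottom` genes) and evaluates it by stratified k-fold
#' cross-validated AUC on that type's cells. A high AUC means the
#' perturbation is transcriptionally detectable in that type. Types with
#' fewer than `min_cells` cells in either condition are skipped with a
#' warning — small clusters cannot support a cross-validated classifier.
#'
#' @param norm_matrix gene x cell normalized expression matrix.
#' @param cell_types per-cell type labels (vector aligned with columns).
#' @param conditions per-cell condition labels (2 conditions).
#' @param perturbed_condition positive class; default the non-first sorted
#'   condition.
#' @param k_folds folds for cross-validation.
#' @param seed RNG seed (per-type seeds derived from it).
#' @param min_cells minimum cells per condition per analyzed type.
#' @param n_top,n_bottom re-optimization gene counts.
#' @param lambda solver penalty, default 1/n per type.
#' @return Tibble with one row per cell type: `cell_type`, per-condition
#'   cell counts, `auc`, `skipped`, and a `cv` list-column of
#'   [cross_validate()] results (`NULL` when skipped).
#' @export
score_cell_types <- function(norm_matrix, cell_types, conditions,
                             perturbed_condition = NULL, k_folds = 20,
                             seed = 1L, min_cells = 20, n_top = 50,
                             n_bottom = 50, lambda = NULL) {
  norm_matrix <- as.matrix(norm_matrix)
  cell_types <- as.character(cell_types)
  conditions <- as.character(conditions)
  stopifnot(
    length(cell_types) == ncol(norm_matrix),
    length(conditions) == ncol(norm_matrix)
  )
  conds <- sort(unique(conditions))
  if (length(conds) != 2L) {
    abort(sprintf("need exactly 2 conditions, found %d", length(conds)))
  }
  pos <- perturbed_condition %||% conds[2]
  types <- unique(cell_types)
  types <- c(intersect(cell_type_levels, types), setdiff(types, cell_type_levels))

  rows <- purrr::imap(stats::setNames(types, types), function(ty, nm) {
    sel <- cell_types == ty
    n_by_cond <- table(factor(conditions[sel], levels = conds))
    if (any(n_by_cond < min_cells)) {
      warn(sprintf(
        "cell type %s skipped: %s cells per condition (minimum %d)",
        ty, paste(n_by_cond, collapse = "/"), min_cells
      ))
      return(tibble::tibble(
        cell_type = ty,
        n_control = as.integer(n_by_cond[setdiff(conds, pos)]),
        n_perturbed = as.integer(n_by_cond[pos]),
        auc = NA_real_, skipped = TRUE, cv = list(NULL)
      ))
    }
    # per-type seed derived from the type name so that results for one type
    # never depend on which other types are present
    type_seed <- if (ty %in% cell_type_levels) {
      match(ty, cell_type_levels)
    } else {
      sum(utf8ToInt(ty)) %% 997L
    }
    cv <- cross_validate(
      norm_matrix[, sel, drop = FALSE], conditions[sel],
      scheme = "kfold", k = k_folds,
      seed = seed + type_seed,
      model_type = "binary", positive_class = pos,
      n_top = n_top, n_bottom = n_bottom, lambda = lambda
    )
    tibble::tibble(
      cell_type = ty,
      n_control = as.integer(n_by_cond[setdiff(conds, pos)]),
      n_perturbed = as.integer(n_by_cond[pos]),
      auc = cv$auc, skipped = FALSE, cv = list(cv)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (all(out$skipped)) abort("all cell types were skipped")
  out
}

#' Top induced and repressed genes of a perturbation classifier
#'
#' Induced genes are the `n` most positively weighted toward the perturbed
#' (positive) class, repressed the `n` most negative; the lists are disjoint
#' by construction. When fewer than `n` genes carry the required sign, the
#' list is shortened with a warning.
#'
#' @param model a `linear_scorer` whose positive class is the perturbed
#'   condition.
#' @param n genes per direction.
#' @return Tibble with `gene_id`, `weight`, `direction`
#'   (`"induced"`/`"repressed"`).
#' @export
top_regulated_genes <- function(model, n = 50) {
  stopifnot(inherits(model, "linear_scorer"))
  ranked <- rank_genes(model)
  ind <- dplyr::filter(ranked, .data$weight > 0) |> head(n)
  rep_ <- dplyr::filter(ranked, .data$weight < 0) |> dplyr::arrange(.data$weight, .data$gene_id) |> head(n)
  if (nrow(ind) < n) {
    warn(sprintf("only %d genes with positive weight (requested %d)", nrow(ind), n))
  }
  if (nrow(rep_) < n) {
    warn(sprintf("only %d genes with negative weight (requested %d)", nrow(rep_), n))
  }
  dplyr::bind_rows(
    dplyr::mutate(ind, direction = "induced"),
    dplyr::mutate(rep_, direction = "repressed")
  ) |> dplyr::select("gene_id", "weight", "direction")
}
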