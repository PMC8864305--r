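#' Fit the pseudo-maturation (pseudotime) model on control cells
#'
#' Trains the regularized all-threshold ordinal model on ordered cell
#' categories of the control condition, re-optimizes on the best
#' `n_top + n_bottom` genes, and attaches cross-validated (default
#' leave-one-out) scores for the control cells — the reference distribution
#' that perturbed or cross-species cells are later compared against. With
#' `pool_progenitors`, AP and BP are merged into one lowest category, as done
#' when progenitors form a very small cluster.
#'
#' @param control_X gene x cell normalized matrix of control cells.
#' @param type_labels per-cell types among AP/BP/N0/N1 (or any ordered set
#'   via `categories`).
#' @param pool_progenitors merge AP and BP into "AP+BP".
#' @param categories category order; default the AP < BP < N0 < N1 levels
#'   present.
#' @param cv_scheme `"loo"` (default) or `"kfold"`.
#' @param k folds when `cv_scheme = "kfold"`.
#' @param select_in_fold repeat gene selection inside every fold. The
#'   default (`FALSE`) selects the gene panel once on all control cells and
#'   cross-validates the restricted model, so control scores live on the
#'   same gene panel as later projections of perturbed cells — the right
#'   contrast for comparing score distributions. Set `TRUE` for a
#'   leakage-free estimate of the model's own predictive accuracy.
#' @param lambda,n_top,n_bottom,seed as in [cross_validate()].
#' @return A `pseudotime_fit`: the best-gene `ordinal_scorer` (`model`), the
#'   control `cv_result` (`cv`), and the control score range used for
#'   min-max scaling.
#' @export
fit_pseudotime <- function(control_X, type_labels, pool_progenitors = FALSE,
                           categories = NULL, cv_scheme = c("loo", "kfold"),
                           k = 20, lambda = NULL, n_top = 50, n_bottom = 50,
                           select_in_fold = FALSE, seed = 1L) {
  cv_scheme <- match.arg(cv_scheme)
  labels <- as.character(type_labels)
  if (pool_progenitors) {
    labels[labels %in% c("AP", "BP")] <- "AP+BP"
  }
  if (is.null(categories)) {
    base <- if (pool_progenitors) c("AP+BP", "N0", "N1") else cell_type_levels
    categories <- intersect(base, unique(labels))
    extra <- setdiff(unique(labels), base)
    if (length(extra)) {
      abort(sprintf(
        "unknown categories %s; supply `categories` explicitly",
        paste(extra, collapse = ", ")
      ))
    }
  }
  if (length(categories) < 2L) abort("fewer than 2 categories after pooling")
  singleton <- names(which(table(labels) == 1L))
  if (length(singleton)) {
    warn(sprintf(
      "category with a single cell (%s): its leave-one-out fold trains without it",
      paste(singleton, collapse = ", ")
    ))
  }
  cv <- cross_validate(
    control_X, labels,
    scheme = cv_scheme, k = k, seed = seed,
    model_type = "ordinal", categories = categories,
    n_top = n_top, n_bottom = n_bottom, lambda = lambda,
    select_in_fold = select_in_fold
  )
  rng <- range(cv$cells$score, na.rm = TRUE)
  structure(
    list(
      model = cv$model, cv = cv, categories = categories,
      pool_progenitors = pool_progenitors, score_range = rng
    ),
    class = "pseudotime_fit"
  )
}

#' @export
print.pseudotime_fit <- function(x, ...) {
  cat(sprintf(
    "<pseudotime_fit> %s, %d control cells, %d model genes\n",
    paste(x$categories, collapse = " < "), nrow(x$cv$cells),
    length(x$model$weights)
  ))
  invisible(x)
}

scale_scores <- function(scores, rng) {
  if (diff(rng) <= 0) {
    return(rep(0.5, length(scores)))
  }
  (scores - rng[1]) / diff(rng)
}

#' Score perturbed cells and compare their pseudotime to control
#'
#' Projects the perturbed cells onto the pseudo-maturation model and
#' compares them to the control cells' cross-validation scores. The shift
#' statistic is `median(perturbed) - median(control)` (negative = delayed
#' maturation); the p-value comes from a two-sided rank-sum test, or from a
#' label-permutation null of the median difference with
#' `test = "permutation"`. Optionally restrict both groups to stated
#' categories (e.g. the postmitotic N0 + N1 cells).
#'
#' @param fit a [fit_pseudotime()] result.
#' @param X_perturbed gene x cell normalized matrix of perturbed cells.
#' @param perturbed_types per-cell categories of the perturbed cells;
#'   required when `restrict_to` is given. Pooling is applied as in the fit.
#' @param restrict_to categories to keep in both groups.
#' @param test `"ranksum"` or `"permutation"`.
#' @param n_perm permutations for `test = "permutation"`.
#' @param seed permutation seed.
#' @param min_coverage forwarded to [project()].
#' @return A `pseudotime_comparison`: tibble `scores` (cell, group,
#'   category, raw and min-max scaled score), `shift`, `p_value`, `test`.
#' @export
score_and_compare <- function(fit, X_perturbed, perturbed_types = NULL,
                              restrict_to = NULL,
                              test = c("ranksum", "permutation"),
                              n_perm = 1000, seed = 1L, min_coverage = 0.5) {
  stopifnot(inherits(fit, "pseudotime_fit"))
  test <- match.arg(test)
  pert_scores <- project(fit$model, X_perturbed, min_coverage = min_coverage)
  pert_types <- if (is.null(perturbed_types)) {
    rep(NA_character_, length(pert_scores))
  } else {
    pt <- as.character(perturbed_types)
    if (fit$pool_progenitors) pt[pt %in% c("AP", "BP")] <- "AP+BP"
    pt
  }
  ctrl <- fit$cv$cells
  df <- dplyr::bind_rows(
    tibble::tibble(
      cell_id = ctrl$cell_id, group = "control",
      category = ctrl$label, raw_score = ctrl$score
    ),
    tibble::tibble(
      cell_id = names(pert_scores) %||% sprintf("q%04d", seq_along(pert_scores)),
      group = "perturbed",
      category = pert_types, raw_score = as.numeric(pert_scores)
    )
  )
  if (!is.null(restrict_to)) {
    if (is.null(perturbed_types)) {
      abort("`perturbed_types` needed to restrict categories")
    }
    df <- dplyr::filter(df, .data$category %in% restrict_to)
    if (!nrow(df) || length(unique(df$group)) < 2L) {
      abort("empty group after category restriction")
    }
  }
  df$scaled_score <- scale_scores(df$raw_score, fit$score_range)
  a <- df$raw_score[df$group == "perturbed"]
  b <- df$raw_score[df$group == "control"]
  shift <- median(a) - median(b)
  p <- if (test == "ranksum") {
    wilcox.test(a, b, exact = FALSE)$p.value
  } else {
    with_seed(seed, {
      pooled <- c(a, b)
      n_a <- length(a)
      null_d <- replicate(n_perm, {
        idx <- sample.int(length(pooled), n_a)
        median(pooled[idx]) - median(pooled[-idx])
      })
      (1 + sum(abs(null_d) >= abs(shift))) / (n_perm + 1)
    })
  }
  structure(
    list(scores = df, shift = shift, p_value = p, test = test),
    class = "pseudotime_comparison"
  )
}

#' @export
print.pseudotime_comparison <- function(x, ...) {
  cat(sprintf(
    "<pseudotime_comparison> shift = %.4g, p = %.3g (%s test)\n",
    x$shift, x$p_value, x$test
  ))
  invisible(x)
}

#' @export
tidy.pseudotime_comparison <- function(x, ...) x$scores

#' @export
glance.pseudotime_comparison <- function(x, ...) {
  tibble::tibble(
    shift = x$shift, p_value = x$p_value, test = x$test,
    n_control = sum(x$scores$group == "control"),
    n_perturbed = sum(x$scores$group == "perturbed")
  )
}

#' Project cells of another species onto the pseudo-maturation model
#'
#' Re-indexes a foreign expression matrix onto the model's genes through an
#' ortholog map (default: case-insensitive gene-symbol matching), imputing
#' unmapped model genes as 0 after standardization, and returns per-cell
#' scores together with the mapped-gene coverage.
#'
#' @param fit a [fit_pseudotime()] result (or a bare scorer).
#' @param foreign_X gene x cell matrix with the foreign gene ids as rows.
#' @param gene_map optional named character vector, foreign id -> model id;
#'   overrides symbol matching.
#' @param min_coverage minimum fraction of model genes that must map.
#' @return List with `scores` (tibble: cell_id, raw_score, scaled_score),
#'   `coverage`, and `unmapped_genes` (model genes without a counterpart).
#' @export
project_cross_species <- function(fit, foreign_X, gene_map = NULL,
                                  min_coverage = 0.5) {
  model <- if (inherits(fit, "pseudotime_fit")) fit$model else fit
  foreign_X <- as.matrix(foreign_X)
  foreign_ids <- rownames(foreign_X)
  mapped_ids <- if (is.null(gene_map)) {
    idx <- match(tolower(foreign_ids), tolower(model$gene_ids))
    ifelse(is.na(idx), NA_character_, model$gene_ids[idx])
  } else {
    unname(gene_map[foreign_ids])
  }
  keep <- !is.na(mapped_ids) & !duplicated(mapped_ids)
  Xm <- foreign_X[keep, , drop = FALSE]
  rownames(Xm) <- mapped_ids[keep]
  unmapped <- setdiff(model$gene_ids, rownames(Xm))
  scores <- suppressWarnings(project(model, Xm, min_coverage = min_coverage))
  scaled <- if (inherits(fit, "pseudotime_fit")) {
    scale_scores(as.numeric(scores), fit$score_range)
  } else {
    rep(NA_real_, length(scores))
  }
  list(
    scores = tibble::tibble(
      cell_id = names(scores) %||% sprintf("f%04d", seq_along(scores)),
      raw_score = as.numeric(scores),
      scaled_score = scaled
    ),
    coverage = attr(scores, "coverage"),
    unmapped_genes = unmapped
  )
}
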