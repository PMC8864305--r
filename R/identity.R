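#' Fit a binary identity model on reference cells
#'
#' The full pipeline behind layer/age identity prediction: hinge classifier
#' on all genes, signed-weight ranking, re-training on the best
#' `n_top + n_bottom` genes, and stratified k-fold (default 20) or
#' leave-one-out cross-validation with ROC/AUC on the reference cells.
#'
#' @param ref_X gene x cell normalized matrix of reference cells.
#' @param binary_labels two-class labels (e.g. "L4" / "L2/3").
#' @param positive_class label scored positive (default last sorted level).
#' @param scheme,k_folds cross-validation scheme.
#' @param seed,n_top,n_bottom,lambda as in [cross_validate()].
#' @return A `cv_result` whose `model` is the re-optimized `linear_scorer`.
#' @export
fit_identity_model <- function(ref_X, binary_labels, positive_class = NULL,
                               scheme = c("kfold", "loo"), k_folds = 20,
                               seed = 1L, n_top = 50, n_bottom = 50,
                               lambda = NULL) {
  scheme <- match.arg(scheme)
  cross_validate(
    ref_X, binary_labels,
    scheme = scheme, k = k_folds, seed = seed,
    model_type = "binary", positive_class = positive_class,
    n_top = n_top, n_bottom = n_bottom, lambda = lambda
  )
}

#' Classify query cells with a fitted identity model
#'
#' Projects query cells and calls the positive class when the score exceeds
#' `threshold` (0 = the decision boundary). Class proportions come with
#' exact (Clopper-Pearson) binomial 95% intervals; per-cell scores are
#' retained for density displays.
#'
#' @param model a `linear_scorer`, or a `cv_result` holding one.
#' @param query_X gene x cell normalized matrix.
#' @param threshold decision threshold on the projected score.
#' @param min_coverage forwarded to [project()].
#' @return List with `cells` (cell_id, score, call) and `proportions`
#'   (class, n, proportion, conf_low, conf_high).
#' @export
classify_query <- function(model, query_X, threshold = 0, min_coverage = 0.5) {
  if (inherits(model, "cv_result")) model <- model$model
  stopifnot(inherits(model, "linear_scorer"))
  query_X <- as.matrix(query_X)
  if (ncol(query_X) == 0L) abort("empty query matrix")
  scores <- project(model, query_X, min_coverage = min_coverage)
  call <- ifelse(
    as.numeric(scores) > threshold, model$positive_class, model$negative_class
  )
  cells <- tibble::tibble(
    cell_id = names(scores) %||% sprintf("q%04d", seq_along(scores)),
    score = as.numeric(scores),
    call = call
  )
  n_total <- nrow(cells)
  props <- purrr::map_dfr(
    c(model$positive_class, model$negative_class),
    function(cl) {
      k <- sum(call == cl)
      ci <- stats::binom.test(k, n_total)$conf.int
      tibble::tibble(
        class = cl, n = k, proportion = k / n_total,
        conf_low = ci[1], conf_high = ci[2]
      )
    }
  )
  list(cells = cells, proportions = props)
}

#' Contingency-table proportion test (Pearson chi-square, Fisher exact)
#'
#' Computes the Pearson chi-square statistic (no continuity correction by
#' default) for an R x C table of class counts; for 2 x 2 tables the
#' two-sided Fisher exact p-value is reported alongside, covering both
#' readings of a "Fisher's chi-square" test.
#'
#' @param counts non-negative integer matrix (>= 2 rows and columns).
#' @param correct apply Yates continuity correction to the chi-square.
#' @return Tibble with one row per method: `method`, `statistic`, `df`,
#'   `p_value`.
#' @export
proportion_test <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    abort("`counts` must be at least 2 x 2")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must hold non-negative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("zero row or column margin")
  }
  chi <- suppressWarnings(chisq.test(counts, correct = correct))
  out <- tibble::tibble(
    method = "chi-square",
    statistic = unname(chi$statistic),
    df = unname(chi$parameter),
    p_value = chi$p.value
  )
  if (all(dim(counts) == c(2L, 2L))) {
    fe <- fisher.test(counts)
    out <- dplyr::bind_rows(out, tibble::tibble(
      method = "fisher-exact", statistic = NA_real_, df = NA_real_,
      p_value = fe$p.value
    ))
  }
  out
}

#' Pseudo-maturation scoring against P3 vs P7 reference models, per layer
#'
#' For each layer, fits a binary age-identity model (P3 vs P7) on the
#' reference cells of that layer, projects the query cells, and compares
#' query scores to the reference cells' cross-validated scores by a
#' two-sided rank-sum test. Layers missing an age class are skipped with a
#' warning.
#'
#' @param ref_X gene x cell normalized reference matrix.
#' @param ref_age,ref_layer per-reference-cell age and layer labels.
#' @param query_X gene x cell normalized query matrix.
#' @param query_layer optional per-query-cell layer; when given, each
#'   layer's model only scores its own query cells.
#' @param positive_class age scored positive (default last sorted, "P7").
#' @param k_folds,seed,n_top,n_bottom,lambda model settings.
#' @return Tibble with one row per layer: cell counts, model AUC, query
#'   median shift relative to reference `positive_class` cells, rank-sum
#'   p-value, plus `cv` and `query_scores` list-columns.
#' @export
pseudo_maturation_p3p7 <- function(ref_X, ref_age, ref_layer, query_X,
                                   query_layer = NULL, positive_class = NULL,
                                   k_folds = 20, seed = 1L, n_top = 50,
                                   n_bottom = 50, lambda = NULL) {
  ref_X <- as.matrix(ref_X)
  ref_age <- as.character(ref_age)
  ref_layer <- as.character(ref_layer)
  layers <- sort(unique(ref_layer))
  rows <- purrr::map(layers, function(ly) {
    sel <- ref_layer == ly
    ages <- unique(ref_age[sel])
    if (length(ages) < 2L) {
      warn(sprintf("layer %s skipped: only age %s present", ly, ages))
      return(NULL)
    }
    cv <- fit_identity_model(
      ref_X[, sel, drop = FALSE], ref_age[sel],
      positive_class = positive_class, k_folds = k_folds,
      seed = seed + match(ly, layers), n_top = n_top, n_bottom = n_bottom,
      lambda = lambda
    )
    qsel <- if (is.null(query_layer)) {
      rep(TRUE, ncol(query_X))
    } else {
      as.character(query_layer) == ly
    }
    if (!any(qsel)) {
      warn(sprintf("layer %s: no query cells", ly))
      return(NULL)
    }
    q <- project(cv$model, as.matrix(query_X)[, qsel, drop = FALSE])
    ref_scores <- cv$cells$score
    p <- wilcox.test(as.numeric(q), ref_scores, exact = FALSE)$p.value
    tibble::tibble(
      layer = ly,
      n_ref = sum(sel), n_query = sum(qsel),
      auc = cv$auc,
      query_median = median(as.numeric(q)),
      ref_median = median(ref_scores),
      shift = median(as.numeric(q)) - median(ref_scores),
      p_value = p,
      cv = list(cv),
      query_scores = list(tibble::tibble(
        cell_id = names(q) %||% sprintf("q%04d", seq_along(q)),
        score = as.numeric(q)
      ))
    )
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (!nrow(out)) abort("no layer had both age classes")
  out
}
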