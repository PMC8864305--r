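#' ROC curve and tie-corrected AUC
#'
#' The AUC is the pairwise concordance probability: over all
#' (positive, negative) cell pairs, the fraction where the positive scores
#' higher, with exact score ties counting 1/2. ROC points trace sensitivity
#' against 1 - specificity over all score thresholds (tied scores collapse
#' onto one threshold).
#'
#' @param scores numeric prediction scores, higher = more positive-like.
#' @param labels binary labels (+/-1, logical, or 2-level factor/character).
#' @param positive_class which label counts as positive (as in
#'   [train_binary()]).
#' @return List with `auc` and `roc`, a tibble of
#'   (`threshold`, `sensitivity`, `specificity`).
#' @export
roc_auc <- function(scores, labels, positive_class = NULL) {
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` lengths differ")
  }
  pos <- if (is.logical(labels)) {
    labels
  } else {
    encode_binary(labels, positive_class)$y > 0
  }
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) abort("both classes must be present")

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  grp <- cumsum(c(TRUE, s[-1] != s[-length(s)]))
  pos_at <- as.numeric(tapply(as.numeric(p), grp, sum))
  neg_at <- as.numeric(tapply(as.numeric(!p), grp, sum))
  pos_above <- cumsum(pos_at) - pos_at
  concordant <- sum(pos_above * neg_at) + 0.5 * sum(pos_at * neg_at)
  auc <- concordant / (n1 * n0)

  thr <- as.numeric(tapply(s, grp, function(v) v[1]))
  roc <- tibble::tibble(
    threshold = c(Inf, as.numeric(thr)),
    sensitivity = c(0, cumsum(pos_at) / n1),
    specificity = c(1, 1 - cumsum(neg_at) / n0)
  )
  list(auc = unname(auc), roc = roc)
}

# stratified fold assignment; balances overall fold sizes by rotating the
# starting fold across classes
make_folds <- function(labels, k, seed) {
  n <- length(labels)
  if (k > n) abort(sprintf("k (%d) exceeds number of cells (%d)", k, n))
  with_seed(seed, {
    folds <- integer(n)
    start <- 0L
    for (cls in sort(unique(as.character(labels)))) {
      idx <- sample(which(as.character(labels) == cls))
      folds[idx] <- ((start + seq_along(idx) - 1L) %% k) + 1L
      start <- start + length(idx)
    }
    folds
  })
}

#' Cross-validated model scores with in-fold gene selection
#'
#' Runs the full pipeline — train on all genes, rank by signed weight,
#' retrain on the best `n_top + n_bottom` genes — inside every training fold,
#' then scores the held-out cells, so gene selection never sees the held-out
#' data. Every cell receives exactly one held-out score; folds are
#' stratified by class and reproducible from `seed`. Leave-one-out is
#' `scheme = "loo"`.
#'
#' With `select_in_fold = FALSE` genes are selected once on the full data
#' and only the restricted model is refitted per fold (the historical
#' variant; optimistic for gene selection).
#'
#' @param X gene x cell normalized expression matrix.
#' @param y_or_labels binary labels or ordered categories.
#' @param scheme `"kfold"` or `"loo"`.
#' @param k number of folds for `"kfold"`.
#' @param seed RNG seed for the fold partition.
#' @param model_type `"binary"` or `"ordinal"`.
#' @param n_top,n_bottom genes kept from each end of the ranking; set both
#'   to `NULL` to skip re-optimization.
#' @param positive_class,categories label handling, as in the trainers.
#' @param lambda,tol,max_iter,standardize solver settings.
#' @param select_in_fold rank/select genes inside each fold (no leakage).
#' @param max_redraws redraws allowed when a training fold misses a class.
#' @return A `cv_result`: tibble `cells` (`cell_id`, `fold`, `label`,
#'   `score`), `auc` + `roc` (binary only), the final model trained on all
#'   cells, the scheme and seed.
#' @export
cross_validate <- function(X, y_or_labels, scheme = c("kfold", "loo"), k = 20,
                           seed = 1L, model_type = c("binary", "ordinal"),
                           n_top = 50, n_bottom = 50, positive_class = NULL,
                           categories = NULL, lambda = NULL, tol = 1e-6,
                           max_iter = 10000, standardize = TRUE,
                           select_in_fold = TRUE, max_redraws = 20L) {
  X <- as.matrix(X)
  scheme <- match.arg(scheme)
  model_type <- match.arg(model_type)
  n <- ncol(X)
  labels <- y_or_labels
  if (scheme == "loo") {
    if (n < 3L) abort("leave-one-out needs >= 3 cells")
    folds <- seq_len(n)
    k_eff <- n
  } else {
    k_eff <- k
    folds <- make_folds(labels, k, seed)
    # every training fold (complement of one fold) must keep >= 2 classes
    redraw <- 0L
    while (redraw < max_redraws) {
      bad <- any(vapply(
        seq_len(k_eff),
        function(f) length(unique(as.character(labels)[folds != f])) < 2L,
        logical(1)
      ))
      if (!bad) break
      redraw <- redraw + 1L
      warn(sprintf("training fold missing a class; redrawing partition (%d)", redraw))
      folds <- make_folds(labels, k, seed + 1000L * redraw)
    }
    if (redraw == max_redraws) abort("could not draw folds covering all classes")
  }

  train_fun <- function(Xs, lab, init = NULL) {
    if (model_type == "binary") {
      train_binary(Xs, lab,
        positive_class = positive_class, lambda = lambda, tol = tol,
        max_iter = max_iter, standardize = standardize, init = init
      )
    } else {
      train_ordinal(Xs, lab,
        categories = categories, lambda = lambda, tol = tol,
        max_iter = max_iter, standardize = standardize, init = init
      )
    }
  }
  do_select <- !is.null(n_top) && !is.null(n_bottom)

  full <- train_fun(X, labels)
  final_model <- if (do_select) {
    retrain_top_genes(X, labels, full,
      n_top = n_top, n_bottom = n_bottom,
      tol = tol, max_iter = max_iter
    )
  } else {
    full
  }
  scores <- rep(NA_real_, n)
  for (f in unique(folds)) {
    tr <- folds != f
    if (length(unique(as.character(labels)[tr])) < 2L) {
      warn(sprintf("fold %d: training data has a single class, skipped", f))
      next
    }
    # fold models start cold: warm-starting from a fit that saw the held-out
    # cells would leak information through the initialization
    fold_model <- if (select_in_fold || !do_select) {
      m0 <- train_fun(X[, tr, drop = FALSE], labels[tr])
      if (do_select) {
        retrain_top_genes(X[, tr, drop = FALSE], labels[tr], m0,
          n_top = n_top, n_bottom = n_bottom, tol = tol, max_iter = max_iter
        )
      } else {
        m0
      }
    } else {
      train_fun(X[final_model$gene_ids, tr, drop = FALSE], labels[tr])
    }
    scores[folds == f] <- project(fold_model, X[, folds == f, drop = FALSE])
  }

  cells <- tibble::tibble(
    cell_id = colnames(X) %||% as.character(seq_len(n)),
    fold = folds,
    label = as.character(labels),
    score = scores
  )
  res <- list(
    cells = cells, scheme = scheme, k = k_eff, seed = seed,
    model = final_model, model_type = model_type
  )
  if (model_type == "binary") {
    ok <- !is.na(scores)
    ra <- roc_auc(scores[ok], labels[ok], positive_class = final_model$positive_class)
    res$auc <- ra$auc
    res$roc <- ra$roc
  } else {
    res$auc <- NA_real_
    res$roc <- NULL
  }
  structure(res, class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %s (%d folds), %d cells%s\n",
    x$scheme, x$k, nrow(x$cells),
    if (!is.na(x$auc)) sprintf(", AUC = %.3f", x$auc) else ""
  ))
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) x$cells

#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, n_cells = nrow(x$cells), scheme = x$scheme, k = x$k,
    seed = x$seed, n_model_genes = length(x$model$weights)
  )
}

#' @describeIn cross_validate ROC curve of a binary `cv_result`.
#' @param object,... `autoplot` arguments.
#' @export
autoplot.cv_result <- function(object, ...) {
  if (is.null(object$roc)) abort("no ROC curve for ordinal cross-validation")
  ggplot2::ggplot(
    object$roc,
    ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)
  ) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}
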