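#' Train a regularized hinge-loss binary classifier
#'
#' Minimizes `(1/n) sum_i max(0, 1 - y_i (w.x_i + b)) + (lambda/2) ||w||^2`
#' with an unregularized bias. Genes are standardized (mean 0, sd 1) on the
#' training cells by default; the standardization parameters travel with the
#' model so that [project()] reproduces in-sample scores exactly. The score
#' of a cell is the linear combination `w.x + b`; positive scores point to
#' `positive_class`.
#'
#' @param X gene x cell normalized expression matrix with gene row names.
#' @param y labels: +/-1 numeric, or a 2-level factor/character vector.
#' @param positive_class which label maps to +1 (default: last sorted level).
#' @param lambda ridge penalty on the gene weights; default 1 (unit ridge on
#'   standardized genes, appropriate for gene counts far exceeding cells).
#' @param tol relative objective tolerance of the solver.
#' @param max_iter iteration cap; exceeding it is an error.
#' @param standardize per-gene standardization on the training cells.
#' @param init optional warm-start parameter vector `c(w, b)`.
#' @return A `linear_scorer` with fields `gene_ids`, `weights`, `bias`,
#'   `lambda`, `mean`, `sd`, `objective`, `positive_class`, `negative_class`.
#' @export
train_binary <- function(X, y, positive_class = NULL, lambda = NULL,
                         tol = 1e-6, max_iter = 10000, standardize = TRUE,
                         init = NULL) {
  X <- as.matrix(X)
  if (tol <= 0) abort("`tol` must be positive")
  enc <- encode_binary(y, positive_class)
  if (length(unique(enc$y)) < 2L) {
    abort("both classes must be present in `y`")
  }
  if (any(!is.finite(X))) abort("`X` contains non-finite values")
  n <- ncol(X)
  lambda <- lambda %||% 1
  if (lambda <= 0) abort("`lambda` must be positive")
  Xt <- t(X)
  std <- if (standardize) {
    standardize_train(Xt)
  } else {
    list(x = Xt, mean = rep(0, ncol(Xt)), sd = rep(1, ncol(Xt)))
  }
  fit <- solve_hinge_binary(std$x, enc$y, lambda, tol, max_iter, init = init)
  gene_ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
  structure(
    list(
      gene_ids = gene_ids,
      weights = stats::setNames(fit$w, gene_ids),
      bias = fit$b,
      lambda = lambda,
      mean = stats::setNames(std$mean, gene_ids),
      sd = stats::setNames(std$sd, gene_ids),
      objective = fit$objective,
      standardized = standardize,
      positive_class = enc$positive,
      negative_class = enc$negative
    ),
    class = "linear_scorer"
  )
}

encode_binary <- function(y, positive_class = NULL) {
  if (is.numeric(y) && all(y %in% c(-1, 1))) {
    return(list(y = as.numeric(y), positive = "1", negative = "-1"))
  }
  y <- as.character(y)
  lev <- sort(unique(y))
  if (length(lev) != 2L) {
    abort(sprintf("`y` must have exactly 2 classes, found %d", length(lev)))
  }
  pos <- positive_class %||% lev[2]
  if (!pos %in% lev) abort(sprintf("positive_class '%s' not among labels", pos))
  neg <- setdiff(lev, pos)
  list(y = ifelse(y == pos, 1, -1), positive = pos, negative = neg)
}

#' Train a regularized all-threshold ordinal regression model
#'
#' Fits linear weights `w` and K-1 strictly increasing thresholds `theta` by
#' minimizing the all-threshold hinge objective
#' `(1/n) sum_i sum_k max(0, 1 - s_ik (w.x_i - theta_k)) + (lambda/2)||w||^2`
#' where `s_ik = +1` if cell i's category lies above threshold k and -1
#' otherwise. The pseudotime (pseudo-maturation) score of a cell is `w.x`.
#'
#' @param X gene x cell normalized expression matrix.
#' @param labels ordered factor (or vector coercible via `categories`).
#' @param categories category order, lowest first; default the ordered-factor
#'   levels of `labels`.
#' @inheritParams train_binary
#' @return An `ordinal_scorer` with `weights`, `thresholds`, `categories`,
#'   standardization parameters and the achieved objective.
#' @export
train_ordinal <- function(X, labels, categories = NULL, lambda = NULL,
                          tol = 1e-6, max_iter = 10000, standardize = TRUE,
                          init = NULL) {
  X <- as.matrix(X)
  if (tol <= 0) abort("`tol` must be positive")
  if (is.null(categories)) {
    categories <- if (is.factor(labels)) levels(labels) else sort(unique(as.character(labels)))
  }
  cat_idx <- match(as.character(labels), categories)
  if (anyNA(cat_idx)) abort("labels outside `categories`")
  present <- sort(unique(cat_idx))
  if (length(present) < 2L) abort("need >= 2 non-empty ordered categories")
  n <- ncol(X)
  lambda <- lambda %||% 1
  Xt <- t(X)
  std <- if (standardize) {
    standardize_train(Xt)
  } else {
    list(x = Xt, mean = rep(0, ncol(Xt)), sd = rep(1, ncol(Xt)))
  }
  fit <- solve_hinge_ordinal(
    std$x, cat_idx, length(categories) - 1L, lambda, tol, max_iter,
    init = init
  )
  gene_ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
  structure(
    list(
      gene_ids = gene_ids,
      weights = stats::setNames(fit$w, gene_ids),
      thresholds = fit$theta,
      categories = categories,
      lambda = lambda,
      mean = stats::setNames(std$mean, gene_ids),
      sd = stats::setNames(std$sd, gene_ids),
      objective = fit$objective,
      standardized = standardize
    ),
    class = "ordinal_scorer"
  )
}

#' @export
print.linear_scorer <- function(x, ...) {
  cat(sprintf(
    "<linear_scorer> %d genes, lambda=%.3g, objective=%.4g (%s vs %s)\n",
    length(x$weights), x$lambda, x$objective, x$positive_class, x$negative_class
  ))
  invisible(x)
}

#' @export
print.ordinal_scorer <- function(x, ...) {
  cat(sprintf(
    "<ordinal_scorer> %d genes, %d categories (%s), lambda=%.3g\n",
    length(x$weights), length(x$categories),
    paste(x$categories, collapse = " < "), x$lambda
  ))
  invisible(x)
}

#' Rank genes of a trained model by signed weight
#'
#' Most positive weight first, ties broken lexicographically by gene id, so
#' the ranking is stable and reproducible.
#'
#' @param model a `linear_scorer` or `ordinal_scorer`.
#' @return Tibble with `gene_id`, `weight`, `rank`.
#' @export
rank_genes <- function(model) {
  stopifnot(inherits(model, c("linear_scorer", "ordinal_scorer")))
  ord <- order(-model$weights, names(model$weights))
  tibble::tibble(
    gene_id = names(model$weights)[ord],
    weight = unname(model$weights[ord]),
    rank = seq_along(ord)
  )
}

#' Re-train a model on its best genes (top and bottom of the ranking)
#'
#' Selects the `n_top` most-positive and `n_bottom` most-negative weighted
#' genes of `model` (signed-weight ranking, ties by gene id) and retrains the
#' same objective restricted to them — the "best 100 genes (top 50 and
#' bottom 50)" re-optimization.
#'
#' @param X gene x cell normalized expression matrix (training data).
#' @param y_or_labels labels as in [train_binary()] / [train_ordinal()].
#' @param model the full-gene trained model to select from.
#' @param n_top,n_bottom gene counts from each end of the ranking.
#' @param ... passed to the trainer.
#' @return A model of the same class fitted on the selected genes.
#' @export
retrain_top_genes <- function(X, y_or_labels, model, n_top = 50, n_bottom = 50,
                              ...) {
  ranked <- rank_genes(model)
  if (n_top + n_bottom > nrow(ranked)) {
    abort(sprintf(
      "n_top + n_bottom (%d) exceeds gene count (%d)",
      n_top + n_bottom, nrow(ranked)
    ))
  }
  genes <- c(
    head(ranked$gene_id, n_top),
    rev(tail(ranked$gene_id, n_bottom))
  )
  Xs <- as.matrix(X)[genes, , drop = FALSE]
  if (inherits(model, "linear_scorer")) {
    train_binary(Xs, y_or_labels,
      positive_class = model$positive_class,
      lambda = model$lambda, standardize = model$standardized,
      init = c(unname(model$weights[genes]), model$bias), ...
    )
  } else {
    train_ordinal(Xs, y_or_labels,
      categories = model$categories,
      lambda = model$lambda, standardize = model$standardized,
      init = c(unname(model$weights[genes]), model$thresholds), ...
    )
  }
}

#' Score cells with a trained model
#'
#' Computes the linear-combination score `w.x` (+ bias for binary models) of
#' each column of `X_new`, standardizing by the model's stored training
#' parameters. Model genes missing from `X_new` contribute 0 after
#' standardization and are reported in a coverage warning; the call errors
#' when coverage falls below `min_coverage`.
#'
#' @param model a `linear_scorer` or `ordinal_scorer`.
#' @param X_new gene x cell matrix; rows matched to model genes by name.
#' @param min_coverage minimum fraction of model genes that must be present.
#' @return Named numeric vector of per-cell scores; the realized coverage is
#'   attached as attribute `"coverage"`.
#' @export
project <- function(model, X_new, min_coverage = 0.5) {
  stopifnot(inherits(model, c("linear_scorer", "ordinal_scorer")))
  X_new <- as.matrix(X_new)
  idx <- match(model$gene_ids, rownames(X_new))
  coverage <- mean(!is.na(idx))
  if (coverage < min_coverage) {
    abort(sprintf(
      "only %.0f%% of model genes present (< %.0f%% required)",
      100 * coverage, 100 * min_coverage
    ))
  }
  missing <- model$gene_ids[is.na(idx)]
  if (length(missing)) {
    warn(sprintf(
      "%d model gene(s) absent from the matrix, contributing 0: %s%s",
      length(missing), paste(head(missing, 5), collapse = ", "),
      if (length(missing) > 5) ", ..." else ""
    ))
  }
  Z <- matrix(0, nrow = length(model$gene_ids), ncol = ncol(X_new))
  ok <- !is.na(idx)
  Z[ok, ] <- (X_new[idx[ok], , drop = FALSE] - model$mean[ok]) / model$sd[ok]
  scores <- drop(crossprod(Z, unname(model$weights)))
  if (inherits(model, "linear_scorer")) scores <- scores + model$bias
  names(scores) <- colnames(X_new)
  attr(scores, "coverage") <- coverage
  scores
}

#' @export
tidy.linear_scorer <- function(x, ...) rank_genes(x)

#' @export
tidy.ordinal_scorer <- function(x, ...) rank_genes(x)

#' @export
glance.linear_scorer <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$weights), lambda = x$lambda, objective = x$objective,
    bias = x$bias, positive_class = x$positive_class
  )
}

#' @export
glance.ordinal_scorer <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$weights), lambda = x$lambda, objective = x$objective,
    n_categories = length(x$categories)
  )
}

#' Serialize a trained scorer to a versioned JSON document
#'
#' @param model a `linear_scorer` or `ordinal_scorer`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_scorer <- function(model, path) {
  stopifnot(inherits(model, c("linear_scorer", "ordinal_scorer")))
  doc <- c(
    list(format = "cortiscore_scorer", version = 1L, type = class(model)[1]),
    lapply(unclass(model), unname),
    list(gene_ids = model$gene_ids)
  )
  doc <- doc[!duplicated(names(doc))]
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scorer
#' @export
read_scorer <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "cortiscore_scorer")) {
    abort("not a cortiscore scorer document")
  }
  type <- doc$type
  doc <- doc[setdiff(names(doc), c("format", "version", "type"))]
  for (nm in c("weights", "mean", "sd")) names(doc[[nm]]) <- doc$gene_ids
  structure(doc, class = type)
}
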