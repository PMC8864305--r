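# Small fixtures, built in code.

# scaled-down trajectory config for fast unit tests
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(
      n_genes = 300, n_marker_genes_per_type = 15, n_mito_genes = 20,
      cells_per_condition = c(scram = 60L, miR = 60L),
      n_induced = 20, n_repressed = 20,
      library_size_mean = 8000
    ),
    list(...)
  )
  do.call(sim_config, args)
}

tiny_dataset <- function(seed = 1L, ...) {
  generate_trajectory_dataset(tiny_config(seed = seed, ...))
}

# deterministic toy count matrix with named genes/cells
toy_counts <- function(mat, genes = NULL, cells = NULL) {
  genes <- genes %||% sprintf("g%02d", seq_len(nrow(mat)))
  cells <- cells %||% sprintf("c%02d", seq_len(ncol(mat)))
  dimnames(mat) <- list(genes, cells)
  mat
}

rlang_ns <- asNamespace("rlang")
`%||%` <- get("%||%", envir = rlang_ns)

# --- independent grid-search oracle for the regularized hinge objectives ---

# binary: exhaustive search over (w1, w2, b) with two refinement stages
grid_oracle_binary <- function(X, y, lambda) {
  obj <- function(par_mat) {
    scores <- X %*% t(par_mat[, 1:2, drop = FALSE])
    scores <- sweep(scores, 2, par_mat[, 3], "+")
    margins <- scores * y
    h <- pmax(0, 1 - margins)
    dim(h) <- dim(margins)
    colMeans(h) +
      lambda / 2 * rowSums(par_mat[, 1:2, drop = FALSE]^2)
  }
  centre <- c(0, 0, 0)
  width <- 3
  best <- Inf
  for (step in c(0.1, 0.01, 0.002)) {
    g <- seq(-width, width, by = step)
    grid <- as.matrix(expand.grid(
      w1 = centre[1] + g, w2 = centre[2] + g, b = centre[3] + g
    ))
    vals <- obj(grid)
    i <- which.min(vals)
    best <- vals[i]
    centre <- grid[i, ]
    width <- step * 2
  }
  best
}

# ordinal (1 gene, K categories): search over (w, theta_1..theta_{K-1})
grid_oracle_ordinal <- function(x, cat_idx, K, lambda) {
  obj <- function(par_mat) {
    vals <- numeric(nrow(par_mat))
    for (i in seq_len(nrow(par_mat))) {
      w <- par_mat[i, 1]
      theta <- par_mat[i, -1]
      f <- x * w
      tot <- 0
      for (k in seq_len(K - 1)) {
        s <- ifelse(cat_idx > k, 1, -1)
        tot <- tot + sum(pmax(0, 1 - s * (f - theta[k])))
      }
      vals[i] <- tot / length(x) + lambda / 2 * w^2
    }
    vals
  }
  centre <- rep(0, K)
  width <- 3
  best <- Inf
  for (step in c(0.2, 0.02, 0.004)) {
    axes <- lapply(seq_len(K), function(j) centre[j] + seq(-width, width, by = step))
    grid <- as.matrix(do.call(expand.grid, axes))
    vals <- obj(grid)
    i <- which.min(vals)
    best <- vals[i]
    centre <- grid[i, ]
    width <- step * 2
  }
  best
}

# tie-aware AUC through the rank-sum (Mann-Whitney) transformation
rank_sum_auc <- function(scores, pos) {
  r <- rank(scores, ties.method = "average")
  n1 <- sum(pos)
  n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# two-sided Fisher exact p by full enumeration of tables with fixed margins
enum_fisher_p <- function(tab) {
  a_obs <- tab[1, 1]
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  a_range <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(a_range, c1, n - c1, r1)
  p_obs <- stats::dhyper(a_obs, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# QC fixture: each cell expresses exactly `detected` genes, a slice of them
# mitochondrial so that the realized count-based mito fraction is `mito_frac`
make_qc_dataset <- function(detected, mito_frac, n_genes = 3000, n_mito = 400) {
  n_cells <- length(detected)
  m <- matrix(0L, n_genes, n_cells)
  for (i in seq_len(n_cells)) {
    n_mt <- round(detected[i] * mito_frac[i])
    m[seq_len(detected[i] - n_mt) + n_mito, i] <- 1L
    if (n_mt > 0) m[seq_len(n_mt), i] <- 1L
  }
  genes <- c(
    sprintf("mt-%03d", seq_len(n_mito)),
    sprintf("g%04d", seq_len(n_genes - n_mito))
  )
  m <- toy_counts(m, genes = genes)
  expr_dataset(m, tibble::tibble(cell_id = colnames(m)))
}
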