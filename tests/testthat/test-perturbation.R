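tiny_perturb_inputs <- function(seed = 1L, ...) {
  ds <- tiny_dataset(seed = seed, ...)
  nm <- normalize_rpm_log(ds)
  list(
    norm = nm,
    types = as.character(ds$cell_meta$true_type),
    cond = ds$cell_meta$condition,
    gene_meta = ds$gene_meta
  )
}

test_that("the perturbed cell type carries the top AUC", {
  inp <- tiny_perturb_inputs(seed = 2, effect_log_fold = 1.5)
  res <- suppressWarnings(score_cell_types(
    inp$norm, inp$types, inp$cond,
    k_folds = 10, min_cells = 10, seed = 2
  ))
  bp <- res$auc[res$cell_type == "BP"]
  expect_identical(res$cell_type[which.max(res$auc)], "BP")
  expect_gte(bp, 0.8)
})

test_that("undersized cell types are skipped and named", {
  inp <- tiny_perturb_inputs(seed = 3)
  types <- inp$types
  types[types == "N1"][-(1:3)] <- "N0" # leave N1 with 3 cells
  expect_warning(
    res <- score_cell_types(
      inp$norm, types, inp$cond,
      k_folds = 5, min_cells = 10, seed = 1
    ),
    "N1 skipped"
  )
  expect_true(res$skipped[res$cell_type == "N1"])
  expect_true(is.na(res$auc[res$cell_type == "N1"]))
})

test_that("results for one type are independent of the other types' cells", {
  inp <- tiny_perturb_inputs(seed = 4)
  keep_bp_n0 <- inp$types %in% c("BP", "N0")
  full <- suppressWarnings(score_cell_types(
    inp$norm, inp$types, inp$cond,
    k_folds = 5, min_cells = 10, seed = 9
  ))
  partial <- suppressWarnings(score_cell_types(
    inp$norm[, keep_bp_n0], inp$types[keep_bp_n0], inp$cond[keep_bp_n0],
    k_folds = 5, min_cells = 10, seed = 9
  ))
  expect_equal(
    full$auc[full$cell_type == "BP"],
    partial$auc[partial$cell_type == "BP"]
  )
})

test_that("AUC of the perturbed type grows with the injected effect size", {
  aucs <- vapply(c(0.25, 1, 2.5), function(eff) {
    inp <- tiny_perturb_inputs(seed = 5, effect_log_fold = eff)
    sel <- inp$types == "BP"
    cross_validate(
      inp$norm[, sel], inp$cond[sel],
      k = 10, seed = 5, positive_class = "miR"
    )$auc
  }, numeric(1))
  expect_true(all(diff(aucs) >= 0)) # non-decreasing, saturation at 1 allowed
  expect_gt(aucs[3], aucs[1])
})

test_that("top regulated gene lists follow weight signs and flip with encoding", {
  m <- structure(
    list(
      gene_ids = c("g1", "g2", "g3"),
      weights = c(g1 = 2, g2 = -3, g3 = 0.1), bias = 0, lambda = 1,
      mean = c(g1 = 0, g2 = 0, g3 = 0), sd = c(g1 = 1, g2 = 1, g3 = 1),
      objective = 0, standardized = FALSE,
      positive_class = "miR", negative_class = "scram"
    ),
    class = "linear_scorer"
  )
  tg <- top_regulated_genes(m, n = 1)
  expect_identical(tg$gene_id[tg$direction == "induced"], "g1")
  expect_identical(tg$gene_id[tg$direction == "repressed"], "g2")
  # flipping the encoding swaps induced and repressed
  m_flip <- m
  m_flip$weights <- -m$weights
  m_flip$positive_class <- "scram"
  m_flip$negative_class <- "miR"
  tg_flip <- top_regulated_genes(m_flip, n = 1)
  expect_identical(tg_flip$gene_id[tg_flip$direction == "induced"], "g2")
  expect_identical(tg_flip$gene_id[tg_flip$direction == "repressed"], "g1")
  expect_warning(
    expect_warning(top_regulated_genes(m, n = 3), "positive weight"),
    "negative weight"
  )
})

test_that("most reported induced genes are truly induced on synthetic data", {
  inp <- tiny_perturb_inputs(seed = 6, effect_log_fold = 1.5)
  sel <- inp$types == "BP"
  cv <- cross_validate(
    inp$norm[, sel], inp$cond[sel],
    k = 10, seed = 3, positive_class = "miR",
    n_top = 20, n_bottom = 20
  )
  tg <- top_regulated_genes(cv$model, n = 20)
  truth_up <- inp$gene_meta$gene_id[inp$gene_meta$true_effect == 1]
  hits <- mean(tg$gene_id[tg$direction == "induced"] %in% truth_up)
  expect_gte(hits, 0.8)
})
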