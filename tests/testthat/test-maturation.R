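tiny_maturation <- function(seed = 1L, delay = 0, n = 60L) {
  ds <- tiny_dataset(
    seed = seed, maturation_delay = delay, effect_log_fold = 0,
    cells_per_condition = c(scram = n, miR = n)
  )
  nm <- normalize_rpm_log(ds)
  list(
    norm = nm, meta = ds$cell_meta,
    ctrl = ds$cell_meta$condition == "scram"
  )
}

test_that("pooling progenitors yields a 3-category model with 2 thresholds", {
  inp <- tiny_maturation(seed = 20)
  fit <- fit_pseudotime(
    inp$norm[, inp$ctrl], inp$meta$true_type[inp$ctrl],
    pool_progenitors = TRUE, cv_scheme = "kfold", k = 5, seed = 1
  )
  expect_identical(fit$categories, c("AP+BP", "N0", "N1"))
  expect_length(fit$model$thresholds, 2)
})

test_that("cross-validated pseudotime tracks the latent maturation", {
  inp <- tiny_maturation(seed = 21)
  fit <- fit_pseudotime(
    inp$norm[, inp$ctrl], inp$meta$true_type[inp$ctrl],
    cv_scheme = "kfold", k = 10, seed = 2, n_top = 25, n_bottom = 25
  )
  sp <- cor(
    fit$cv$cells$score, inp$meta$true_maturation[inp$ctrl],
    method = "spearman"
  )
  expect_gte(sp, 0.9)
  # in-sample and held-out scores agree on well-separated data
  in_sample <- project(fit$model, inp$norm[, inp$ctrl])
  expect_gte(cor(in_sample, fit$cv$cells$score, method = "spearman"), 0.9)
})

test_that("comparing a group against itself gives no shift", {
  inp <- tiny_maturation(seed = 22)
  fit <- fit_pseudotime(
    inp$norm[, inp$ctrl], inp$meta$true_type[inp$ctrl],
    cv_scheme = "kfold", k = 5, seed = 3
  )
  cmp <- score_and_compare(
    fit, inp$norm[, inp$ctrl],
    perturbed_types = inp$meta$true_type[inp$ctrl]
  )
  # perturbed scores are in-sample while control scores are cross-validated,
  # so equality is approximate: the shift stays inside the null band
  perm <- score_and_compare(
    fit, inp$norm[, inp$ctrl],
    perturbed_types = inp$meta$true_type[inp$ctrl],
    test = "permutation", n_perm = 200, seed = 4
  )
  expect_gt(perm$p_value, 0.05)
  expect_s3_class(tidy(cmp), "tbl_df")
})

test_that("an injected maturation delay is detected as a negative shift", {
  inp <- tiny_maturation(seed = 23, delay = -0.25, n = 80L)
  fit <- fit_pseudotime(
    inp$norm[, inp$ctrl], inp$meta$true_type[inp$ctrl],
    cv_scheme = "kfold", k = 10, seed = 5
  )
  cmp <- score_and_compare(
    fit, inp$norm[, !inp$ctrl],
    perturbed_types = inp$meta$true_type[!inp$ctrl]
  )
  expect_lt(cmp$shift, 0)
  expect_lt(cmp$p_value, 0.01)
  # restricting to postmitotic categories keeps the call
  cmp_n <- score_and_compare(
    fit, inp$norm[, !inp$ctrl],
    perturbed_types = inp$meta$true_type[!inp$ctrl],
    restrict_to = c("N0", "N1")
  )
  expect_true(all(cmp_n$scores$category %in% c("N0", "N1")))
})

test_that("zero delay stays inside the permutation null band", {
  inp <- tiny_maturation(seed = 24, delay = 0)
  fit <- fit_pseudotime(
    inp$norm[, inp$ctrl], inp$meta$true_type[inp$ctrl],
    cv_scheme = "kfold", k = 5, seed = 6
  )
  cmp <- score_and_compare(
    fit, inp$norm[, !inp$ctrl],
    perturbed_types = inp$meta$true_type[!inp$ctrl],
    test = "permutation", n_perm = 400, seed = 7
  )
  expect_gt(cmp$p_value, 0.05)
})

test_that("cross-species projection maps symbols case-insensitively", {
  inp <- tiny_maturation(seed = 25)
  fit <- fit_pseudotime(
    inp$norm[, inp$ctrl], inp$meta$true_type[inp$ctrl],
    cv_scheme = "kfold", k = 5, seed = 8
  )
  upper <- inp$norm[, inp$ctrl]
  rownames(upper) <- toupper(rownames(upper))
  res <- project_cross_species(fit, upper)
  expect_equal(res$coverage, 1)
  expect_equal(
    res$scores$raw_score,
    as.numeric(project(fit$model, inp$norm[, inp$ctrl]))
  )
  # explicit map overrides symbol matching
  map <- setNames(fit$model$gene_ids, paste0("X_", fit$model$gene_ids))
  renamed <- inp$norm[fit$model$gene_ids, inp$ctrl]
  rownames(renamed) <- paste0("X_", fit$model$gene_ids)
  res2 <- project_cross_species(fit, renamed, gene_map = map)
  expect_equal(res2$scores$raw_score, res$scores$raw_score)
})

test_that("scores degrade gracefully when a third of model genes are missing", {
  inp <- tiny_maturation(seed = 26)
  fit <- fit_pseudotime(
    inp$norm[, inp$ctrl], inp$meta$true_type[inp$ctrl],
    cv_scheme = "kfold", k = 5, seed = 9
  )
  full <- project(fit$model, inp$norm[, inp$ctrl])
  set.seed(10)
  dropped <- sample(fit$model$gene_ids, round(0.3 * length(fit$model$gene_ids)))
  sub <- inp$norm[setdiff(rownames(inp$norm), dropped), inp$ctrl]
  res <- project_cross_species(fit, sub)
  expect_setequal(res$unmapped_genes, dropped)
  expect_gte(
    cor(res$scores$raw_score, as.numeric(full), method = "spearman"), 0.8
  )
})
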