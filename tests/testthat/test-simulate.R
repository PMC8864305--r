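test_that("identical config and seed give bitwise-identical datasets", {
  a <- tiny_dataset(seed = 5)
  b <- tiny_dataset(seed = 5)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$cell_meta, b$cell_meta)
  expect_identical(a$gene_meta, b$gene_meta)
  c <- tiny_dataset(seed = 6)
  expect_false(identical(as.matrix(a$counts), as.matrix(c$counts)))
})

test_that("invalid configurations are rejected", {
  expect_error(tiny_config(type_boundaries = c(0.5, 0.25, 0.75)), "increasing")
  expect_error(tiny_config(perturbed_cell_type = "L4"), "AP/BP/N0/N1")
  expect_error(tiny_config(effect_log_fold = NaN), "finite")
  expect_error(tiny_config(library_size_mean = -10), "library_size_mean")
  expect_error(tiny_config(n_genes = 100), "exceed")
})

test_that("BP/AP composition multiplier reproduces the target ratio shift", {
  # control ratio ~1, perturbed ~3.65x control (the progenitor-ratio shift
  # reported for the miR-137 condition: 3.76 / 1.03)
  mult <- 3.76 / 1.03
  cfg <- sim_config(
    n_genes = 400, n_marker_genes_per_type = 15, n_mito_genes = 20,
    cells_per_condition = c(scram = 192L, miR = 222L),
    bp_ap_ratio_multiplier = mult, seed = 11
  )
  ds <- generate_trajectory_dataset(cfg)
  cm <- ds$cell_meta
  r <- function(cond) {
    sum(cm$condition == cond & cm$true_type == "BP") /
      sum(cm$condition == cond & cm$true_type == "AP")
  }
  realized <- r("miR") / r("scram")
  expect_lt(abs(realized - 3.65) / 3.65, 0.15)
})

test_that("with zero effect and zero delay no gene separates the conditions", {
  ds <- tiny_dataset(seed = 21, effect_log_fold = 0, maturation_delay = 0)
  nm <- normalize_rpm_log(ds)
  grp <- ds$cell_meta$condition == "miR"
  diff_obs <- rowMeans(nm[, grp]) - rowMeans(nm[, !grp])
  # permutation oracle for the null spread of per-gene mean differences
  set.seed(99)
  perm_diffs <- replicate(200, {
    g <- sample(grp)
    rowMeans(nm[, g]) - rowMeans(nm[, !g])
  })
  sigma <- apply(perm_diffs, 1, sd)
  frac_within <- mean(abs(diff_obs) <= 4 * sigma)
  expect_gte(frac_within, 0.95)
})

test_that("marker genes are most expressed in their own cell type", {
  ds <- tiny_dataset(seed = 3)
  nm <- normalize_rpm_log(ds)
  gm <- ds$gene_meta
  types <- levels(ds$cell_meta$true_type)
  for (ty in types) {
    mk <- which(!is.na(gm$marker_set) & gm$marker_set == ty)
    own <- mean(nm[mk, ds$cell_meta$true_type == ty])
    for (other in setdiff(types, ty)) {
      expect_gt(own, mean(nm[mk, ds$cell_meta$true_type == other]))
    }
  }
})

test_that("layer mixture generator hits the stated proportions at the edges", {
  cfg <- tiny_config(seed = 2)
  d0 <- generate_layer_dataset(cfg, 0, n_ref = 30, n_query = 50)
  q0 <- d0$cell_meta$true_class[d0$cell_meta$population == "query"]
  expect_true(all(q0 == "L4"))
  d1 <- generate_layer_dataset(cfg, 1, n_ref = 30, n_query = 50)
  q1 <- d1$cell_meta$true_class[d1$cell_meta$population == "query"]
  expect_true(all(q1 == "L2/3"))
  expect_error(generate_layer_dataset(cfg, 1.2), "mixture_proportion")
})

test_that("layer mixture ground-truth count falls in the binomial 99% interval", {
  cfg <- tiny_config(seed = 8)
  ds <- generate_layer_dataset(cfg, 0.7, n_ref = 50, n_query = 400)
  k <- sum(ds$cell_meta$true_class[ds$cell_meta$population == "query"] == "L2/3")
  band <- qbinom(c(0.005, 0.995), 400, 0.7)
  expect_gte(k, band[1])
  expect_lte(k, band[2])
})

test_that("track simulation matches its contract", {
  tr <- generate_tracks(n_cells = 20, seed = 4)
  frames_per_cell <- table(tr$cell_id)
  expect_true(all(frames_per_cell == 73)) # 12 h at 10-min intervals
  # no transitions when transition_prob = 0
  tr0 <- generate_tracks(n_cells = 15, transition_prob = 0, seed = 4)
  expect_false(any(tr0$morphology == "bipolar"))
  # morphology switch is irreversible
  morph_runs <- tapply(tr$morphology, tr$cell_id, function(m) {
    all(diff(m == "bipolar") >= 0)
  })
  expect_true(all(morph_runs))
  expect_error(generate_tracks(transition_prob = 1.5), "transition_prob")
  expect_identical(
    tibble::as_tibble(generate_tracks(n_cells = 5, seed = 9)),
    tibble::as_tibble(generate_tracks(n_cells = 5, seed = 9))
  )
})

test_that("transition fraction follows the geometric survival law", {
  p <- 0.05
  tr <- generate_tracks(n_cells = 200, transition_prob = p, seed = 12)
  per_cell <- tapply(tr$morphology, tr$cell_id, function(m) any(m == "bipolar"))
  expected <- 1 - (1 - p)^72
  band <- qbinom(c(0.005, 0.995), 200, expected) / 200
  expect_gte(mean(per_cell), band[1])
  expect_lte(mean(per_cell), band[2])
})
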