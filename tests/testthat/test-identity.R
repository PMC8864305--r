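layer_fixture <- function(seed = 1L, mixture = 0.7, n_ref = 60, n_query = 100) {
  ds <- generate_layer_dataset(
    tiny_config(seed = seed), mixture,
    n_ref = n_ref, n_query = n_query
  )
  list(
    ds = ds, norm = normalize_rpm_log(ds),
    ref = ds$cell_meta$population == "ref"
  )
}

test_that("identity models separate well-defined reference programs", {
  fx <- layer_fixture(seed = 2)
  cv <- fit_identity_model(
    fx$norm[, fx$ref], fx$ds$cell_meta$true_class[fx$ref],
    k_folds = 10, seed = 1
  )
  expect_gte(cv$auc, 0.95)
})

test_that("permuted reference labels give chance-level AUC", {
  fx <- layer_fixture(seed = 3)
  set.seed(11)
  perm <- sample(fx$ds$cell_meta$true_class[fx$ref])
  cv <- fit_identity_model(fx$norm[, fx$ref], perm, k_folds = 10, seed = 1)
  expect_gte(cv$auc, 0.3)
  expect_lte(cv$auc, 0.7)
})

test_that("query classification recovers reference cells and mixtures", {
  fx <- layer_fixture(seed = 4)
  cv <- fit_identity_model(
    fx$norm[, fx$ref], fx$ds$cell_meta$true_class[fx$ref],
    k_folds = 10, seed = 2
  )
  # querying pure reference-class cells returns proportion 1
  pure <- fx$ds$cell_meta$true_class == "L2/3" & fx$ref
  cls_pure <- classify_query(cv, fx$norm[, pure])
  expect_equal(
    cls_pure$proportions$proportion[cls_pure$proportions$class == "L2/3"], 1
  )
  # mixture recovery
  cls <- classify_query(cv, fx$norm[, !fx$ref])
  p23 <- cls$proportions$proportion[cls$proportions$class == "L2/3"]
  band <- qbinom(c(0.005, 0.995), 100, 0.7) / 100
  expect_gte(p23, band[1])
  expect_lte(p23, band[2])
  # an infinite threshold calls everything negative
  cls_inf <- classify_query(cv, fx$norm[, !fx$ref], threshold = Inf)
  expect_true(all(cls_inf$cells$call == cv$model$negative_class))
})

test_that("chi-square matches the 2x2 closed form exhaustively", {
  closed_form <- function(a, b, c, d) {
    n <- a + b + c + d
    n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  }
  expect_equal(
    proportion_test(matrix(c(20, 5, 5, 20), 2))$statistic[1], 18
  )
  expect_equal(
    proportion_test(matrix(c(10, 10, 10, 10), 2))$statistic[1], 0
  )
  expect_equal(
    proportion_test(matrix(c(10, 10, 10, 10), 2))$p_value[1], 1
  )
  set.seed(12)
  for (i in 1:200) {
    tab <- matrix(sample(1:12, 4, replace = TRUE), 2)
    if (sum(tab) > 50) next
    res <- proportion_test(tab)
    expect_equal(
      res$statistic[res$method == "chi-square"],
      closed_form(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    )
  }
})

test_that("Fisher exact p matches full margin enumeration for n <= 30", {
  set.seed(13)
  checked <- 0
  while (checked < 60) {
    tab <- matrix(sample(0:10, 4, replace = TRUE), 2)
    if (sum(tab) > 30 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    res <- proportion_test(tab)
    expect_equal(
      res$p_value[res$method == "fisher-exact"],
      enum_fisher_p(tab),
      tolerance = 1e-10
    )
    checked <- checked + 1
  }
  expect_equal(
    proportion_test(matrix(c(1, 0, 0, 1), 2))$p_value[2], 1
  )
})

test_that("proportion test input validation", {
  expect_error(proportion_test(matrix(1:3, 1)), "2 x 2")
  expect_error(proportion_test(matrix(c(2.5, 1, 1, 1), 2)), "integers")
  expect_error(proportion_test(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("mixture proportion recovery is unbiased across the range", {
  errs <- vapply(c(0.2, 0.5, 0.8), function(p) {
    fx <- layer_fixture(seed = round(100 * p), mixture = p, n_query = 200)
    cv <- fit_identity_model(
      fx$norm[, fx$ref], fx$ds$cell_meta$true_class[fx$ref],
      k_folds = 5, seed = 3
    )
    cls <- classify_query(cv, fx$norm[, !fx$ref])
    truth <- mean(fx$ds$cell_meta$true_class[!fx$ref] == "L2/3")
    abs(cls$proportions$proportion[cls$proportions$class == "L2/3"] - truth)
  }, numeric(1))
  expect_lte(mean(errs), 0.03)
})

test_that("per-layer age models score queries and skip incomplete layers", {
  cfg <- tiny_config(seed = 6)
  ds <- generate_layer_dataset(cfg, 0.5, n_ref = 50, n_query = 60, labels = c("P3", "P7"))
  nm <- normalize_rpm_log(ds)
  ref <- ds$cell_meta$population == "ref"
  age <- ds$cell_meta$true_class
  layer <- rep(c("L2/3", "L4"), length.out = ncol(nm))
  res <- suppressWarnings(pseudo_maturation_p3p7(
    nm[, ref], age[ref], layer[ref], nm[, !ref],
    query_layer = layer[!ref], k_folds = 5, seed = 2
  ))
  expect_setequal(res$layer, c("L2/3", "L4"))
  expect_true(all(res$auc > 0.9))
  # query = pure P7 cells lands at the P7 pole
  p7 <- ref & age == "P7" & layer == "L2/3"
  res_p7 <- suppressWarnings(pseudo_maturation_p3p7(
    nm[, ref & layer == "L2/3"], age[ref & layer == "L2/3"],
    layer[ref & layer == "L2/3"], nm[, p7],
    k_folds = 5, seed = 2
  ))
  expect_gt(res_p7$query_median, 0)
  # a layer missing one age class is skipped with a warning
  only_p3 <- ref & (age == "P3" | layer == "L2/3")
  expect_warning(
    pseudo_maturation_p3p7(
      nm[, only_p3], age[only_p3], layer[only_p3], nm[, !ref],
      k_folds = 5, seed = 2
    ),
    "skipped"
  )
})
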