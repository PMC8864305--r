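cfg_get <- function(config, key, scenario, default = NULL, required = FALSE) {
  if (!is.null(config[[key]])) {
    return(config[[key]])
  }
  if (required) {
    abort(sprintf("missing config key `%s` for scenario '%s'", key, scenario))
  }
  default
}

sim_config_from <- function(config, seed) {
  args <- config$sim %||% list()
  args$seed <- seed
  do.call(sim_config, args)
}

prep_typed_dataset <- function(config, seed, scenario, log) {
  ds <- generate_trajectory_dataset(sim_config_from(config, seed))
  log("simulated", sprintf("%d genes x %d cells", nrow(ds$counts), ncol(ds$counts)))
  thr <- qc_thresholds(
    min_genes_detected = cfg_get(config, "min_genes", scenario, 500),
    max_mito_fraction = cfg_get(config, "max_mito", scenario, 0.15)
  )
  qc <- qc_filter(ds, thr)
  log("qc_filter", sprintf(
    "%d/%d cells kept", ncol(qc$dataset$counts), ncol(ds$counts)
  ))
  norm <- normalize_rpm_log(qc$dataset)
  typing <- assign_cell_types(norm, default_marker_sets(qc$dataset))
  log("cell_typing", paste(
    sprintf("%s=%d", levels(typing$cell_type), table(typing$cell_type)),
    collapse = ", "
  ))
  list(dataset = qc$dataset, qc_report = qc$report, norm = norm, typing = typing)
}

#' Run an end-to-end analysis scenario
#'
#' Orchestrates the pipeline stages in their analysis order — simulate,
#' QC-filter, normalize, type, model, score — for one of the scenarios
#' `simulate`, `perturbation`, `pseudotime`, `identity` or `migration`, and
#' writes stage outputs plus a machine-readable run manifest to `out_dir`.
#' Outputs are identical for identical config + seed.
#'
#' @param config path to a YAML file, or an equivalent named list. Must name
#'   a `scenario`; a `sim` sub-list overrides [sim_config()] defaults;
#'   scenario-level keys (`min_genes`, `max_mito`, `k_folds`,
#'   `mixture_proportion`, `maturation_delay`, ...) tune the stages.
#' @param seed integer seed governing every random stage.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a list of in-memory results; files and
#'   `manifest.json` are written to `out_dir`.
#' @export
run_pipeline <- function(config, seed = 1L, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a file path or a named list")
  scenario <- cfg_get(config, "scenario", "(none)", required = TRUE)
  known <- c("simulate", "perturbation", "pseudotime", "identity", "migration")
  if (!scenario %in% known) {
    abort(sprintf(
      "unknown scenario '%s' (expected one of %s)",
      scenario, paste(known, collapse = ", ")
    ))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  log <- function(stage, msg) {
    stages[[length(stages) + 1]] <<- list(stage = stage, detail = msg)
    inform(sprintf("[%s] %s", stage, msg))
  }
  outputs <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(df, path, progress = FALSE)
    outputs <<- c(outputs, name)
  }
  results <- list()

  if (scenario == "simulate") {
    ds <- generate_trajectory_dataset(sim_config_from(config, seed))
    log("simulated", sprintf("%d genes x %d cells", nrow(ds$counts), ncol(ds$counts)))
    paths <- write_expression(ds, out_dir, prefix = "sim")
    outputs <- c(outputs, basename(paths))
    results$dataset <- ds
  } else if (scenario == "perturbation") {
    prep <- prep_typed_dataset(config, seed, scenario, log)
    res <- score_cell_types(
      prep$norm, prep$typing$cell_type, prep$dataset$cell_meta$condition,
      k_folds = cfg_get(config, "k_folds", scenario, 20),
      min_cells = cfg_get(config, "min_cells", scenario, 20),
      seed = seed + 100L
    )
    log("perturbation", paste(
      sprintf("AUC(%s)=%.3f", res$cell_type, res$auc),
      collapse = ", "
    ))
    emit(prep$qc_report, "qc_report.tsv")
    emit(dplyr::select(res, -"cv"), "celltype_auc.tsv")
    genes <- purrr::map_dfr(which(!res$skipped), function(i) {
      dplyr::mutate(
        top_regulated_genes(res$cv[[i]]$model),
        cell_type = res$cell_type[i], .before = 1
      )
    })
    emit(genes, "top_regulated_genes.tsv")
    results$scores <- res
    results$prep <- prep
  } else if (scenario == "pseudotime") {
    config$sim <- config$sim %||% list()
    config$sim$maturation_delay <- cfg_get(config, "maturation_delay", scenario,
      config$sim$maturation_delay %||% -0.2
    )
    prep <- prep_typed_dataset(config, seed, scenario, log)
    ctrl_cond <- names(table(prep$dataset$cell_meta$condition))[1]
    is_ctrl <- prep$dataset$cell_meta$condition == ctrl_cond
    fit <- fit_pseudotime(
      prep$norm[, is_ctrl, drop = FALSE],
      prep$typing$cell_type[is_ctrl],
      pool_progenitors = cfg_get(config, "pool_progenitors", scenario, FALSE),
      cv_scheme = cfg_get(config, "cv_scheme", scenario, "loo"),
      seed = seed + 100L
    )
    cmp <- score_and_compare(
      fit, prep$norm[, !is_ctrl, drop = FALSE],
      perturbed_types = prep$typing$cell_type[!is_ctrl]
    )
    log("pseudotime", sprintf("shift=%.4f p=%.3g", cmp$shift, cmp$p_value))
    emit(cmp$scores, "pseudotime_scores.tsv")
    emit(glance(cmp), "pseudotime_comparison.tsv")
    results$fit <- fit
    results$comparison <- cmp
  } else if (scenario == "identity") {
    cfg <- sim_config_from(config, seed)
    mix <- cfg_get(config, "mixture_proportion", scenario, 0.7)
    ds <- generate_layer_dataset(
      cfg, mix,
      n_ref = cfg_get(config, "n_ref", scenario, 200),
      n_query = cfg_get(config, "n_query", scenario, 400)
    )
    log("simulated", sprintf("%d cells (mixture %.2f)", ncol(ds$counts), mix))
    norm <- normalize_rpm_log(ds)
    is_ref <- ds$cell_meta$population == "ref"
    cv <- fit_identity_model(
      norm[, is_ref, drop = FALSE], ds$cell_meta$true_class[is_ref],
      k_folds = cfg_get(config, "k_folds", scenario, 20), seed = seed + 100L
    )
    cls <- classify_query(cv, norm[, !is_ref, drop = FALSE])
    log("identity", sprintf(
      "reference AUC=%.3f; query %s", cv$auc,
      paste(sprintf("%s=%.1f%%", cls$proportions$class,
        100 * cls$proportions$proportion), collapse = ", ")
    ))
    emit(cls$cells, "query_calls.tsv")
    emit(cls$proportions, "query_proportions.tsv")
    results$cv <- cv
    results$classification <- cls
    results$dataset <- ds
  } else if (scenario == "migration") {
    tr <- generate_tracks(
      n_cells = cfg_get(config, "n_cells", scenario, 200),
      transition_prob = cfg_get(config, "transition_prob", scenario, 0.03),
      pause_prob = cfg_get(config, "pause_prob", scenario, 0.2),
      seed = seed
    )
    log("simulated", sprintf("%d tracks", dplyr::n_distinct(tr$cell_id)))
    sub <- subsample_equal_per_slice(tr, seed = seed + 1L)
    met <- track_set_metrics(sub)
    mbt <- mbt_fraction(tr)
    log("migration", sprintf(
      "MBT fraction=%.3f (%d/%d)", mbt$fraction, mbt$n_transitioned,
      mbt$n_eligible
    ))
    emit(met, "track_metrics.tsv")
    emit(
      tibble::tibble(
        fraction = mbt$fraction, n_eligible = mbt$n_eligible,
        n_transitioned = mbt$n_transitioned
      ),
      "mbt_fraction.tsv"
    )
    results$tracks <- tr
    results$metrics <- met
    results$mbt <- mbt
  }

  manifest <- list(
    package = "cortiscore",
    version = as.character(utils::packageVersion("cortiscore")),
    scenario = scenario,
    seed = as.integer(seed),
    config = config,
    stages = stages,
    outputs = outputs
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(results)
}
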