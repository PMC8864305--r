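#' Configuration for the synthetic trajectory generator
#'
#' Defines the study conditions emulated by [generate_trajectory_dataset()]:
#' a latent maturation axis m in \[0, 1\] partitioned into the four cortical
#' states AP < BP < N0 < N1 (apical/basal progenitors, newborn and
#' differentiating neurons), marker-gene programs riding logistic ramps in m,
#' mitochondrial genes with per-cell damage fractions, library-size
#' variation, and a perturbed condition that may carry induced/repressed
#' genes in one cell type, a maturation delay, and a BP/AP composition shift.
#'
#' Default cell numbers mirror post-QC embryonic experiments
#' (192 control, 222 perturbed cells); counts are gamma-Poisson
#' (negative binomial) with dispersion `count_dispersion`.
#'
#' @param n_genes total number of genes (mitochondrial genes included).
#' @param n_marker_genes_per_type markers per cell type, disjoint sets.
#' @param n_mito_genes mitochondrial genes (ids prefixed "mt-").
#' @param cells_per_condition named integer vector, condition -> cell count;
#'   the first name is the control condition.
#' @param perturbed_condition which condition carries the perturbation;
#'   defaults to the second name of `cells_per_condition`.
#' @param maturation_shape1,maturation_shape2 Beta parameters of the latent
#'   maturation distribution.
#' @param type_boundaries three strictly increasing cut points in (0, 1)
#'   partitioning m into AP/BP/N0/N1.
#' @param perturbed_cell_type cell type carrying the transcriptional effect.
#' @param n_induced,n_repressed numbers of affected genes.
#' @param effect_log_fold effect size in log2 units, applied only in
#'   `perturbed_cell_type` x `perturbed_condition`.
#' @param maturation_delay additive shift on m in the perturbed condition
#'   (negative = delayed differentiation), truncated to \[0, 1\].
#' @param bp_ap_ratio_multiplier target multiplier of the BP/AP cell-count
#'   ratio in the perturbed condition relative to control.
#' @param marker_fold peak fold-elevation of a marker gene in its own type.
#' @param library_size_mean,library_size_dispersion mean and log-normal sdlog
#'   of per-cell library sizes (total UMIs).
#' @param count_dispersion negative-binomial overdispersion (0 = Poisson).
#' @param age_label age annotation copied into cell metadata.
#' @param seed integer RNG seed; identical config + seed gives identical data.
#'
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 1200,
                       n_marker_genes_per_type = 25,
                       n_mito_genes = 50,
                       cells_per_condition = c(scram = 192L, miR = 222L),
                       perturbed_condition = NULL,
                       maturation_shape1 = 1.2,
                       maturation_shape2 = 1.2,
                       type_boundaries = c(0.25, 0.5, 0.75),
                       perturbed_cell_type = "BP",
                       n_induced = 50,
                       n_repressed = 50,
                       effect_log_fold = 1,
                       maturation_delay = 0,
                       bp_ap_ratio_multiplier = 1,
                       marker_fold = 8,
                       library_size_mean = 20000,
                       library_size_dispersion = 0.35,
                       count_dispersion = 0.15,
                       age_label = "E15.5",
                       seed = 1L) {
  cfg <- list(
    n_genes = n_genes, n_marker_genes_per_type = n_marker_genes_per_type,
    n_mito_genes = n_mito_genes, cells_per_condition = cells_per_condition,
    perturbed_condition = perturbed_condition,
    maturation_shape1 = maturation_shape1, maturation_shape2 = maturation_shape2,
    type_boundaries = type_boundaries, perturbed_cell_type = perturbed_cell_type,
    n_induced = n_induced, n_repressed = n_repressed,
    effect_log_fold = effect_log_fold, maturation_delay = maturation_delay,
    bp_ap_ratio_multiplier = bp_ap_ratio_multiplier, marker_fold = marker_fold,
    library_size_mean = library_size_mean,
    library_size_dispersion = library_size_dispersion,
    count_dispersion = count_dispersion, age_label = age_label,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

cell_type_levels <- c("AP", "BP", "N0", "N1")

validate_sim_config <- function(cfg) {
  for (nm in c(
    "n_genes", "n_marker_genes_per_type", "n_mito_genes", "n_induced",
    "n_repressed"
  )) {
    stopifnot_scalar_number(cfg[[nm]], nm, lower = 0)
  }
  for (nm in c(
    "maturation_shape1", "maturation_shape2", "bp_ap_ratio_multiplier",
    "marker_fold", "library_size_mean", "library_size_dispersion"
  )) {
    stopifnot_scalar_number(cfg[[nm]], nm, lower = 1e-12)
  }
  stopifnot_scalar_number(cfg$count_dispersion, "count_dispersion", lower = 0)
  stopifnot_scalar_number(cfg$effect_log_fold, "effect_log_fold")
  stopifnot_scalar_number(cfg$maturation_delay, "maturation_delay", -1, 1)
  b <- cfg$type_boundaries
  if (length(b) != 3L || any(!is.finite(b)) || any(diff(b) <= 0) ||
    b[1] <= 0 || b[3] >= 1) {
    abort("`type_boundaries` must be 3 strictly increasing cut points in (0,1)")
  }
  if (!cfg$perturbed_cell_type %in% cell_type_levels) {
    abort(sprintf(
      "`perturbed_cell_type` must be one of %s",
      paste(cell_type_levels, collapse = "/")
    ))
  }
  cc <- cfg$cells_per_condition
  if (is.null(names(cc)) || any(names(cc) == "") || any(cc < 0) ||
    any(!is.finite(cc))) {
    abort("`cells_per_condition` must be a named non-negative vector")
  }
  pc <- cfg$perturbed_condition
  if (!is.null(pc) && !pc %in% names(cc)) {
    abort("`perturbed_condition` must name an entry of `cells_per_condition`")
  }
  n_special <- 4L * cfg$n_marker_genes_per_type + cfg$n_mito_genes +
    cfg$n_induced + cfg$n_repressed
  if (n_special > cfg$n_genes) {
    abort("marker + mito + effect genes exceed `n_genes`")
  }
  invisible(cfg)
}

# smooth occupancy of type interval [lo, hi] along maturation m
logistic_window <- function(m, lo, hi, tau = 0.04) {
  up <- if (is.finite(lo)) stats::plogis((m - lo) / tau) else 1
  down <- if (is.finite(hi)) stats::plogis((hi - m) / tau) else 1
  up * down
}

type_intervals <- function(boundaries) {
  lo <- c(-Inf, boundaries)
  hi <- c(boundaries, Inf)
  stats::setNames(Map(c, lo, hi), cell_type_levels)
}

assign_type_from_m <- function(m, boundaries) {
  idx <- findInterval(m, boundaries) + 1L
  factor(cell_type_levels[idx], levels = cell_type_levels, ordered = TRUE)
}

# gamma-Poisson draw, elementwise mean mu, shared dispersion phi
nb_counts <- function(mu, phi) {
  n <- length(mu)
  lambda <- if (phi > 0) rgamma(n, shape = 1 / phi, scale = mu * phi) else mu
  cnt <- rpois(n, lambda)
  dim(cnt) <- dim(mu)
  cnt
}

mito_fraction_draw <- function(n) {
  damaged <- runif(n) < 0.07
  f <- rbeta(n, 2.5, 47.5)
  f[damaged] <- rbeta(sum(damaged), 8, 24)
  f
}

#' Generate a synthetic four-state differentiation trajectory dataset
#'
#' Draws a ground-truth-annotated gene x cell UMI matrix under the conditions
#' encoded in a [sim_config()]: each cell gets a latent maturation m from the
#' condition's Beta law (shifted by `maturation_delay` in the perturbed
#' condition), a type from `type_boundaries`, and counts from a gamma-Poisson
#' model whose per-gene means combine a log-normal baseline, logistic marker
#' ramps along m, per-cell mitochondrial fractions, and the induced/repressed
#' effects restricted to the perturbed cell type and condition. When
#' `bp_ap_ratio_multiplier` differs from 1, the perturbed condition's BP/AP
#' cell composition is reweighted to that multiple of the realized control
#' ratio (AP+BP total preserved).
#'
#' @param config a [sim_config()].
#' @return An [expr_dataset()] whose `cell_meta` carries `condition`, `age`,
#'   `replicate`, `true_maturation`, `true_type`, `picture_qc`, and whose
#'   `gene_meta` carries `mito`, `marker_set`, `true_effect`, `base_mean`.
#' @export
generate_trajectory_dataset <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    n_mk <- config$n_marker_genes_per_type
    n_mito <- config$n_mito_genes
    n_nonmito <- config$n_genes - n_mito
    gene_id <- c(
      sprintf("g%04d", seq_len(n_nonmito)),
      if (n_mito > 0) sprintf("mt-g%03d", seq_len(n_mito))
    )
    mito <- c(rep(FALSE, n_nonmito), rep(TRUE, n_mito))

    alpha <- stats::rlnorm(config$n_genes, meanlog = 0, sdlog = 1.2)

    marker_set <- rep(NA_character_, config$n_genes)
    pool <- seq_len(n_nonmito)
    if (n_mk > 0) {
      mk_idx <- sample(pool, 4L * n_mk)
      marker_set[mk_idx] <- rep(cell_type_levels, each = n_mk)
      pool <- setdiff(pool, mk_idx)
    }
    true_effect <- integer(config$n_genes)
    n_eff <- config$n_induced + config$n_repressed
    if (n_eff > 0) {
      # effects live on reasonably expressed genes: a 2-fold change on a
      # near-zero-count gene carries no signal at these library sizes
      expressed <- pool[alpha[pool] >= stats::median(alpha[pool])]
      eff_idx <- sample(expressed, n_eff)
      true_effect[eff_idx] <- rep(
        c(1L, -1L),
        c(config$n_induced, config$n_repressed)
      )
    }

    conditions <- names(config$cells_per_condition)
    perturbed <- config$perturbed_condition %||%
      (if (length(conditions) >= 2) conditions[2] else NA_character_)
    control <- conditions[1]

    cell_rows <- purrr::map(conditions, function(cond) {
      n <- config$cells_per_condition[[cond]]
      m <- rbeta(n, config$maturation_shape1, config$maturation_shape2)
      if (identical(cond, perturbed) && config$maturation_delay != 0) {
        m <- pmin(pmax(m + config$maturation_delay, 0), 1)
      }
      tibble::tibble(condition = cond, true_maturation = m)
    })
    cell_meta <- dplyr::bind_rows(cell_rows)
    cell_meta$true_type <- assign_type_from_m(
      cell_meta$true_maturation, config$type_boundaries
    )

    # composition shift: move cells between AP and BP in the perturbed
    # condition until BP/AP there is ~multiplier x the realized control ratio
    if (!is.na(perturbed) && config$bp_ap_ratio_multiplier != 1) {
      b <- config$type_boundaries
      ctrl <- cell_meta$condition == control
      pert <- cell_meta$condition == perturbed
      r_ctrl <- sum(ctrl & cell_meta$true_type == "BP") /
        max(1L, sum(ctrl & cell_meta$true_type == "AP"))
      s <- sum(pert & cell_meta$true_type %in% c("AP", "BP"))
      r_target <- config$bp_ap_ratio_multiplier * r_ctrl
      n_bp_target <- round(s * r_target / (1 + r_target))
      n_bp_now <- sum(pert & cell_meta$true_type == "BP")
      shift_n <- n_bp_target - n_bp_now
      if (shift_n > 0) {
        from <- which(pert & cell_meta$true_type == "AP")
        take <- sample(from, min(shift_n, length(from)))
        cell_meta$true_maturation[take] <- runif(length(take), b[1], b[2])
      } else if (shift_n < 0) {
        from <- which(pert & cell_meta$true_type == "BP")
        take <- sample(from, min(-shift_n, length(from)))
        cell_meta$true_maturation[take] <- runif(length(take), 0, b[1])
      }
      cell_meta$true_type <- assign_type_from_m(
        cell_meta$true_maturation, config$type_boundaries
      )
    }

    n_cells <- nrow(cell_meta)
    cell_meta <- dplyr::mutate(
      cell_meta,
      cell_id = sprintf("c%04d", dplyr::row_number()),
      age = config$age_label,
      replicate = rep_len(1:3, n_cells),
      picture_qc = TRUE,
      .before = 1
    )

    intervals <- type_intervals(config$type_boundaries)
    m <- cell_meta$true_maturation

    # per-cell relative expression: baseline x marker ramps x effects
    rel <- matrix(alpha, nrow = config$n_genes, ncol = n_cells)
    for (ty in cell_type_levels) {
      g <- which(!is.na(marker_set) & marker_set == ty)
      if (!length(g)) next
      ramp <- logistic_window(m, intervals[[ty]][1], intervals[[ty]][2])
      rel[g, ] <- rel[g, , drop = FALSE] *
        rep(1 + (config$marker_fold - 1) * ramp, each = length(g))
    }
    hit_cells <- which(
      cell_meta$condition == perturbed &
        cell_meta$true_type == config$perturbed_cell_type
    )
    if (length(hit_cells) && config$effect_log_fold != 0) {
      up <- which(true_effect == 1L)
      dn <- which(true_effect == -1L)
      rel[up, hit_cells] <- rel[up, hit_cells, drop = FALSE] *
        2^config$effect_log_fold
      rel[dn, hit_cells] <- rel[dn, hit_cells, drop = FALSE] *
        2^(-config$effect_log_fold)
    }

    mito_frac <- mito_fraction_draw(n_cells)
    nm_idx <- which(!mito)
    mt_idx <- which(mito)
    col_nm <- colSums(rel[nm_idx, , drop = FALSE])
    rel[nm_idx, ] <- sweep(
      rel[nm_idx, , drop = FALSE], 2, (1 - mito_frac) / col_nm, "*"
    )
    if (length(mt_idx)) {
      col_mt <- colSums(rel[mt_idx, , drop = FALSE])
      rel[mt_idx, ] <- sweep(
        rel[mt_idx, , drop = FALSE], 2, mito_frac / col_mt, "*"
      )
    }

    lib <- stats::rlnorm(
      n_cells,
      meanlog = log(config$library_size_mean) - config$library_size_dispersion^2 / 2,
      sdlog = config$library_size_dispersion
    )
    mu <- sweep(rel, 2, lib, "*")
    counts <- nb_counts(mu, config$count_dispersion)
    dimnames(counts) <- list(gene_id, cell_meta$cell_id)

    gene_meta <- tibble::tibble(
      gene_id = gene_id, mito = mito, marker_set = marker_set,
      true_effect = true_effect, base_mean = alpha
    )
    expr_dataset(counts, cell_meta, gene_meta)
  })
}

#' Generate synthetic layer-identity reference and query populations
#'
#' Emulates two transcriptionally distinct neuronal reference populations
#' (default labels "L4" and "L2/3", each carrying a disjoint marker program)
#' plus a query population mixing the two programs in a stated proportion —
#' the setting of binary layer-identity prediction with projection of
#' perturbed cells.
#'
#' @param config a [sim_config()]; gene-level and count-model settings are
#'   reused, trajectory-specific fields are ignored.
#' @param mixture_proportion probability that a query cell carries the
#'   second (`labels[2]`) program.
#' @param n_ref reference cells per class.
#' @param n_query query cells.
#' @param labels length-2 class labels, e.g. `c("L4", "L2/3")` or
#'   `c("P3", "P7")`.
#' @return An [expr_dataset()]; `cell_meta$population` distinguishes
#'   `ref` / `query`, `cell_meta$true_class` holds the generating program.
#' @export
generate_layer_dataset <- function(config, mixture_proportion,
                                   n_ref = 200L, n_query = 400L,
                                   labels = c("L4", "L2/3")) {
  validate_sim_config(config)
  stopifnot_scalar_number(mixture_proportion, "mixture_proportion", 0, 1)
  if (length(labels) != 2L) abort("`labels` must have length 2")
  with_seed(config$seed, {
    n_mk <- max(1L, config$n_marker_genes_per_type)
    n_mito <- config$n_mito_genes
    n_nonmito <- config$n_genes - n_mito
    gene_id <- c(
      sprintf("g%04d", seq_len(n_nonmito)),
      if (n_mito > 0) sprintf("mt-g%03d", seq_len(n_mito))
    )
    mito <- c(rep(FALSE, n_nonmito), rep(TRUE, n_mito))
    alpha <- stats::rlnorm(config$n_genes, meanlog = 0, sdlog = 1.2)
    mk_idx <- sample(seq_len(n_nonmito), 2L * n_mk)
    marker_set <- rep(NA_character_, config$n_genes)
    marker_set[mk_idx] <- rep(labels, each = n_mk)

    true_class <- c(
      rep(labels, each = n_ref),
      labels[1 + (runif(n_query) < mixture_proportion)]
    )
    population <- c(rep("ref", 2L * n_ref), rep("query", n_query))
    n_cells <- length(true_class)

    rel <- matrix(alpha, nrow = config$n_genes, ncol = n_cells)
    for (k in 1:2) {
      g <- which(!is.na(marker_set) & marker_set == labels[k])
      on <- true_class == labels[k]
      rel[g, on] <- rel[g, on, drop = FALSE] * config$marker_fold
    }
    mito_frac <- mito_fraction_draw(n_cells)
    nm_idx <- which(!mito)
    rel[nm_idx, ] <- sweep(
      rel[nm_idx, , drop = FALSE], 2,
      (1 - mito_frac) / colSums(rel[nm_idx, , drop = FALSE]), "*"
    )
    mt_idx <- which(mito)
    if (length(mt_idx)) {
      rel[mt_idx, ] <- sweep(
        rel[mt_idx, , drop = FALSE], 2,
        mito_frac / colSums(rel[mt_idx, , drop = FALSE]), "*"
      )
    }
    lib <- stats::rlnorm(
      n_cells,
      meanlog = log(config$library_size_mean) - config$library_size_dispersion^2 / 2,
      sdlog = config$library_size_dispersion
    )
    counts <- nb_counts(sweep(rel, 2, lib, "*"), config$count_dispersion)
    cell_meta <- tibble::tibble(
      cell_id = sprintf("c%04d", seq_len(n_cells)),
      population = population,
      true_class = true_class,
      condition = ifelse(population == "ref", paste0("ref_", true_class), "query"),
      picture_qc = TRUE
    )
    dimnames(counts) <- list(gene_id, cell_meta$cell_id)
    gene_meta <- tibble::tibble(
      gene_id = gene_id, mito = mito, marker_set = marker_set,
      true_effect = 0L, base_mean = alpha
    )
    expr_dataset(counts, cell_meta, gene_meta)
  })
}
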