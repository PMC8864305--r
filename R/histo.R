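sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) {
    return(NA_real_)
  }
  sd(x) / sqrt(length(x))
}

#' Laminar position frequency distribution in 10 bins
#'
#' Positions are normalized cortical depths in percent of distance from the
#' white matter (0 = WM, 100 = pial surface). The cortex is divided into
#' `n_bins` half-open bins `[0,10), [10,20), ...`, the last bin closed at
#' 100; frequencies are computed per brain (summing to 1) and averaged
#' across brains with SEM.
#'
#' @param positions tibble/data.frame with columns `brain_id` and
#'   `y_percent` (values in \[0, 100\]).
#' @param n_bins number of bins.
#' @return List with `per_brain` (brain_id, bin, lower, upper, frequency)
#'   and `summary` (bin, mean_frequency, sem).
#' @export
bin_positions <- function(positions, n_bins = 10) {
  positions <- tibble::as_tibble(positions)
  if (!all(c("brain_id", "y_percent") %in% names(positions))) {
    abort("`positions` needs `brain_id` and `y_percent` columns")
  }
  y <- positions$y_percent
  if (any(!is.finite(y)) || any(y < 0 | y > 100)) {
    abort("`y_percent` values must lie in [0, 100]")
  }
  width <- 100 / n_bins
  bin <- pmin(floor(y / width) + 1L, n_bins) # closes the last bin at 100
  per_brain <- tibble::tibble(brain_id = positions$brain_id, bin = bin) |>
    dplyr::count(.data$brain_id, .data$bin) |>
    dplyr::group_by(.data$brain_id) |>
    dplyr::mutate(frequency = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    tidyr::complete(
      .data$brain_id,
      bin = seq_len(n_bins), fill = list(n = 0L, frequency = 0)
    ) |>
    dplyr::mutate(
      lower = (.data$bin - 1) * width, upper = .data$bin * width
    ) |>
    dplyr::select("brain_id", "bin", "lower", "upper", "frequency")
  summary <- per_brain |>
    dplyr::group_by(.data$bin, .data$lower, .data$upper) |>
    dplyr::summarise(
      mean_frequency = mean(.data$frequency),
      sem = sem(.data$frequency),
      .groups = "drop"
    )
  list(per_brain = per_brain, summary = summary)
}

#' Marker-positive percentages or ratios with per-section aggregation
#'
#' Computes for every section either the percentage
#' `100 * pos / (pos + neg)` (e.g. KI67+ among electroporated cells) or the
#' ratio `pos / neg` (e.g. PAX6+ / EOMES+), then aggregates sections to a
#' per-brain mean with SEM and brains to an overall mean with SEM.
#'
#' @param counts tibble with columns `brain_id`, `section_id`, `pos`, `neg`.
#' @param mode `"percentage"` or `"ratio"`.
#' @return List with `per_section`, `per_brain` (mean, sem over sections)
#'   and `overall` (mean, sem over brains).
#' @export
marker_ratio <- function(counts, mode = c("percentage", "ratio")) {
  mode <- match.arg(mode)
  counts <- tibble::as_tibble(counts)
  need <- c("brain_id", "section_id", "pos", "neg")
  if (!all(need %in% names(counts))) {
    abort(sprintf("`counts` needs columns: %s", paste(need, collapse = ", ")))
  }
  if (any(counts$pos < 0 | counts$neg < 0)) abort("counts must be non-negative")
  value <- if (mode == "percentage") {
    denom <- counts$pos + counts$neg
    if (any(denom == 0)) abort("section with zero pos + neg cells")
    100 * counts$pos / denom
  } else {
    if (any(counts$neg == 0)) abort("zero denominator count in a section")
    counts$pos / counts$neg
  }
  per_section <- dplyr::mutate(counts, value = value)
  per_brain <- per_section |>
    dplyr::group_by(.data$brain_id) |>
    dplyr::summarise(
      mean = mean(.data$value), sem = sem(.data$value),
      n_sections = dplyr::n(), .groups = "drop"
    )
  overall <- tibble::tibble(
    mean = mean(per_brain$mean),
    sem = sem(per_brain$mean),
    n_brains = nrow(per_brain)
  )
  list(per_section = per_section, per_brain = per_brain, overall = overall)
}
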