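step_lengths <- function(x, y) sqrt(diff(x)^2 + diff(y)^2)

#' Detect pausing steps of a migration track
#'
#' A step counts as a pause when the Euclidean displacement over one frame
#' interval is strictly under `pause_threshold` (the "under 12 um per
#' 10 min" rule — a displacement of exactly 12 um is movement).
#'
#' @param x_um,y_um track coordinates at uniform frame intervals.
#' @param pause_threshold um per frame step.
#' @return Logical vector, one entry per step (length = frames - 1).
#' @export
detect_pauses <- function(x_um, y_um, pause_threshold = 12) {
  if (length(x_um) < 2L) abort("a track needs at least 2 frames")
  step_lengths(x_um, y_um) < pause_threshold
}

#' Speed and directionality metrics of one track
#'
#' `average_speed` is the total path length divided by the elapsed time;
#' `movement_speed` excludes pausing steps (path over non-pause steps
#' divided by their time; 0 with a flag when every step pauses);
#' `directionality` is the straight-line start-to-end distance divided by
#' the path length, in \[0, 1\]. Speeds are in um/min.
#'
#' @inheritParams detect_pauses
#' @param frame_interval minutes per step.
#' @return One-row tibble: `average_speed`, `movement_speed`,
#'   `directionality`, `path_length`, `n_steps`, `n_pauses`, `all_paused`.
#' @export
track_metrics <- function(x_um, y_um, frame_interval = 10,
                          pause_threshold = 12) {
  if (length(x_um) < 2L) abort("a track needs at least 2 frames")
  if (any(!is.finite(c(x_um, y_um)))) abort("non-finite coordinates")
  steps <- step_lengths(x_um, y_um)
  pauses <- steps < pause_threshold
  path <- sum(steps)
  elapsed <- length(steps) * frame_interval
  net <- sqrt((x_um[length(x_um)] - x_um[1])^2 + (y_um[length(y_um)] - y_um[1])^2)
  moving <- !pauses
  all_paused <- !any(moving)
  tibble::tibble(
    average_speed = path / elapsed,
    movement_speed = if (all_paused) 0 else sum(steps[moving]) / (sum(moving) * frame_interval),
    directionality = if (path > 0) net / path else 0,
    path_length = path,
    n_steps = length(steps),
    n_pauses = sum(pauses),
    all_paused = all_paused
  )
}

#' Per-cell migration metrics of a track set
#'
#' @param tracks a `track_set` (see [generate_tracks()], [read_tracks()]).
#' @param pause_threshold um per frame step counting as a pause.
#' @return Tibble with one row per cell: ids plus [track_metrics()] columns.
#' @export
track_set_metrics <- function(tracks, pause_threshold = 12) {
  fi <- attr(tracks, "frame_interval") %||% 10
  tibble::as_tibble(tracks) |>
    dplyr::arrange(.data$cell_id, .data$frame) |>
    dplyr::group_by(.data$cell_id, .data$slice_id) |>
    dplyr::group_modify(function(d, g) {
      track_metrics(d$x_um, d$y_um,
        frame_interval = fi, pause_threshold = pause_threshold
      )
    }) |>
    dplyr::ungroup()
}

#' Multipolar-to-bipolar transition fraction within an ROI
#'
#' Denominator: tracks that are multipolar at t = 0 and start inside the
#' ROI box. Numerator: those whose morphology becomes bipolar within
#' `duration` hours.
#'
#' @param tracks a `track_set` with per-frame `morphology`.
#' @param roi an [roi_box()]; defaults to the one attached to `tracks`.
#' @param duration observation window in hours.
#' @return List with `fraction`, `n_eligible`, `n_transitioned`, and
#'   `transitions`, a per-eligible-track tibble of transition times (min,
#'   NA when never bipolar).
#' @export
mbt_fraction <- function(tracks, roi = NULL, duration = 12) {
  roi <- roi %||% attr(tracks, "roi")
  if (is.null(roi)) abort("no ROI given and none attached to the tracks")
  df <- tibble::as_tibble(tracks)
  if (!"morphology" %in% names(df) || all(df$morphology == "unknown")) {
    abort("tracks carry no morphology labels")
  }
  per <- df |>
    dplyr::arrange(.data$cell_id, .data$frame) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      start_multipolar = .data$morphology[1] == "multipolar",
      start_in_roi = in_roi(.data$x_um[1], .data$y_um[1], roi),
      t_bipolar = if (any(.data$morphology == "bipolar")) {
        min(.data$t_min[.data$morphology == "bipolar"])
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  eligible <- dplyr::filter(per, .data$start_multipolar, .data$start_in_roi)
  if (!nrow(eligible)) abort("no eligible multipolar track starts inside the ROI")
  transitioned <- !is.na(eligible$t_bipolar) & eligible$t_bipolar <= duration * 60
  list(
    fraction = mean(transitioned),
    n_eligible = nrow(eligible),
    n_transitioned = sum(transitioned),
    transitions = dplyr::select(eligible, "cell_id", "t_bipolar")
  )
}

#' Subsample an equal number of tracks per slice
#'
#' Draws `min(count per slice)` tracks uniformly without replacement from
#' every slice, removing the over-representation of densely tracked slices.
#'
#' @param tracks a `track_set`.
#' @param seed RNG seed; identical seed gives an identical selection.
#' @return A `track_set` containing the selected tracks.
#' @export
subsample_equal_per_slice <- function(tracks, seed = 1L) {
  df <- tibble::as_tibble(tracks)
  per_slice <- df |>
    dplyr::distinct(.data$cell_id, .data$slice_id) |>
    dplyr::count(.data$slice_id)
  n_keep <- min(per_slice$n)
  keep <- with_seed(seed, {
    df |>
      dplyr::distinct(.data$cell_id, .data$slice_id) |>
      dplyr::group_by(.data$slice_id) |>
      dplyr::group_map(function(d, g) sample(d$cell_id, n_keep)) |>
      unlist()
  })
  new_track_set(
    dplyr::filter(df, .data$cell_id %in% keep),
    roi = attr(tracks, "roi"),
    frame_interval = attr(tracks, "frame_interval") %||% 10
  )
}

#' Compare a migration metric across groups (Kruskal-Wallis)
#'
#' @param metrics per-cell metrics tibble with a grouping column.
#' @param metric column name to compare.
#' @param group grouping column name.
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @export
compare_migration_groups <- function(metrics, metric, group = "condition") {
  kw <- kruskal.test(metrics[[metric]], factor(metrics[[group]]))
  tibble::tibble(
    statistic = unname(kw$statistic),
    df = unname(kw$parameter),
    p_value = kw$p.value
  )
}
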