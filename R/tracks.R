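#' Rectangular region of interest for migration analysis
#'
#' By convention the pial surface lies toward +y and the upper border of the
#' box (`ymax`) sits on the boundary between the intermediate zone and the
#' deep layers, matching live-imaging practice of drawing a 300 x 150 um box
#' at the transition zone.
#'
#' @param width,height box dimensions in um.
#' @param xmin left edge; `ymax` upper edge (um).
#' @return An `roi_box` with `xmin`, `xmax`, `ymin`, `ymax`.
#' @export
roi_box <- function(width = 300, height = 150, xmin = 0, ymax = 0) {
  stopifnot_scalar_number(width, "width", lower = 1e-9)
  stopifnot_scalar_number(height, "height", lower = 1e-9)
  structure(
    list(xmin = xmin, xmax = xmin + width, ymin = ymax - height, ymax = ymax),
    class = "roi_box"
  )
}

in_roi <- function(x, y, roi) {
  x >= roi$xmin & x <= roi$xmax & y >= roi$ymin & y <= roi$ymax
}

new_track_set <- function(df, roi = NULL, frame_interval = 10) {
  out <- tibble::new_tibble(df, class = "track_set")
  attr(out, "roi") <- roi
  attr(out, "frame_interval") <- frame_interval
  out
}

#' Simulate migrating-neuron tracks with a multipolar-to-bipolar switch
#'
#' Cells start in a multipolar phase (isotropic, low-displacement steps) at
#' positions uniform in the ROI, switch irreversibly to a bipolar phase
#' (directed steps toward the pial side, +y) with probability
#' `transition_prob` per frame, and in the bipolar phase pause (near-zero
#' step) with probability `pause_prob` per frame. Positions are sampled at
#' fixed `frame_interval` over `duration`, giving
#' `floor(duration * 60 / frame_interval) + 1` frames per track (73 at the
#' default 10-min interval over 12 h).
#'
#' @param n_cells number of tracks.
#' @param frame_interval minutes between frames.
#' @param duration imaging duration in hours.
#' @param multipolar_speed,bipolar_speed mean step length, um per frame.
#' @param transition_prob per-frame multipolar-to-bipolar probability.
#' @param pause_prob per-frame pause probability while bipolar.
#' @param roi an [roi_box()]; starting positions are uniform inside it.
#' @param n_slices tracks are attributed round-robin to this many slices.
#' @param seed RNG seed.
#' @return A `track_set` tibble with columns `cell_id`, `slice_id`, `frame`,
#'   `t_min`, `x_um`, `y_um`, `morphology`, carrying the ROI and frame
#'   interval as attributes.
#' @export
generate_tracks <- function(n_cells = 200, frame_interval = 10, duration = 12,
                            multipolar_speed = 5, bipolar_speed = 18,
                            transition_prob = 0.03, pause_prob = 0.2,
                            roi = roi_box(), n_slices = 4, seed = 1L) {
  stopifnot_scalar_number(frame_interval, "frame_interval", lower = 1e-9)
  stopifnot_scalar_number(duration, "duration", lower = 1e-9)
  stopifnot_scalar_number(transition_prob, "transition_prob", 0, 1)
  stopifnot_scalar_number(pause_prob, "pause_prob", 0, 1)
  n_steps <- floor(duration * 60 / frame_interval)
  with_seed(seed, {
    tracks <- purrr::map(seq_len(n_cells), function(i) {
      x <- numeric(n_steps + 1)
      y <- numeric(n_steps + 1)
      morph <- character(n_steps + 1)
      x[1] <- runif(1, roi$xmin, roi$xmax)
      y[1] <- runif(1, roi$ymin, roi$ymax)
      bipolar <- FALSE
      morph[1] <- "multipolar"
      for (s in seq_len(n_steps)) {
        if (!bipolar && runif(1) < transition_prob) bipolar <- TRUE
        if (!bipolar) {
          ang <- runif(1, 0, 2 * pi)
          len <- abs(rnorm(1, multipolar_speed, multipolar_speed / 3))
          dx <- len * cos(ang)
          dy <- len * sin(ang)
        } else if (runif(1) < pause_prob) {
          dx <- rnorm(1, 0, 0.5)
          dy <- rnorm(1, 0, 0.5)
        } else {
          dx <- rnorm(1, 0, 2)
          dy <- rnorm(1, bipolar_speed, 2)
        }
        x[s + 1] <- x[s] + dx
        y[s + 1] <- y[s] + dy
        morph[s + 1] <- if (bipolar) "bipolar" else "multipolar"
      }
      tibble::tibble(
        cell_id = sprintf("t%04d", i),
        slice_id = sprintf("s%02d", 1 + (i - 1) %% n_slices),
        frame = 0:n_steps,
        t_min = (0:n_steps) * frame_interval,
        x_um = x, y_um = y,
        morphology = morph
      )
    })
    new_track_set(dplyr::bind_rows(tracks), roi = roi, frame_interval = frame_interval)
  })
}

#' Read / write migration tracks as CSV
#'
#' CSV columns: `cell_id`, `slice_id`, `frame`, `t_min`, `x_um`, `y_um`,
#' `morphology`.
#'
#' @param path CSV file.
#' @param frame_interval minutes between frames; inferred from `t_min` when
#'   possible.
#' @return [read_tracks()] a `track_set`; [write_tracks()] the path,
#'   invisibly.
#' @export
read_tracks <- function(path, frame_interval = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("cell_id", "frame", "t_min", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(sprintf("track CSV lacks columns: %s", paste(miss, collapse = ", ")))
  }
  if (!"slice_id" %in% names(df)) df$slice_id <- "s01"
  if (!"morphology" %in% names(df)) df$morphology <- "unknown"
  if (is.null(frame_interval)) {
    dt <- unique(diff(sort(unique(df$t_min))))
    frame_interval <- if (length(dt)) min(dt) else 10
  }
  new_track_set(df, roi = NULL, frame_interval = frame_interval)
}

#' @rdname read_tracks
#' @param tracks a `track_set`.
#' @export
write_tracks <- function(tracks, path) {
  readr::write_csv(tibble::as_tibble(tracks), path, progress = FALSE)
  invisible(path)
}
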