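worked_track <- list(x = c(0, 5, 5, 5, 20), y = c(0, 0, 8, 8, 8))

test_that("pause detection applies the strict under-12-um rule", {
  expect_identical(
    detect_pauses(worked_track$x, worked_track$y),
    c(TRUE, TRUE, TRUE, FALSE)
  )
  expect_false(detect_pauses(c(0, 12), c(0, 0))) # exactly 12 um moves
  expect_true(detect_pauses(c(0, 11.9), c(0, 0)))
  expect_true(all(detect_pauses(rep(3, 10), rep(4, 10))))
  expect_error(detect_pauses(0, 0), "2 frames")
})

test_that("the worked 5-frame track yields the hand-computed metrics", {
  m <- track_metrics(worked_track$x, worked_track$y)
  expect_equal(m$average_speed, 0.7)
  expect_equal(m$movement_speed, 1.5)
  expect_equal(m$directionality, sqrt(464) / 28)
  expect_equal(m$n_pauses, 3L)
})

test_that("straight, stationary and closed-loop tracks hit the boundaries", {
  straight <- track_metrics(seq(0, 120, by = 20), rep(0, 7))
  expect_equal(straight$average_speed, 2)
  expect_equal(straight$directionality, 1)
  still <- track_metrics(rep(1, 5), rep(2, 5))
  expect_true(still$all_paused)
  expect_equal(still$movement_speed, 0)
  loop <- track_metrics(c(0, 20, 20, 0, 0), c(0, 0, 20, 20, 0))
  expect_equal(loop$directionality, 0)
})

test_that("movement speed is at least average speed when pauses exist", {
  set.seed(51)
  for (i in 1:20) {
    x <- cumsum(rnorm(15, 0, 8))
    y <- cumsum(rnorm(15, 0, 8))
    m <- track_metrics(x, y)
    if (m$n_pauses > 0 && !m$all_paused) {
      expect_gte(m$movement_speed, m$average_speed)
    }
    expect_gte(m$directionality, 0)
    expect_lte(m$directionality, 1)
  }
})

test_that("metrics are invariant to rigid motions of the coordinates", {
  set.seed(52)
  x <- cumsum(rnorm(20, 3, 6))
  y <- cumsum(rnorm(20, 3, 6))
  base <- track_metrics(x, y)
  th <- 0.83
  xr <- cos(th) * x - sin(th) * y + 40
  yr <- sin(th) * x + cos(th) * y - 17
  rot <- track_metrics(xr, yr)
  expect_equal(base, rot)
})

test_that("MBT denominator requires a multipolar start inside the ROI", {
  roi <- roi_box()
  mk_track <- function(id, x0, y0, morphs) {
    tibble::tibble(
      cell_id = id, slice_id = "s01", frame = seq_along(morphs) - 1,
      t_min = (seq_along(morphs) - 1) * 10,
      x_um = x0, y_um = y0, morphology = morphs
    )
  }
  df <- dplyr::bind_rows(
    mk_track("in_transits", 100, -50, c("multipolar", "multipolar", "bipolar")),
    mk_track("in_stays", 100, -50, rep("multipolar", 3)),
    mk_track("outside", 900, -50, c("multipolar", "bipolar", "bipolar")),
    mk_track("starts_bipolar", 100, -50, rep("bipolar", 3))
  )
  tr <- cortiscore:::new_track_set(df, roi = roi)
  res <- mbt_fraction(tr, roi)
  expect_identical(res$n_eligible, 2L)
  expect_identical(res$n_transitioned, 1L)
  expect_equal(res$fraction, 0.5)
})

test_that("simulated MBT fraction falls inside the closed-form binomial band", {
  p <- 0.04
  tr <- generate_tracks(n_cells = 250, transition_prob = p, seed = 17)
  res <- mbt_fraction(tr)
  expected <- 1 - (1 - p)^72
  band <- qbinom(c(0.005, 0.995), res$n_eligible, expected) / res$n_eligible
  expect_gte(res$fraction, band[1])
  expect_lte(res$fraction, band[2])
})

test_that("per-slice subsampling applies the minimum rule deterministically", {
  tr <- generate_tracks(n_cells = 21, n_slices = 3, seed = 3)
  df <- tibble::as_tibble(tr)
  # unbalance the slices: 10, 4, 7 tracks
  keep <- c(sprintf("t%04d", 1:10))
  ids_by_slice <- split(unique(df$cell_id), rep(c("s01", "s02", "s03"), c(10, 4, 7)))
  df$slice_id <- rep(NA_character_, nrow(df))
  for (s in names(ids_by_slice)) {
    df$slice_id[df$cell_id %in% ids_by_slice[[s]]] <- s
  }
  tr2 <- cortiscore:::new_track_set(df, roi = attr(tr, "roi"))
  sub <- subsample_equal_per_slice(tr2, seed = 8)
  counts <- dplyr::count(dplyr::distinct(tibble::as_tibble(sub), cell_id, slice_id), slice_id)
  expect_true(all(counts$n == 4))
  sub2 <- subsample_equal_per_slice(tr2, seed = 8)
  expect_identical(tibble::as_tibble(sub), tibble::as_tibble(sub2))
  # a single slice passes through unchanged
  one <- cortiscore:::new_track_set(
    dplyr::mutate(df, slice_id = "s01"),
    roi = attr(tr, "roi")
  )
  expect_identical(
    sort(unique(subsample_equal_per_slice(one, 1)$cell_id)),
    sort(unique(df$cell_id))
  )
})

test_that("track CSV IO round-trips and metrics summarise per cell", {
  tr <- generate_tracks(n_cells = 6, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks(tr, path)
  back <- read_tracks(path)
  expect_equal(
    as.data.frame(tibble::as_tibble(back)),
    as.data.frame(tibble::as_tibble(tr)),
    ignore_attr = TRUE
  )
  expect_equal(attr(back, "frame_interval"), 10)
  met <- track_set_metrics(back)
  expect_identical(nrow(met), 6L)
  kw <- compare_migration_groups(
    dplyr::mutate(met, condition = rep(c("scram", "miR"), 3)),
    "average_speed"
  )
  expect_true(kw$p_value >= 0 && kw$p_value <= 1)
})
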