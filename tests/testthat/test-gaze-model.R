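test_that("parse_gaze reads delimited rows per the column spec", {
  lines <- c("t,x,y", "0,10,20", "0.02,12,22")
  traj <- parse_gaze(lines, column_spec(header_lines = 1), 50, "s1")
  expect_equal(nrow(traj$samples), 2)
  expect_equal(traj$samples$t[1], 0)
  expect_equal(traj$samples$x[1], 10)
  expect_equal(traj$samples$y[1], 20)

  # header-only file yields an empty trajectory
  empty <- parse_gaze("t,x,y", column_spec(header_lines = 1), 50, "s1")
  expect_equal(nrow(empty$samples), 0)
})

test_that("parse_gaze handles alternative layouts and time units", {
  # tab-separated, reordered columns, pupil + label, millisecond timestamps
  lines <- c("junk header", "junk2",
             paste(c(100, "3.1", 5, 7, "fixation"), collapse = "\t"),
             paste(c(104, "3.2", 6, 8, "saccade"), collapse = "\t"))
  spec <- column_spec(header_lines = 2, delimiter = "\t", t_col = 0,
                      x_col = 2, y_col = 3, pupil_col = 1, label_col = 4,
                      time_unit = "milliseconds")
  traj <- parse_gaze(lines, spec, 250, "s2")
  expect_equal(traj$samples$t, c(0.1, 0.104))
  expect_equal(traj$samples$pupil, c(3.1, 3.2))
  expect_equal(traj$samples$label, c("fixation", "saccade"))

  # sample_index unit divides by the sampling rate
  idx <- parse_gaze(c("i,x,y", "0,1,1", "1,2,2", "2,3,3"),
                    column_spec(header_lines = 1, time_unit = "sample_index"),
                    sampling_rate = 500, "s3")
  expect_equal(idx$samples$t, c(0, 1, 2) / 500)
})

test_that("millisecond fixture matches an independent line-by-line re-parse", {
  path <- withr::local_tempfile(fileext = ".csv")
  truth <- make_gaze_csv(path, n = 1000, unit = "milliseconds")
  spec <- column_spec(header_lines = 1, t_col = 0, x_col = 1, y_col = 2,
                      time_unit = "milliseconds")
  traj <- parse_gaze(path, spec, 250)
  ref <- naive_reparse(path)
  expect_equal(nrow(traj$samples), 1000)
  expect_equal(traj$samples$t, ref$time / 1000)
  expect_equal(max(traj$samples$t), truth$t[1000] / 1000)
  expect_equal(traj$samples$x, ref$gx)
  expect_equal(traj$samples$y, ref$gy)
})

test_that("parse errors name the offending line", {
  bad_row <- c("t,x,y", "0,1,2", "oops")
  expect_error(parse_gaze(bad_row, column_spec(header_lines = 1), 50),
               "line 3")
  non_mono <- c("t,x,y", "0,1,2", "0.5,1,2", "0.2,1,2")
  expect_error(parse_gaze(non_mono, column_spec(header_lines = 1), 50),
               "non-monotonic.*line.*3.*4")
  bad_num <- c("t,x,y", "0,1,2", "0.1,abc,2")
  expect_error(parse_gaze(bad_num, column_spec(header_lines = 1), 50),
               "line 3")
})

test_that("write_gaze/parse_gaze round trip preserves values at text precision", {
  v <- tiny_video()
  g <- gen_gaze(3, v, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_gaze(g$trajectory, path)
  back <- parse_gaze(path, canonical_column_spec(), 250, video = v)
  expect_equal(back$samples$t, g$trajectory$samples$t, tolerance = 1e-6)
  expect_equal(back$samples$x, g$trajectory$samples$x, tolerance = 1e-6)
  expect_equal(back$samples$y, g$trajectory$samples$y, tolerance = 1e-6)
  expect_equal(back$samples$pupil, g$trajectory$samples$pupil,
               tolerance = 1e-6)
  expect_equal(back$samples$label, g$trajectory$samples$label)
})

test_that("frame intervals are half-open and tile time", {
  v <- video_meta(640, 480, 25)
  expect_equal(frame_interval(0, v), cbind(t_start = 0, t_end = 0.04))
  # a boundary time belongs to the frame that starts there
  expect_equal(frame_interval(0.04, v), cbind(t_start = 0.04, t_end = 0.08))
  expect_error(frame_interval(-0.1, v), "t must be >= 0")

  # brute-force oracle at an awkward frame rate: scan frame indices
  v2 <- video_meta(640, 480, 29.97)
  set.seed(3)
  ts <- runif(500, 0, 60)
  iv <- frame_interval(ts, v2)
  for (i in seq_along(ts)) {
    n_scan <- 0L
    while (!((n_scan / 29.97) <= ts[i] && ts[i] < ((n_scan + 1) / 29.97)))
      n_scan <- n_scan + 1L
    expect_equal(unname(iv[i, "t_start"]), n_scan / 29.97)
    expect_equal(unname(iv[i, "t_end"]), (n_scan + 1) / 29.97)
  }
  # tiling: every sample in exactly one interval; intervals disjoint
  idx <- frame_index(ts, v2)
  expect_true(all(iv[, "t_start"] <= ts & ts < iv[, "t_end"]))
  expect_true(all(abs(iv[, "t_end"] - iv[, "t_start"] - 1 / 29.97) < 1e-12))
  expect_equal(idx, floor(ts * 29.97 + 1e-9))
})

test_that("I-DT labels stationary gaze as fixation, jumps as saccade", {
  fix <- gaze_trajectory("s", data.frame(
    t = seq(0, 0.49, by = 0.01), x = rep(100, 50), y = rep(100, 50)), 100)
  out <- classify_events(fix, dispersion_px = 10, min_duration_s = 0.1)
  expect_true(all(out$samples$label == "fixation"))

  jump <- gaze_trajectory("s", data.frame(
    t = seq(0, 0.49, by = 0.01),
    x = rep(c(0, 500), 25), y = rep(c(0, 500), 25)), 100)
  out2 <- classify_events(jump, dispersion_px = 10, min_duration_s = 0.1)
  expect_true(all(out2$samples$label == "saccade"))
})

test_that("I-DT recovers generated fixation structure", {
  v <- tiny_video()
  g <- gen_gaze(5, v, seed = 5, jitter_px = 1)
  out <- classify_events(g$trajectory, dispersion_px = 10,
                         min_duration_s = 0.1)
  truth <- g$trajectory$samples$label
  got <- out$samples$label
  recall <- mean(got[truth == "fixation"] == "fixation")
  expect_gte(recall, 0.9)
  # every sample is labeled exactly once
  expect_true(all(got %in% c("fixation", "saccade")))
  # fixation runs respect the minimum duration
  r <- rle(got)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tt <- out$samples$t
  dt <- 1 / out$sampling_rate
  for (k in which(r$values == "fixation"))
    expect_gte(tt[ends[k]] + dt - tt[starts[k]], 0.1)
})

test_that("classify_events honors the overwrite flag", {
  traj <- gaze_trajectory("s", data.frame(
    t = seq(0, 0.49, by = 0.01), x = rep(100, 50), y = rep(100, 50),
    label = c("saccade", rep(NA_character_, 49))), 100)
  kept <- classify_events(traj, 10, 0.1, overwrite = FALSE)
  expect_equal(kept$samples$label[1], "saccade")
  over <- classify_events(traj, 10, 0.1, overwrite = TRUE)
  expect_equal(over$samples$label[1], "fixation")
})

test_that("off-screen samples are retained and flagged", {
  v <- tiny_video()
  traj <- gaze_trajectory("s", data.frame(t = c(0, 0.01), x = c(10, -5),
                                          y = c(10, 10)), 100, video = v)
  expect_equal(traj$samples$onscreen, c(TRUE, FALSE))
  expect_equal(nrow(traj$samples), 2)
})

test_that("run config round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  spec <- column_spec(2, "\t", 0, 2, 3, pupil_col = 1,
                      time_unit = "milliseconds")
  write_run_config(spec, tiny_video(), 250, path)
  cfg <- read_run_config(path)
  expect_equal(cfg$spec, spec)
  expect_equal(cfg$video, tiny_video())
  expect_equal(cfg$sampling_rate, 250)
})
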