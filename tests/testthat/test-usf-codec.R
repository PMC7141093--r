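test_that("each sample becomes a point event on its frame interval", {
  v <- video_meta(640, 480, 25)
  traj <- gaze_trajectory("s1", data.frame(t = 0, x = 100, y = 50), 250)
  doc <- gaze_to_usf(traj, v)
  ev <- usf_events(doc)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$kind, "point")
  expect_equal(ev[[1]]$t_start, 0)
  expect_equal(ev[[1]]$t_end, 0.04)
  expect_equal(ev[[1]]$geometry$x, 100)
  expect_equal(ev[[1]]$geometry$y, 50)
  expect_error(gaze_to_usf(traj, NULL), "video_meta")
})

test_that("samples sharing a frame become co-timed events", {
  v <- video_meta(640, 480, 25)  # 40 ms frames
  traj <- gaze_trajectory("s1", data.frame(
    t = c(0, 0.01, 0.02, 0.03), x = 1:4, y = 1:4), 100)
  ev <- usf_events(gaze_to_usf(traj, v))
  expect_length(ev, 4)
  for (e in ev) {
    expect_equal(e$t_start, 0)
    expect_equal(e$t_end, 0.04)
  }
})

test_that("pupil size scales the point radius; fixations become rectangles", {
  v <- video_meta(640, 480, 25)
  traj <- gaze_trajectory("s1", data.frame(
    t = c(0, 0.1, 0.2), x = c(10, 20, 30), y = c(10, 20, 30),
    pupil = c(2, 4, 4), label = c("saccade", "saccade", "fixation")), 10)
  # reference pupil = median = 4 -> radii 4 and 8 at base_radius 8
  ev <- usf_events(gaze_to_usf(traj, v, base_radius = 8))
  expect_equal(ev[[1]]$geometry$radius, 8 * 2 / 4)
  expect_equal(ev[[2]]$geometry$radius, 8)
  expect_equal(ev[[3]]$kind, "rectangle")
  expect_equal(ev[[3]]$geometry$width, 16)
})

test_that("USF round trip is lossless to 6-decimal text precision", {
  v <- tiny_video()
  g <- gen_gaze(6, v, seed = 21)  # several hundred samples
  expect_gte(nrow(g$trajectory$samples), 200)
  labeled <- classify_events(g$trajectory, default_dispersion(v), 0.1)
  doc <- gaze_to_usf(labeled, v)
  path <- withr::local_tempfile(fileext = ".usf")
  write_usf(doc, path)
  back <- usf_to_gaze(read_usf(path))[[labeled$subject_id]]
  for (col in c("t", "x", "y", "pupil"))
    expect_equal(back$samples[[col]], labeled$samples[[col]],
                 tolerance = 1e-6, label = col)
  expect_equal(back$samples$label, labeled$samples$label)
  expect_equal(back$sampling_rate, labeled$sampling_rate)
})

test_that("USF serialization is idempotent byte-for-byte", {
  v <- tiny_video()
  g <- gen_gaze(2, v, seed = 8)
  p1 <- withr::local_tempfile(fileext = ".usf")
  p2 <- withr::local_tempfile(fileext = ".usf")
  write_usf(gaze_to_usf(g$trajectory, v), p1)
  write_usf(read_usf(p1), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("every per-frame event interval equals a frame interval", {
  v <- tiny_video()
  g <- gen_gaze(3, v, seed = 13)
  ev <- usf_events(gaze_to_usf(g$trajectory, v))
  for (e in ev) {
    n <- round(e$t_start * v$fps)
    expect_equal(e$t_start, n / v$fps, tolerance = 1e-9)
    expect_equal(e$t_end, (n + 1) / v$fps, tolerance = 1e-9)
  }
})

test_that("annotation intervals split on the frame grid", {
  v <- video_meta(640, 480, 25)
  ann <- object_annotation("car", list(
    list(t_start = 0, t_end = 0.12, geometry = c(10, 20, 30, 40))))
  doc <- annotations_to_usf(list(ann), v, granularity = "per_frame")
  expect_length(doc$streams$car$events, 3)  # 0.12 s / 0.04 s
  whole <- annotations_to_usf(list(ann), v, granularity = "per_interval")
  expect_length(whole$streams$car$events, 1)
  expect_equal(whole$streams$car$events[[1]]$t_end, 0.12)

  empty <- annotations_to_usf(list(), v)
  expect_length(empty$streams, 0)
  expect_equal(empty$metadata$tool, "gazemux")
})

test_that("moving synthetic annotations survive the USF round trip", {
  v <- tiny_video()
  anns <- gen_annotations(v, 2, seed = 4, duration_s = 1)
  doc <- annotations_to_usf(anns, v, granularity = "per_interval")
  path <- withr::local_tempfile(fileext = ".usf")
  write_usf(doc, path)
  back <- read_usf(path)
  for (ann in anns) {
    evs <- back$streams[[ann$object_id]]$events
    expect_length(evs, length(ann$intervals))
    for (k in seq_along(evs)) {
      g0 <- ann$intervals[[k]]$geometry
      g1 <- evs[[k]]$geometry
      expect_equal(g1$x, g0[1], tolerance = 1e-6)
      expect_equal(g1$y, g0[2], tolerance = 1e-6)
      expect_equal(g1$width, g0[3], tolerance = 1e-6)
      expect_equal(g1$height, g0[4], tolerance = 1e-6)
    }
  }
})

test_that("polygon annotations are encoded vertex-exact", {
  v <- tiny_video()
  tri <- rbind(c(1.5, 2), c(10, 2), c(5, 9.25))
  ann <- object_annotation("tri", list(
    list(t_start = 0, t_end = 0.04, geometry = tri)))
  path <- withr::local_tempfile(fileext = ".usf")
  write_usf(annotations_to_usf(list(ann), v), path)
  back <- read_usf(path)$streams$tri$events[[1]]
  expect_equal(back$kind, "polygon")
  expect_equal(back$geometry$vertices, tri, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(object_annotation("bad", list(
    list(t_start = 0, t_end = 1, geometry = rbind(c(0, 0), c(1, 1))))),
    "polygon")
})

test_that("documents without extra payload decode in declared degraded mode", {
  v <- video_meta(640, 480, 25)
  ev <- shape_event(0.04, 0.08, "point", list(x = 5, y = 6, radius = 2),
                    source = "s1")
  doc <- usf_document(list(s1 = list(type = "gaze", sampling_rate = 25,
                                     events = list(ev))), video = v)
  expect_warning(out <- usf_to_gaze(doc), class = "gazemux_loss_warning")
  expect_equal(out$s1$samples$t, 0.04)  # frame-interval start

  # zero streams -> empty list, no warning
  expect_silent(none <- usf_to_gaze(usf_document()))
  expect_length(none, 0)
})
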