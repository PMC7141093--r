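test_that("rectangles and polygons map to exact vertex walks", {
  rect <- shape_event(0, 1, "rectangle",
                      list(x = 10, y = 20, width = 20, height = 20))
  expect_equal(ass_draw_commands(rect),
               "m 10 20 l 30 20 l 30 40 l 10 40")
  tri <- shape_event(0, 1, "polygon",
                     list(vertices = rbind(c(0, 0), c(8, 0), c(4, 6))))
  expect_equal(ass_draw_commands(tri), "m 0 0 l 8 0 l 4 6")
})

test_that("a zero-radius point degenerates to a move-only drawing", {
  pt <- shape_event(0, 1, "point", list(x = 7, y = 9, radius = 0))
  expect_equal(ass_draw_commands(pt), "m 7 9")
})

test_that("Bezier circles stay within 1 px of the true radius (r = 50)", {
  pt <- shape_event(0, 1, "point", list(x = 100, y = 100, radius = 50))
  seg <- parse_draw_commands(ass_draw_commands(pt))
  expect_length(seg$beziers, 4)
  ts <- seq(0, 1, length.out = 200)
  for (b in seg$beziers) {
    # dense cubic Bezier evaluation (independent of the emitter)
    bx <- (1 - ts)^3 * b[1, 1] + 3 * (1 - ts)^2 * ts * b[2, 1] +
      3 * (1 - ts) * ts^2 * b[3, 1] + ts^3 * b[4, 1]
    by <- (1 - ts)^3 * b[1, 2] + 3 * (1 - ts)^2 * ts * b[2, 2] +
      3 * (1 - ts) * ts^2 * b[3, 2] + ts^3 * b[4, 2]
    d <- sqrt((bx - 100)^2 + (by - 100)^2)
    expect_lt(max(abs(d - 50)), 1)
  }
})

test_that("Bezier radial error is below 3% of r across radii", {
  for (r in c(5, 12, 30, 80)) {
    pt <- shape_event(0, 1, "point", list(x = 0, y = 0, radius = r))
    seg <- parse_draw_commands(ass_draw_commands(pt))
    ts <- seq(0, 1, length.out = 100)
    worst <- 0
    for (b in seg$beziers) {
      bx <- (1 - ts)^3 * b[1, 1] + 3 * (1 - ts)^2 * ts * b[2, 1] +
        3 * (1 - ts) * ts^2 * b[3, 1] + ts^3 * b[4, 1]
      by <- (1 - ts)^3 * b[1, 2] + 3 * (1 - ts)^2 * ts * b[2, 2] +
        3 * (1 - ts) * ts^2 * b[3, 2] + ts^3 * b[4, 2]
      worst <- max(worst, abs(sqrt(bx^2 + by^2) - r))
    }
    # integer coordinate rounding adds up to ~1 px on top of the 0.027%
    # analytic Bezier error, so allow 0.03 r + 1 px
    expect_lt(worst, 0.03 * r + 1)
  }
})

test_that("event times snap to centiseconds with a 1 cs floor", {
  v <- tiny_video()
  ev <- list(
    shape_event(0.1234, 0.1238, "point", list(x = 1, y = 1, radius = 2),
                source = "s"),
    shape_event(0.5, 0.5604, "point", list(x = 1, y = 1, radius = 2),
                source = "s"))
  doc <- shapes_to_ass(ev, v)
  expect_equal(doc$events$start, c(0.12, 0.5))
  expect_equal(doc$events$end, c(0.13, 0.56))  # floor kicks in for event 1
  expect_true(all(doc$events$end > doc$events$start))
})

test_that("serialize/parse is the identity on ASS documents", {
  v <- tiny_video()
  g <- gen_gaze(3, v, seed = 9)
  labeled <- classify_events(g$trajectory, default_dispersion(v), 0.1)
  doc <- shapes_to_ass(usf_events(gaze_to_usf(labeled, v)), v)
  back <- parse_ass(write_ass(doc))
  expect_equal(back$play_res_x, doc$play_res_x)
  expect_equal(back$styles, doc$styles)
  expect_equal(back$events, doc$events)

  # empty events section parses to zero events
  empty <- parse_ass(write_ass(shapes_to_ass(list(), v)))
  expect_equal(nrow(empty$events), 0)
})

test_that("rect/polygon vertices survive the lossy conversion exactly", {
  v <- tiny_video()
  rect <- shape_event(0, 0.04, "rectangle",
                      list(x = 3, y = 4, width = 10, height = 5),
                      source = "s")
  doc <- shapes_to_ass(list(rect), v)
  verts <- parse_draw_commands(doc$events$text[1])$vertices
  expect_equal(verts, rbind(c(3, 4), c(13, 4), c(13, 9), c(3, 9)),
               ignore_attr = TRUE)
})

test_that("parse_ass rejects malformed input with a line number", {
  v <- tiny_video()
  lines <- write_ass(shapes_to_ass(list(), v))
  no_playres <- lines[!grepl("^PlayRes", lines)]
  expect_error(parse_ass(no_playres), "PlayRes")
  expect_error(parse_ass(c("[Bogus Section]", "Foo: 1")),
               "unknown section.*line 1")
  expect_error(parse_ass(c(lines, "Garbage line")), "malformed line")
})

test_that("merging conserves events, sorts them, and assigns colours", {
  v <- tiny_video()
  mk_track <- function(n, seed) {
    g <- gen_gaze(n, v, seed = seed)
    shapes_to_ass(usf_events(gaze_to_usf(g$trajectory, v)), v)
  }
  expect_equal(nrow(merge_ass_tracks(list())$events), 0)

  one <- mk_track(2, 31)
  m1 <- merge_ass_tracks(list(one))
  expect_equal(nrow(m1$events), nrow(one$events))
  expect_equal(m1$styles$primary_colour[1],
               gazemux:::rgb_to_ass_colour(default_palette()[1]))

  docs <- lapply(c(41, 42, 43), function(s) mk_track(2, s))
  merged <- merge_ass_tracks(docs)
  expect_equal(nrow(merged$events),
               sum(vapply(docs, function(d) nrow(d$events), numeric(1))))
  expect_false(is.unsorted(merged$events$start))
  expect_length(unique(merged$styles$primary_colour), 3)

  # conservation over 20 random track sets
  set.seed(99)
  for (rep in 1:20) {
    k <- sample(1:4, 1)
    ds <- lapply(seq_len(k), function(i) mk_track(sample(1:3, 1), rep * 10 + i))
    m <- merge_ass_tracks(ds)
    expect_equal(nrow(m$events),
                 sum(vapply(ds, function(d) nrow(d$events), numeric(1))))
    expect_false(is.unsorted(m$events$start))
  }
})

test_that("merging tracks with mismatched PlayRes fails loudly", {
  a <- ass_document(640, 480,
                    data.frame(name = "s", primary_colour = "&H000000FF",
                               outline_colour = "&H000000FF"))
  b <- ass_document(1280, 720,
                    data.frame(name = "s", primary_colour = "&H000000FF",
                               outline_colour = "&H000000FF"))
  expect_error(merge_ass_tracks(list(a, b)), "PlayRes mismatch")
})

test_that("emitted files are accepted by parse_ass (self-consistency)", {
  v <- tiny_video()
  for (seed in c(1, 2)) {
    g <- gen_gaze(2, v, seed = seed)
    doc <- shapes_to_ass(usf_events(gaze_to_usf(g$trajectory, v)), v)
    path <- withr::local_tempfile(fileext = ".ass")
    write_ass(doc, path)
    expect_no_error(parse_ass(path))
  }
})
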