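test_that("Bresenham lines: known cases", {
  expect_equal(sort_px(raster_line(c(0, 0), c(3, 0))),
               cbind(x = 0:3, y = 0L), ignore_attr = TRUE)
  expect_equal(raster_line(c(0, 0), c(0, 0)),
               cbind(x = 0L, y = 0L), ignore_attr = TRUE)
  # (0,0)->(5,3): minor coordinate is the nearest pixel to the ideal line
  px <- raster_line(c(0, 0), c(5, 3))
  expect_equal(px[, "x"], 0:5)
  expect_equal(px[, "y"], round(0:5 * 3 / 5 + 1e-9))
})

test_that("Bresenham lines match the nearest-pixel walk on random instances", {
  set.seed(17)
  for (k in 1:100) {
    p0 <- sample(-30:30, 2)
    p1 <- sample(-30:30, 2)
    px <- raster_line(p0, p1)
    dx <- p1[1] - p0[1]; dy <- p1[2] - p0[2]
    n <- max(abs(dx), abs(dy))
    expect_equal(nrow(px), n + 1L)
    expect_equal(px[1, ], c(x = p0[1], y = p0[2]))
    expect_equal(px[nrow(px), ], c(x = p1[1], y = p1[2]))
    # brute force: walk the parametric line; each step's pixel must be
    # within half a pixel of the ideal position on the minor axis
    if (n > 0) {
      tt <- (seq_len(n + 1L) - 1L) / n
      ideal_x <- p0[1] + tt * dx
      ideal_y <- p0[2] + tt * dy
      expect_true(all(abs(px[, "x"] - ideal_x) <= 0.5 + 1e-9))
      expect_true(all(abs(px[, "y"] - ideal_y) <= 0.5 + 1e-9))
    }
    # 8-connectivity between consecutive pixels
    if (nrow(px) > 1) {
      steps <- abs(diff(px))
      expect_true(all(steps <= 1))
    }
  }
})

test_that("midpoint circles: known cases, symmetry, negative radius", {
  expect_equal(raster_circle(c(5, 7), 0), cbind(x = 5L, y = 7L),
               ignore_attr = TRUE)
  expect_equal(sort_px(raster_circle(c(0, 0), 1)),
               sort_px(rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))),
               ignore_attr = TRUE)
  expect_error(raster_circle(c(0, 0), -2), "radius")
  # 8-way symmetry about the center
  px <- raster_circle(c(0, 0), 10)
  for (tf in list(c(1, -1), c(-1, 1), c(-1, -1)))
    expect_equal(sort_px(px), sort_px(cbind(px[, 1] * tf[1],
                                            px[, 2] * tf[2])),
                 ignore_attr = TRUE)
  expect_equal(sort_px(px), sort_px(px[, 2:1]), ignore_attr = TRUE)
})

test_that("midpoint circles equal the per-octant brute-force minimizer", {
  set.seed(23)
  for (r in c(0:12, sample(13:30, 8))) {
    got <- sort_px(raster_circle(c(0, 0), r))
    expect_equal(got, brute_circle(r), ignore_attr = TRUE,
                 label = paste("radius", r))
  }
})

test_that("scan-line fill: axis-aligned square and degenerate polygons", {
  px <- fill_polygon(rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4)))
  expect_equal(nrow(px), 16)
  expect_true(all(px[, "x"] %in% 0:3 & px[, "y"] %in% 0:3))
  # collinear "polygon" has zero area
  expect_equal(nrow(fill_polygon(rbind(c(0, 0), c(5, 5), c(10, 10)))), 0)
  expect_error(fill_polygon(rbind(c(0, 0), c(1, 1))), ">= 3")
})

test_that("scan-line fill equals the point-in-polygon oracle on random 7-gons", {
  set.seed(29)
  for (k in 1:100) {
    v <- cbind(runif(7, 0, 63), runif(7, 0, 63))
    got <- fill_polygon(v)
    want <- sort_px(pip_grid_pixels(v, 64, 64))
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) expect_equal(sort_px(got), want, ignore_attr = TRUE)
    # spot-check the vectorized oracle against the scalar one
    if (k == 1 && nrow(want))
      expect_true(point_in_polygon(want[1, 1] + 0.5, want[1, 2] + 0.5, v))
    # the area bound needs a simple polygon: sort vertices by angle around
    # the centroid (shoelace area is meaningless for self-intersections)
    ctr <- colMeans(v)
    vs <- v[order(atan2(v[, 2] - ctr[2], v[, 1] - ctr[1])), ]
    per <- sum(sqrt(rowSums((vs - vs[c(2:7, 1), ])^2)))
    expect_lte(abs(nrow(fill_polygon(vs)) - shoelace(vs)), per)
  }
})

test_that("render_overlay draws only the active events and clips to frame", {
  v <- tiny_video()
  ev <- list(
    shape_event(0, 0.04, "point", list(x = 20, y = 20, radius = 5),
                style = shape_style("#FF0000")),
    shape_event(0.04, 0.08, "rectangle",
                list(x = 5, y = 5, width = 8, height = 8),
                style = shape_style("#00FF00")))
  none <- render_overlay(ev, 0.2, v)
  expect_equal(sum(!is.na(none$colors)), 0)
  # half-open membership: t = t_end belongs to the next event only
  at_boundary <- render_overlay(ev, 0.04, v)
  expect_true(all(stats::na.omit(c(at_boundary$colors)) == "#00FF00"))

  off <- shape_event(0, 1, "rectangle",
                     list(x = 200, y = 200, width = 10, height = 10))
  expect_equal(sum(!is.na(render_overlay(list(off), 0, v)$colors)), 0)

  partially_off <- shape_event(0, 1, "point",
                               list(x = 0, y = 0, radius = 10))
  px <- overlay_pixels(render_overlay(list(partially_off), 0, v))
  expect_true(all(px[, "x"] >= 0 & px[, "x"] < v$width))
  expect_true(all(px[, "y"] >= 0 & px[, "y"] < v$height))
  expect_error(render_overlay(ev, -1, v), "t must be >= 0")
})

test_that("a composite frame equals the union of its primitive oracles", {
  v <- tiny_video()
  # three circles plus one square active at once, as in a multi-sample frame
  ev <- list(
    shape_event(0, 0.04, "point", list(x = 10, y = 10, radius = 4)),
    shape_event(0, 0.04, "point", list(x = 30, y = 20, radius = 6)),
    shape_event(0, 0.04, "point", list(x = 50, y = 30, radius = 3)),
    shape_event(0, 0.04, "rectangle",
                list(x = 12, y = 30, width = 10, height = 8)))
  got <- overlay_pixels(render_overlay(ev, 0.02, v))
  circles <- rbind(
    sweep(brute_circle(4), 2, c(-10, -10)),
    sweep(brute_circle(6), 2, c(-30, -20)),
    sweep(brute_circle(3), 2, c(-50, -30)))
  square <- rbind(
    cbind(12:22, 30), cbind(12:22, 38), cbind(12, 30:38), cbind(22, 30:38))
  want <- unique(rbind(circles, square))
  want <- want[want[, 1] >= 0 & want[, 1] < v$width &
                 want[, 2] >= 0 & want[, 2] < v$height, ]
  expect_equal(sort_px(got), sort_px(want), ignore_attr = TRUE)
})

test_that("overlap resolves in painter's order and is order-stable for disjoint shapes", {
  v <- tiny_video()
  a <- shape_event(0, 1, "rectangle", list(x = 5, y = 5, width = 6, height = 6),
                   style = shape_style("#FF0000", fill = TRUE))
  b <- shape_event(0, 1, "rectangle", list(x = 8, y = 8, width = 6, height = 6),
                   style = shape_style("#0000FF", fill = TRUE))
  ov <- render_overlay(list(a, b), 0, v)
  expect_equal(ov$colors[10, 10], "#0000FF")  # (x=9,y=9) overlap -> later wins
  # disjoint shapes: order does not matter
  c1 <- shape_event(0, 1, "point", list(x = 40, y = 10, radius = 3),
                    style = shape_style("#FF0000"))
  d1 <- shape_event(0, 1, "point", list(x = 20, y = 35, radius = 3),
                    style = shape_style("#00FF00"))
  expect_equal(render_overlay(list(c1, d1), 0, v)$colors,
               render_overlay(list(d1, c1), 0, v)$colors)
})

test_that("filled circles are span fills; PNG export writes valid RGBA", {
  v <- tiny_video()
  ev <- shape_event(0, 1, "point", list(x = 20, y = 20, radius = 6),
                    style = shape_style("#FF0000", fill = TRUE))
  px <- overlay_pixels(render_overlay(list(ev), 0, v))
  boundary <- sweep(brute_circle(6), 2, c(-20, -20))
  spans <- lapply(split(boundary[, 1], boundary[, 2]), range)
  want <- do.call(rbind, lapply(names(spans), function(yy)
    cbind(spans[[yy]][1]:spans[[yy]][2], as.integer(yy))))
  expect_equal(sort_px(px), sort_px(want), ignore_attr = TRUE)

  path <- withr::local_tempfile(fileext = ".png")
  overlay_to_png(render_overlay(list(ev), 0, v), path)
  img <- png::readPNG(path)
  expect_equal(dim(img), c(v$height, v$width, 4))
  expect_equal(sum(img[, , 4] > 0), nrow(px))  # alpha marks drawn pixels
})
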