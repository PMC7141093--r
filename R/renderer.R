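## Reference software rasterizer. Mirrors the overlay drawing a patched
## player performs on its subpictures: integer Bresenham lines, midpoint
## circles, and even-odd scan-line polygon fill, composited in painter's
## order into an offline RGBA buffer. Binary (no anti-aliasing) on purpose:
## every primitive is checkable against a brute-force oracle.

#' Bresenham line rasterization
#'
#' 8-connected integer line including both endpoints.
#'
#' @param p0,p1 Integer endpoints `c(x, y)`.
#' @return Integer matrix with columns `x`, `y`, one row per pixel, in
#'   traversal order from `p0` to `p1`.
#' @examples
#' raster_line(c(0, 0), c(3, 0))
#' @export
raster_line <- function(p0, p1) {
  p0 <- as.integer(round(p0)); p1 <- as.integer(round(p1))
  x <- p0[1]; y <- p0[2]
  dx <- abs(p1[1] - x); dy <- -abs(p1[2] - y)
  sx <- if (x < p1[1]) 1L else -1L
  sy <- if (y < p1[2]) 1L else -1L
  err <- dx + dy
  n <- max(dx, -dy) + 1L
  out <- matrix(0L, n, 2, dimnames = list(NULL, c("x", "y")))
  for (i in seq_len(n)) {
    out[i, ] <- c(x, y)
    if (x == p1[1] && y == p1[2]) break
    e2 <- 2L * err
    if (e2 >= dy) { err <- err + dy; x <- x + sx }
    if (e2 <= dx) { err <- err + dx; y <- y + sy }
  }
  out
}

#' Midpoint circle rasterization
#'
#' Boundary of a circle of integer radius, 8-way symmetric about the center.
#'
#' @param center Integer center `c(x, y)`.
#' @param r Radius in pixels (>= 0).
#' @return Integer matrix with columns `x`, `y` (unique pixels).
#' @export
raster_circle <- function(center, r) {
  if (r < 0) stop("raster_circle: radius must be >= 0")
  center <- as.integer(round(center)); r <- as.integer(round(r))
  cx <- center[1]; cy <- center[2]
  if (r == 0L) return(matrix(c(cx, cy), 1, 2,
                             dimnames = list(NULL, c("x", "y"))))
  pts <- list()
  x <- r; y <- 0L
  err <- 1L - r
  while (x >= y) {
    pts[[length(pts) + 1L]] <- rbind(
      c(cx + x, cy + y), c(cx - x, cy + y), c(cx + x, cy - y),
      c(cx - x, cy - y), c(cx + y, cy + x), c(cx - y, cy + x),
      c(cx + y, cy - x), c(cx - y, cy - x))
    y <- y + 1L
    if (err < 0L) {
      err <- err + 2L * y + 1L
    } else {
      x <- x - 1L
      err <- err + 2L * (y - x) + 1L
    }
  }
  m <- unique(do.call(rbind, pts))
  colnames(m) <- c("x", "y")
  m
}

#' Even-odd scan-line polygon fill
#'
#' Fills a polygon by sampling pixel centers `(x + 0.5, y + 0.5)`: a pixel
#' is filled iff its center is inside under the even-odd rule, so
#' self-intersecting polygons are allowed and boundary handling is exact.
#'
#' @param vertices An `n x 2` matrix (n >= 3) of polygon vertices in pixels.
#' @return Integer matrix with columns `x`, `y` of filled pixels.
#' @export
fill_polygon <- function(vertices) {
  v <- as.matrix(vertices)
  if (nrow(v) < 3L) stop("fill_polygon: need >= 3 vertices")
  n <- nrow(v)
  xs <- v[, 1]; ys <- v[, 2]
  y0 <- floor(min(ys)); y1 <- ceiling(max(ys))
  rows <- list()
  for (py in y0:y1) {
    yc <- py + 0.5
    # crossings of edges with the scanline through the pixel centers;
    # half-open [min, max) vertex rule avoids double-counting vertices
    cross <- numeric(0)
    for (e in seq_len(n)) {
      ax <- xs[e]; ay <- ys[e]
      bx <- xs[e %% n + 1L]; by <- ys[e %% n + 1L]
      if ((ay <= yc && by > yc) || (by <= yc && ay > yc)) {
        cross <- c(cross, ax + (yc - ay) / (by - ay) * (bx - ax))
      }
    }
    if (length(cross) < 2L) next
    cross <- sort(cross)
    for (k in seq(1L, length(cross) - 1L, by = 2L)) {
      # pixel centers x+0.5 strictly inside (cross[k], cross[k+1])
      xa <- ceiling(cross[k] - 0.5 + 1e-12)
      xb <- floor(cross[k + 1L] - 0.5 - 1e-12)
      if (xb >= xa)
        rows[[length(rows) + 1L]] <- cbind(x = xa:xb, y = py)
    }
  }
  if (length(rows) == 0L)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  m <- do.call(rbind, rows)
  storage.mode(m) <- "integer"
  colnames(m) <- c("x", "y")
  m
}

# boundary pixels of one shape event (unclipped)
.shape_outline_pixels <- function(ev) {
  g <- ev$geometry
  switch(ev$kind,
    point = raster_circle(c(g$x, g$y), g$radius),
    rectangle = {
      x0 <- round(g$x); y0 <- round(g$y)
      x1 <- round(g$x + g$width); y1 <- round(g$y + g$height)
      unique(rbind(raster_line(c(x0, y0), c(x1, y0)),
                   raster_line(c(x1, y0), c(x1, y1)),
                   raster_line(c(x1, y1), c(x0, y1)),
                   raster_line(c(x0, y1), c(x0, y0))))
    },
    polygon = {
      v <- round(g$vertices)
      n <- nrow(v)
      segs <- lapply(seq_len(n), function(e)
        raster_line(v[e, ], v[e %% n + 1L, ]))
      unique(do.call(rbind, segs))
    })
}

# filled pixels of one shape event (unclipped), including its boundary
.shape_fill_pixels <- function(ev) {
  g <- ev$geometry
  boundary <- .shape_outline_pixels(ev)
  inner <- switch(ev$kind,
    point = {
      # span fill between the boundary x-extents of each scanline
      spans <- lapply(split(boundary[, "x"], boundary[, "y"]), range)
      do.call(rbind, lapply(names(spans), function(yy)
        cbind(x = spans[[yy]][1]:spans[[yy]][2], y = as.integer(yy))))
    },
    rectangle = fill_polygon(rbind(
      c(g$x, g$y), c(g$x + g$width, g$y),
      c(g$x + g$width, g$y + g$height), c(g$x, g$y + g$height))),
    polygon = fill_polygon(g$vertices))
  m <- unique(rbind(boundary, inner))
  storage.mode(m) <- "integer"
  colnames(m) <- c("x", "y")
  m
}

#' Render the overlay for one time point
#'
#' Draws exactly the shape events whose half-open interval `[t_start,
#' t_end)` contains `t` into an offline overlay buffer the size of the video
#' frame. Outlines use the Bresenham primitives; events whose style has the
#' fill flag (or `fill = TRUE` forcing it globally) are filled with the
#' scan-line algorithm. Shapes are clipped to the frame. Overlapping shapes
#' resolve in painter's order: the later event in the list wins per pixel.
#'
#' @param events List of [shape_event()].
#' @param t Time in seconds (>= 0).
#' @param video A [video_meta()].
#' @param fill `NA` (default) to honor each event's own fill flag, or
#'   TRUE/FALSE to force filling on or off for all events.
#' @return An object of class `raster_overlay`: list with `width`, `height`
#'   and `colors`, a height x width character matrix of "#RRGGBB" values
#'   (`NA` = transparent), indexed `[y + 1, x + 1]`.
#' @export
render_overlay <- function(events, t, video, fill = NA) {
  stopifnot(inherits(video, "video_meta"))
  if (t < 0) stop("render_overlay: t must be >= 0")
  colors <- matrix(NA_character_, nrow = video$height, ncol = video$width)
  for (ev in events) {
    if (!(ev$t_start <= t && t < ev$t_end)) next
    do_fill <- if (is.na(fill)) ev$style$fill else isTRUE(fill)
    px <- if (do_fill) .shape_fill_pixels(ev) else .shape_outline_pixels(ev)
    col <- if (do_fill && ev$style$fill) ev$style$fill_color else
      ev$style$outline
    keep <- px[, "x"] >= 0L & px[, "x"] < video$width &
      px[, "y"] >= 0L & px[, "y"] < video$height
    px <- px[keep, , drop = FALSE]
    if (nrow(px)) colors[cbind(px[, "y"] + 1L, px[, "x"] + 1L)] <- col
  }
  structure(list(width = video$width, height = video$height,
                 colors = colors), class = "raster_overlay")
}

#' @export
print.raster_overlay <- function(x, ...) {
  cat(sprintf("<raster_overlay> %dx%d, %d pixel(s) drawn\n", x$width,
              x$height, sum(!is.na(x$colors))))
  invisible(x)
}

#' Drawn pixels of an overlay as a matrix
#' @param overlay A `raster_overlay`.
#' @return Integer matrix with columns `x`, `y` of drawn pixels.
#' @export
overlay_pixels <- function(overlay) {
  idx <- which(!is.na(overlay$colors), arr.ind = TRUE)
  m <- cbind(x = as.integer(idx[, "col"] - 1L),
             y = as.integer(idx[, "row"] - 1L))
  m[order(m[, "y"], m[, "x"]), , drop = FALSE]
}

#' Export an overlay as a PNG
#'
#' Writes an RGBA image with transparent background, optionally composited
#' over a frame image (PNG of the same size).
#'
#' @param overlay A `raster_overlay` from [render_overlay()].
#' @param path Output PNG path.
#' @param frame_png Optional path to a background frame PNG.
#' @return `path`, invisibly.
#' @export
overlay_to_png <- function(overlay, path, frame_png = NULL) {
  h <- overlay$height; w <- overlay$width
  img <- array(0, dim = c(h, w, 4))
  if (!is.null(frame_png)) {
    bg <- png::readPNG(frame_png)
    if (length(dim(bg)) == 2L) bg <- array(rep(bg, 3), dim = c(dim(bg), 3))
    if (!all(dim(bg)[1:2] == c(h, w)))
      stop("overlay_to_png: frame size does not match overlay")
    img[, , 1:3] <- bg[, , 1:3]
    img[, , 4] <- 1
  }
  drawn <- which(!is.na(overlay$colors), arr.ind = TRUE)
  if (nrow(drawn)) {
    rgb <- grDevices::col2rgb(overlay$colors[drawn]) / 255
    for (ch in 1:3)
      img[cbind(drawn, ch)] <- rgb[ch, ]
    img[cbind(drawn, 4L)] <- 1
  }
  png::writePNG(img, path)
  invisible(path)
}
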