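# Shared fixtures and independent oracles. Oracles here are deliberately
# naive (enumeration / brute force) and never call the code paths they check.

tiny_video <- function() video_meta(64, 48, 25)

# brute-force midpoint-circle oracle: per octant scanline, the x minimizing
# the integer radial error, mirrored 8 ways
brute_circle <- function(r) {
  if (r == 0) return(matrix(c(0L, 0L), 1, 2))
  oct <- list(); y <- 0L
  repeat {
    xs <- 0:(r + 1L)
    x <- xs[which.min(abs(xs^2 + y^2 - r^2))]
    if (x < y) break
    oct[[y + 1L]] <- c(x, y); y <- y + 1L
  }
  oct <- do.call(rbind, oct)
  m <- unique(do.call(rbind, lapply(seq_len(nrow(oct)), function(i) {
    x <- oct[i, 1]; y <- oct[i, 2]
    rbind(c(x, y), c(-x, y), c(x, -y), c(-x, -y),
          c(y, x), c(-y, x), c(y, -x), c(-y, -x))
  })))
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

sort_px <- function(m) m[order(m[, 1], m[, 2]), , drop = FALSE]

# even-odd point-in-polygon test by ray casting (horizontal ray to +inf)
point_in_polygon <- function(px, py, v) {
  n <- nrow(v); inside <- FALSE
  for (e in seq_len(n)) {
    ax <- v[e, 1]; ay <- v[e, 2]
    bx <- v[e %% n + 1L, 1]; by <- v[e %% n + 1L, 2]
    if ((ay <= py && by > py) || (by <= py && ay > py)) {
      xc <- ax + (py - ay) / (by - ay) * (bx - ax)
      if (xc > px) inside <- !inside
    }
  }
  inside
}

# vectorized even-odd test of all pixel centers of a w x h grid; returns an
# (x, y) matrix of inside pixels. Same ray-casting rule as point_in_polygon.
pip_grid_pixels <- function(v, w, h) {
  centers_x <- rep(0:(w - 1) + 0.5, times = h)
  centers_y <- rep(0:(h - 1) + 0.5, each = w)
  crossings <- integer(length(centers_x))
  n <- nrow(v)
  for (e in seq_len(n)) {
    ax <- v[e, 1]; ay <- v[e, 2]
    bx <- v[e %% n + 1L, 1]; by <- v[e %% n + 1L, 2]
    hit <- (ay <= centers_y & by > centers_y) |
      (by <= centers_y & ay > centers_y)
    if (any(hit)) {
      xc <- ax + (centers_y[hit] - ay) / (by - ay) * (bx - ax)
      crossings[hit] <- crossings[hit] + (xc > centers_x[hit])
    }
  }
  inside <- crossings %% 2L == 1L
  cbind(x = as.integer(centers_x[inside] - 0.5),
        y = as.integer(centers_y[inside] - 0.5))
}

# shoelace polygon area
shoelace <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

# one-line naive re-parse of write_gaze output (independent of parse_gaze)
naive_reparse <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  raw
}

make_gaze_csv <- function(path, n = 20, unit = "milliseconds", seed = 7) {
  set.seed(seed)
  t <- switch(unit,
              milliseconds = seq(0, by = 4, length.out = n),
              seconds = seq(0, by = 0.004, length.out = n))
  x <- round(runif(n, 0, 640), 2)
  y <- round(runif(n, 0, 480), 2)
  writeLines(c("time,gx,gy", paste(t, x, y, sep = ",")), path)
  list(t = t, x = x, y = y)
}
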