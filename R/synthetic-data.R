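## Seeded generators for every input the tool consumes: gaze trajectories
## with known fixation/saccade structure, moving object annotations, EEG
## with a controlled alpha-band burst schedule, and a procedural stimulus
## video. Ground truth is always returned alongside the data so recovery
## tests can score against it. Saccades are linear interpolations between
## fixation centers — adequate for format and recovery testing; no
## oculomotor realism (main-sequence velocity profiles) is claimed.

#' Generate a synthetic gaze trajectory with known event structure
#'
#' Alternates fixations (Gaussian jitter around a uniformly drawn on-screen
#' point) and saccades (linear interpolation to the next fixation center).
#' Pupil size follows a smoothed positive random walk. Defaults emulate a
#' 250 Hz eye tracker viewing a short stimulus: fixations of 0.2-0.4 s
#' separated by 20-60 ms saccades, with 3 px within-fixation jitter.
#'
#' @param n_fixations Number of fixations (0 gives an empty trajectory).
#' @param video A [video_meta()].
#' @param seed Integer seed fixing the full output.
#' @param sampling_rate Sampling rate in Hz (default 250).
#' @param fixation_duration_s Range (min, max) of fixation durations.
#' @param saccade_duration_s Range (min, max) of saccade durations.
#' @param jitter_px SD of within-fixation Gaussian jitter in pixels.
#' @param pupil_base Mean relative pupil size (arbitrary units).
#' @param subject_id Subject id for the trajectory.
#' @return List with `trajectory` (a [gaze_trajectory()] whose `label`
#'   column holds the ground truth) and `events`: data frame of segments
#'   (`kind`, `t_start`, `t_end`, `cx`, `cy`).
#' @export
gen_gaze <- function(n_fixations, video, seed,
                     sampling_rate = 250,
                     fixation_duration_s = c(0.2, 0.4),
                     saccade_duration_s = c(0.02, 0.06),
                     jitter_px = 3,
                     pupil_base = 3,
                     subject_id = "synthetic") {
  stopifnot(inherits(video, "video_meta"), n_fixations >= 0,
            sampling_rate > 0, jitter_px > 0)
  empty_events <- data.frame(kind = character(), t_start = numeric(),
                             t_end = numeric(), cx = numeric(),
                             cy = numeric(), stringsAsFactors = FALSE)
  if (n_fixations == 0L)
    return(list(trajectory = gaze_trajectory(subject_id,
                  data.frame(t = numeric(), x = numeric(), y = numeric()),
                  sampling_rate, video = video),
                events = empty_events))
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    code
  }
  withr_seed({
    margin <- 0.1
    cx <- stats::runif(n_fixations, margin * video$width,
                       (1 - margin) * video$width)
    cy <- stats::runif(n_fixations, margin * video$height,
                       (1 - margin) * video$height)
    fd <- stats::runif(n_fixations, fixation_duration_s[1],
                       fixation_duration_s[2])
    sd_ <- stats::runif(max(0L, n_fixations - 1L), saccade_duration_s[1],
                        saccade_duration_s[2])
    segs <- list()
    for (i in seq_len(n_fixations)) {
      segs[[length(segs) + 1L]] <- list(kind = "fixation", dur = fd[i],
                                        from = c(cx[i], cy[i]),
                                        to = c(cx[i], cy[i]))
      if (i < n_fixations)
        segs[[length(segs) + 1L]] <- list(kind = "saccade", dur = sd_[i],
                                          from = c(cx[i], cy[i]),
                                          to = c(cx[i + 1], cy[i + 1]))
    }
    dt <- 1 / sampling_rate
    t <- x <- y <- lab <- NULL
    events <- list()
    k0 <- 0L  # global sample counter keeps the time base uniform
    for (sg in segs) {
      n_s <- max(1L, round(sg$dur * sampling_rate))
      tt <- (k0 + seq_len(n_s) - 1L) * dt
      frac <- if (n_s == 1L) 0.5 else (seq_len(n_s) - 1L) / (n_s - 1L)
      if (sg$kind == "fixation") {
        xx <- sg$from[1] + stats::rnorm(n_s, 0, jitter_px)
        yy <- sg$from[2] + stats::rnorm(n_s, 0, jitter_px)
      } else {
        xx <- sg$from[1] + frac * (sg$to[1] - sg$from[1])
        yy <- sg$from[2] + frac * (sg$to[2] - sg$from[2])
      }
      events[[length(events) + 1L]] <-
        data.frame(kind = sg$kind, t_start = tt[1], t_end = tt[n_s] + dt,
                   cx = (sg$from[1] + sg$to[1]) / 2,
                   cy = (sg$from[2] + sg$to[2]) / 2,
                   stringsAsFactors = FALSE)
      t <- c(t, tt); x <- c(x, xx); y <- c(y, yy)
      lab <- c(lab, rep(sg$kind, n_s))
      k0 <- k0 + n_s
    }
    # pupil: positive smoothed random walk around pupil_base
    n <- length(t)
    walk <- cumsum(stats::rnorm(n, 0, 0.02))
    walk <- stats::filter(walk, rep(1 / 25, 25), sides = 2)
    walk[is.na(walk)] <- 0
    pupil <- pmax(0.5, pupil_base + as.numeric(walk))
    x <- pmin(pmax(x, 0), video$width - 1e-6)
    y <- pmin(pmax(y, 0), video$height - 1e-6)
    traj <- gaze_trajectory(subject_id,
      data.frame(t = t, x = x, y = y, pupil = pupil, label = lab,
                 stringsAsFactors = FALSE),
      sampling_rate, video = video)
    list(trajectory = traj, events = do.call(rbind, events))
  })
}

#' Generate moving object annotations
#'
#' Each object is a rectangle (or polygon) moving along a piecewise-linear
#' path, emitted as one static-geometry interval per video frame so the
#' geometry at any frame midpoint is exactly reproducible. All geometry is
#' clipped to the frame.
#'
#' @param video A [video_meta()].
#' @param n_objects Number of objects (0 gives an empty list).
#' @param seed Integer seed.
#' @param duration_s Annotated time span (default 2 s).
#' @param shape `"rectangle"` or `"polygon"` (triangle) geometry.
#' @return List of [object_annotation()].
#' @export
gen_annotations <- function(video, n_objects, seed, duration_s = 2,
                            shape = c("rectangle", "polygon")) {
  shape <- match.arg(shape)
  stopifnot(inherits(video, "video_meta"), n_objects >= 0, duration_s > 0)
  if (n_objects == 0L) return(list())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  n_frames <- max(1L, floor(duration_s * video$fps))
  out <- vector("list", n_objects)
  for (i in seq_len(n_objects)) {
    w <- stats::runif(1, 0.1, 0.25) * video$width
    h <- stats::runif(1, 0.1, 0.25) * video$height
    x0 <- stats::runif(1, 0, video$width - w)
    y0 <- stats::runif(1, 0, video$height - h)
    x1 <- stats::runif(1, 0, video$width - w)
    y1 <- stats::runif(1, 0, video$height - h)
    intervals <- vector("list", n_frames)
    for (fidx in seq_len(n_frames)) {
      frac <- (fidx - 0.5) / n_frames  # path position at the frame midpoint
      px <- x0 + frac * (x1 - x0)
      py <- y0 + frac * (y1 - y0)
      geom <- if (shape == "rectangle") c(px, py, w, h) else
        rbind(c(px + w / 2, py), c(px + w, py + h), c(px, py + h))
      intervals[[fidx]] <- list(t_start = (fidx - 1) / video$fps,
                                t_end = fidx / video$fps,
                                geometry = geom)
    }
    out[[i]] <- object_annotation(sprintf("object%02d", i), intervals)
  }
  out
}

#' Generate EEG with a controlled alpha-burst schedule
#'
#' White noise plus an alpha-frequency sinusoid gated on during the given
#' burst intervals; the schedule is the ground truth for end-to-end
#' sonification recovery tests.
#'
#' @param fs Sampling rate in Hz (default 250).
#' @param duration_s Trace duration in seconds.
#' @param burst_schedule Two-column matrix of (on_start, on_end) seconds;
#'   `NULL` or 0-row for no bursts.
#' @param alpha_freq Burst frequency in Hz (default 10, mid alpha band).
#' @param alpha_amp Burst amplitude in microvolts (default 20).
#' @param noise_sd White-noise SD in microvolts (default 2).
#' @param seed Integer seed.
#' @return List with `eeg` (an [eeg_trace()]) and `schedule` (the burst
#'   matrix).
#' @export
gen_eeg <- function(fs = 250, duration_s = 4, burst_schedule = NULL,
                    alpha_freq = 10, alpha_amp = 20, noise_sd = 2, seed = 1) {
  stopifnot(fs > 0, duration_s > 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  n <- round(fs * duration_s)
  t <- (seq_len(n) - 1L) / fs
  x <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
  if (!is.null(burst_schedule) && NROW(burst_schedule) > 0) {
    burst_schedule <- matrix(as.numeric(burst_schedule), ncol = 2)
    gate <- rep(FALSE, n)
    for (k in seq_len(nrow(burst_schedule)))
      gate <- gate | (t >= burst_schedule[k, 1] & t < burst_schedule[k, 2])
    x <- x + alpha_amp * sin(2 * pi * alpha_freq * t) * gate
  } else {
    burst_schedule <- matrix(numeric(0), ncol = 2)
  }
  list(eeg = eeg_trace(x, fs), schedule = burst_schedule)
}

# one synthetic RGB frame: solid background plus a binary frame-index strip
# and a moving bar, returned as raw interleaved RGB bytes (row-major)
.synthetic_frame <- function(frame_idx, width, height) {
  r <- matrix(40L, height, width)
  g <- matrix(40L, height, width)
  b <- matrix(80L, height, width)
  # binary frame counter as 8 blocks along the top rows
  bits <- as.integer(intToBits(frame_idx))[1:8]
  bw <- max(1L, width %/% 8L)
  for (k in 1:8) {
    if (bits[k] == 1L) {
      cols <- ((k - 1L) * bw + 1L):min(k * bw, width)
      r[1:min(4L, height), cols] <- 255L
      g[1:min(4L, height), cols] <- 255L
      b[1:min(4L, height), cols] <- 255L
    }
  }
  # moving vertical bar
  bar <- (frame_idx %% width) + 1L
  g[, bar] <- 220L
  rgb <- array(0L, dim = c(3, width, height))
  rgb[1, , ] <- t(r); rgb[2, , ] <- t(g); rgb[3, , ] <- t(b)
  as.raw(as.vector(rgb))
}

#' Generate a procedural stimulus video
#'
#' Writes an MKV with one uncompressed RGB video track whose frames show a
#' solid background, a binary frame-index strip, and a moving bar — a
#' stimulus stand-in so muxing tests need no real recording. Frame count =
#' `floor(duration_s * fps)`.
#'
#' @param video A [video_meta()] (keep it small: frames are uncompressed).
#' @param duration_s Duration in seconds (> 0).
#' @param out_path Output MKV path.
#' @return `out_path` invisibly, with attribute `n_frames`.
#' @export
gen_video <- function(video, duration_s, out_path) {
  stopifnot(inherits(video, "video_meta"))
  if (duration_s <= 0) stop("gen_video: duration_s must be > 0")
  n_frames <- floor(duration_s * video$fps)
  if (n_frames < 1L) stop("gen_video: duration shorter than one frame")
  frame_ms <- 1000 / video$fps
  blocks <- lapply(seq_len(n_frames), function(i) list(
    t_ms = (i - 1L) * frame_ms, duration_ms = NULL,
    data = .synthetic_frame(i - 1L, video$width, video$height)))
  mkv_write(list(list(
    type = "video", name = "stimulus", codec_id = "V_UNCOMPRESSED",
    video = list(width = video$width, height = video$height),
    default_duration_ns = round(1e9 / video$fps),
    blocks = blocks)), list(), out_path)
  invisible(structure(out_path, n_frames = n_frames))
}
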