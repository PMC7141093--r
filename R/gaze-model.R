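#' Video metadata
#'
#' Describes the stimulus video that gaze samples are aligned to: its pixel
#' resolution and frame rate. Shapes are placed in the same pixel coordinate
#' space as the video (origin top-left, x rightward, y downward, 0-based).
#'
#' @param width Frame width in pixels (positive integer).
#' @param height Frame height in pixels (positive integer).
#' @param fps Frame rate in frames per second (positive).
#' @return An object of class `video_meta`.
#' @examples
#' video_meta(1280, 720, 25)
#' @export
video_meta <- function(width, height, fps) {
  stopifnot(is.numeric(width), is.numeric(height), is.numeric(fps))
  width <- as.integer(width); height <- as.integer(height); fps <- as.double(fps)
  if (width <= 0L || height <= 0L || fps <= 0)
    stop("video_meta: width, height and fps must all be positive")
  structure(list(width = width, height = height, fps = fps),
            class = "video_meta")
}

#' @export
print.video_meta <- function(x, ...) {
  cat(sprintf("<video_meta> %dx%d @ %g fps\n", x$width, x$height, x$fps))
  invisible(x)
}

#' Column layout of a delimited gaze file
#'
#' Eye trackers emit delimited text in many dialects: the number of header
#' lines, the delimiter, which columns hold time and the gaze point, and the
#' unit of the timestamp all vary between vendors. A `column_spec` pins these
#' down so [parse_gaze()] can read any of them.
#'
#' @param header_lines Number of lines before the first data row (>= 0).
#' @param delimiter Single-character field separator (default ",").
#' @param t_col,x_col,y_col 0-based column indices of timestamp, x and y.
#' @param pupil_col,label_col Optional 0-based indices of relative pupil size
#'   and of an event label column; `NA` if absent.
#' @param time_unit One of `"seconds"`, `"milliseconds"`, `"microseconds"`,
#'   `"sample_index"`. Sample indices are divided by the sampling rate.
#' @return An object of class `column_spec`.
#' @export
column_spec <- function(header_lines = 0L, delimiter = ",",
                        t_col = 0L, x_col = 1L, y_col = 2L,
                        pupil_col = NA_integer_, label_col = NA_integer_,
                        time_unit = c("seconds", "milliseconds",
                                      "microseconds", "sample_index")) {
  time_unit <- match.arg(time_unit)
  header_lines <- as.integer(header_lines)
  if (header_lines < 0L) stop("column_spec: header_lines must be >= 0")
  if (!is.character(delimiter) || nchar(delimiter) != 1L)
    stop("column_spec: delimiter must be a single character")
  idx <- c(t = as.integer(t_col), x = as.integer(x_col), y = as.integer(y_col))
  opt <- c(pupil = as.integer(pupil_col), label = as.integer(label_col))
  used <- c(idx, opt[!is.na(opt)])
  if (any(used < 0L)) stop("column_spec: column indices must be >= 0")
  if (anyDuplicated(used)) stop("column_spec: column indices must be distinct")
  structure(list(header_lines = header_lines, delimiter = delimiter,
                 t_col = idx[["t"]], x_col = idx[["x"]], y_col = idx[["y"]],
                 pupil_col = opt[["pupil"]], label_col = opt[["label"]],
                 time_unit = time_unit),
            class = "column_spec")
}

#' Gaze trajectory container
#'
#' One subject's time-ordered point-of-regard samples. Stored as a data frame
#' with columns `t` (seconds from video start), `x`, `y` (video pixels),
#' `pupil` (relative pupil size, `NA` when not recorded), `label`
#' (`"fixation"`, `"saccade"` or `NA`) and `onscreen` (FALSE for samples
#' outside the frame, which are kept, never dropped).
#'
#' @param subject_id Identifier of the subject (used as track name later).
#' @param samples Data frame with at least columns `t`, `x`, `y`.
#' @param sampling_rate Nominal sampling rate in Hz; may exceed the video
#'   frame rate, in which case several samples share a frame.
#' @param video Optional [video_meta()] used to flag off-screen samples.
#' @return An object of class `gaze_trajectory`.
#' @export
gaze_trajectory <- function(subject_id, samples, sampling_rate, video = NULL) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("gaze_trajectory: sampling_rate must be > 0")
  samples <- as.data.frame(samples)
  for (col in c("t", "x", "y"))
    if (is.null(samples[[col]])) stop("gaze_trajectory: samples need column ", col)
  n <- nrow(samples)
  if (is.null(samples$pupil)) samples$pupil <- rep(NA_real_, n)
  if (is.null(samples$label)) samples$label <- rep(NA_character_, n)
  if (n > 0L) {
    if (any(samples$t < 0)) stop("gaze_trajectory: negative timestamps")
    if (any(!is.finite(samples$x)) || any(!is.finite(samples$y)))
      stop("gaze_trajectory: non-finite coordinates")
    if (n > 1L) {
      bad <- which(diff(samples$t) <= 0)
      if (length(bad))
        stop(sprintf(
          "gaze_trajectory: timestamps not strictly increasing at rows %d/%d (t = %g, %g)",
          bad[1], bad[1] + 1L, samples$t[bad[1]], samples$t[bad[1] + 1L]))
    }
  }
  samples$onscreen <- if (is.null(video)) rep(TRUE, n) else
    samples$x >= 0 & samples$x < video$width &
    samples$y >= 0 & samples$y < video$height
  rownames(samples) <- NULL
  structure(list(subject_id = subject_id,
                 samples = samples[c("t", "x", "y", "pupil", "label", "onscreen")],
                 sampling_rate = as.double(sampling_rate)),
            class = "gaze_trajectory")
}

#' @export
print.gaze_trajectory <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("<gaze_trajectory> subject '%s': %d samples @ %g Hz",
              x$subject_id, n, x$sampling_rate))
  if (n > 0) cat(sprintf(", t in [%g, %g] s", x$samples$t[1], x$samples$t[n]))
  cat("\n")
  invisible(x)
}

#' Object annotation
#'
#' A named object of interest annotated over one or more time intervals, each
#' with a geometry: a bounding rectangle `c(x, y, width, height)` or a polygon
#' given as a two-column vertex matrix (>= 3 vertices), all in video pixels.
#'
#' @param object_id Identifier of the annotated object.
#' @param intervals List of lists with fields `t_start`, `t_end`, `geometry`.
#'   A numeric length-4 geometry is a rectangle; a matrix is a polygon.
#' @return An object of class `object_annotation`.
#' @export
object_annotation <- function(object_id, intervals) {
  stopifnot(is.character(object_id), length(object_id) == 1L, is.list(intervals))
  for (iv in intervals) {
    if (!is.numeric(iv$t_start) || !is.numeric(iv$t_end) || iv$t_start >= iv$t_end)
      stop("object_annotation: each interval needs t_start < t_end")
    g <- iv$geometry
    if (is.matrix(g)) {
      if (ncol(g) != 2L || nrow(g) < 3L)
        stop("object_annotation: polygon needs a >=3 x 2 vertex matrix")
    } else if (!(is.numeric(g) && length(g) == 4L)) {
      stop("object_annotation: geometry must be c(x,y,w,h) or a vertex matrix")
    }
  }
  structure(list(object_id = object_id, intervals = intervals),
            class = "object_annotation")
}

.parse_label <- function(s) {
  s <- tolower(trimws(s))
  ifelse(s %in% c("fixation", "fix", "f"), "fixation",
         ifelse(s %in% c("saccade", "sac", "s"), "saccade", NA_character_))
}

#' Parse a delimited gaze recording
#'
#' Reads gaze samples from delimited text according to a [column_spec()]:
#' skips the declared header lines, picks the configured columns, converts
#' the timestamp to seconds (dividing sample indices by `sampling_rate`),
#' and validates that time is strictly increasing.
#'
#' @param input Path to a file, or a character vector of lines.
#' @param spec A [column_spec()].
#' @param sampling_rate Sampling rate in Hz (required; also used to convert
#'   `time_unit = "sample_index"`).
#' @param subject_id Subject identifier; defaults to the file base name.
#' @param video Optional [video_meta()] for off-screen flagging.
#' @return A [gaze_trajectory()].
#' @examples
#' lines <- c("t,x,y", "0,10,20", "0.02,12,22")
#' parse_gaze(lines, column_spec(header_lines = 1), sampling_rate = 50,
#'            subject_id = "s1")
#' @export
parse_gaze <- function(input, spec, sampling_rate, subject_id = NULL,
                       video = NULL) {
  stopifnot(inherits(spec, "column_spec"))
  if (length(input) == 1L && file.exists(input)) {
    if (is.null(subject_id))
      subject_id <- tools::file_path_sans_ext(basename(input))
    lines <- readLines(input, warn = FALSE)
  } else {
    lines <- as.character(input)
    if (is.null(subject_id)) subject_id <- "subject"
  }
  if (spec$header_lines > length(lines))
    stop("parse_gaze: header_lines exceeds file length")
  body <- lines[seq_along(lines) > spec$header_lines]
  keep <- nzchar(trimws(body))
  body <- body[keep]
  line_no <- (seq_along(lines)[seq_along(lines) > spec$header_lines])[keep]
  n <- length(body)
  need <- max(spec$t_col, spec$x_col, spec$y_col,
              spec$pupil_col, spec$label_col, na.rm = TRUE) + 1L
  t <- x <- y <- pupil <- numeric(n)
  label <- character(n)
  if (n > 0L) {
    fields <- strsplit(body, spec$delimiter, fixed = TRUE)
    for (i in seq_len(n)) {
      f <- fields[[i]]
      if (length(f) < need)
        stop(sprintf("parse_gaze: line %d has %d fields, need %d",
                     line_no[i], length(f), need))
      num <- function(j, what) {
        v <- suppressWarnings(as.numeric(f[j + 1L]))
        if (is.na(v) && !identical(trimws(f[j + 1L]), "NA"))
          stop(sprintf("parse_gaze: line %d: cannot read %s from '%s'",
                       line_no[i], what, f[j + 1L]))
        v
      }
      t[i] <- num(spec$t_col, "timestamp")
      x[i] <- num(spec$x_col, "x")
      y[i] <- num(spec$y_col, "y")
      pupil[i] <- if (is.na(spec$pupil_col)) NA_real_ else num(spec$pupil_col, "pupil")
      label[i] <- if (is.na(spec$label_col)) NA_character_ else
        .parse_label(f[spec$label_col + 1L])
    }
  }
  t <- switch(spec$time_unit,
              seconds      = t,
              milliseconds = t / 1e3,
              microseconds = t / 1e6,
              sample_index = t / sampling_rate)
  if (n > 1L) {
    bad <- which(diff(t) <= 0)
    if (length(bad))
      stop(sprintf(
        "parse_gaze: non-monotonic timestamps at lines %d and %d (t = %g, %g s)",
        line_no[bad[1]], line_no[bad[1] + 1L], t[bad[1]], t[bad[1] + 1L]))
  }
  gaze_trajectory(subject_id,
                  data.frame(t = t, x = x, y = y, pupil = pupil,
                             label = label, stringsAsFactors = FALSE),
                  sampling_rate, video = video)
}

#' Write a gaze trajectory as normalized CSV
#'
#' Emits the package's canonical delimited layout: header
#' `t,x,y[,pupil][,label]`, times in seconds, six decimal places, "." decimal
#' separator. [parse_gaze()] with the matching [column_spec()] is its inverse
#' up to that text precision.
#'
#' @param traj A [gaze_trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gaze <- function(traj, path) {
  stopifnot(inherits(traj, "gaze_trajectory"))
  s <- traj$samples
  has_pupil <- any(!is.na(s$pupil))
  has_label <- any(!is.na(s$label))
  cols <- c("t", "x", "y", if (has_pupil) "pupil", if (has_label) "label")
  lines <- paste(cols, collapse = ",")
  if (nrow(s) > 0L) {
    parts <- list(.num6(s$t), .num6(s$x), .num6(s$y))
    if (has_pupil) parts <- c(parts, list(ifelse(is.na(s$pupil), "NA", .num6(s$pupil))))
    if (has_label) parts <- c(parts, list(ifelse(is.na(s$label), "none", s$label)))
    lines <- c(lines, do.call(paste, c(parts, sep = ",")))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' The canonical column spec matching [write_gaze()] output.
#' @param has_pupil,has_label Whether the optional columns are present.
#' @return A [column_spec()].
#' @export
canonical_column_spec <- function(has_pupil = TRUE, has_label = TRUE) {
  column_spec(header_lines = 1L, delimiter = ",", t_col = 0L, x_col = 1L,
              y_col = 2L,
              pupil_col = if (has_pupil) 3L else NA_integer_,
              label_col = if (has_label) {if (has_pupil) 4L else 3L} else NA_integer_,
              time_unit = "seconds")
}

# fixed 6-decimal, "."-separated, locale-independent numeric text
.num6 <- function(v) {
  out <- sprintf("%.6f", v)
  out[!is.finite(v)] <- "NA"
  out
}

#' Display interval of the video frame containing a time point
#'
#' Time is tiled into half-open frame intervals `[n/fps, (n+1)/fps)`; every
#' sample time falls in exactly one of them, so a boundary time belongs to
#' the frame that starts there.
#'
#' @param t Time(s) in seconds, >= 0 (vectorized).
#' @param video A [video_meta()].
#' @return A two-column matrix with columns `t_start`, `t_end` (seconds).
#' @examples
#' frame_interval(0.04, video_meta(640, 480, 25)) # [0.04, 0.08)
#' @export
frame_interval <- function(t, video) {
  stopifnot(inherits(video, "video_meta"))
  if (any(t < 0)) stop("frame_interval: t must be >= 0")
  n <- frame_index(t, video)
  cbind(t_start = n / video$fps, t_end = (n + 1) / video$fps)
}

#' Frame index containing a time point
#' @inheritParams frame_interval
#' @return Integer frame index `floor(t * fps)`, adjusted so that a time
#'   sitting exactly on a frame boundary maps to the frame that starts there
#'   even when `t * fps` lands a floating-point ulp below the integer.
#' @export
frame_index <- function(t, video) {
  if (any(t < 0)) stop("frame_index: t must be >= 0")
  raw <- t * video$fps
  n <- floor(raw)
  # counter floating-point droop at exact boundaries (e.g. 0.04 * 25)
  up <- (raw - n) > (1 - 1e-9)
  as.integer(n + up)
}

#' Dispersion-threshold (I-DT) fixation/saccade classification
#'
#' Labels each sample either `"fixation"` or `"saccade"` using the classic
#' dispersion-threshold procedure: a window is grown while its dispersion
#' `(max x - min x) + (max y - min y)` stays within `dispersion_px`; if the
#' window reaches `min_duration_s` it is extended maximally and its samples
#' are labeled fixation, otherwise the window start is a saccade sample.
#'
#' @param traj A non-empty [gaze_trajectory()].
#' @param dispersion_px Dispersion threshold in pixels (> 0). The artifact
#'   default used elsewhere is 2% of the larger video dimension.
#' @param min_duration_s Minimum fixation duration in seconds (> 0).
#' @param overwrite Overwrite labels already present? Default TRUE.
#' @return The trajectory with its `label` column filled.
#' @export
classify_events <- function(traj, dispersion_px, min_duration_s = 0.1,
                            overwrite = TRUE) {
  stopifnot(inherits(traj, "gaze_trajectory"))
  s <- traj$samples
  n <- nrow(s)
  if (n == 0L) stop("classify_events: empty trajectory")
  if (dispersion_px <= 0 || min_duration_s <= 0)
    stop("classify_events: thresholds must be > 0")
  lab <- rep("saccade", n)
  disp <- function(i, j)
    (max(s$x[i:j]) - min(s$x[i:j])) + (max(s$y[i:j]) - min(s$y[i:j]))
  i <- 1L
  while (i <= n) {
    # smallest window at i spanning min_duration_s
    j <- i
    while (j < n && s$t[j] - s$t[i] < min_duration_s) j <- j + 1L
    if (s$t[j] - s$t[i] >= min_duration_s && disp(i, j) <= dispersion_px) {
      while (j < n && disp(i, j + 1L) <= dispersion_px) j <- j + 1L
      lab[i:j] <- "fixation"
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (overwrite) {
    traj$samples$label <- lab
  } else {
    keep <- !is.na(s$label)
    traj$samples$label <- ifelse(keep, s$label, lab)
  }
  traj
}

#' Default I-DT dispersion threshold for a video: 2% of max(width, height).
#' @param video A [video_meta()].
#' @return Threshold in pixels.
#' @export
default_dispersion <- function(video) 0.02 * max(video$width, video$height)

#' Read/write a key-value run configuration (column layout + video metadata)
#'
#' Serialized as YAML so the same settings can be reused across runs and
#' attached to output containers for provenance.
#'
#' @param spec A [column_spec()].
#' @param video A [video_meta()].
#' @param sampling_rate Sampling rate in Hz.
#' @param path File path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns a list with elements `spec`, `video`,
#'   `sampling_rate`.
#' @export
write_run_config <- function(spec, video, sampling_rate, path) {
  stopifnot(inherits(spec, "column_spec"), inherits(video, "video_meta"))
  yaml::write_yaml(list(
    column_spec = unclass(spec),
    video = unclass(video),
    sampling_rate = sampling_rate), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cs <- cfg$column_spec
  list(
    spec = column_spec(cs$header_lines, cs$delimiter, cs$t_col, cs$x_col,
                       cs$y_col,
                       if (is.null(cs$pupil_col)) NA_integer_ else cs$pupil_col,
                       if (is.null(cs$label_col)) NA_integer_ else cs$label_col,
                       cs$time_unit),
    video = video_meta(cfg$video$width, cfg$video$height, cfg$video$fps),
    sampling_rate = cfg$sampling_rate)
}
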