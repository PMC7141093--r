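## ASS (Advanced Sub Station Alpha) codec: lossy conversion of shape events
## to subtitle files with vector drawing commands (m = move, l = line,
## b = cubic Bezier) that stock media players render, plus a parser for the
## emitted subset and MergeSub-style merging of several subject tracks into
## one colour-coded track.

#' Default 8-colour palette for distinguishing subject tracks.
#' @return Character vector of "#RRGGBB" colours.
#' @export
default_palette <- function() {
  c("#FF0000", "#00FF00", "#0000FF", "#FFFF00",
    "#FF00FF", "#00FFFF", "#FF8000", "#FFFFFF")
}

# "#RRGGBB" <-> ASS "&H00BBGGRR" (BGR order, leading alpha byte 00)
rgb_to_ass_colour <- function(hex) {
  stopifnot(all(grepl("^#[0-9A-Fa-f]{6}$", hex)))
  paste0("&H00", toupper(substr(hex, 6, 7)), toupper(substr(hex, 4, 5)),
         toupper(substr(hex, 2, 3)))
}

ass_colour_to_rgb <- function(ass) {
  m <- regmatches(ass, regexec("^&H([0-9A-Fa-f]{2})?([0-9A-Fa-f]{2})([0-9A-Fa-f]{2})([0-9A-Fa-f]{2})$", ass))[[1]]
  if (length(m) == 0L) stop("ass_colour_to_rgb: bad colour '", ass, "'")
  toupper(paste0("#", m[5], m[4], m[3]))
}

#' ASS document
#'
#' A parsed/constructed Advanced Sub Station Alpha script: the script-info
#' header (with the mandatory PlayResX/PlayResY drawing resolution), a style
#' table, and a time-sorted event list whose text fields hold drawing
#' commands.
#'
#' @param play_res_x,play_res_y Script drawing resolution (the video
#'   resolution, so drawing coordinates equal video pixels).
#' @param styles Data frame with columns `name`, `primary_colour` (ASS
#'   `&HAABBGGRR` notation), `outline_colour`.
#' @param events Data frame with columns `layer` (int), `start`, `end`
#'   (seconds on the centisecond grid), `style`, `name`, `text`.
#' @param title Script title.
#' @return An object of class `ass_document`.
#' @export
ass_document <- function(play_res_x, play_res_y,
                         styles = data.frame(name = character(),
                                             primary_colour = character(),
                                             outline_colour = character(),
                                             stringsAsFactors = FALSE),
                         events = data.frame(layer = integer(),
                                             start = numeric(),
                                             end = numeric(),
                                             style = character(),
                                             name = character(),
                                             text = character(),
                                             stringsAsFactors = FALSE),
                         title = "gaze overlay") {
  stopifnot(play_res_x > 0, play_res_y > 0)
  if (nrow(events)) {
    if (any(events$end <= events$start))
      stop("ass_document: events need start < end")
    if (is.unsorted(events$start))
      stop("ass_document: events must be sorted by start time")
    if (!all(events$style %in% styles$name))
      stop("ass_document: event style missing from style table")
  }
  rownames(styles) <- rownames(events) <- NULL
  structure(list(title = title, play_res_x = as.integer(play_res_x),
                 play_res_y = as.integer(play_res_y),
                 styles = styles, events = events),
            class = "ass_document")
}

#' @export
print.ass_document <- function(x, ...) {
  cat(sprintf("<ass_document> %dx%d, %d style(s), %d event(s)\n",
              x$play_res_x, x$play_res_y, nrow(x$styles), nrow(x$events)))
  invisible(x)
}

# round-half-up to integer (ASS renderers disagree on fractional coords)
.ri <- function(v) floor(v + 0.5)

# snap seconds to the centisecond grid
.cs <- function(t) round(t * 100) / 100

#' Drawing-command string for one shape event
#'
#' Rectangles and polygons become closed `m`/`l` vertex walks; points become
#' circles approximated by four cubic Bezier quadrants with the standard
#' control-point factor `k = 0.5523 * r`. Coordinates are rounded half-up to
#' integers.
#'
#' @param ev A [shape_event()].
#' @return The drawing-command body (without override tags).
#' @export
ass_draw_commands <- function(ev) {
  stopifnot(inherits(ev, "shape_event"))
  g <- ev$geometry
  switch(ev$kind,
    rectangle = {
      x0 <- .ri(g$x); y0 <- .ri(g$y)
      x1 <- .ri(g$x + g$width); y1 <- .ri(g$y + g$height)
      sprintf("m %d %d l %d %d l %d %d l %d %d",
              x0, y0, x1, y0, x1, y1, x0, y1)
    },
    polygon = {
      v <- g$vertices
      paste(c(sprintf("m %d %d", .ri(v[1, 1]), .ri(v[1, 2])),
              sprintf("l %d %d", .ri(v[-1, 1]), .ri(v[-1, 2]))),
            collapse = " ")
    },
    point = {
      cx <- g$x; cy <- g$y; r <- g$radius
      if (.ri(r) <= 0)
        return(sprintf("m %d %d", .ri(cx), .ri(cy)))
      k <- 0.5523 * r
      p <- function(x, y) sprintf("%d %d", .ri(x), .ri(y))
      paste("m", p(cx + r, cy),
            "b", p(cx + r, cy + k), p(cx + k, cy + r), p(cx, cy + r),
            "b", p(cx - k, cy + r), p(cx - r, cy + k), p(cx - r, cy),
            "b", p(cx - r, cy - k), p(cx - k, cy - r), p(cx, cy - r),
            "b", p(cx + k, cy - r), p(cx + r, cy - k), p(cx + r, cy))
    })
}

#' Convert shape events to an ASS document
#'
#' The lossy out-of-the-box representation: geometry survives as drawing
#' commands, times are rounded to the centisecond grid (with a minimum
#' 1 cs duration so no event vanishes), and the non-visual `extra` payload
#' is dropped. One style is created per distinct event source.
#'
#' @param events List of [shape_event()] (e.g. [usf_events()] output).
#' @param video A [video_meta()] providing PlayResX/PlayResY.
#' @param color "#RRGGBB" primary colour applied to all generated styles.
#' @param title Script title.
#' @return An [ass_document()].
#' @export
shapes_to_ass <- function(events, video, color = "#FF0000",
                          title = "gaze overlay") {
  stopifnot(inherits(video, "video_meta"))
  sources <- unique(vapply(events, function(e) {
    if (nzchar(e$source)) e$source else "track"
  }, character(1)))
  if (length(sources) == 0L) sources <- character(0)
  styles <- data.frame(name = sources,
                       primary_colour = rep(rgb_to_ass_colour(color),
                                            length(sources)),
                       outline_colour = rep(rgb_to_ass_colour(color),
                                            length(sources)),
                       stringsAsFactors = FALSE)
  n <- length(events)
  ev <- data.frame(layer = integer(n), start = numeric(n), end = numeric(n),
                   style = character(n), name = character(n),
                   text = character(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    e <- events[[i]]
    t0 <- .cs(e$t_start)
    t1 <- max(.cs(e$t_end), t0 + 0.01)
    ev$layer[i] <- 0L
    ev$start[i] <- t0
    ev$end[i] <- t1
    ev$style[i] <- if (nzchar(e$source)) e$source else "track"
    ev$name[i] <- ""
    ev$text[i] <- paste0("{\\an7\\pos(0,0)\\p1}", ass_draw_commands(e),
                         "{\\p0}")
  }
  ev <- ev[order(ev$start), , drop = FALSE]
  ass_document(video$width, video$height, styles, ev, title = title)
}

.ass_time <- function(t) {
  cs <- round(t * 100)
  h <- cs %/% 360000; cs <- cs - h * 360000
  m <- cs %/% 6000; cs <- cs - m * 6000
  s <- cs %/% 100; cc <- cs - s * 100
  sprintf("%d:%02d:%02d.%02d", h, m, s, cc)
}

.parse_ass_time <- function(s) {
  p <- strsplit(s, "[:.]")[[1]]
  if (length(p) != 4L) stop("bad ASS timestamp '", s, "'")
  v <- as.numeric(p)
  v[1] * 3600 + v[2] * 60 + v[3] + v[4] / 100
}

.STYLE_FORMAT <- c("Name", "Fontname", "Fontsize", "PrimaryColour",
                   "SecondaryColour", "OutlineColour", "BackColour", "Bold",
                   "Italic", "Underline", "StrikeOut", "ScaleX", "ScaleY",
                   "Spacing", "Angle", "BorderStyle", "Outline", "Shadow",
                   "Alignment", "MarginL", "MarginR", "MarginV", "Encoding")
.EVENT_FORMAT <- c("Layer", "Start", "End", "Style", "Name", "MarginL",
                   "MarginR", "MarginV", "Effect", "Text")

.style_line <- function(name, primary, outline) {
  paste0("Style: ", name, ",Arial,20,", primary, ",", primary, ",",
         outline, ",&H00000000,0,0,0,0,100,100,0,0,1,2,0,7,0,0,0,1")
}

#' Serialize an ASS document
#'
#' Sections `[Script Info]`, `[V4+ Styles]`, `[Events]`; Dialogue lines with
#' layer 0 and `H:MM:SS.CC` timestamps; UTF-8.
#'
#' @param doc An [ass_document()].
#' @param path Output path, or `NULL` to return the lines.
#' @return `path` invisibly, or a character vector of lines if `path` is
#'   `NULL`.
#' @export
write_ass <- function(doc, path = NULL) {
  stopifnot(inherits(doc, "ass_document"))
  lines <- c(
    "[Script Info]",
    paste0("Title: ", doc$title),
    "ScriptType: v4.00+",
    paste0("PlayResX: ", doc$play_res_x),
    paste0("PlayResY: ", doc$play_res_y),
    "",
    "[V4+ Styles]",
    paste0("Format: ", paste(.STYLE_FORMAT, collapse = ", ")),
    if (nrow(doc$styles))
      .style_line(doc$styles$name, doc$styles$primary_colour,
                  doc$styles$outline_colour),
    "",
    "[Events]",
    paste0("Format: ", paste(.EVENT_FORMAT, collapse = ", ")))
  if (nrow(doc$events)) {
    e <- doc$events
    lines <- c(lines, sprintf("Dialogue: %d,%s,%s,%s,%s,0,0,0,,%s",
                              e$layer, .ass_time(e$start), .ass_time(e$end),
                              e$style, e$name, e$text))
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Parse an ASS script (the subset emitted by [write_ass()])
#'
#' Inverse of [write_ass()] on its own output. PlayResX/PlayResY are
#' mandatory; an unknown section or a malformed line raises an error naming
#' the line number.
#'
#' @param input Path to an .ass file, or a character vector of lines.
#' @return An [ass_document()].
#' @export
parse_ass <- function(input) {
  lines <- if (length(input) == 1L && file.exists(input))
    readLines(input, warn = FALSE, encoding = "UTF-8") else as.character(input)
  section <- ""
  title <- ""
  prx <- pry <- NA_integer_
  styles <- list(); events <- list()
  known <- c("[script info]", "[v4+ styles]", "[v4 styles]", "[events]")
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, ";")) next
    if (startsWith(ln, "[")) {
      if (!(tolower(ln) %in% known))
        stop(sprintf("parse_ass: unknown section '%s' at line %d", ln, i))
      section <- tolower(ln)
      next
    }
    kv <- regmatches(ln, regexec("^([A-Za-z]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) == 0L)
      stop(sprintf("parse_ass: malformed line %d: '%s'", i, ln))
    key <- kv[2]; val <- kv[3]
    if (section == "[script info]") {
      if (key == "Title") title <- val
      if (key == "PlayResX") prx <- as.integer(val)
      if (key == "PlayResY") pry <- as.integer(val)
    } else if (section %in% c("[v4+ styles]", "[v4 styles]")) {
      if (key == "Style") {
        f <- strsplit(val, ",", fixed = TRUE)[[1]]
        if (length(f) < 23L)
          stop(sprintf("parse_ass: style with %d fields at line %d",
                       length(f), i))
        styles[[length(styles) + 1L]] <-
          data.frame(name = trimws(f[1]), primary_colour = trimws(f[4]),
                     outline_colour = trimws(f[6]), stringsAsFactors = FALSE)
      } else if (key != "Format") {
        stop(sprintf("parse_ass: unknown style field '%s' at line %d", key, i))
      }
    } else if (section == "[events]") {
      if (key == "Dialogue") {
        f <- strsplit(val, ",", fixed = TRUE)[[1]]
        if (length(f) < 10L)
          stop(sprintf("parse_ass: dialogue with %d fields at line %d",
                       length(f), i))
        text <- paste(f[10:length(f)], collapse = ",")
        events[[length(events) + 1L]] <-
          data.frame(layer = as.integer(f[1]),
                     start = .parse_ass_time(trimws(f[2])),
                     end = .parse_ass_time(trimws(f[3])),
                     style = trimws(f[4]), name = f[5], text = text,
                     stringsAsFactors = FALSE)
      } else if (key != "Format") {
        stop(sprintf("parse_ass: unknown event field '%s' at line %d", key, i))
      }
    } else {
      stop(sprintf("parse_ass: content before any section at line %d", i))
    }
  }
  if (is.na(prx) || is.na(pry))
    stop("parse_ass: PlayResX/PlayResY are mandatory and missing")
  styles <- if (length(styles)) do.call(rbind, styles) else
    data.frame(name = character(), primary_colour = character(),
               outline_colour = character(), stringsAsFactors = FALSE)
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(layer = integer(), start = numeric(), end = numeric(),
               style = character(), name = character(), text = character(),
               stringsAsFactors = FALSE)
  ass_document(prx, pry, styles, events, title = title)
}

#' Merge several ASS tracks into one colour-coded track
#'
#' The MergeSub operation: players show only one subtitle track at a time,
#' so to compare subjects their per-subject tracks are merged into a single
#' track, each input restyled with a distinct palette colour. Events are
#' re-sorted by (start time, input index); order within an input is stable.
#'
#' @param docs List of [ass_document()] sharing the same PlayRes.
#' @param palette Vector of "#RRGGBB" colours, recycled if shorter than
#'   `docs`; defaults to [default_palette()].
#' @return A single merged [ass_document()].
#' @export
merge_ass_tracks <- function(docs, palette = default_palette()) {
  if (length(docs) == 0L)
    return(ass_document(1, 1, title = "merged (empty)"))
  for (d in docs) stopifnot(inherits(d, "ass_document"))
  prx <- vapply(docs, `[[`, integer(1), "play_res_x")
  pry <- vapply(docs, `[[`, integer(1), "play_res_y")
  if (length(unique(prx)) > 1L || length(unique(pry)) > 1L)
    stop(sprintf(
      "merge_ass_tracks: PlayRes mismatch between tracks: %s",
      paste(sprintf("#%d=%dx%d", seq_along(docs), prx, pry), collapse = ", ")))
  styles <- list(); events <- list()
  for (i in seq_along(docs)) {
    d <- docs[[i]]
    col <- rgb_to_ass_colour(palette[(i - 1L) %% length(palette) + 1L])
    prefix <- sprintf("t%02d_", i)
    st <- d$styles
    if (nrow(st) == 0L)
      st <- data.frame(name = "track", primary_colour = col,
                       outline_colour = col, stringsAsFactors = FALSE)
    st$name <- paste0(prefix, st$name)
    st$primary_colour <- col
    st$outline_colour <- col
    styles[[i]] <- st
    ev <- d$events
    if (nrow(ev)) {
      ev$style <- paste0(prefix, ev$style)
      ev$.input <- i
      ev$.pos <- seq_len(nrow(ev))
      events[[i]] <- ev
    }
  }
  styles <- do.call(rbind, styles)
  if (length(events)) {
    ev <- do.call(rbind, events)
    ev <- ev[order(ev$start, ev$.input, ev$.pos), , drop = FALSE]
    ev$.input <- ev$.pos <- NULL
  } else {
    ev <- docs[[1]]$events[0, , drop = FALSE]
  }
  ass_document(docs[[1]]$play_res_x, docs[[1]]$play_res_y, styles, ev,
               title = "merged tracks")
}

#' Parse a drawing-command string back to vertices / Bezier segments
#'
#' Used by the renderer and by geometry-fidelity tests: returns the `m`/`l`
#' vertex walk and any cubic Bezier segments from a `{\\p1}...{\\p0}` text.
#'
#' @param text Event text (override tags allowed) or a bare command string.
#' @return List with `vertices` (n x 2 matrix of m/l points, possibly 1 row)
#'   and `beziers` (list of 4 x 2 control-point matrices).
#' @export
parse_draw_commands <- function(text) {
  body <- gsub("\\{[^}]*\\}", "", text)
  tok <- strsplit(trimws(body), "\\s+")[[1]]
  if (length(tok) == 0L || tok[1] == "")
    return(list(vertices = matrix(numeric(0), ncol = 2), beziers = list()))
  verts <- list(); bez <- list()
  cur <- NULL
  i <- 1L
  mode <- ""
  nums <- function(k) as.numeric(tok[i + seq_len(k)])
  while (i <= length(tok)) {
    if (tok[i] %in% c("m", "l", "b")) {
      mode <- tok[i]; i <- i + 1L
    } else {
      if (mode == "b") {
        v <- nums(5L); v <- c(as.numeric(tok[i]), v)
        if (anyNA(v)) stop("parse_draw_commands: bad Bezier coordinates")
        p0 <- if (!is.null(cur)) cur else v[1:2]
        bez[[length(bez) + 1L]] <- rbind(p0, v[1:2], v[3:4], v[5:6])
        cur <- v[5:6]
        verts[[length(verts) + 1L]] <- cur
        i <- i + 6L
      } else {
        v <- c(as.numeric(tok[i]), as.numeric(tok[i + 1L]))
        if (anyNA(v)) stop("parse_draw_commands: bad coordinates near '",
                           tok[i], "'")
        cur <- v
        verts[[length(verts) + 1L]] <- v
        i <- i + 2L
      }
    }
  }
  list(vertices = do.call(rbind, verts), beziers = bez)
}
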