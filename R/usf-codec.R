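TOOL_NAME <- "gazemux"
TOOL_VERSION <- "0.1.0"

#' Style of a drawn shape
#'
#' @param outline Outline colour as "#RRGGBB".
#' @param fill Fill the shape? (scan-line fill in the renderer).
#' @param fill_color Fill colour; defaults to the outline colour.
#' @return An object of class `shape_style`.
#' @export
shape_style <- function(outline = "#FF0000", fill = FALSE,
                        fill_color = outline) {
  stopifnot(grepl("^#[0-9A-Fa-f]{6}$", outline),
            grepl("^#[0-9A-Fa-f]{6}$", fill_color))
  structure(list(outline = toupper(outline), fill = isTRUE(fill),
                 fill_color = toupper(fill_color)), class = "shape_style")
}

#' Timed geometric primitive
#'
#' The unit of subtitle-track payload: a point (circle), rectangle or polygon
#' shown during a half-open time interval, with a drawing style, the source
#' it came from (subject or object id), and an ordered key-value `extra`
#' payload carrying everything that cannot be visualized (raw timestamp,
#' pupil size, event label) so that encoding stays lossless.
#'
#' @param t_start,t_end Interval in seconds, `t_start < t_end`.
#' @param kind `"point"`, `"rectangle"` or `"polygon"`.
#' @param geometry For a point: `list(x, y, radius)`; rectangle:
#'   `list(x, y, width, height)`; polygon: `list(vertices = <n x 2 matrix>)`.
#' @param style A [shape_style()].
#' @param source Subject or object identifier.
#' @param extra Named list of scalar payload values (kept in order).
#' @return An object of class `shape_event`.
#' @export
shape_event <- function(t_start, t_end, kind, geometry,
                        style = shape_style(), source = "",
                        extra = list()) {
  kind <- match.arg(kind, c("point", "rectangle", "polygon"))
  if (!(t_start < t_end)) stop("shape_event: need t_start < t_end")
  g <- geometry
  switch(kind,
    point = {
      stopifnot(is.numeric(g$x), is.numeric(g$y), is.numeric(g$radius))
      if (g$radius < 0) stop("shape_event: radius must be >= 0")
    },
    rectangle = {
      stopifnot(is.numeric(g$x), is.numeric(g$y))
      if (g$width < 0 || g$height < 0)
        stop("shape_event: width/height must be >= 0")
    },
    polygon = {
      v <- g$vertices
      if (!is.matrix(v) || ncol(v) != 2L || nrow(v) < 3L)
        stop("shape_event: polygon needs >= 3 vertices (n x 2 matrix)")
    })
  structure(list(t_start = as.double(t_start), t_end = as.double(t_end),
                 kind = kind, geometry = g, style = style,
                 source = as.character(source), extra = extra),
            class = "shape_event")
}

#' USF subtitle document with shape extension
#'
#' In-memory representation of a Universal Subtitle Format document: a
#' metadata block and one subtitle stream per source (subject or object),
#' each a list of [shape_event()]s. The serialized XML dialect is fixed by
#' this package and documented in [write_usf()]; it is the lossless carrier
#' of all gaze metadata.
#'
#' @param streams Named list (by source id) of lists with fields `type`
#'   (`"gaze"` or `"annotation"`), `sampling_rate` (or `NA`), and `events`
#'   (list of [shape_event()]).
#' @param title Document title.
#' @param author Author string recorded in the metadata block.
#' @param video Optional [video_meta()] recorded for frame alignment.
#' @return An object of class `usf_document`.
#' @export
usf_document <- function(streams = list(), title = "gaze metadata",
                         author = "", video = NULL) {
  structure(list(metadata = list(title = title, author = author,
                                 tool = TOOL_NAME, version = TOOL_VERSION),
                 video = video, streams = streams),
            class = "usf_document")
}

#' @export
print.usf_document <- function(x, ...) {
  cat(sprintf("<usf_document> '%s': %d stream(s)\n", x$metadata$title,
              length(x$streams)))
  for (nm in names(x$streams))
    cat(sprintf("  %s [%s]: %d event(s)\n", nm, x$streams[[nm]]$type,
                length(x$streams[[nm]]$events)))
  invisible(x)
}

# radius of the visualized circle: scaled by relative pupil size when present
.point_radius <- function(pupil, base_radius, reference_pupil) {
  if (is.na(pupil) || is.na(reference_pupil) || reference_pupil <= 0)
    return(base_radius)
  base_radius * (pupil / reference_pupil)
}

#' Encode a gaze trajectory as a USF stream
#'
#' Each sample becomes one shape event spanning the half-open display
#' interval of the video frame it falls into; when the tracker samples
#' faster than the video frame rate, several events share one interval and
#' are shown together. Saccade-labeled (or unlabeled) samples become points
#' (circles) whose radius scales with relative pupil size
#' (`base_radius * pupil / reference_pupil`); fixation-labeled samples
#' become squares of the same nominal size. The raw timestamp, pupil size
#' and label ride along in the event's `extra` payload, so nothing is lost.
#'
#' @param traj A [gaze_trajectory()].
#' @param video A [video_meta()] (required: events are frame-aligned).
#' @param style A [shape_style()] for the stream.
#' @param base_radius Circle radius in pixels for a sample at the reference
#'   pupil size (default 8).
#' @param reference_pupil Pupil size mapped to `base_radius`; default is the
#'   trajectory's median recorded pupil size.
#' @return A [usf_document()] with one stream named after the subject.
#' @export
gaze_to_usf <- function(traj, video, style = shape_style(),
                        base_radius = 8,
                        reference_pupil = NULL) {
  stopifnot(inherits(traj, "gaze_trajectory"))
  if (!inherits(video, "video_meta"))
    stop("gaze_to_usf: a video_meta is required to align samples to frames")
  s <- traj$samples
  if (is.null(reference_pupil))
    reference_pupil <- if (all(is.na(s$pupil))) NA_real_ else
      stats::median(s$pupil, na.rm = TRUE)
  events <- vector("list", nrow(s))
  if (nrow(s) > 0L) {
    iv <- frame_interval(s$t, video)
    for (i in seq_len(nrow(s))) {
      extra <- list(t = .num6(s$t[i]))
      if (!is.na(s$pupil[i])) extra$pupil <- .num6(s$pupil[i])
      if (!is.na(s$label[i])) extra$label <- s$label[i]
      if (!s$onscreen[i]) extra$offscreen <- "yes"
      r <- .point_radius(s$pupil[i], base_radius, reference_pupil)
      events[[i]] <- if (identical(s$label[i], "fixation")) {
        # raw centre rides in extra: the rect corner is derived (rounded) text
        extra <- c(list(x = .num6(s$x[i]), y = .num6(s$y[i])), extra)
        shape_event(iv[i, 1], iv[i, 2], "rectangle",
                    list(x = s$x[i] - r, y = s$y[i] - r,
                         width = 2 * r, height = 2 * r),
                    style = style, source = traj$subject_id, extra = extra)
      } else {
        shape_event(iv[i, 1], iv[i, 2], "point",
                    list(x = s$x[i], y = s$y[i], radius = r),
                    style = style, source = traj$subject_id, extra = extra)
      }
    }
  }
  streams <- list()
  streams[[traj$subject_id]] <- list(type = "gaze",
                                     sampling_rate = traj$sampling_rate,
                                     events = events)
  usf_document(streams, title = paste("gaze:", traj$subject_id),
               video = video)
}

#' Encode object annotations as USF streams
#'
#' Bounding rectangles and polygons per time interval become shape events;
#' with per-frame granularity each annotation interval is split at the video
#' frame grid (one event per overlapped frame), with per-interval granularity
#' the interval is kept whole.
#'
#' @param annotations List of [object_annotation()] (or a single one).
#' @param video A [video_meta()].
#' @param style A [shape_style()] (a filled style is typical for boxes).
#' @param granularity `"per_frame"` or `"per_interval"`.
#' @return A [usf_document()] with one stream per object.
#' @export
annotations_to_usf <- function(annotations, video,
                               style = shape_style("#00FF00"),
                               granularity = c("per_frame", "per_interval")) {
  granularity <- match.arg(granularity)
  if (inherits(annotations, "object_annotation"))
    annotations <- list(annotations)
  stopifnot(inherits(video, "video_meta"))
  streams <- list()
  for (ann in annotations) {
    stopifnot(inherits(ann, "object_annotation"))
    events <- list()
    for (iv in ann$intervals) {
      geom <- iv$geometry
      mk <- function(t0, t1) {
        if (is.matrix(geom))
          shape_event(t0, t1, "polygon", list(vertices = geom),
                      style = style, source = ann$object_id)
        else
          shape_event(t0, t1, "rectangle",
                      list(x = geom[1], y = geom[2],
                           width = geom[3], height = geom[4]),
                      style = style, source = ann$object_id)
      }
      if (granularity == "per_interval") {
        events[[length(events) + 1L]] <- mk(iv$t_start, iv$t_end)
      } else {
        n0 <- frame_index(iv$t_start, video)
        # last frame whose interval intersects [t_start, t_end)
        n1 <- frame_index(max(iv$t_start, iv$t_end - 1e-9), video)
        for (n in n0:n1) {
          t0 <- n / video$fps
          t1 <- (n + 1) / video$fps
          events[[length(events) + 1L]] <- mk(t0, t1)
        }
      }
    }
    streams[[ann$object_id]] <- list(type = "annotation",
                                     sampling_rate = NA_real_,
                                     events = events)
  }
  usf_document(streams, title = "object annotations", video = video)
}

#' Decode gaze trajectories from a USF document
#'
#' Exact inverse of [gaze_to_usf()]: the raw timestamps, pupil sizes and
#' labels in each event's `extra` payload are used, not the frame-quantized
#' display intervals. A foreign document lacking the payload is decoded in
#' a declared degraded mode — times become frame-interval starts — with a
#' warning of class `gazemux_loss_warning`.
#'
#' @param doc A [usf_document()].
#' @return A list of [gaze_trajectory()], one per `"gaze"` stream (streams
#'   of other types are ignored).
#' @export
usf_to_gaze <- function(doc) {
  stopifnot(inherits(doc, "usf_document"))
  out <- list()
  for (nm in names(doc$streams)) {
    st <- doc$streams[[nm]]
    if (!identical(st$type, "gaze")) next
    n <- length(st$events)
    t <- x <- y <- pupil <- numeric(n)
    label <- character(n)
    degraded <- FALSE
    for (i in seq_len(n)) {
      ev <- st$events[[i]]
      g <- ev$geometry
      if (!is.null(ev$extra$x) && !is.null(ev$extra$y)) {
        x[i] <- as.numeric(ev$extra$x); y[i] <- as.numeric(ev$extra$y)
      } else if (ev$kind == "rectangle") {
        x[i] <- g$x + g$width / 2; y[i] <- g$y + g$height / 2
      } else {
        x[i] <- g$x; y[i] <- g$y
      }
      if (!is.null(ev$extra$t)) {
        t[i] <- as.numeric(ev$extra$t)
      } else {
        t[i] <- ev$t_start; degraded <- TRUE
      }
      pupil[i] <- if (is.null(ev$extra$pupil)) NA_real_ else
        as.numeric(ev$extra$pupil)
      label[i] <- if (is.null(ev$extra$label)) NA_character_ else
        ev$extra$label
    }
    if (degraded)
      warning(structure(class = c("gazemux_loss_warning", "warning",
                                  "condition"),
                        list(message = sprintf(
          "stream '%s': no raw-timestamp payload; times quantized to frame intervals",
          nm), call = NULL)))
    sr <- if (is.null(st$sampling_rate) || is.na(st$sampling_rate)) 1 else
      st$sampling_rate
    out[[nm]] <- gaze_trajectory(nm,
      data.frame(t = t, x = x, y = y, pupil = pupil, label = label,
                 stringsAsFactors = FALSE), sr, video = doc$video)
  }
  out
}

## ---- XML serialization -----------------------------------------------------
## The serialized dialect (normative for this package):
##   <USFSubtitles version="1.1">
##     <metadata><title/><author><name/></author><comment/></metadata>
##     <video width height fps/>                       (optional)
##     <subtitles source type sampling_rate>
##       <subtitle start stop>
##         <shape type="point|rectangle|polygon" ...numeric attrs...
##                outline fill fillcolor/>
##         <comment key="..." value="..."/>            (extra payload)
##       </subtitle>
##     </subtitles>
##   </USFSubtitles>
## All numbers are fixed 6-decimal, "." separator. Polygon vertices are a
## "x1,y1 x2,y2 ..." points attribute.

.shape_node_attrs <- function(ev) {
  g <- ev$geometry
  a <- c(type = ev$kind)
  a <- c(a, switch(ev$kind,
    point = c(x = .num6(g$x), y = .num6(g$y), radius = .num6(g$radius)),
    rectangle = c(x = .num6(g$x), y = .num6(g$y),
                  width = .num6(g$width), height = .num6(g$height)),
    polygon = c(points = paste(paste(.num6(g$vertices[, 1]),
                                     .num6(g$vertices[, 2]), sep = ","),
                               collapse = " "))))
  c(a, outline = ev$style$outline,
    fill = if (ev$style$fill) "yes" else "no",
    fillcolor = ev$style$fill_color)
}

#' Write a USF document as XML
#'
#' Serializes to UTF-8 XML with fixed 6-decimal numeric notation; the
#' shape-attribute dialect written here is the package's normative format
#' (the upstream draw-command grammar was never finalized). Writing is
#' idempotent: `write(read(write(doc)))` is byte-identical to `write(doc)`.
#'
#' @param doc A [usf_document()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_usf <- function(doc, path) {
  stopifnot(inherits(doc, "usf_document"))
  root <- xml2::xml_new_root("USFSubtitles", version = "1.1")
  meta <- xml2::xml_add_child(root, "metadata")
  xml2::xml_add_child(meta, "title", doc$metadata$title)
  au <- xml2::xml_add_child(meta, "author")
  xml2::xml_add_child(au, "name", doc$metadata$author)
  xml2::xml_add_child(meta, "comment",
                      paste0("tool=", doc$metadata$tool, " ",
                             doc$metadata$version))
  if (!is.null(doc$video))
    xml2::xml_add_child(root, "video",
                        width = as.character(doc$video$width),
                        height = as.character(doc$video$height),
                        fps = .num6(doc$video$fps))
  for (nm in names(doc$streams)) {
    st <- doc$streams[[nm]]
    sub <- xml2::xml_add_child(root, "subtitles", source = nm,
                               type = st$type)
    if (!is.null(st$sampling_rate) && !is.na(st$sampling_rate))
      xml2::xml_set_attr(sub, "sampling_rate", .num6(st$sampling_rate))
    for (ev in st$events) {
      node <- xml2::xml_add_child(sub, "subtitle",
                                  start = .num6(ev$t_start),
                                  stop = .num6(ev$t_end))
      sh <- xml2::xml_add_child(node, "shape")
      a <- .shape_node_attrs(ev)
      for (k in names(a)) xml2::xml_set_attr(sh, k, a[[k]])
      for (k in names(ev$extra))
        xml2::xml_add_child(node, "comment", key = k,
                            value = as.character(ev$extra[[k]]))
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' Read a USF document written by [write_usf()]
#'
#' @param path Path to a USF XML file.
#' @return A [usf_document()].
#' @export
read_usf <- function(path) {
  x <- xml2::read_xml(path)
  if (xml2::xml_name(x) != "USFSubtitles")
    stop("read_usf: not a USF document (root is <", xml2::xml_name(x), ">)")
  title <- xml2::xml_text(xml2::xml_find_first(x, "./metadata/title"))
  author <- xml2::xml_text(xml2::xml_find_first(x, "./metadata/author/name"))
  vn <- xml2::xml_find_first(x, "./video")
  video <- if (inherits(vn, "xml_missing")) NULL else
    video_meta(as.integer(xml2::xml_attr(vn, "width")),
               as.integer(xml2::xml_attr(vn, "height")),
               as.numeric(xml2::xml_attr(vn, "fps")))
  streams <- list()
  for (sub in xml2::xml_find_all(x, "./subtitles")) {
    src <- xml2::xml_attr(sub, "source")
    sr <- xml2::xml_attr(sub, "sampling_rate")
    events <- lapply(xml2::xml_find_all(sub, "./subtitle"), function(node) {
      t0 <- as.numeric(xml2::xml_attr(node, "start"))
      t1 <- as.numeric(xml2::xml_attr(node, "stop"))
      sh <- xml2::xml_find_first(node, "./shape")
      if (inherits(sh, "xml_missing"))
        stop("read_usf: <subtitle> without <shape>")
      kind <- xml2::xml_attr(sh, "type")
      num <- function(a) as.numeric(xml2::xml_attr(sh, a))
      geometry <- switch(kind,
        point = list(x = num("x"), y = num("y"), radius = num("radius")),
        rectangle = list(x = num("x"), y = num("y"),
                         width = num("width"), height = num("height")),
        polygon = {
          pts <- strsplit(strsplit(xml2::xml_attr(sh, "points"), " ",
                                   fixed = TRUE)[[1]], ",", fixed = TRUE)
          list(vertices = matrix(as.numeric(unlist(pts)), ncol = 2,
                                 byrow = TRUE))
        },
        stop("read_usf: unknown shape type '", kind, "'"))
      style <- shape_style(xml2::xml_attr(sh, "outline"),
                           identical(xml2::xml_attr(sh, "fill"), "yes"),
                           xml2::xml_attr(sh, "fillcolor"))
      cm <- xml2::xml_find_all(node, "./comment")
      extra <- as.list(xml2::xml_attr(cm, "value"))
      names(extra) <- xml2::xml_attr(cm, "key")
      shape_event(t0, t1, kind, geometry, style = style, source = src,
                  extra = extra)
    })
    streams[[src]] <- list(type = xml2::xml_attr(sub, "type"),
                           sampling_rate = if (is.na(sr)) NA_real_ else
                             as.numeric(sr),
                           events = events)
  }
  doc <- usf_document(streams, title = title, video = video)
  doc$metadata$author <- author
  doc
}

#' All shape events of a USF document as one list (stream order preserved).
#' @param doc A [usf_document()].
#' @return List of [shape_event()].
#' @export
usf_events <- function(doc) {
  stopifnot(inherits(doc, "usf_document"))
  do.call(c, c(lapply(unname(doc$streams), `[[`, "events"), list()))
}
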