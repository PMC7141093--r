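## Minimal EBML (Extensible Binary Meta Language) writer/reader — the
## binary grammar underlying Matroska containers. Only what the container
## module needs: elements with explicit sizes, unsigned integers, IEEE
## doubles, UTF-8 strings and binary payloads. Files handled here are small
## (test fixtures, subtitle/audio tracks), so whole-file raw vectors are fine.

# hex element id -> raw bytes as stored in the file (class/length bits kept)
.id_raw <- function(hex) {
  n <- nchar(hex)
  as.raw(strtoi(substring(hex, seq(1, n, 2), seq(2, n, 2)), 16L))
}

# EBML variable-size integer (the data-size encoding: marker bit + value)
ebml_vint <- function(value) {
  value <- as.numeric(value)
  if (value < 0) stop("ebml_vint: negative size")
  for (w in 1:8) {
    if (value < 2^(7 * w) - 1) {
      bytes <- integer(w)
      v <- value
      for (i in w:1) { bytes[i] <- v %% 256; v <- v %/% 256 }
      bytes[1] <- bytes[1] + 2^(8 - w)
      return(as.raw(bytes))
    }
  }
  stop("ebml_vint: value too large")
}

# unsigned integer payload, minimal big-endian width (>= 1 byte)
.uint_raw <- function(value) {
  value <- as.numeric(value)
  if (value < 0) stop("uint: negative")
  bytes <- integer(0)
  repeat {
    bytes <- c(value %% 256, bytes)
    value <- value %/% 256
    if (value == 0) break
  }
  as.raw(bytes)
}

.raw_uint <- function(r) {
  v <- 0
  for (b in as.integer(r)) v <- v * 256 + b
  v
}

# signed 16-bit big-endian (block relative timestamps)
.int16_raw <- function(v) {
  if (v < 0) v <- v + 65536
  as.raw(c(v %/% 256, v %% 256))
}

ebml_element <- function(id_hex, payload) {
  c(.id_raw(id_hex), ebml_vint(length(payload)), payload)
}
ebml_uint <- function(id_hex, value) ebml_element(id_hex, .uint_raw(value))
ebml_float <- function(id_hex, value)
  ebml_element(id_hex, writeBin(as.double(value), raw(), size = 8,
                                endian = "big"))
ebml_string <- function(id_hex, s)
  ebml_element(id_hex, charToRaw(enc2utf8(s)))

## ---- reading ---------------------------------------------------------------

# read an element id at offset; returns hex string and width
.read_id <- function(buf, pos) {
  b0 <- as.integer(buf[pos])
  w <- if (b0 >= 128L) 1L else if (b0 >= 64L) 2L else if (b0 >= 32L) 3L else
    if (b0 >= 16L) 4L else stop("EBML: invalid element id at byte ", pos)
  list(hex = toupper(paste(format(buf[pos:(pos + w - 1L)]), collapse = "")),
       width = w)
}

# read a data-size vint at offset; returns value and width
.read_size <- function(buf, pos) {
  b0 <- as.integer(buf[pos])
  w <- 1L
  mask <- 128L
  while (w <= 8L && b0 < mask) { w <- w + 1L; mask <- mask %/% 2L }
  if (w > 8L) stop("EBML: invalid size at byte ", pos)
  v <- b0 - mask
  if (w > 1L) for (b in as.integer(buf[(pos + 1L):(pos + w - 1L)]))
    v <- v * 256 + b
  list(value = v, width = w)
}

# shallow parse of the children of buf[pos..end]: list of (id, data_start,
# data_size) without descending
ebml_children <- function(buf, pos, end) {
  out <- list()
  while (pos <= end) {
    id <- .read_id(buf, pos)
    sz <- .read_size(buf, pos + id$width)
    data_start <- pos + id$width + sz$width
    out[[length(out) + 1L]] <- list(id = id$hex, start = data_start,
                                    size = sz$value)
    pos <- data_start + sz$value
  }
  out
}

ebml_payload <- function(buf, child) {
  if (child$size == 0) return(raw(0))
  buf[child$start:(child$start + child$size - 1L)]
}

## ---- Matroska ids used by this package -------------------------------------
.MKV <- list(
  EBML = "1A45DFA3", EBMLVersion = "4286", EBMLReadVersion = "42F7",
  EBMLMaxIDLength = "42F2", EBMLMaxSizeLength = "42F3", DocType = "4282",
  DocTypeVersion = "4287", DocTypeReadVersion = "4285",
  Segment = "18538067",
  Info = "1549A966", TimestampScale = "2AD7B1", Duration = "4489",
  MuxingApp = "4D80", WritingApp = "5741",
  Tracks = "1654AE6B", TrackEntry = "AE", TrackNumber = "D7",
  TrackUID = "73C5", TrackType = "83", FlagLacing = "9C", Name = "536E",
  Language = "22B59C", CodecID = "86", CodecPrivate = "63A2",
  DefaultDuration = "23E383",
  Video = "E0", PixelWidth = "B0", PixelHeight = "BA", ColourSpace = "2EB524",
  Audio = "E1", SamplingFrequency = "B5", Channels = "9F", BitDepth = "6264",
  Attachments = "1941A469", AttachedFile = "61A7", FileDescription = "467E",
  FileName = "466E", FileMimeType = "4660", FileData = "465C",
  FileUID = "46AE",
  Cluster = "1F43B675", Timestamp = "E7", SimpleBlock = "A3",
  BlockGroup = "A0", Block = "A1", BlockDuration = "9B")

.TRACK_TYPE <- c(video = 1, audio = 2, subtitle = 17)

#' Write a Matroska container
#'
#' The package's built-in muxing backend: writes an MKV file from in-memory
#' track and attachment descriptions. Timestamps use the default 1 ms tick
#' (TimestampScale 1e6 ns); blocks are grouped into one cluster per second.
#' Subtitle blocks carry an explicit BlockDuration (BlockGroup); video and
#' audio use SimpleBlocks.
#'
#' @param tracks List of track descriptions: each a list with `type`
#'   ("video", "audio" or "subtitle"), `name`, `codec_id`, optional
#'   `codec_private` (raw), optional `video = list(width, height)`,
#'   `audio = list(fs, channels, bits)`, `default_duration_ns`, and
#'   `blocks`: a list of `list(t_ms, duration_ms (or NULL), data (raw))`.
#' @param attachments List of `list(name, description, mime, data (raw))`.
#' @param path Output file path.
#' @param duration_ms Declared segment duration in ms (computed from blocks
#'   when `NULL`).
#' @return `path`, invisibly.
#' @export
mkv_write <- function(tracks, attachments = list(), path,
                      duration_ms = NULL) {
  M <- .MKV
  header <- ebml_element(M$EBML, c(
    ebml_uint(M$EBMLVersion, 1), ebml_uint(M$EBMLReadVersion, 1),
    ebml_uint(M$EBMLMaxIDLength, 4), ebml_uint(M$EBMLMaxSizeLength, 8),
    ebml_string(M$DocType, "matroska"),
    ebml_uint(M$DocTypeVersion, 4), ebml_uint(M$DocTypeReadVersion, 2)))

  all_t <- unlist(lapply(tracks, function(tr)
    vapply(tr$blocks, function(b) b$t_ms + (b$duration_ms %||% 0),
           numeric(1))))
  if (is.null(duration_ms))
    duration_ms <- if (length(all_t)) max(all_t) else 0
  info <- ebml_element(M$Info, c(
    ebml_uint(M$TimestampScale, 1e6),
    ebml_float(M$Duration, duration_ms),
    ebml_string(M$MuxingApp, paste(TOOL_NAME, TOOL_VERSION)),
    ebml_string(M$WritingApp, paste(TOOL_NAME, TOOL_VERSION))))

  entries <- raw(0)
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    e <- c(ebml_uint(M$TrackNumber, i),
           ebml_uint(M$TrackUID, i),
           ebml_uint(M$TrackType, .TRACK_TYPE[[tr$type]]),
           ebml_uint(M$FlagLacing, 0),
           ebml_string(M$Name, tr$name %||% paste0("track", i)),
           ebml_string(M$Language, "und"),
           ebml_string(M$CodecID, tr$codec_id))
    if (!is.null(tr$codec_private) && length(tr$codec_private))
      e <- c(e, ebml_element(M$CodecPrivate, tr$codec_private))
    if (!is.null(tr$default_duration_ns))
      e <- c(e, ebml_uint(M$DefaultDuration, tr$default_duration_ns))
    if (identical(tr$type, "video"))
      e <- c(e, ebml_element(M$Video, c(
        ebml_uint(M$PixelWidth, tr$video$width),
        ebml_uint(M$PixelHeight, tr$video$height),
        ebml_element(M$ColourSpace, charToRaw("RGB8")))))
    if (identical(tr$type, "audio"))
      e <- c(e, ebml_element(M$Audio, c(
        ebml_float(M$SamplingFrequency, tr$audio$fs),
        ebml_uint(M$Channels, tr$audio$channels),
        ebml_uint(M$BitDepth, tr$audio$bits))))
    entries <- c(entries, ebml_element(M$TrackEntry, e))
  }
  tracks_elem <- ebml_element(M$Tracks, entries)

  attach_elem <- raw(0)
  if (length(attachments)) {
    af <- raw(0)
    for (i in seq_along(attachments)) {
      a <- attachments[[i]]
      af <- c(af, ebml_element(M$AttachedFile, c(
        ebml_string(M$FileDescription, a$description %||% ""),
        ebml_string(M$FileName, a$name),
        ebml_string(M$FileMimeType, a$mime %||% "application/octet-stream"),
        ebml_element(M$FileData, a$data),
        ebml_uint(M$FileUID, i))))
    }
    attach_elem <- ebml_element(M$Attachments, af)
  }

  # collect all blocks, tagged with their track number, cluster by second
  blocks <- list()
  for (i in seq_along(tracks)) {
    for (b in tracks[[i]]$blocks) {
      b$track <- i
      blocks[[length(blocks) + 1L]] <- b
    }
  }
  clusters <- raw(0)
  if (length(blocks)) {
    t_ms <- vapply(blocks, `[[`, numeric(1), "t_ms")
    blocks <- blocks[order(t_ms)]
    t_ms <- sort(t_ms)
    grp <- floor(t_ms / 1000)
    for (g in unique(grp)) {
      base <- g * 1000
      body <- ebml_uint(M$Timestamp, base)
      for (b in blocks[grp == g]) {
        rel <- round(b$t_ms - base)
        hdr <- c(ebml_vint(b$track), .int16_raw(rel))
        if (is.null(b$duration_ms)) {
          body <- c(body, ebml_element(M$SimpleBlock,
                                       c(hdr, as.raw(0x80), b$data)))
        } else {
          body <- c(body, ebml_element(M$BlockGroup, c(
            ebml_element(M$Block, c(hdr, as.raw(0x00), b$data)),
            ebml_uint(M$BlockDuration, round(b$duration_ms)))))
        }
      }
      clusters <- c(clusters, ebml_element(M$Cluster, body))
    }
  }

  segment <- ebml_element(M$Segment,
                          c(info, tracks_elem, attach_elem, clusters))
  writeBin(c(header, segment), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a Matroska container written by [mkv_write()]
#'
#' Parses the EBML tree and returns tracks (with their blocks reassembled
#' and absolute timestamps restored), attachments (byte-exact) and segment
#' info. Raises an error if the file is not an EBML/Matroska document.
#'
#' @param path Path to an MKV file.
#' @return List with `info` (timestamp_scale, duration_ms, muxing_app),
#'   `tracks` (per track: number, type, name, codec_id, codec_private,
#'   video/audio parameters, `blocks` as in [mkv_write()]), and
#'   `attachments` (name, description, mime, data).
#' @export
mkv_read <- function(path) {
  if (!file.exists(path)) stop("mkv_read: no such file: ", path)
  buf <- readBin(path, "raw", file.size(path))
  M <- .MKV
  if (length(buf) < 8L) stop("mkv_read: not an EBML file (too short)")
  top <- tryCatch(ebml_children(buf, 1L, length(buf)),
                  error = function(e) stop("mkv_read: cannot parse '", path,
                                           "': ", conditionMessage(e)))
  ids <- vapply(top, `[[`, character(1), "id")
  if (!(M$EBML %in% ids) || !(M$Segment %in% ids))
    stop("mkv_read: '", path, "' is not a Matroska file")
  seg <- top[[which(ids == M$Segment)[1]]]
  seg_children <- ebml_children(buf, seg$start, seg$start + seg$size - 1L)

  info <- list(timestamp_scale = 1e6, duration_ms = NA_real_,
               muxing_app = "")
  tracks <- list()
  attachments <- list()
  u <- function(ch) .raw_uint(ebml_payload(buf, ch))
  s <- function(ch) rawToChar(ebml_payload(buf, ch))
  f <- function(ch) {
    p <- ebml_payload(buf, ch)
    readBin(p, "double", 1, size = length(p), endian = "big")
  }
  kids <- function(ch) if (ch$size == 0) list() else
    ebml_children(buf, ch$start, ch$start + ch$size - 1L)

  for (ch in seg_children) {
    if (ch$id == M$Info) {
      for (k in kids(ch)) {
        if (k$id == M$TimestampScale) info$timestamp_scale <- u(k)
        if (k$id == M$Duration) info$duration_ms <- f(k)
        if (k$id == M$MuxingApp) info$muxing_app <- s(k)
      }
    } else if (ch$id == M$Tracks) {
      for (te in kids(ch)) {
        if (te$id != M$TrackEntry) next
        tr <- list(number = NA, type = NA, name = "", codec_id = "",
                   codec_private = raw(0), blocks = list())
        for (k in kids(te)) {
          if (k$id == M$TrackNumber) tr$number <- u(k)
          if (k$id == M$TrackType)
            tr$type <- names(.TRACK_TYPE)[match(u(k), .TRACK_TYPE)]
          if (k$id == M$Name) tr$name <- s(k)
          if (k$id == M$CodecID) tr$codec_id <- s(k)
          if (k$id == M$CodecPrivate) tr$codec_private <- ebml_payload(buf, k)
          if (k$id == M$DefaultDuration) tr$default_duration_ns <- u(k)
          if (k$id == M$Video) {
            v <- list()
            for (vk in kids(k)) {
              if (vk$id == M$PixelWidth) v$width <- u(vk)
              if (vk$id == M$PixelHeight) v$height <- u(vk)
            }
            tr$video <- v
          }
          if (k$id == M$Audio) {
            a <- list()
            for (ak in kids(k)) {
              if (ak$id == M$SamplingFrequency) a$fs <- f(ak)
              if (ak$id == M$Channels) a$channels <- u(ak)
              if (ak$id == M$BitDepth) a$bits <- u(ak)
            }
            tr$audio <- a
          }
        }
        tracks[[length(tracks) + 1L]] <- tr
      }
    } else if (ch$id == M$Attachments) {
      for (ae in kids(ch)) {
        if (ae$id != M$AttachedFile) next
        a <- list(name = "", description = "", mime = "", data = raw(0))
        for (k in kids(ae)) {
          if (k$id == M$FileName) a$name <- s(k)
          if (k$id == M$FileDescription) a$description <- s(k)
          if (k$id == M$FileMimeType) a$mime <- s(k)
          if (k$id == M$FileData) a$data <- ebml_payload(buf, k)
        }
        attachments[[length(attachments) + 1L]] <- a
      }
    }
  }
  track_index <- vapply(tracks, function(t) as.integer(t$number), integer(1))

  # second pass: clusters
  for (ch in seg_children) {
    if (ch$id != M$Cluster) next
    base <- 0
    for (k in kids(ch)) {
      if (k$id == M$Timestamp) base <- u(k)
      add_block <- function(payload, duration_ms) {
        tn <- .read_size(payload, 1L)  # track number is a vint
        rel <- as.integer(payload[tn$width + 1L]) * 256 +
          as.integer(payload[tn$width + 2L])
        if (rel >= 32768L) rel <- rel - 65536L
        data <- payload[-seq_len(tn$width + 3L)]
        ti <- match(tn$value, track_index)
        if (is.na(ti)) return()
        tracks[[ti]]$blocks[[length(tracks[[ti]]$blocks) + 1L]] <<-
          list(t_ms = base + rel, duration_ms = duration_ms, data = data)
      }
      if (k$id == M$SimpleBlock) {
        add_block(ebml_payload(buf, k), NULL)
      } else if (k$id == M$BlockGroup) {
        payload <- NULL; dur <- NULL
        for (bk in kids(k)) {
          if (bk$id == M$Block) payload <- ebml_payload(buf, bk)
          if (bk$id == M$BlockDuration) dur <- u(bk)
        }
        if (!is.null(payload)) add_block(payload, dur)
      }
    }
  }
  list(info = info, tracks = tracks, attachments = attachments)
}
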