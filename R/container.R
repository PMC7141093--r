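## Muxing/demuxing: one MKV bundles the stimulus video, one ASS subtitle
## track per subject, sonification audio tracks, and the raw gaze/config
## files as attachments — the single-file exchange unit this package is
## about. Uses the package's built-in EBML backend (see ebml.R), so no
## system muxer is needed.

#' Declaration of what goes into one container
#'
#' @param video Path to the stimulus video (an MKV readable by [mkv_read()],
#'   e.g. from [gen_video()]), or `NULL` for a metadata-only container.
#' @param subtitles Named character vector or list: `name = path` of .ass
#'   files; names become track names (subject ids).
#' @param audio Named character vector or list: `name = path` of .wav files.
#' @param attachments Character vector of file paths attached byte-exact
#'   (raw gaze CSVs, run configs).
#' @param output Output MKV path.
#' @return An object of class `container_manifest`.
#' @export
container_manifest <- function(video = NULL, subtitles = character(),
                               audio = character(), attachments = character(),
                               output) {
  subtitles <- unlist(subtitles); audio <- unlist(audio)
  if (length(subtitles) && is.null(names(subtitles)))
    names(subtitles) <- tools::file_path_sans_ext(basename(subtitles))
  if (length(audio) && is.null(names(audio)))
    names(audio) <- tools::file_path_sans_ext(basename(audio))
  nm <- c(names(subtitles), names(audio))
  if (anyDuplicated(nm))
    stop("container_manifest: duplicate track names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  for (p in c(video, subtitles, audio, attachments))
    if (!file.exists(p)) stop("container_manifest: no such file: ", p)
  structure(list(video = video, subtitles = subtitles, audio = audio,
                 attachments = attachments, output = output),
            class = "container_manifest")
}

## ---- ASS <-> Matroska block conversion (S_TEXT/ASS convention) ------------
## CodecPrivate holds the script header up to the [Events] Format line;
## each block is "ReadOrder,Layer,Style,Name,MarginL,MarginR,MarginV,
## Effect,Text" with times carried by the block timestamp + duration.

.ass_codec_private <- function(doc) {
  lines <- write_ass(doc)
  cut <- which(startsWith(lines, "Format: Layer"))
  charToRaw(paste(lines[seq_len(cut[length(cut)])], collapse = "\n"))
}

.ass_to_blocks <- function(doc) {
  e <- doc$events
  lapply(seq_len(nrow(e)), function(i) list(
    t_ms = round(e$start[i] * 1000),
    duration_ms = round((e$end[i] - e$start[i]) * 1000),
    data = charToRaw(sprintf("%d,%d,%s,%s,0,0,0,,%s",
                             i - 1L, e$layer[i], e$style[i], e$name[i],
                             e$text[i]))))
}

.blocks_to_ass <- function(codec_private, blocks) {
  header <- rawToChar(codec_private)
  dialogue <- character(0)
  if (length(blocks)) {
    ord <- integer(length(blocks))
    lines <- character(length(blocks))
    for (i in seq_along(blocks)) {
      b <- blocks[[i]]
      f <- strsplit(rawToChar(b$data), ",", fixed = TRUE)[[1]]
      ord[i] <- as.integer(f[1])
      text <- paste(f[9:length(f)], collapse = ",")
      dur <- b$duration_ms %||% 10
      lines[i] <- sprintf("Dialogue: %s,%s,%s,%s,%s,0,0,0,,%s",
                          f[2], .ass_time(b$t_ms / 1000),
                          .ass_time((b$t_ms + dur) / 1000),
                          f[3], f[4], text)
    }
    dialogue <- lines[order(ord)]
  }
  c(strsplit(header, "\n", fixed = TRUE)[[1]], dialogue)
}

## ---- mux / demux / inspect -------------------------------------------------

#' Mux tracks and attachments into one MKV
#'
#' Reads the manifest's video (its video track is copied over), converts
#' each ASS file to a subtitle track, each WAV to a PCM audio track, and
#' embeds the attachments byte-exact, producing a single Matroska file.
#'
#' @param manifest A [container_manifest()].
#' @return The output path, invisibly, with a `log` attribute recording
#'   what was muxed.
#' @export
mux <- function(manifest) {
  stopifnot(inherits(manifest, "container_manifest"))
  tracks <- list()
  log <- character(0)
  if (!is.null(manifest$video)) {
    src <- mkv_read(manifest$video)
    vt <- NULL
    for (tr in src$tracks) if (identical(tr$type, "video")) { vt <- tr; break }
    if (is.null(vt)) stop("mux: ", manifest$video, " has no video track")
    tracks[[length(tracks) + 1L]] <-
      list(type = "video", name = vt$name, codec_id = vt$codec_id,
           codec_private = vt$codec_private, video = vt$video,
           default_duration_ns = vt$default_duration_ns, blocks = vt$blocks)
    log <- c(log, sprintf("video: %s (%d frames)", manifest$video,
                          length(vt$blocks)))
  }
  for (nm in names(manifest$subtitles)) {
    doc <- parse_ass(manifest$subtitles[[nm]])
    tracks[[length(tracks) + 1L]] <-
      list(type = "subtitle", name = nm, codec_id = "S_TEXT/ASS",
           codec_private = .ass_codec_private(doc),
           blocks = .ass_to_blocks(doc))
    log <- c(log, sprintf("subtitle '%s': %d events", nm, nrow(doc$events)))
  }
  for (nm in names(manifest$audio)) {
    wav <- read_wav(manifest$audio[[nm]])
    pcm <- as.integer(round(pmax(-1, pmin(1, wav$samples)) * 32767))
    chunk <- as.integer(wav$fs %/% 10)  # 100 ms blocks
    starts <- seq(1L, length(pcm), by = chunk)
    blocks <- lapply(starts, function(s0) {
      idx <- s0:min(s0 + chunk - 1L, length(pcm))
      list(t_ms = (s0 - 1L) / wav$fs * 1000, duration_ms = NULL,
           data = writeBin(pcm[idx], raw(), size = 2, endian = "little"))
    })
    tracks[[length(tracks) + 1L]] <-
      list(type = "audio", name = nm, codec_id = "A_PCM/INT/LIT",
           audio = list(fs = wav$fs, channels = 1, bits = 16),
           blocks = blocks)
    log <- c(log, sprintf("audio '%s': %.2f s", nm,
                          length(pcm) / wav$fs))
  }
  attachments <- lapply(manifest$attachments, function(p) list(
    name = basename(p), description = "raw data",
    mime = "application/octet-stream",
    data = readBin(p, "raw", file.size(p))))
  mkv_write(tracks, attachments, manifest$output)
  log <- c(log, sprintf("attachments: %d", length(attachments)),
           sprintf("wrote %s (%d bytes)", manifest$output,
                   file.size(manifest$output)))
  invisible(structure(manifest$output, log = log))
}

#' Extract every track and attachment from an MKV
#'
#' Subtitle tracks are reassembled into .ass files (accepted by
#' [parse_ass()] with the original event count), audio tracks become .wav
#' files, the video track is rewrapped as a single-track .mkv, and
#' attachments are written byte-identical to what was muxed.
#'
#' @param path Container path.
#' @param out_dir Output directory (created if needed).
#' @return Named list of extracted file paths by category: `video`,
#'   `subtitles`, `audio`, `attachments`.
#' @export
demux <- function(path, out_dir) {
  mkv <- mkv_read(path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list(video = character(0), subtitles = character(0),
              audio = character(0), attachments = character(0))
  safe <- function(s) gsub("[^A-Za-z0-9._-]", "_", s)
  for (tr in mkv$tracks) {
    if (identical(tr$type, "subtitle")) {
      p <- file.path(out_dir, paste0(safe(tr$name), ".ass"))
      writeLines(.blocks_to_ass(tr$codec_private, tr$blocks), p,
                 useBytes = TRUE)
      out$subtitles <- c(out$subtitles, p)
    } else if (identical(tr$type, "audio")) {
      p <- file.path(out_dir, paste0(safe(tr$name), ".wav"))
      pcm <- unlist(lapply(tr$blocks, function(b)
        readBin(b$data, "integer", length(b$data) %/% 2, size = 2,
                endian = "little")))
      write_wav(pcm / 32767, p, fs = tr$audio$fs)
      out$audio <- c(out$audio, p)
    } else if (identical(tr$type, "video")) {
      p <- file.path(out_dir, paste0(safe(tr$name), ".mkv"))
      mkv_write(list(list(type = "video", name = tr$name,
                          codec_id = tr$codec_id,
                          codec_private = tr$codec_private,
                          video = tr$video,
                          default_duration_ns = tr$default_duration_ns,
                          blocks = tr$blocks)), list(), p)
      out$video <- c(out$video, p)
    }
  }
  for (a in mkv$attachments) {
    p <- file.path(out_dir, safe(a$name))
    writeBin(a$data, p)
    out$attachments <- c(out$attachments, p)
  }
  out
}

#' Track inventory of a container
#'
#' @param path Container path.
#' @return List with `tracks`: data frame (number, type, codec, name,
#'   n_blocks, fps for video), and `attachments`: data frame (name, mime,
#'   size).
#' @export
inspect <- function(path) {
  mkv <- mkv_read(path)
  tracks <- do.call(rbind, lapply(mkv$tracks, function(tr) data.frame(
    number = tr$number, type = tr$type, codec = tr$codec_id,
    name = tr$name, n_blocks = length(tr$blocks),
    fps = if (identical(tr$type, "video") &&
              !is.null(tr$default_duration_ns))
      1e9 / tr$default_duration_ns else NA_real_,
    stringsAsFactors = FALSE)))
  if (is.null(tracks))
    tracks <- data.frame(number = integer(), type = character(),
                         codec = character(), name = character(),
                         n_blocks = integer(), fps = numeric(),
                         stringsAsFactors = FALSE)
  attachments <- do.call(rbind, lapply(mkv$attachments, function(a)
    data.frame(name = a$name, mime = a$mime, size = length(a$data),
               stringsAsFactors = FALSE)))
  if (is.null(attachments))
    attachments <- data.frame(name = character(), mime = character(),
                              size = integer(), stringsAsFactors = FALSE)
  list(tracks = tracks, attachments = attachments,
       duration_ms = mkv$info$duration_ms)
}
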