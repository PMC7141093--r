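## Auditory display of EEG metadata: the alpha-band (8-13 Hz) power envelope
## of a raw EEG trace drives either the pitch (frequency modulation) or the
## loudness (amplitude modulation) of a 220 Hz carrier -- the note "a" -- and
## the result is written as PCM WAV for muxing as an audio track.

#' Uniformly sampled single-channel EEG trace
#'
#' @param samples Numeric signal values (microvolts).
#' @param fs Sampling rate in Hz (> 0).
#' @return An object of class `eeg_trace`.
#' @export
eeg_trace <- function(samples, fs) {
  if (!is.numeric(fs) || fs <= 0) stop("eeg_trace: fs must be > 0")
  samples <- as.double(samples)
  if (length(samples) < 1L) stop("eeg_trace: need at least one sample")
  structure(list(samples = samples, fs = as.double(fs)), class = "eeg_trace")
}

#' @export
print.eeg_trace <- function(x, ...) {
  cat(sprintf("<eeg_trace> %d samples @ %g Hz (%.2f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Read / write an EEG trace as delimited text (one value per line)
#'
#' There is no canonical plain-text EEG format; the artifact uses one value
#' per line with the sampling rate carried separately (argument or config).
#'
#' @param path File path.
#' @param fs Sampling rate in Hz.
#' @param eeg An [eeg_trace()].
#' @return `read_eeg()` returns an [eeg_trace()]; `write_eeg()` the path.
#' @export
read_eeg <- function(path, fs) {
  eeg_trace(as.numeric(readLines(path, warn = FALSE)), fs)
}

#' @rdname read_eeg
#' @export
write_eeg <- function(eeg, path) {
  stopifnot(inherits(eeg, "eeg_trace"))
  writeLines(.num6(eeg$samples), path)
  invisible(path)
}

#' Power envelope driving the sonification
#'
#' @param values Nonnegative per-audio-sample power values (normalized to
#'   `[0, 1]` when produced by [alpha_power()] with `normalize = TRUE`).
#' @param audio_fs Audio sampling rate in Hz.
#' @param peak_power The pre-normalization envelope maximum (for reference).
#' @return An object of class `power_envelope`.
#' @export
power_envelope <- function(values, audio_fs = 44100, peak_power = NA_real_) {
  values <- as.double(values)
  if (any(values < 0)) stop("power_envelope: values must be >= 0")
  if (audio_fs <= 0) stop("power_envelope: audio_fs must be > 0")
  structure(list(values = values, audio_fs = as.double(audio_fs),
                 peak_power = peak_power), class = "power_envelope")
}

#' Alpha-band power envelope of an EEG trace
#'
#' Band-passes the trace to the alpha band with a zero-phase 4th-order
#' Butterworth design (order-2 forward-backward filtering), squares it,
#' smooths with a moving average of `window_s`, resamples the result to the
#' audio rate, and (by default) normalizes so the envelope maximum maps
#' to 1. An all-zero trace yields an all-zero envelope.
#'
#' @param eeg An [eeg_trace()]; its rate must exceed twice the band's upper
#'   edge (else the band is aliased and an error is raised).
#' @param band Pass band in Hz, default `c(8, 13)` (the alpha rhythm).
#' @param window_s Moving-average window in seconds (default 0.25).
#' @param audio_fs Output audio rate, default 44100 Hz.
#' @param normalize Divide by the envelope maximum? Default TRUE.
#' @return A [power_envelope()] spanning the trace duration at `audio_fs`;
#'   `peak_power` holds the pre-normalization maximum (approx. `A^2/2` for a
#'   pure in-band sinusoid of amplitude A).
#' @export
alpha_power <- function(eeg, band = c(8, 13), window_s = 0.25,
                        audio_fs = 44100, normalize = TRUE) {
  stopifnot(inherits(eeg, "eeg_trace"))
  if (eeg$fs <= 2 * band[2])
    stop(sprintf(
      "alpha_power: sampling rate %g Hz aliases the %g-%g Hz band (need fs > %g)",
      eeg$fs, band[1], band[2], 2 * band[2]))
  x <- eeg$samples - mean(eeg$samples)  # demean: avoids DC edge transients
  n <- length(x)
  bf <- signal::butter(2, band / (eeg$fs / 2), type = "pass")
  filtered <- if (n > 12L) signal::filtfilt(bf, x) else rep(0, n)
  p <- filtered^2
  # moving average with edge-truncated windows (no NA padding at the ends)
  w <- max(1L, round(window_s * eeg$fs))
  half <- w %/% 2L
  cs <- cumsum(c(0, p))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  smooth <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  # resample to the audio clock
  dur <- n / eeg$fs
  n_audio <- max(1L, round(dur * audio_fs))
  t_in <- (seq_len(n) - 1L) / eeg$fs
  t_out <- (seq_len(n_audio) - 1L) / audio_fs
  env <- if (n == 1L) rep(smooth, n_audio) else
    stats::approx(t_in, smooth, xout = t_out, rule = 2)$y
  env[env < 0] <- 0
  peak <- max(env)
  if (normalize && peak > 0) env <- env / peak
  power_envelope(env, audio_fs, peak_power = peak)
}

#' Frequency-modulation sonification
#'
#' Phase-integrated FM of a fixed-amplitude carrier: the instantaneous
#' frequency is `carrier + deviation * env[k]`, so stronger alpha power
#' sounds higher-pitched. With an all-zero envelope the output is the pure
#' unmodulated 220 Hz carrier.
#'
#' @param env A [power_envelope()] (values in `[0, 1]`).
#' @param carrier Carrier frequency in Hz, default 220 (note "a").
#' @param deviation Peak frequency deviation in Hz, default 110.
#' @return Numeric audio samples in `[-1, 1]` at `env$audio_fs`.
#' @export
fm_synthesize <- function(env, carrier = 220, deviation = 110) {
  stopifnot(inherits(env, "power_envelope"))
  fs <- env$audio_fs
  if (fs <= 2 * (carrier + deviation))
    stop(sprintf(
      "fm_synthesize: peak frequency %g Hz violates Nyquist at %g Hz",
      carrier + deviation, fs))
  if (length(env$values) == 0L) return(numeric(0))
  inst <- carrier + deviation * env$values
  sin(2 * pi * cumsum(inst) / fs)
}

#' Amplitude-modulation sonification
#'
#' The carrier's loudness follows the alpha power: `s[n] = env[n] *
#' sin(2 pi carrier n / fs)` — a louder tone means stronger power.
#'
#' @inheritParams fm_synthesize
#' @return Numeric audio samples at `env$audio_fs`.
#' @export
am_synthesize <- function(env, carrier = 220) {
  stopifnot(inherits(env, "power_envelope"))
  fs <- env$audio_fs
  if (fs <= 2 * carrier)
    stop(sprintf("am_synthesize: carrier %g Hz violates Nyquist at %g Hz",
                 carrier, fs))
  if (length(env$values) == 0L) return(numeric(0))
  n <- seq_along(env$values)
  env$values * sin(2 * pi * carrier * n / fs)
}

#' Write / read mono 16-bit PCM WAV
#'
#' Minimal RIFF/WAVE I/O for the sonified audio (mono, 16-bit little-endian
#' PCM). Samples outside `[-1, 1]` are clipped on write.
#'
#' @param samples Numeric samples in `[-1, 1]`.
#' @param path File path.
#' @param fs Sampling rate in Hz (default 44100).
#' @return `write_wav()` returns `path` invisibly; `read_wav()` a list with
#'   `samples` (in `[-1, 1]`) and `fs`.
#' @export
write_wav <- function(samples, path, fs = 44100) {
  s <- pmax(-1, pmin(1, as.double(samples)))
  pcm <- as.integer(round(s * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2), con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  if (n) writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("read_wav: not a RIFF file")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("read_wav: not a WAVE file")
  fs <- NA_integer_; bits <- NA_integer_; channels <- NA_integer_
  samples <- numeric(0)
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || !nzchar(id)) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      channels <- fmt[2]
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (id == "data") {
      if (bits != 16L || channels != 1L)
        stop("read_wav: only mono 16-bit PCM is supported")
      samples <- readBin(con, "integer", size %/% 2, size = 2,
                         endian = "little") / 32767
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.na(fs)) stop("read_wav: missing fmt chunk")
  list(samples = samples, fs = fs)
}

#' Dominant spectral peak of an audio signal
#'
#' FFT magnitude-spectrum maximum; frequency resolution is `fs / n`.
#'
#' @param samples Audio samples.
#' @param fs Sampling rate in Hz.
#' @return Peak frequency in Hz.
#' @export
dominant_frequency <- function(samples, fs) {
  n <- length(samples)
  if (n < 2L) stop("dominant_frequency: need >= 2 samples")
  mag <- Mod(stats::fft(samples))[seq_len(n %/% 2)]
  freq <- (seq_len(n %/% 2) - 1L) * fs / n
  freq[which.max(mag)]
}
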