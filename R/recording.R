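#' Construct a continuous recording
#'
#' A continuous recording is one channel of gain-corrected extracellular
#' voltage, stored as a numeric vector of samples in microvolts together with
#' its sample rate. All downstream windows are specified in milliseconds and
#' converted to samples at the recording's rate; the canonical processing rate
#' is 10 kHz.
#'
#' @param samples Numeric vector of voltage samples (uV). Must be finite.
#' @param rate Sample rate in samples/s (> 0).
#' @param t0 Recording start time in seconds (default 0).
#' @param meta Named list of free-form provenance (gain, source file, ...).
#' @return An object of class `oligo_recording` with fields `samples`, `rate`,
#'   `t0` and `meta`.
#' @export
recording <- function(samples, rate, t0 = 0, meta = list()) {
  samples <- as.numeric(samples)
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stop("`rate` must be a single positive number", call. = FALSE)
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("recording samples must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  structure(
    list(samples = samples, rate = as.numeric(rate), t0 = as.numeric(t0),
         meta = meta),
    class = "oligo_recording"
  )
}

#' @export
print.oligo_recording <- function(x, ...) {
  cat(sprintf("<oligo_recording> %d samples @ %g Hz (%.3f s), range [%.2f, %.2f] uV\n",
              length(x$samples), x$rate, duration(x),
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `oligo_recording`.
#' @return Length in seconds, `length(samples)/rate`.
#' @export
duration <- function(rec) length(rec$samples) / rec$rate

read_sidecar <- function(path) {
  if (!file.exists(path)) return(list())
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, ":", fixed = TRUE)
  out <- lapply(kv, function(p) trimws(paste(p[-1], collapse = ":")))
  names(out) <- vapply(kv, function(p) trimws(p[[1]]), character(1))
  for (k in c("rate", "gain", "t0")) {
    if (!is.null(out[[k]])) out[[k]] <- as.numeric(out[[k]])
  }
  out
}

write_sidecar <- function(path, meta) {
  keys <- names(meta)
  writeLines(paste0(keys, ": ", vapply(meta, format, character(1))), path)
}

#' Read a continuous recording from disk
#'
#' Supported containers: `raw-f32` (headerless little-endian float32, one
#' channel, with a `<path>.meta` key-value sidecar), `wav` (RIFF/WAVE, PCM16 or
#' IEEE float32, mono), and `tsv` (one voltage value per line, sidecar as for
#' raw). Samples are divided by the amplifier `gain` so the returned trace is
#' expressed in microvolts.
#'
#' @param path File to read.
#' @param format One of `"raw-f32"`, `"wav"`, `"tsv"`. Guessed from the file
#'   extension when missing.
#' @param meta Named list overriding/supplying sidecar entries (`rate`, `gain`,
#'   `t0`). `rate` is required for raw/tsv; `gain` defaults to 1.
#' @return An [recording()] object; `meta` records the source path and gain.
#' @export
read_recording <- function(path, format = NULL, meta = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     wav = "wav", tsv = "tsv", txt = "tsv", f32 = "raw-f32",
                     raw = "raw-f32",
                     stop("cannot guess format for: ", path, call. = FALSE))
  }
  format <- match.arg(format, c("raw-f32", "wav", "tsv"))
  side <- read_sidecar(paste0(path, ".meta"))
  side[names(meta)] <- meta
  gain <- if (is.null(side$gain)) 1 else side$gain
  t0 <- if (is.null(side$t0)) 0 else side$t0

  if (format == "wav") {
    wav <- read_wav(path)
    samples <- wav$samples / gain
    rate <- if (is.null(side$rate)) wav$rate else side$rate
  } else {
    if (is.null(side$rate)) {
      stop("sidecar or `meta` must supply `rate` for format ", format,
           call. = FALSE)
    }
    rate <- side$rate
    samples <- if (format == "raw-f32") {
      n <- file.info(path)$size / 4
      readBin(path, what = "numeric", n = n, size = 4, endian = "little")
    } else {
      as.numeric(readLines(path, warn = FALSE))
    }
    samples <- samples / gain
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("non-finite samples in ", path, call. = FALSE)
  }
  recording(samples, rate, t0 = t0,
            meta = list(source = path, gain = gain, format = format))
}

#' Write a continuous recording to disk
#'
#' Inverse of [read_recording()]. For `raw-f32` and `tsv` a `<path>.meta`
#' sidecar carrying `rate`, `gain` and `t0` is written next to the data file.
#' WAV output uses IEEE float32, which round-trips exactly.
#'
#' @inheritParams read_recording
#' @param rec An `oligo_recording`.
#' @param gain Gain to store; samples are multiplied back by `gain` on disk so
#'   that `read_recording()` recovers the original microvolt trace.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("raw-f32", "wav", "tsv"),
                            gain = 1) {
  format <- match.arg(format)
  raw_vals <- rec$samples * gain
  if (format == "wav") {
    write_wav(raw_vals, rec$rate, path)
  } else {
    if (format == "raw-f32") {
      writeBin(as.numeric(raw_vals), path, size = 4, endian = "little")
    } else {
      writeLines(format(raw_vals, digits = 17, scientific = FALSE, trim = TRUE),
                 path)
    }
    write_sidecar(paste0(path, ".meta"),
                  list(rate = rec$rate, gain = gain, t0 = rec$t0))
  }
  invisible(path)
}

# Minimal RIFF/WAVE codec, mono, PCM16 or IEEE float32. The installed R stack
# has no WAV reader, and the format is simple enough to parse directly.
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1, 4, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)
  fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || !nzchar(id)) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        code = readBin(body[1:2], "integer", 1, 2, endian = "little"),
        channels = readBin(body[3:4], "integer", 1, 2, endian = "little"),
        rate = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(body[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("WAV data chunk before fmt chunk", call. = FALSE)
      if (fmt$channels != 1) stop("only mono WAV supported", call. = FALSE)
      if (fmt$code == 1 && fmt$bits == 16) {
        samples <- readBin(con, "integer", size / 2, 2, signed = TRUE,
                           endian = "little") / 32768
      } else if (fmt$code == 3 && fmt$bits == 32) {
        samples <- readBin(con, "numeric", size / 4, 4, endian = "little")
      } else {
        stop("unsupported WAV encoding (code ", fmt$code, ", ", fmt$bits,
             " bit)", call. = FALSE)
      }
    } else {
      readBin(con, "raw", size + size %% 2)  # skip, chunks are word-aligned
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk in WAV file", call. = FALSE)
  list(samples = samples, rate = fmt$rate)
}

write_wav <- function(samples, rate, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  data_bytes <- 4L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")     # IEEE float
  writeBin(1L, con, size = 2, endian = "little")     # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(as.numeric(samples), con, size = 4, endian = "little")
  invisible(path)
}

#' Resample a recording to a new rate
#'
#' Fourier-domain (exactly band-limited) resampling: the spectrum is
#' truncated (downsampling) or zero-padded (upsampling) and inverted at the
#' new length, which is both linear and distortion-free for in-band content.
#' The acquisition convention oversamples at 40 kHz to avoid sampling jitter
#' in peak alignment and then decimates to the 10 kHz processing rate; any
#' rate ratio is supported. As with any Fourier method the trace is treated
#' as periodic, so a few samples at the extreme edges can show wrap-around
#' ripple for strongly non-periodic traces.
#'
#' @param rec An `oligo_recording`.
#' @param target_rate New rate in samples/s (> 0).
#' @return A resampled `oligo_recording`; duration is preserved to within one
#'   sample period.
#' @export
resample_recording <- function(rec, target_rate) {
  if (!is.numeric(target_rate) || length(target_rate) != 1 || target_rate <= 0) {
    stop("`target_rate` must be a single positive number", call. = FALSE)
  }
  if (target_rate == rec$rate) return(rec)
  m <- round(length(rec$samples) * target_rate / rec$rate)
  out <- fft_resample(rec$samples, m)
  recording(out, target_rate, t0 = rec$t0,
            meta = c(rec$meta, list(resampled_from = rec$rate)))
}

# Resample a real vector to length m by spectrum truncation/zero-padding,
# combining (down) or splitting (up) the Nyquist bin to keep the spectrum
# Hermitian.
fft_resample <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  X <- fft(x)
  Y <- complex(real = rep(0, m), imaginary = rep(0, m))
  if (m < n) {
    h <- m %/% 2
    Y[1:(h + 1)] <- X[1:(h + 1)]
    if (h > 1) Y[(m - h + 2):m] <- X[(n - h + 2):n]
    if (m %% 2 == 0) Y[h + 1] <- X[h + 1] + X[n - h + 1]
  } else {
    h <- n %/% 2
    Y[1:(h + 1)] <- X[1:(h + 1)]
    if (h > 1) Y[(m - h + 2):m] <- X[(n - h + 2):n]
    if (n %% 2 == 0) {
      Y[h + 1] <- X[h + 1] / 2
      Y[m - h + 1] <- Conj(X[h + 1]) / 2
    }
  }
  Re(fft(Y, inverse = TRUE)) / n
}

#' Write / read spike event tables
#'
#' Events are tibbles with a `timestamp` column (seconds from recording start)
#' plus arbitrary further columns (`label`, `waveform_id`, ...). The on-disk
#' form is tab-separated text; timestamps are written with 0.1-ms resolution
#' (four decimals) and round-trip losslessly at that resolution.
#'
#' @param events A data frame with at least a numeric `timestamp` column.
#' @param path File to write/read.
#' @return `write_events()` returns `path` invisibly; `read_events()` returns a
#'   tibble. Malformed rows abort with their line numbers.
#' @export
write_events <- function(events, path) {
  events <- tibble::as_tibble(events)
  if (!"timestamp" %in% names(events)) {
    stop("`events` must have a `timestamp` column", call. = FALSE)
  }
  out <- events
  out$timestamp <- sprintf("%.4f", events$timestamp)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ev <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(ev)
  if (nrow(probs) > 0) {
    stop("malformed event rows at line(s): ",
         paste(unique(probs$row), collapse = ", "), call. = FALSE)
  }
  if (nrow(ev) > 0 && "timestamp" %in% names(ev)) {
    if (anyNA(ev$timestamp)) {
      stop("non-numeric timestamps at line(s): ",
           paste(which(is.na(ev$timestamp)) + 1L, collapse = ", "),
           call. = FALSE)
    }
  }
  ev
}
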