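# Minimal RIFF/WAVE mono reader and writer (PCM 16-bit and IEEE float32).
# Kept deliberately small: the pipeline needs only mono fixed-rate files.

#' Write a recording to a WAV file
#'
#' Writes mono RIFF/WAVE. 16-bit PCM clamps samples to \[-1, 1\] and quantizes
#' to 32767 steps; float32 stores the samples losslessly.
#'
#' @param rec An [recording()] object.
#' @param path Output file path.
#' @param format `"pcm16"` (default) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, format = c("pcm16", "float32")) {
  stopifnot(is_recording(rec))
  format <- match.arg(format)
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(rec$samples)
  bits <- if (format == "pcm16") 16L else 32L
  block <- bits %/% 8L
  data_size <- n * block
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(if (format == "pcm16") 1L else 3L, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(rec$rate), con, size = 4, endian = "little")
  writeBin(as.integer(rec$rate * block), con, size = 4, endian = "little")
  writeBin(as.integer(block), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "pcm16") {
    q <- as.integer(round(pmax(pmin(rec$samples, 1), -1) * 32767))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(rec$samples, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' Parses RIFF/WAVE chunks; accepts mono 16-bit PCM or 32-bit IEEE float.
#' Stereo or other encodings are rejected rather than silently downmixed.
#'
#' @param path WAV file path.
#' @param source_label Label stored on the returned recording; defaults to the
#'   file name.
#' @return An [recording()] object.
#' @export
read_wav <- function(path, source_label = basename(path)) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  readBin(con, "integer", size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    abort(sprintf("'%s' is not a RIFF/WAVE file.", path), class = "stemsound_data_error")
  }
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        audio_format = readBin(con, "integer", size = 2, endian = "little", signed = FALSE),
        channels = readBin(con, "integer", size = 2, endian = "little", signed = FALSE),
        rate = readBin(con, "integer", size = 4, endian = "little"),
        byte_rate = readBin(con, "integer", size = 4, endian = "little"),
        block_align = readBin(con, "integer", size = 2, endian = "little", signed = FALSE),
        bits = readBin(con, "integer", size = 2, endian = "little", signed = FALSE)
      )
      extra <- size - 16L
      if (extra > 0) readBin(con, "raw", n = extra)
    } else if (id == "data") {
      if (is.null(fmt)) {
        abort(sprintf("'%s': data chunk precedes fmt chunk.", path),
              class = "stemsound_data_error")
      }
      if (fmt$channels != 1L) {
        abort(sprintf("'%s' has %d channels; only mono is supported.", path, fmt$channels),
              class = "stemsound_data_error")
      }
      if (fmt$audio_format == 1L && fmt$bits == 16L) {
        raw <- readBin(con, "integer", n = size %/% 2L, size = 2, endian = "little")
        samples <- raw / 32767
      } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
        samples <- readBin(con, "double", n = size %/% 4L, size = 4, endian = "little")
      } else {
        abort(sprintf("'%s': unsupported encoding (format %d, %d bit).",
                      path, fmt$audio_format, fmt$bits),
              class = "stemsound_data_error")
      }
      break
    } else {
      readBin(con, "raw", n = size + (size %% 2L))   # skip unknown chunk (word aligned)
    }
  }
  if (is.null(samples)) {
    abort(sprintf("'%s' contains no data chunk.", path), class = "stemsound_data_error")
  }
  recording(samples, fmt$rate, source_label)
}
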