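# Minimal single-channel PCM WAV reader/writer.
#
# The pipeline only needs mono 16- or 24-bit PCM with random access to sample
# ranges (for chunked streaming), plus a JSON sidecar carrying the hydrophone
# calibration, since WAV cannot express physical pressure units.

wav_header_size <- 44L

#' Inspect a PCM WAV file
#'
#' Parses the RIFF header and returns the format fields needed for streaming.
#'
#' @param path path to a WAV file.
#' @return list with `fs`, `bits`, `n_samples`, `n_channels`, `data_offset`
#'   (byte offset of the first sample).
#' @export
wav_info <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stopf("'%s' is not a RIFF/WAVE file", path)
  invisible(readBin(con, "integer", 1, size = 4))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stopf("'%s' is not a RIFF/WAVE file", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4) stopf("no data chunk in '%s'", path)
    sz <- readBin(con, "integer", 1, size = 4)
    if (identical(id, "fmt ")) {
      audio_format <- readBin(con, "integer", 1, size = 2, signed = FALSE)
      n_channels <- readBin(con, "integer", 1, size = 2, signed = FALSE)
      fs <- readBin(con, "integer", 1, size = 4)
      invisible(readBin(con, "integer", 1, size = 4)) # byte rate
      invisible(readBin(con, "integer", 1, size = 2)) # block align
      bits <- readBin(con, "integer", 1, size = 2, signed = FALSE)
      if (audio_format != 1L) stopf("only PCM WAV is supported (format %d)", audio_format)
      if (n_channels != 1L) stopf("only mono WAV is supported (%d channels)", n_channels)
      if (!bits %in% c(16L, 24L)) stopf("only 16/24-bit PCM supported (%d bits)", bits)
      fmt <- list(fs = fs, bits = bits, n_channels = n_channels)
      if (sz > 16L) invisible(readBin(con, "raw", sz - 16L))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stopf("data chunk before fmt chunk in '%s'", path)
      offset <- seek(con)
      return(c(fmt, list(
        n_samples = sz %/% (fmt$bits %/% 8L),
        data_offset = offset
      )))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
  }
}

#' Read a sample range from a PCM WAV file
#'
#' @param path path to a WAV file.
#' @param from,to 1-based inclusive sample indices; defaults cover the file.
#' @return integer vector of raw counts.
#' @export
read_wav <- function(path, from = 1L, to = NULL) {
  info <- wav_info(path)
  if (is.null(to)) to <- info$n_samples
  from <- max(1L, as.integer(from))
  to <- min(info$n_samples, as.integer(to))
  if (to < from) return(integer(0))
  n <- to - from + 1L
  bytes <- info$bits %/% 8L
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, info$data_offset + (from - 1L) * bytes)
  if (info$bits == 16L) {
    readBin(con, "integer", n, size = 2, signed = TRUE, endian = "little")
  } else {
    raw3 <- readBin(con, "raw", n * 3L)
    b <- matrix(as.integer(raw3), nrow = 3L)
    v <- b[1, ] + b[2, ] * 256L + b[3, ] * 65536L
    ifelse(v >= 8388608L, v - 16777216L, v)
  }
}

#' Streaming WAV writer
#'
#' Opens a mono PCM WAV file for sequential writing. The total sample count
#' must be known up front so the RIFF sizes can be written immediately;
#' `$write()` appends integer counts, `$close()` verifies the promised length.
#'
#' @param path output path.
#' @param fs sample rate, Hz.
#' @param n_samples total samples that will be written.
#' @param bits 16 or 24.
#' @return list with functions `write(counts)` and `close()`.
#' @export
wav_writer <- function(path, fs, n_samples, bits = 16L) {
  bits <- as.integer(bits)
  if (!bits %in% c(16L, 24L)) stopf("bits must be 16 or 24")
  bytes <- bits %/% 8L
  data_size <- as.numeric(n_samples) * bytes
  con <- file(path, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4)
  writeBin(1L, con, size = 2)          # PCM
  writeBin(1L, con, size = 2)          # mono
  writeBin(as.integer(fs), con, size = 4)
  writeBin(as.integer(fs * bytes), con, size = 4)
  writeBin(as.integer(bytes), con, size = 2)
  writeBin(bits, con, size = 2)
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4)
  written <- 0
  limit <- 2^(bits - 1) - 1
  list(
    write = function(counts) {
      counts <- as.integer(round(counts))
      if (any(abs(counts) > limit, na.rm = TRUE)) {
        close(con)
        stopf(paste0(
          "sample counts exceed %d-bit full scale; the scene is clipping. ",
          "Lower the source levels or raise the configured full-scale level."
        ), bits)
      }
      if (bits == 16L) {
        writeBin(counts, con, size = 2, endian = "little")
      } else {
        v <- ifelse(counts < 0L, counts + 16777216L, counts)
        b <- rbind(v %% 256L, (v %/% 256L) %% 256L, (v %/% 65536L) %% 256L)
        writeBin(as.raw(b), con)
      }
      written <<- written + length(counts)
      invisible(length(counts))
    },
    close = function() {
      close(con)
      if (written != n_samples) {
        stopf("wav_writer: wrote %d samples, promised %d", written, n_samples)
      }
      invisible(path)
    }
  )
}

#' Write a short mono WAV in one call
#'
#' Convenience wrapper over [wav_writer()] for in-memory signals.
#'
#' @param counts integer sample counts.
#' @inheritParams wav_writer
#' @export
write_wav <- function(counts, path, fs, bits = 16L) {
  w <- wav_writer(path, fs, length(counts), bits)
  w$write(counts)
  w$close()
}

#' Hydrophone calibration sidecars
#'
#' A flat system sensitivity in dB re counts/uPa links WAV integer counts to
#' pressure: `counts = pressure_uPa * 10^(sensitivity/20)`. The sidecar JSON
#' stores the sensitivity and sample rate next to the audio so calibration is
#' invertible.
#'
#' @param path path of the JSON sidecar.
#' @param fs sample rate, Hz.
#' @param sensitivity_db flat sensitivity, dB re counts/uPa.
#' @return `read_calibration()` returns a list with `fs`, `sensitivity_db`
#'   and the linear factor `counts_per_upa`.
#' @export
write_calibration <- function(path, fs, sensitivity_db) {
  jsonlite::write_json(
    list(fs = fs, sensitivity_db_re_counts_per_upa = sensitivity_db),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  j <- jsonlite::read_json(path)
  if (is.null(j$sensitivity_db_re_counts_per_upa)) {
    stopf("'%s' is not a calibration sidecar (missing sensitivity)", path)
  }
  list(
    fs = as.numeric(j$fs),
    sensitivity_db = as.numeric(j$sensitivity_db_re_counts_per_upa),
    counts_per_upa = 10^(as.numeric(j$sensitivity_db_re_counts_per_upa) / 20)
  )
}

#' Default calibration sidecar path for a WAV file
#' @param wav_path path to a WAV file.
#' @return the conventional `<name>_calibration.json` path next to it.
#' @export
calibration_path <- function(wav_path) {
  paste0(sub("\\.wav$", "", wav_path, ignore.case = TRUE), "_calibration.json")
}
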