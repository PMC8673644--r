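# Chunked, calibrated audio streaming and tabular product I/O.
#
# Chunks tile the file with half-open cores [start, start + chunk) and carry
# `overlap` seconds of extra context on each side, so events spanning a core
# boundary are always fully visible to whichever chunk owns their peak.

#' Stream a calibrated WAV file in chunks
#'
#' Returns a pull-based reader. Each call to `$read()` yields an audio chunk
#' whose *core* interval tiles the file without gaps or overlap, plus
#' `overlap_seconds` of context on either side (truncated at the file edges).
#' Samples are converted to pressure in uPa using the calibration sidecar.
#'
#' @param path WAV file path.
#' @param calibration calibration list from [read_calibration()], or a path
#'   to the sidecar JSON; defaults to `<path>_calibration.json`.
#' @param chunk_seconds core chunk length, s.
#' @param overlap_seconds context on each side of the core, s; must be
#'   shorter than `chunk_seconds` and at least the longest event a consumer
#'   must see in one piece.
#' @return list with `read()` (returns an `audio_chunk` or NULL at EOF),
#'   `reset()`, `n_chunks`, `info`.
#' @export
stream_audio <- function(path, calibration = NULL, chunk_seconds = 5,
                         overlap_seconds = 0.05) {
  info <- wav_info(path)
  if (is.null(calibration)) calibration <- calibration_path(path)
  if (is.character(calibration)) {
    if (!file.exists(calibration)) {
      stopf("no calibration sidecar for '%s'; counts cannot be mapped to uPa", path)
    }
    calibration <- read_calibration(calibration)
  }
  if (chunk_seconds <= overlap_seconds) {
    stopf("chunk_seconds must exceed overlap_seconds")
  }
  fs <- info$fs
  core_n <- round(chunk_seconds * fs)
  pad_n <- round(overlap_seconds * fs)
  n_chunks <- ceiling(info$n_samples / core_n)
  scale <- 1 / calibration$counts_per_upa
  k <- 0L
  list(
    read = function() {
      if (k >= n_chunks) return(NULL)
      k <<- k + 1L
      core_from <- (k - 1L) * core_n + 1
      core_to <- min(k * core_n, info$n_samples)
      from <- max(1, core_from - pad_n)
      to <- min(info$n_samples, core_to + pad_n)
      counts <- read_wav(path, from, to)
      structure(list(
        samples = counts * scale,
        start_time = (from - 1) / fs,
        core_start = (core_from - 1) / fs,
        core_end = core_to / fs,
        core_offset = core_from - from,   # samples of left context
        fs = fs
      ), class = "audio_chunk")
    },
    reset = function() { k <<- 0L; invisible(NULL) },
    n_chunks = n_chunks,
    info = info,
    calibration = calibration
  )
}

#' Read an entire calibrated WAV into memory
#'
#' @inheritParams stream_audio
#' @return list with `samples` (uPa) and `fs`.
#' @export
read_audio <- function(path, calibration = NULL) {
  info <- wav_info(path)
  if (is.null(calibration)) calibration <- calibration_path(path)
  if (is.character(calibration)) calibration <- read_calibration(calibration)
  list(samples = read_wav(path) / calibration$counts_per_upa, fs = info$fs)
}

# ---------------------------------------------------------------------------
# Detection tables: CSV metadata + float32 binary feature sidecar.

detection_meta_cols <- c("id", "file", "time_s", "start_s", "end_s",
                         "rl_pp_db", "duration_us")

#' Construct a detection set
#'
#' Bundles detection metadata with the fixed-length per-detection feature
#' arrays (waveform snippet, envelope, spectrum).
#'
#' @param meta data.frame with columns `id`, `file`, `time_s`, `start_s`,
#'   `end_s`, `rl_pp_db`, `duration_us`.
#' @param snippet,envelope matrices, one row per detection, uPa.
#' @param spectrum matrix, one row per detection, dB re 1 uPa^2/Hz on the
#'   detector's frequency grid.
#' @param fs sample rate, Hz.
#' @param spectrum_freqs frequency of each spectrum column, Hz.
#' @export
detection_set <- function(meta, snippet, envelope, spectrum, fs,
                          spectrum_freqs) {
  missing_cols <- setdiff(detection_meta_cols, names(meta))
  if (length(missing_cols)) {
    stopf("detection table is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(meta$id)) stopf("detection ids must be unique")
  structure(list(
    meta = as.data.frame(meta), snippet = snippet, envelope = envelope,
    spectrum = spectrum, fs = fs, spectrum_freqs = spectrum_freqs
  ), class = "detection_set")
}

#' @export
print.detection_set <- function(x, ...) {
  cat(sprintf("<detection_set> %d detections, fs %g Hz\n", nrow(x$meta), x$fs))
  if (nrow(x$meta)) {
    cat(sprintf("  time span %.2f-%.2f s, RL %.1f-%.1f dB pp re 1 uPa\n",
                min(x$meta$time_s), max(x$meta$time_s),
                min(x$meta$rl_pp_db), max(x$meta$rl_pp_db)))
    cat(sprintf("  snippet %d samples, spectrum %d bins (%g-%g Hz)\n",
                ncol(x$snippet), ncol(x$spectrum),
                min(x$spectrum_freqs), max(x$spectrum_freqs)))
  }
  invisible(x)
}

#' Write / read a detection table
#'
#' Metadata goes to `<base>.csv`; the snippet, envelope and spectrum arrays
#' go to `<base>_features.bin` as row-major float32 with a small JSON header
#' (`<base>_features.json`) recording dimensions, sample rate and the
#' spectrum frequency grid. Feature values survive a round trip bit-exactly
#' at float32 precision.
#'
#' @param det a [detection_set()].
#' @param base path prefix (no extension).
#' @return `read_detections()` returns a [detection_set()].
#' @export
write_detections <- function(det, base) {
  dir.create(dirname(base), showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(det$meta, paste0(base, ".csv"))
  n <- nrow(det$meta)
  hdr <- list(
    n = n, snippet_len = ncol(det$snippet), envelope_len = ncol(det$envelope),
    spectrum_len = ncol(det$spectrum), fs = det$fs,
    spectrum_freqs = det$spectrum_freqs, storage = "float32-row-major"
  )
  jsonlite::write_json(hdr, paste0(base, "_features.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(paste0(base, "_features.bin"), "wb")
  on.exit(close(con))
  # one detection's features are contiguous: snippet | envelope | spectrum
  block <- cbind(det$snippet, det$envelope, det$spectrum)
  writeBin(as.numeric(t(block)), con, size = 4)
  invisible(base)
}

#' @rdname write_detections
#' @export
read_detections <- function(base) {
  meta <- as.data.frame(data.table::fread(paste0(base, ".csv")))
  if (!nrow(meta)) {
    meta <- meta[, intersect(detection_meta_cols, names(meta)), drop = FALSE]
  }
  missing_cols <- setdiff(detection_meta_cols, names(meta))
  if (length(missing_cols)) {
    stopf("'%s.csv' is missing column(s): %s", base,
          paste(missing_cols, collapse = ", "))
  }
  hdr <- jsonlite::read_json(paste0(base, "_features.json"),
                             simplifyVector = TRUE)
  n <- hdr$n
  row_len <- hdr$snippet_len + hdr$envelope_len + hdr$spectrum_len
  con <- file(paste0(base, "_features.bin"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n * row_len, size = 4)
  block <- matrix(vals, nrow = max(n, 0L), ncol = row_len, byrow = TRUE)
  s1 <- seq_len(hdr$snippet_len)
  s2 <- hdr$snippet_len + seq_len(hdr$envelope_len)
  s3 <- hdr$snippet_len + hdr$envelope_len + seq_len(hdr$spectrum_len)
  detection_set(meta,
                snippet = block[, s1, drop = FALSE],
                envelope = block[, s2, drop = FALSE],
                spectrum = block[, s3, drop = FALSE],
                fs = hdr$fs, spectrum_freqs = hdr$spectrum_freqs)
}
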