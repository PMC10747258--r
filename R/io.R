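#' Read and write Doppler ultrasound recordings
#'
#' `write_wav()`/`read_wav()` handle mono 16-bit PCM RIFF files; amplitudes
#' are unit-normalized to \[-1, 1\] before quantization, so absolute scale is
#' not round-tripped (the pipeline is scale-invariant). `write_recording_csv()`
#' and `read_recording_csv()` use a one-amplitude-per-row CSV whose header
#' comment line carries the sampling rate. Beat annotations use a one-column
#' CSV `beat_time_s`.
#'
#' @param rec A [dus_recording()].
#' @param path File path.
#' @name dus_io
NULL

#' @rdname dus_io
#' @export
write_wav <- function(rec, path) {
  fs <- as.integer(round(sampling_rate(rec)))
  x <- rec$amplitude
  peak <- max(abs(x), 1e-12)
  pcm <- as.integer(round(x / peak * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname dus_io
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) abort("not a RIFF/WAVE file.")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) abort("not a RIFF/WAVE file.")
  fs <- NULL
  bits <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) abort("no 'data' chunk found.")
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) abort("only mono PCM WAV is supported.")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (bits != 16L) abort("only 16-bit PCM WAV is supported.")
      seek(con, size - 16L, origin = "current")
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer", size / 2L, size = 2,
                     signed = TRUE, endian = "little")
      break
    } else {
      seek(con, size, origin = "current")
    }
  }
  dus_recording(pcm / 32767, fs = fs)
}

#' @rdname dus_io
#' @export
write_recording_csv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz=%g", sampling_rate(rec)), con)
  writeLines("amplitude", con)
  writeLines(format(rec$amplitude, trim = TRUE, digits = 15), con)
  invisible(path)
}

#' @rdname dus_io
#' @param fs Sampling rate in Hz; if `NULL`, taken from the `# fs_hz=` header
#'   comment.
#' @export
read_recording_csv <- function(path, fs = NULL) {
  first <- readLines(path, n = 1L)
  if (is.null(fs)) {
    m <- regmatches(first, regexec("fs_hz=([0-9.eE+-]+)", first))[[1]]
    if (length(m) < 2L) abort("no `fs` given and no '# fs_hz=' header found.")
    fs <- as.numeric(m[2])
  }
  df <- utils::read.csv(path, comment.char = "#")
  dus_recording(df[[1]], fs = fs)
}

#' Read and write beat-time annotations
#'
#' @param schedule A [make_beat_schedule()] result.
#' @param path File path of a CSV with column `beat_time_s`.
#' @name annotation_io
#' @export
write_annotations_csv <- function(schedule, path) {
  utils::write.csv(data.frame(beat_time_s = schedule$beat_time), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname annotation_io
#' @export
read_annotations_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!"beat_time_s" %in% names(df)) abort("expected a `beat_time_s` column.")
  beats <- sort(df$beat_time_s)
  out <- tibble(beat_time = beats)
  class(out) <- c("beat_schedule", class(out))
  attr(out, "pattern") <- "annotated"
  attr(out, "duration") <- max(beats)
  out
}
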