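# Core record container and file I/O (CSV, paired 16-bit PCM WAV).

#' Construct a paired DUS/fECG record
#'
#' A `fetal_record` holds a single-channel Doppler ultrasound (DUS) audio
#' trace and, optionally, the simultaneously recorded extracted fetal ECG,
#' with sampling metadata.  All absolute times in the package are seconds;
#' within-beat offsets and intervals are milliseconds.
#'
#' @param dus numeric vector, DUS samples (arbitrary units).
#' @param fecg numeric vector of the same length, or `NULL`.
#' @param fs sampling rate in Hz (> 0).
#' @param record_id identifier string.
#' @param ga_crl optional reference gestational age in weeks (CRL-based).
#' @param meta named list of free-form annotations.
#' @return object of class `fetal_record` with fields `dus`, `fecg`, `fs`,
#'   `duration` (seconds, `length(dus)/fs`), `record_id`, `ga_crl`, `meta`.
#' @export
fetal_record <- function(dus, fecg = NULL, fs, record_id = "record",
                         ga_crl = NA_real_, meta = list()) {
  stopifnot(is.numeric(dus), length(dus) > 0, is.numeric(fs), fs > 0)
  if (!is.null(fecg) && length(fecg) != length(dus)) {
    stop("`dus` and `fecg` must have equal length", call. = FALSE)
  }
  structure(
    list(
      dus = as.numeric(dus),
      fecg = if (is.null(fecg)) NULL else as.numeric(fecg),
      fs = as.numeric(fs),
      duration = length(dus) / fs,
      record_id = as.character(record_id),
      ga_crl = as.numeric(ga_crl),
      meta = meta
    ),
    class = "fetal_record"
  )
}

#' @export
print.fetal_record <- function(x, ...) {
  cat(sprintf(
    "<fetal_record '%s'>  fs = %g Hz, duration = %.3f s, fECG: %s, ga_crl = %s\n",
    x$record_id, x$fs, x$duration,
    if (is.null(x$fecg)) "absent" else "present",
    if (is.na(x$ga_crl)) "NA" else sprintf("%.1f wk", x$ga_crl)
  ))
  invisible(x)
}

#' Read a record from disk
#'
#' Supported formats: `"csv"` (two columns `dus`, `fecg`; the sampling rate
#' is taken from a `# fs=<Hz>` comment on the first line or the `fs`
#' argument) and `"wav-pair"` (two mono 16-bit PCM WAV files; `path` is the
#' DUS file and the fECG is looked up by replacing a `_dus` suffix with
#' `_fecg`, or may be given via `fecg_path`).  Sample values are passed
#' through unchanged -- no rescaling is applied.
#'
#' @param path file path (for `wav-pair`, the DUS file).
#' @param format `"csv"` or `"wav-pair"`; default guesses from the extension.
#' @param fs sampling rate in Hz, required for CSV files without an `fs`
#'   header comment; ignored (taken from the header) for WAV.
#' @param fecg_path optional explicit path of the fECG WAV file.
#' @param record_id identifier; default is the file stem.
#' @return [fetal_record()]
#' @export
load_record <- function(path, format = c("auto", "csv", "wav-pair"),
                        fs = NULL, fecg_path = NULL, record_id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", wav = "wav-pair",
                     stop("unknown format for extension '", ext, "'", call. = FALSE))
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  record_id <- record_id %||% sub("_dus$", "", tools::file_path_sans_ext(basename(path)))
  if (format == "csv") {
    first <- readLines(path, n = 1L)
    if (grepl("^#\\s*fs\\s*=", first)) {
      fs <- as.numeric(sub("^#\\s*fs\\s*=\\s*", "", first))
      df <- utils::read.csv(path, comment.char = "#")
    } else {
      if (is.null(fs)) stop("CSV carries no sampling rate; supply `fs`", call. = FALSE)
      df <- utils::read.csv(path)
    }
    if (!"dus" %in% names(df)) stop("CSV must have a 'dus' column", call. = FALSE)
    fecg <- if ("fecg" %in% names(df)) df$fecg else NULL
    return(fetal_record(df$dus, fecg, fs = fs, record_id = record_id))
  }
  # wav-pair
  dus_wav <- read_wav_mono(path)
  fecg_path <- fecg_path %||% {
    cand <- sub("_dus\\.wav$", "_fecg.wav", path)
    if (identical(cand, path) || !file.exists(cand)) NULL else cand
  }
  fecg <- if (is.null(fecg_path)) NULL else read_wav_mono(fecg_path)$samples
  if (!is.null(fecg) && length(fecg) != length(dus_wav$samples)) {
    stop("DUS and fECG WAV files differ in length", call. = FALSE)
  }
  fetal_record(dus_wav$samples, fecg, fs = dus_wav$fs, record_id = record_id)
}

#' Write a record to disk
#'
#' CSV output stores the sampling rate as a `# fs=<Hz>` comment so the file
#' round-trips through [load_record()] without extra arguments.  WAV output
#' writes `<stem>_dus.wav` / `<stem>_fecg.wav` as mono 16-bit PCM; samples
#' must already be integers in \[-32768, 32767\] (integer formats round-trip
#' bit for bit, so no implicit scaling is done).
#'
#' @param record [fetal_record()]
#' @param path output path; for `"wav-pair"`, the path stem (no extension).
#' @param format `"csv"` or `"wav-pair"`.
#' @return `path`, invisibly.
#' @export
save_record <- function(record, path, format = c("csv", "wav-pair")) {
  format <- match.arg(format)
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# fs=%.10g", record$fs), con)
    df <- data.frame(dus = record$dus)
    if (!is.null(record$fecg)) df$fecg <- record$fecg
    utils::write.csv(df, con, row.names = FALSE)
    return(invisible(path))
  }
  write_wav_mono(paste0(path, "_dus.wav"), record$dus, record$fs)
  if (!is.null(record$fecg)) write_wav_mono(paste0(path, "_fecg.wav"), record$fecg, record$fs)
  invisible(path)
}

# --- minimal RIFF/PCM16 WAV I/O ---------------------------------------------

read_wav_mono <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE")) {
    stop("not a WAVE file: ", path, call. = FALSE)
  }
  fs <- NULL; n_channels <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (!nzchar(id)) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", size / 2, 2, endian = "little", signed = FALSE)
      n_channels <- fmt[2]
      fs <- fmt[3] + 65536 * fmt[4]
      bits <- fmt[8]
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", size / 2, 2, endian = "little", signed = TRUE)
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(fs) || is.null(samples)) stop("malformed WAV: ", path, call. = FALSE)
  if (n_channels != 1L) stop("only mono WAV supported (", n_channels, " channels)", call. = FALSE)
  if (bits != 16L) stop("only 16-bit PCM WAV supported", call. = FALSE)
  list(samples = as.numeric(samples), fs = fs)
}

write_wav_mono <- function(path, samples, fs) {
  s <- as.integer(round(samples))
  if (any(s < -32768L | s > 32767L)) {
    stop("WAV output requires integer samples in [-32768, 32767]", call. = FALSE)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(s)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_size, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")            # PCM, mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs) * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(c(2L, 16L), con, size = 2, endian = "little")           # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(s, con, size = 2, endian = "little")
  invisible(path)
}

# --- cohort table I/O -------------------------------------------------------

#' Write a cohort results table
#'
#' Writes one row per record as CSV with a stable column order; missing
#' values are encoded as empty cells.  Numeric columns are written at full
#' precision and round-trip through [read_cohort_table()].
#'
#' @param table data frame / tibble of per-record results.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table), path, na = "")
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
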