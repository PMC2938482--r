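# File I/O: float WAV (RIFF) reader/writer and schema-checked CSV tables.
# The WAV layer is deliberately minimal: IEEE-float (format code 3) mono or
# multi-channel data, 32- or 64-bit. 64-bit is the default so that a
# write -> read cycle reproduces R doubles exactly.

#' Write samples to a float WAV file
#'
#' @param samples numeric vector (mono) or matrix with one column per channel.
#' @param fs sample rate in Hz (stored exactly in the header).
#' @param path output file.
#' @param bits 32 or 64 (IEEE float sample width; 64 is lossless for doubles).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, fs, path, bits = 64) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("samples must be a numeric vector or matrix")
  }
  if (!bits %in% c(32, 64)) stop("bits must be 32 or 64")
  if (fs <= 0 || fs != round(fs)) stop("fs must be a positive integer sample rate")
  n_ch <- ncol(samples)
  bytes_per_sample <- bits / 8
  block_align <- n_ch * bytes_per_sample
  data_bytes <- nrow(samples) * block_align
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")           # IEEE float
  writeBin(as.integer(n_ch), con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * block_align), con, size = 4, endian = "little")
  writeBin(as.integer(block_align), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  interleaved <- as.numeric(t(samples))
  writeBin(interleaved, con, size = bytes_per_sample, endian = "little")
  invisible(path)
}

#' Read a float WAV file
#'
#' Parses RIFF/WAVE containers with IEEE-float (format 3) samples; unknown
#' chunks are skipped.
#'
#' @param path WAV file written by [write_wav()] or any float-format WAV.
#' @return list with `samples` (matrix, one column per channel), `fs`, `bits`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file (offset 0): ", path)
  readBin(con, "integer", size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file (offset 8): ", path)
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        format = readBin(con, "integer", size = 2, endian = "little"),
        n_ch = readBin(con, "integer", size = 2, endian = "little"),
        fs = readBin(con, "integer", size = 4, endian = "little"),
        byte_rate = readBin(con, "integer", size = 4, endian = "little"),
        block_align = readBin(con, "integer", size = 2, endian = "little"),
        bits = readBin(con, "integer", size = 2, endian = "little")
      )
      if (size > 16) readBin(con, "raw", n = size - 16)
    } else if (id == "data") {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt chunk")
      if (fmt$format != 3) stop("unsupported WAV format code ", fmt$format,
                                " (only IEEE float is supported)")
      n_values <- size / (fmt$bits / 8)
      raw_vals <- readBin(con, "double", n = n_values, size = fmt$bits / 8,
                          endian = "little")
      samples <- matrix(raw_vals, ncol = fmt$n_ch, byrow = TRUE)
    } else {
      readBin(con, "raw", n = size + size %% 2)
    }
    if (!is.null(fmt) && !is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  list(samples = samples, fs = fmt$fs, bits = fmt$bits)
}

#' Write an impulse-response pair as stereo WAV plus JSON sidecar
#'
#' The sidecar (`<path>.json`) records source angle, microphone site and fs.
#'
#' @param ir an `impulse_response_pair`.
#' @param path output WAV path.
#' @return `path`, invisibly.
#' @export
write_ir_pair <- function(ir, path) {
  stopifnot(inherits(ir, "impulse_response_pair"))
  write_wav(cbind(ir$left_ir, ir$right_ir), ir$fs, path)
  meta <- list(source_angle = ir$source_angle, mic_site = ir$mic_site, fs = ir$fs)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an impulse-response pair written by [write_ir_pair()]
#' @param path WAV path (sidecar `<path>.json` must exist).
#' @return an `impulse_response_pair`.
#' @export
read_ir_pair <- function(path) {
  w <- read_wav(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  impulse_response_pair(w$samples[, 1], w$samples[, 2], w$fs,
                        source_angle = meta$source_angle,
                        mic_site = meta$mic_site)
}

#' Read a CSV table and check its schema
#'
#' @param path CSV file.
#' @param required character vector of column names that must be present.
#' @return data.frame.
#' @export
read_table_checked <- function(path, required = character()) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

#' Write a data.frame as CSV (no row names; deterministic formatting)
#' @param df data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table_checked <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
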