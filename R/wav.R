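# Minimal RIFF/WAVE I/O, IEEE float32 mono. Calibrated pressure (Pa) is
# stored as-is in the float samples, so write/read round-trips at float32
# precision.

#' Write a waveform to a WAV file
#'
#' Writes mono IEEE float32 RIFF/WAVE. If the waveform carries a component
#' table in its metadata, a sidecar CSV (`<path>.components.csv`) with
#' columns `freq_hz`, `amp_rel_db`, `phase_rad` is written alongside.
#'
#' @param wave A `waveform`.
#' @param path Output file path.
#' @param sidecar Write the component-table sidecar CSV when available?
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, sidecar = TRUE) {
  stopifnot(inherits(wave, "waveform"))
  con <- file(path, "wb")
  on.exit(close(con))
  x <- as.numeric(wave$samples)
  sr <- as.integer(round(wave$sample_rate))
  data_bytes <- 4L * length(x)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")   # format 3 = IEEE float
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(as.integer(sr * 4L), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(x, con, size = 4, endian = "little")
  if (sidecar && !is.null(wave$meta$components)) {
    comp <- wave$meta$components[, c("freq_hz", "amp_rel_db", "phase_rad")]
    utils::write.csv(comp, paste0(path, ".components.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read a float32 WAV file written by [write_wav()]
#'
#' @param path WAV file path.
#' @return A `waveform`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, "integer", size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  sr <- NULL
  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk in ", path)
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", size = 2, endian = "little")
      readBin(con, "integer", size = 2, endian = "little")
      sr <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "raw", n = size - 8)
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk before fmt chunk in ", path)
      if (fmt != 3L) stop("only IEEE float WAV supported")
      x <- readBin(con, "double", n = size / 4, size = 4, endian = "little")
      return(new_waveform(x, sr))
    } else {
      readBin(con, "raw", n = size)
    }
  }
}
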