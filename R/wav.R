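# Minimal mono RIFF/WAVE I/O (PCM 16-bit and IEEE float32), sufficient for
# exchanging 50 kHz recordings with external tools.

#' Write a mono WAV file
#'
#' @param x numeric vector of samples. For \code{type = "pcm16"} values are
#'   clipped to \[-1, 1\] and scaled to full 16-bit range; for
#'   \code{type = "float32"} they are written as-is.
#' @param path output file.
#' @param fs sample rate, Hz.
#' @param type \code{"pcm16"} or \code{"float32"}.
#' @return \code{path}, invisibly.
#' @export
write_wav <- function(x, path, fs = 50000, type = c("pcm16", "float32")) {
  type <- match.arg(type)
  n <- length(x)
  bits <- if (type == "pcm16") 16L else 32L
  bytes <- bits %/% 8L
  fmt_tag <- if (type == "pcm16") 1L else 3L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + n * bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_tag, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytes), con, size = 4, endian = "little")
  writeBin(as.integer(bytes), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n * bytes), con, size = 4, endian = "little")
  if (type == "pcm16") {
    v <- pmax(-1, pmin(1, x))
    writeBin(as.integer(round(v * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(as.double(x), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file written by [write_wav()] (PCM16 or float32)
#'
#' @param path input file.
#' @return list with \code{x} (samples; PCM16 rescaled to \[-1, 1\]) and
#'   \code{fs}.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  stop_if_not(identical(hdr, "RIFF"), "not a RIFF file")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  stop_if_not(identical(readChar(con, 4), "WAVE"), "not a WAVE file")
  fmt_tag <- NULL; fs <- NULL; bits <- NULL; x <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_tag <- readBin(con, "integer", 1, size = 2, endian = "little")
      nch <- readBin(con, "integer", 1, size = 2, endian = "little")
      stop_if_not(nch == 1L, "only mono WAV supported")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
    } else if (id == "data") {
      if (fmt_tag == 1L && bits == 16L) {
        x <- readBin(con, "integer", sz / 2, size = 2,
                     signed = TRUE, endian = "little") / 32767
      } else if (fmt_tag == 3L && bits == 32L) {
        x <- readBin(con, "double", sz / 4, size = 4, endian = "little")
      } else stop("unsupported WAV encoding", call. = FALSE)
      break
    } else {
      invisible(readBin(con, "raw", sz))
    }
  }
  stop_if_not(!is.null(x), "no data chunk found")
  list(x = x, fs = fs)
}
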