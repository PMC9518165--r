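# Minimal RIFF/WAVE reader and writer. Supports PCM 16-bit and IEEE float
# (32-bit) chunks, mono or stereo; enough for the fixtures and clips this
# package produces and consumes.

#' Read a PCM WAV file
#'
#' @param path path to a `.wav` file (PCM 16-bit or IEEE float 32-bit).
#' @return list with `samples` (numeric matrix, one column per channel,
#'   scaled to \[-1, 1\]) and `sampleRate` (Hz).
#' @export
readWavPcm <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        audioFormat   = readBin(raw[1:2], "integer", 1L, 2L, signed = FALSE, endian = "little"),
        nChannels     = readBin(raw[3:4], "integer", 1L, 2L, signed = FALSE, endian = "little"),
        sampleRate    = readBin(raw[5:8], "integer", 1L, 4L, endian = "little"),
        bitsPerSample = readBin(raw[15:16], "integer", 1L, 2L, signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      data <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data)) stop("malformed WAV (missing fmt/data): ", path)
  if (length(data) == 0L) stop("empty WAV data chunk: ", path)

  if (fmt$audioFormat == 1L && fmt$bitsPerSample == 16L) {
    x <- readBin(data, "integer", length(data) %/% 2L, size = 2L,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$audioFormat == 3L && fmt$bitsPerSample == 32L) {
    x <- readBin(data, "double", length(data) %/% 4L, size = 4L, endian = "little")
  } else {
    stop("unsupported WAV encoding (need PCM16 or float32): format ",
         fmt$audioFormat, ", ", fmt$bitsPerSample, " bit")
  }
  nch <- max(1L, fmt$nChannels)
  n <- length(x) %/% nch
  list(samples = matrix(x[seq_len(n * nch)], ncol = nch, byrow = TRUE),
       sampleRate = fmt$sampleRate)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param x an [AudioClip-class] or numeric vector in \[-1, 1\].
#' @param path output path.
#' @param sampleRate sample rate in Hz (taken from the clip if `x` is one).
#' @return `path`, invisibly.
#' @export
writeWavPcm <- function(x, path, sampleRate = NULL) {
  if (is(x, "AudioClip")) {
    sampleRate <- sampleRate(x)
    x <- samples(x)
  }
  if (is.null(sampleRate)) stop("sampleRate required for a bare vector")
  pcm <- as.integer(pmax(-32768, pmin(32767, round(x * 32767))))
  con <- file(path, "wb")
  on.exit(close(con))
  dataSize <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")   # PCM
  writeBin(1L, con, size = 2L, endian = "little")   # mono
  writeBin(as.integer(sampleRate), con, size = 4L, endian = "little")
  writeBin(as.integer(sampleRate * 2L), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")   # block align
  writeBin(16L, con, size = 2L, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}
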