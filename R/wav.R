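## Minimal RIFF/WAVE I/O (mono). Writes 16-bit PCM; reads 16-bit PCM and
## 32-bit IEEE float. Kept deliberately small: session bundles only ever
## contain mono speech responses.

readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        audioFormat = readBin(raw[1:2], "integer", 1L, size = 2L,
                              endian = "little", signed = FALSE),
        channels = readBin(raw[3:4], "integer", 1L, size = 2L,
                           endian = "little", signed = FALSE),
        sampleRate = readBin(raw[5:8], "integer", 1L, size = 4L,
                             endian = "little"),
        bitsPerSample = readBin(raw[15:16], "integer", 1L, size = 2L,
                                endian = "little", signed = FALSE))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt: ", path)
      if (fmt$channels != 1L) stop("only mono WAV supported: ", path)
      if (fmt$audioFormat == 1L && fmt$bitsPerSample == 16L) {
        x <- readBin(con, "integer", size / 2L, size = 2L, endian = "little",
                     signed = TRUE)
        samples <- x / 32768
      } else if (fmt$audioFormat == 3L && fmt$bitsPerSample == 32L) {
        samples <- readBin(con, "double", size / 4L, size = 4L,
                           endian = "little")
      } else {
        stop(sprintf("unsupported WAV encoding (format %d, %d bit): %s",
                     fmt$audioFormat, fmt$bitsPerSample, path))
      }
    } else {
      invisible(readBin(con, "raw", size + (size %% 2L)))
    }
    if (!is.null(fmt) && !is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk found in WAV: ", path)
  list(samples = samples, sampleRate = fmt$sampleRate)
}

writeWav <- function(samples, sampleRate, path) {
  samples <- pmin(1, pmax(-1, samples))
  pcm <- as.integer(pmin(32767, pmax(-32768, round(samples * 32768))))
  dataSize <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
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
  writeBin(16L, con, size = 2L, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(dataSize, con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}
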