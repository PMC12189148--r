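# Minimal RIFF/WAV I/O (PCM 16/24/32-bit and IEEE float), sufficient for
# field recordings; samples are exchanged as floats in [-1, 1].

read_u32 <- function(con) {
  v <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (length(v) == 0) stop_io("unexpected end of WAV file")
  if (v < 0) v <- v + 2^32
  v
}

#' Read a WAV file
#'
#' Supports PCM 16/24/32-bit and IEEE float 32/64-bit, plus the extensible
#' header variant. Multichannel audio is averaged to mono with a note.
#'
#' @param path Path to a WAV file.
#' @return List with `samples` (numeric in \[-1, 1\]) and `sample_rate`.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file '%s' not found", path))
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(rawToChar(readBin(con, "raw", 4)), "RIFF"))
    stop_io("not a RIFF file")
  read_u32(con)
  if (!identical(rawToChar(readBin(con, "raw", 4)), "WAVE"))
    stop_io("not a WAVE file")

  fmt <- NULL; data <- NULL
  repeat {
    id_raw <- readBin(con, "raw", 4)
    if (length(id_raw) < 4) break
    id <- rawToChar(id_raw)
    size <- read_u32(con)
    if (id == "fmt ") {
      body <- readBin(con, "raw", size)
      if (length(body) < 16) stop_io("truncated fmt chunk")
      u16 <- function(off) sum(as.integer(body[off + 1:2]) * c(1, 256))
      u32 <- function(off) sum(as.integer(body[off + 1:4]) * 256^(0:3))
      fmt <- list(format = u16(0), n_channels = u16(2),
                  sample_rate = u32(4), bits = u16(14))
      if (fmt$format == 65534) {  # WAVE_FORMAT_EXTENSIBLE
        if (length(body) < 26) stop_io("truncated extensible fmt chunk")
        fmt$format <- u16(24)
      }
    } else if (id == "data") {
      data <- readBin(con, "raw", size)
      if (length(data) < size)
        stop_io(sprintf("truncated WAV data: expected %d bytes, got %d",
                        size, length(data)))
    } else {
      seek(con, size + size %% 2, origin = "current")
    }
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt)) stop_io("WAV file has no fmt chunk")
  if (is.null(data)) stop_io("WAV file has no data chunk")

  bytes_per <- fmt$bits %/% 8
  n_vals <- length(data) %/% bytes_per
  if (n_vals == 0) stop_io("WAV file contains no samples")
  x <- if (fmt$format == 1) {
    if (fmt$bits == 16) {
      readBin(data, "integer", n_vals, size = 2, signed = TRUE,
              endian = "little") / 2^15
    } else if (fmt$bits == 24) {
      m <- matrix(as.integer(data[seq_len(n_vals * 3)]), nrow = 3)
      v <- m[1, ] + m[2, ] * 256 + m[3, ] * 65536
      v <- ifelse(v >= 2^23, v - 2^24, v)
      v / 2^23
    } else if (fmt$bits == 32) {
      readBin(data, "integer", n_vals, size = 4, endian = "little") / 2^31
    } else stop_io(sprintf("unsupported PCM bit depth: %d", fmt$bits))
  } else if (fmt$format == 3) {
    if (!fmt$bits %in% c(32, 64))
      stop_io(sprintf("unsupported float bit depth: %d", fmt$bits))
    readBin(data, "double", n_vals, size = bytes_per, endian = "little")
  } else {
    stop_io(sprintf("unsupported WAV format code: %d", fmt$format))
  }

  if (fmt$n_channels > 1) {
    inform(sprintf("averaging %d channels to mono", fmt$n_channels))
    n_frames <- length(x) %/% fmt$n_channels
    x <- colMeans(matrix(x[seq_len(n_frames * fmt$n_channels)],
                         nrow = fmt$n_channels))
  }
  list(samples = x, sample_rate = fmt$sample_rate)
}

#' Write a WAV file
#'
#' @param samples Numeric vector in \[-1, 1\] (clipped if outside).
#' @param sample_rate Sampling rate in Hz.
#' @param path Output path.
#' @param format `"pcm16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path,
                      format = c("pcm16", "float32")) {
  format <- match.arg(format)
  samples <- pmin(pmax(samples, -1), 1)
  con <- file(path, "wb")
  on.exit(close(con))
  bits <- if (format == "pcm16") 16L else 32L
  code <- if (format == "pcm16") 1L else 3L
  bytes_per <- bits %/% 8L
  data_size <- length(samples) * bytes_per

  w_u32 <- function(v) writeBin(as.integer(v), con, size = 4,
                                endian = "little")
  w_u16 <- function(v) writeBin(as.integer(v), con, size = 2,
                                endian = "little")
  writeChar("RIFF", con, eos = NULL); w_u32(36 + data_size)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w_u32(16)
  w_u16(code); w_u16(1); w_u32(sample_rate)
  w_u32(sample_rate * bytes_per); w_u16(bytes_per); w_u16(bits)
  writeChar("data", con, eos = NULL); w_u32(data_size)
  if (format == "pcm16") {
    writeBin(as.integer(round(samples * (2^15 - 1))), con, size = 2,
             endian = "little")
  } else {
    writeBin(samples, con, size = 4, endian = "little")
  }
  invisible(path)
}
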