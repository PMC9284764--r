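# Minimal EDF (European Data Format) writer/reader for continuous
# recordings. One data record per second; 16-bit little-endian samples with
# per-channel physical scaling, so read(write(x)) agrees with x to within
# one quantization step of the stored physical range.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Uses 1-second data records; the recording must therefore contain a whole
#' number of seconds of data. Each channel is quantized to 16 bits over a
#' symmetric physical range covering its data, so the round-trip error is at
#' most one quantization step (range / 65535).
#'
#' @param raw a `raw_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(raw, path) {
  stopifnot(inherits(raw, "raw_recording"))
  fs <- as.integer(raw$sample_rate_hz)
  n <- ncol(raw$data)
  ns <- nrow(raw$data)
  if (n == 0) stop("cannot write a zero-length recording")
  if (n %% fs != 0)
    stop("EDF writer requires a whole number of seconds of data")
  n_rec <- n %/% fs

  pmax_ <- apply(abs(raw$data), 1, max)
  pmax_[pmax_ == 0] <- 1
  pmin_ <- -pmax_
  dmin <- -32768L; dmax <- 32767L
  scale <- (pmax_ - pmin_) / (dmax - dmin)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, width)
    writeChar(paste(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  fld(raw$channel_labels, 16)                       # label
  fld(rep("", ns), 80)                              # transducer
  fld(rep("uV", ns), 8)                             # physical dimension
  fld(formatC(pmin_, format = "g", digits = 7), 8)  # physical min
  fld(formatC(pmax_, format = "g", digits = 7), 8)  # physical max
  fld(rep(dmin, ns), 8)                             # digital min
  fld(rep(dmax, ns), 8)                             # digital max
  fld(rep("", ns), 80)                              # prefiltering
  fld(rep(fs, ns), 8)                               # samples per record
  fld(rep("", ns), 32)                              # reserved

  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    block <- raw$data[, idx, drop = FALSE]
    dig <- round((block - pmin_) / scale) + dmin
    dig <- pmin(pmax(dig, dmin), dmax)
    writeBin(as.integer(t(dig)), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @return a `raw_recording` (without schedule or blink reference; those
#'   travel in the events table).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                      # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("unreadable EDF header")
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  vapply(seq_len(ns), function(i) rd(80), "")
  vapply(seq_len(ns), function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(80), "")
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(32), "")
  if (length(unique(spr)) != 1)
    stop("mixed per-channel sampling rates are not supported")
  fs <- spr[1] / rec_dur
  scale <- (pmax_ - pmin_) / (dmax - dmin)

  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    dig <- readBin(con, "integer", n = ns * spr[1], size = 2L,
                   signed = TRUE, endian = "little")
    block <- matrix(dig, nrow = spr[1], ncol = ns)
    idx <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    data[, idx] <- t(block) * scale + (pmin_ - dmin * scale)
  }
  new_raw_recording(data, fs, labels)
}
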