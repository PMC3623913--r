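# Minimal EDF (European Data Format) reader/writer for continuous EEG.
# EDF stores an ASCII fixed-width header followed by 16-bit little-endian
# integer data records; physical values are recovered by per-signal linear
# scaling. Only equal-rate continuous signals are handled, which is all the
# speller pipeline needs; no installed R package provides EDF I/O.

edf_pad <- function(x, width) {
  x <- as.character(x)
  check_that(nchar(x) <= width, "EDF header field too long: '%s'", x)
  formatC(x, width = width, flag = "-")
}

is_edf_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8)
  # EDF version field: "0" followed by seven ASCII spaces
  length(magic) == 8 && magic[1] == as.raw(0x30) &&
    all(magic[2:8] == as.raw(0x20))
}

#' Write continuous signals to an EDF file
#'
#' Signals are quantized to 16-bit integers over their physical range, so
#' the round-trip error is bounded by one quantization step per channel.
#' The recording is padded with zeros to a whole number of 1-second data
#' records. Use the native container ([write_session()]) when lossless
#' storage or epoch semantics are needed.
#'
#' @param signals numeric matrix `[channels, samples]` (microvolts).
#' @param fs sampling rate in Hz (integer; one data record per second).
#' @param labels channel labels, one per row of `signals`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, fs, labels, path) {
  signals <- as.matrix(signals)
  ns <- nrow(signals)
  check_that(length(labels) == ns, "need one label per channel")
  check_that(fs == round(fs) && fs > 0, "fs must be a positive integer")
  spr <- as.integer(fs)                      # samples per 1 s record
  n_rec <- as.integer(ceiling(ncol(signals) / spr))
  pad <- n_rec * spr - ncol(signals)
  if (pad > 0) signals <- cbind(signals, matrix(0, ns, pad))

  pmax_ <- apply(signals, 1, function(r) max(abs(r), 1e-6))
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad("1", 8), edf_pad(ns, 4))
  sig_hdr <- paste0(
    paste(vapply(labels, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(vapply(sprintf("%.6g", -pmax_), edf_pad, "", width = 8), collapse = ""),
    paste(vapply(sprintf("%.6g", pmax_), edf_pad, "", width = 8), collapse = ""),
    paste(rep(edf_pad(dmin, 8), ns), collapse = ""),
    paste(rep(edf_pad(dmax, 8), ns), collapse = ""),
    paste(rep(edf_pad("BP:0.1-40Hz", 80), ns), collapse = ""),
    paste(rep(edf_pad(spr, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = ""))
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)

  # re-read the formatted physical extrema so scaling matches the header
  pm <- as.numeric(sprintf("%.6g", pmax_))
  scale_ <- (dmax - dmin) / (2 * pm)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (s in seq_len(ns)) {
      dig <- round((signals[s, cols] + pm[s]) * scale_[s] + dmin)
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read continuous signals from an EDF file
#'
#' @param path EDF file path. All signals must share one sampling rate.
#' @return list with `signals` (matrix `[channels, samples]`), `fs` and
#'   `montage` (labels in file order).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  num <- function(n) {
    v <- suppressWarnings(as.numeric(trimws(rd(n))))
    check_that(is.finite(v), "malformed EDF header in %s", path)
    v
  }
  version <- trimws(rd(8))
  check_that(identical(version, "0"), "malformed EDF header (version '%s')", version)
  rd(80); rd(80); rd(8); rd(8)               # patient, recording, date, time
  num(8)                                     # header bytes
  rd(44)
  n_rec <- num(8)
  rec_dur <- num(8)
  ns <- as.integer(num(4))
  check_that(ns >= 1, "EDF file has no signals")

  fields <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- trimws(fields(16))
  fields(80); fields(8)                      # transducer, dimension
  pmin_ <- as.numeric(trimws(fields(8)))
  pmax_ <- as.numeric(trimws(fields(8)))
  dmin <- as.numeric(trimws(fields(8)))
  dmax <- as.numeric(trimws(fields(8)))
  fields(80)                                 # prefilter
  spr <- as.integer(trimws(fields(8)))
  fields(32)
  check_that(length(unique(spr)) == 1,
             "EDF signals with differing sampling rates are not supported")
  fs <- spr[1] / rec_dur
  gain <- (pmax_ - pmin_) / (dmax - dmin)

  signals <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2,
                     signed = TRUE, endian = "little")
      check_that(length(dig) == spr[s], "truncated EDF data in %s", path)
      signals[s, cols] <- pmin_[s] + (dig - dmin[s]) * gain[s]
    }
  }
  list(signals = signals, fs = fs, montage = montage(labels))
}
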