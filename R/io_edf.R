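# Minimal EDF (European Data Format) reader/writer: fixed-layout ASCII
# header, 16-bit little-endian samples, 1-second data records. Sufficient
# for round-tripping continuous multichannel recordings; no EDF+ annotations.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

.edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = width - 2)
  if (nchar(s) > width) s <- substr(s, 1, width)
  .edf_pad(s, width)
}

#' Write a recording as EDF
#'
#' Signals are quantized to 16 bits over a per-channel physical range taken
#' from the data min/max with a 5\% margin (constant channels get a unit
#' range). The sampling rate must be a whole number of samples per 1-s data
#' record; a trailing partial second is zero-padded.
#'
#' @param rec an [recording()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- length(rec$data)
  n <- length(rec$data[[1]])
  n_rec <- ceiling(n / fs)
  phys <- lapply(rec$data, function(x) {
    lo <- min(x); hi <- max(x)
    if (hi - lo < 1e-12) { lo <- lo - 1; hi <- hi + 1 }
    m <- 0.05 * (hi - lo)
    c(lo - m, hi + m)
  })
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8), .edf_pad("X X X X", 80), .edf_pad("Startdate X", 80),
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256 * (ns + 1), 8), .edf_pad("", 44),
    .edf_pad(n_rec, 8), .edf_pad("1", 8), .edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, .edf_pad, "", width = width),
                     collapse = ""), con, eos = NULL)
  }
  field(rec$channel_labels, 16)
  field(rep("", ns), 80)
  field(rep("uV", ns), 8)
  field(vapply(phys, function(p) .edf_num(p[1], 8), ""), 8)
  field(vapply(phys, function(p) .edf_num(p[2], 8), ""), 8)
  field(rep("-32768", ns), 8)
  field(rep("32767", ns), 8)
  field(rep("", ns), 80)
  field(rep(fs, ns), 8)
  field(rep("", ns), 32)
  # digitize channels once; physical min/max re-parsed from their 8-char
  # ASCII form so that read(write(x)) uses identical scaling
  dig <- vector("list", ns)
  for (j in seq_len(ns)) {
    pmin <- as.numeric(.edf_num(phys[[j]][1], 8))
    pmax <- as.numeric(.edf_num(phys[[j]][2], 8))
    x <- c(rec$data[[j]], numeric(n_rec * fs - n))
    d <- round((x - pmin) / (pmax - pmin) * 65535 - 32768)
    dig[[j]] <- as.integer(pmin(pmax(d, -32768), 32767))
  }
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (j in seq_len(ns))
      writeBin(dig[[j]][idx], con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return an [recording()] object (units as stored; µV for files written by
#'   [write_edf()]).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  readChar(con, 8)                      # version
  readChar(con, 80 + 80 + 8 + 8)        # patient/recording ids, date, time
  as.integer(rd(8))                     # header bytes
  readChar(con, 44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdv(16)
  rdv(80)                               # transducer
  rdv(8)                                # physical dimension
  pmin <- as.numeric(rdv(8))
  pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8))
  dmax <- as.numeric(rdv(8))
  rdv(80)                               # prefilter
  spr <- as.integer(rdv(8))             # samples per record
  rdv(32)
  data <- lapply(seq_len(ns), function(j) numeric(n_rec * spr[j]))
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[j], size = 2, signed = TRUE,
                     endian = "little")
      data[[j]][((r - 1) * spr[j] + 1):(r * spr[j])] <-
        pmin[j] + (raw - dmin[j]) / (dmax[j] - dmin[j]) * (pmax[j] - pmin[j])
    }
  }
  if (length(unique(spr)) != 1)
    stop("EDF with per-channel sampling rates is not supported")
  names(data) <- labels
  recording(data, fs = spr[1] / rec_dur, channel_labels = labels)
}

#' Worst-case quantization error of an EDF round trip
#'
#' Half the physical-unit size of one digital step for each channel, given
#' the ranges [write_edf()] would choose.
#'
#' @param rec an [recording()] object.
#' @return numeric vector, one bound per channel (µV).
#' @export
edf_quantization_bound <- function(rec) {
  vapply(rec$data, function(x) {
    lo <- min(x); hi <- max(x)
    if (hi - lo < 1e-12) { lo <- lo - 1; hi <- hi + 1 }
    m <- 0.05 * (hi - lo)
    # ranges pass through an 8-char ASCII field; reproduce that rounding
    lo2 <- as.numeric(.edf_num(lo - m, 8))
    hi2 <- as.numeric(.edf_num(hi + m, 8))
    (hi2 - lo2) / 65535
  }, numeric(1))
}
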