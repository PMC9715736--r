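# Minimal European Data Format (EDF) support for continuous multichannel
# recordings: one physical unit (uV), one sampling rate shared by all
# signals, 16-bit samples, 1-second data records. This covers the layout
# produced by standard resting-state EEG exports; annotations, per-signal
# rates and EDF+ discontinuous records are out of scope.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width)  # left-aligned, space padded
}

#' Write an EEG recording as an EDF file
#'
#' Samples are quantized to 16 bits over the recording's physical range.
#' The recording is split into 1-second data records; a trailing partial
#' second is zero-padded (with a warning).
#'
#' @param rec An [eeg_recording()]; `fs` must be a whole number.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(fs)
  nc <- n_channels(rec); ns <- n_samples(rec)
  n_rec <- as.integer(ceiling(ns / fs))
  if (n_rec * fs != ns) {
    warning("recording is not a whole number of seconds; zero-padding ",
            n_rec * fs - ns, " samples")
  }
  pmax_ <- max(abs(rec$data), 1e-6)
  pmin_ <- -pmax_
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con, eos = NULL)
  wr("0", 8)                                   # version
  wr(rec$subject_id, 80)                       # patient id
  wr("microstatr export", 80)                  # recording id
  wr("01.01.00", 8); wr("00.00.00", 8)         # start date / time
  wr(256L * (1L + nc), 8)                      # header length
  wr("", 44)                                   # reserved
  wr(n_rec, 8)                                 # number of data records
  wr("1", 8)                                   # record duration (s)
  wr(nc, 4)                                    # number of signals
  for (lab in rec$channel_labels) wr(lab, 16)
  for (i in seq_len(nc)) wr("", 80)            # transducer
  for (i in seq_len(nc)) wr("uV", 8)           # physical dimension
  for (i in seq_len(nc)) wr(sprintf("%.6g", pmin_), 8)
  for (i in seq_len(nc)) wr(sprintf("%.6g", pmax_), 8)
  for (i in seq_len(nc)) wr(dmin, 8)
  for (i in seq_len(nc)) wr(dmax, 8)
  for (i in seq_len(nc)) wr("", 80)            # prefiltering
  for (i in seq_len(nc)) wr(fs, 8)             # samples per record
  for (i in seq_len(nc)) wr("", 32)            # reserved

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  padded <- cbind(rec$data,
                  matrix(0, nc, n_rec * fs - ns))
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    block <- t(padded[, idx, drop = FALSE])    # fs x nc, signal-major on write
    dig <- as.integer(round((as.numeric(block) - pmin_) * scale + dmin))
    dig <- pmin(pmax(dig, dmin), dmax)
    writeBin(dig, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into an EEG recording
#'
#' Requires all signals to share one sampling rate (the continuous-EEG
#' layout written by [write_edf()] and by common acquisition exports).
#'
#' @param path Input file path.
#' @return An [eeg_recording()] with potentials in the file's physical units.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (file.size(path) < 256) stop("parse error in ", path,
                                  ": file shorter than an EDF header")
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("parse error in ", path,
                           ": unsupported EDF version '", version, "'")
  patient <- rd(80); rd(80); rd(8); rd(8)
  header_len <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nc <- as.integer(rd(4))
  if (is.na(nc) || nc < 1) stop("parse error in ", path,
                                ": invalid signal count")
  labels <- vapply(seq_len(nc), function(i) rd(16), character(1))
  for (i in seq_len(nc)) rd(80)
  for (i in seq_len(nc)) rd(8)                 # physical dimension
  pmin_ <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(nc)) rd(80)
  spr <- vapply(seq_len(nc), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(nc)) rd(32)
  if (length(unique(spr)) != 1) {
    stop("parse error in ", path, ": signals have differing sampling rates")
  }
  seek(con, header_len)
  fs <- spr[1] / rec_dur
  data <- matrix(0, nc, n_rec * spr[1])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = nc * spr[1], size = 2,
                   endian = "little")
    if (length(raw) != nc * spr[1]) {
      stop("parse error in ", path, ": data record ", r, " truncated")
    }
    block <- matrix(raw, nrow = spr[1], ncol = nc)
    idx <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    data[, idx] <- t(block) * scale + (pmin_ - dmin * scale)
  }
  eeg_recording(data, fs = fs, channel_labels = labels,
                subject_id = if (nzchar(patient)) patient else "subject")
}
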