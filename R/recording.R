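#' Multichannel EEG recording
#'
#' Container for a channels x samples potential matrix with its sampling
#' rate and channel labels. All analysis stages consume and return this
#' object.
#'
#' @param data Numeric matrix, channels x samples, in microvolts (or
#'   normalized units after [normalize_global()]).
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_labels Character vector, one label per channel. Defaults
#'   to `Ch01, Ch02, ...`.
#' @param subject_id Identifier string attached to exported files.
#' @return An object of class `eeg_recording` with fields `data`, `fs`,
#'   `channel_labels`, `subject_id`.
#' @export
eeg_recording <- function(data, fs, channel_labels = NULL,
                          subject_id = "subject") {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("EEG data must be numeric")
  if (any(!is.finite(data))) stop("EEG data contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("sampling rate fs must be a single positive number")
  }
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("Ch%02d", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stop("channel_labels length (", length(channel_labels),
         ") does not match channel count (", nrow(data), ")")
  }
  structure(list(data = data, fs = as.numeric(fs),
                 channel_labels = as.character(channel_labels),
                 subject_id = as.character(subject_id)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

n_channels <- function(rec) nrow(rec$data)
n_samples <- function(rec) ncol(rec$data)

#' Write an EEG recording as a delimited matrix file
#'
#' Fixed dialect: tab-delimited, channels as rows; one header line of
#' `key=value` pairs (`subject_id`, `fs`, `n_channels`, `n_samples`)
#' followed by one line per channel, `label<TAB>v1<TAB>v2...`. Values are
#' written with 17 significant digits so a write/read round trip is
#' bit-exact.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eeg_matrix <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  header <- sprintf("subject_id=%s\tfs=%.17g\tn_channels=%d\tn_samples=%d",
                    rec$subject_id, rec$fs, n_channels(rec), n_samples(rec))
  body <- vapply(seq_len(n_channels(rec)), function(i) {
    paste(c(rec$channel_labels[i], sprintf("%.17g", rec$data[i, ])),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an EEG recording
#'
#' @param path Input file path.
#' @param format `"matrix"` (the package's delimited dialect, see
#'   [write_eeg_matrix()]) or `"edf"` (European Data Format, see
#'   [read_edf()]).
#' @return An [eeg_recording()].
#' @export
read_eeg <- function(path, format = c("matrix", "edf")) {
  format <- match.arg(format)
  if (format == "edf") return(read_edf(path))
  read_eeg_matrix(path)
}

#' @rdname read_eeg
#' @export
read_eeg_matrix <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  if (length(lines) < 2) stop("parse error in ", path,
                              ": expected a header line and channel rows")
  hdr <- strsplit(strsplit(lines[1], "\t", fixed = TRUE)[[1]], "=",
                  fixed = TRUE)
  if (any(lengths(hdr) != 2)) {
    stop("parse error in ", path, " line 1: malformed header")
  }
  hv <- stats::setNames(vapply(hdr, `[`, character(1), 2),
                        vapply(hdr, `[`, character(1), 1))
  for (key in c("fs", "n_channels", "n_samples")) {
    if (is.na(hv[key])) stop("parse error in ", path,
                             " line 1: missing header field '", key, "'")
  }
  nc <- as.integer(hv["n_channels"]); ns <- as.integer(hv["n_samples"])
  if (length(lines) - 1L != nc) {
    stop("parse error in ", path, ": header declares ", nc,
         " channels but file has ", length(lines) - 1L, " data rows")
  }
  labels <- character(nc)
  data <- matrix(NA_real_, nc, ns)
  for (i in seq_len(nc)) {
    parts <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1]]
    if (length(parts) != ns + 1L) {
      stop("parse error in ", path, " line ", i + 1L, ": expected ",
           ns + 1L, " fields, found ", length(parts))
    }
    labels[i] <- parts[1]
    data[i, ] <- as.numeric(parts[-1])
  }
  if (any(!is.finite(data))) {
    stop("parse error in ", path, ": non-numeric sample values")
  }
  eeg_recording(data, fs = as.numeric(hv["fs"]), channel_labels = labels,
                subject_id = unname(hv["subject_id"]) %||% "subject")
}

#' Read and write subject metadata tables
#'
#' Tab-delimited table with columns `subject_id`, `group` (`patient` /
#' `healthy`), `age`, `sex` (`M`/`F`), `fma_total`, `fma_upper`,
#' `fma_lower`, `iadl`. Scale scores may be `NA` for healthy subjects;
#' patient rows must carry all four.
#'
#' @param meta Data frame with the columns above.
#' @param path File path.
#' @return `read_metadata` returns the validated data frame.
#' @export
write_metadata <- function(meta, path) {
  validate_metadata(meta)
  data.table::fwrite(meta, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  meta <- as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
  validate_metadata(meta)
  meta
}

validate_metadata <- function(meta) {
  required <- c("subject_id", "group", "age", "sex",
                "fma_total", "fma_upper", "fma_lower", "iadl")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    stop("metadata table missing columns: ", paste(missing, collapse = ", "))
  }
  if (!all(meta$group %in% c("patient", "healthy"))) {
    stop("metadata group must be 'patient' or 'healthy'")
  }
  pat <- meta[meta$group == "patient",
              c("fma_total", "fma_upper", "fma_lower", "iadl")]
  if (nrow(pat) && any(is.na(pat))) {
    stop("patient rows must carry all four clinical scale scores")
  }
  invisible(meta)
}
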