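#' Common average reference
#'
#' Re-references every time sample by subtracting the instantaneous mean
#' across electrodes, so each column of the data matrix has zero mean.
#' Standard practice before microstate analysis, and the reference under
#' which spatial correlation equals cosine similarity. Idempotent.
#'
#' @param rec An [eeg_recording()] with at least 2 channels.
#' @return The re-referenced recording.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (n_channels(rec) < 2) {
    stop("common average reference is undefined for a single channel")
  }
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec
}

#' Decimate a recording to a lower sampling rate
#'
#' Applies an anti-aliasing low-pass FIR filter (via [signal::decimate()])
#' before keeping every `factor`-th sample, e.g. 1000 Hz -> 250 Hz with
#' `factor = 4`.
#'
#' @param rec An [eeg_recording()].
#' @param factor Integer decimation factor >= 1; `1` is the identity.
#' @return The decimated recording with `fs / factor`.
#' @export
decimate_recording <- function(rec, factor) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.numeric(factor) || length(factor) != 1 || factor < 1 ||
      factor != round(factor)) {
    stop("decimation factor must be a positive integer")
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(rec)
  out <- t(apply(rec$data, 1, function(ch) {
    signal::decimate(ch, factor, ftype = "fir")
  }))
  eeg_recording(out, fs = rec$fs / factor,
                channel_labels = rec$channel_labels,
                subject_id = rec$subject_id)
}

#' Normalize a recording by its mean global field power
#'
#' Divides the whole data matrix by the record's mean GFP so the output has
#' mean GFP exactly 1. This preserves the relative GFP time course (the
#' per-class mean-GFP feature stays meaningful) while removing global
#' amplitude differences between subjects. Idempotent and scale-invariant:
#' `normalize_global(c * rec)` equals `normalize_global(rec)` for any c > 0.
#'
#' @param rec An [eeg_recording()] with at least 2 channels and nonzero GFP.
#' @return The normalized recording (unitless amplitudes).
#' @export
normalize_global <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  g <- mean(compute_gfp(rec)$values)
  if (g <= 0) stop("cannot normalize: record has zero mean GFP")
  rec$data <- rec$data / g
  rec
}

#' Band-pass filter a recording (optional plumbing)
#'
#' Zero-phase FIR band-pass (default 1-45 Hz), available for real
#' recordings; synthetic data is generated clean and does not need it.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Band edges in Hz.
#' @param order FIR order (default 128).
#' @return The filtered recording.
#' @export
bandpass_filter <- function(rec, low = 1, high = 45, order = 128) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!(low > 0 && high > low && high < nyq)) {
    stop("band edges must satisfy 0 < low < high < fs/2")
  }
  h <- signal::fir1(order, c(low, high) / nyq, type = "pass")
  rec$data <- t(apply(rec$data, 1, function(ch) {
    as.numeric(signal::filtfilt(h, 1, ch))
  }))
  rec
}
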