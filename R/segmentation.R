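#' Global field power
#'
#' GFP at time t is the spatial standard deviation of the scalp map:
#' `sqrt( sum_i (V_i(t) - Vmean(t))^2 / N )`, with `N` the electrode count
#' (population divisor, not N-1). GFP is invariant to re-referencing
#' (adding a constant to all channels at a time point) and scales linearly
#' with global amplitude.
#'
#' @param rec An [eeg_recording()] with >= 2 channels.
#' @return A `gfp_series` object: list with `values` (non-negative, one per
#'   sample) and `fs`.
#' @export
compute_gfp <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (n_channels(rec) < 2) stop("GFP requires at least 2 channels")
  centered <- sweep(rec$data, 2, colMeans(rec$data))
  values <- sqrt(colMeans(centered^2))
  structure(list(values = values, fs = rec$fs), class = "gfp_series")
}

#' @export
print.gfp_series <- function(x, ...) {
  cat(sprintf("<gfp_series> %d samples @ %g Hz, mean %.4g\n",
              length(x$values), x$fs, mean(x$values)))
  invisible(x)
}

#' Locate GFP local maxima
#'
#' Strict local maxima (greater than both neighbors); a flat run higher
#' than both flanks counts as one peak at its first sample; endpoints are
#' never peaks. When two maxima fall within `min_separation_ms`, the one
#' with larger GFP survives (greedy by descending amplitude, ties by
#' earlier index).
#'
#' @param gfp A `gfp_series` from [compute_gfp()] (length >= 3), or a plain
#'   numeric vector together with `fs`.
#' @param min_separation_ms Minimum peak separation in ms (default 10; 0
#'   disables the pruning).
#' @param fs Sampling rate, only needed when `gfp` is a bare vector.
#' @return Integer vector of peak sample indices, strictly increasing
#'   (possibly empty).
#' @export
find_gfp_peaks <- function(gfp, min_separation_ms = 10, fs = NULL) {
  if (inherits(gfp, "gfp_series")) {
    v <- gfp$values; fs <- gfp$fs
  } else {
    v <- as.numeric(gfp)
    if (is.null(fs)) stop("fs is required when gfp is a bare vector")
  }
  n <- length(v)
  if (n < 3) stop("GFP series must have length >= 3")

  # Candidate peaks: collapse plateaus to their first sample, then require
  # the value to exceed the nearest differing neighbors on both sides.
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  m <- length(r$values)
  cand <- integer(0)
  for (j in seq_len(m)) {
    if (j == 1L || j == m) next          # runs touching the endpoints
    if (r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L]) {
      cand <- c(cand, starts[j])
    }
  }
  if (!length(cand) || min_separation_ms <= 0) return(sort(cand))

  min_sep <- min_separation_ms / 1000 * fs
  ord <- cand[order(-v[cand], cand)]
  kept <- integer(0)
  for (idx in ord) {
    if (!length(kept) || all(abs(kept - idx) >= min_sep)) {
      kept <- c(kept, idx)
    }
  }
  sort(kept)
}

#' Extract topographic maps at GFP peaks
#'
#' The scalp maps at GFP local maxima ("original maps") are the
#' highest-signal-to-noise topographies and are the clustering input.
#'
#' @param rec An [eeg_recording()].
#' @param peaks Integer sample indices (from [find_gfp_peaks()]).
#' @return A `peak_maps` object: list with `maps` (n_peaks x channels),
#'   `peak_indices`, `peak_gfp`, `fs`, `channel_labels`.
#' @export
extract_peak_maps <- function(rec, peaks) {
  stopifnot(inherits(rec, "eeg_recording"))
  peaks <- as.integer(peaks)
  if (length(peaks) && (min(peaks) < 1 || max(peaks) > n_samples(rec))) {
    stop("peak index out of range 1..", n_samples(rec))
  }
  gfp <- compute_gfp(rec)$values
  structure(list(
    maps = t(rec$data[, peaks, drop = FALSE]),
    peak_indices = peaks,
    peak_gfp = gfp[peaks],
    fs = rec$fs,
    channel_labels = rec$channel_labels
  ), class = "peak_maps")
}

#' @export
print.peak_maps <- function(x, ...) {
  cat(sprintf("<peak_maps> %d maps x %d channels\n",
              nrow(x$maps), ncol(x$maps)))
  invisible(x)
}

# Pool peak-map sets from several recordings into one clustering input.
pool_peak_maps <- function(peak_list) {
  stopifnot(length(peak_list) >= 1)
  structure(list(
    maps = do.call(rbind, lapply(peak_list, `[[`, "maps")),
    peak_indices = unlist(lapply(peak_list, `[[`, "peak_indices")),
    peak_gfp = unlist(lapply(peak_list, `[[`, "peak_gfp")),
    fs = peak_list[[1]]$fs,
    channel_labels = peak_list[[1]]$channel_labels
  ), class = "peak_maps")
}
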