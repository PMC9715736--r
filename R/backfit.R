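#' Microstate label sequence
#'
#' Per-sample class labels plus the derived run-length segment list.
#' Labels are integer class indices `1..k` with `NA` as the unassigned
#' sentinel (spatially flat samples); consecutive segments always carry
#' different classes and `NA` runs break segments.
#'
#' @param labels Integer vector (NA allowed) of per-sample classes.
#' @param fs Sampling rate in Hz.
#' @param k Number of classes.
#' @param similarity Optional n_samples x k matrix of absolute spatial
#'   correlations to each prototype (kept by [assign_labels()]; used by the
#'   smoothing merge rule).
#' @param class_labels Optional character labels, length k.
#' @return A `label_sequence` object with fields `labels`, `fs`, `k`,
#'   `segments` (data.frame: class, start, length), `similarity`,
#'   `class_labels`.
#' @export
label_sequence <- function(labels, fs, k, similarity = NULL,
                           class_labels = NULL) {
  labels <- as.integer(labels)
  if (any(!is.na(labels) & (labels < 1 | labels > k))) {
    stop("labels must be in 1..k or NA")
  }
  structure(list(
    labels = labels, fs = as.numeric(fs), k = as.integer(k),
    segments = segments_from_labels(labels),
    similarity = similarity,
    class_labels = class_labels %||% paste0("M", seq_len(k))
  ), class = "label_sequence")
}

#' @export
print.label_sequence <- function(x, ...) {
  cat(sprintf("<label_sequence> %d samples @ %g Hz, %d classes, %d segments\n",
              length(x$labels), x$fs, x$k, nrow(x$segments)))
  invisible(x)
}

# Run-length segments of a label vector; NA runs are excluded.
segments_from_labels <- function(labels) {
  if (!length(labels)) {
    return(data.frame(class = integer(0), start = integer(0),
                      length = integer(0)))
  }
  r <- rle(ifelse(is.na(labels), -1L, labels))
  len <- r$lengths
  start <- cumsum(len) - len + 1L
  keep <- r$values != -1L
  data.frame(class = r$values[keep], start = start[keep],
             length = len[keep])
}

#' Back-fit a recording onto prototypes (winner-take-all)
#'
#' Every sample is labeled with the prototype of highest absolute spatial
#' correlation (polarity-ignorant, consistent with the clustering); ties go
#' to the lowest class index. Spatially flat samples (zero variance across
#' channels) get the unassigned sentinel `NA` and are excluded from
#' features.
#'
#' @param rec An [eeg_recording()].
#' @param prototypes A `prototype_set` with matching channel count.
#' @return An unsmoothed [label_sequence()] carrying the per-sample
#'   `similarity` matrix.
#' @export
assign_labels <- function(rec, prototypes) {
  stopifnot(inherits(rec, "eeg_recording"),
            inherits(prototypes, "prototype_set"))
  if (ncol(prototypes$maps) != n_channels(rec)) {
    stop("prototype channel count (", ncol(prototypes$maps),
         ") does not match recording (", n_channels(rec), ")")
  }
  sim <- abs(spatial_corr_matrix(t(rec$data), prototypes$maps))
  flat <- apply(sim, 1, function(row) all(is.na(row)))
  labels <- rep(NA_integer_, n_samples(rec))
  if (any(!flat)) {
    labels[!flat] <- max.col(sim[!flat, , drop = FALSE],
                             ties.method = "first")
  }
  label_sequence(labels, fs = rec$fs, k = prototypes$k, similarity = sim,
                 class_labels = prototypes$labels)
}

#' Temporal smoothing by short-segment rejection
#'
#' Segments shorter than `min_duration_ms` are not sub-stable microstates;
#' they are absorbed iteratively: the shortest sub-threshold segment (ties
#' by earliest start) is dissolved, each of its samples relabeled to the
#' flanking segment whose prototype has the higher absolute correlation at
#' that sample (when the sequence carries a `similarity` matrix; otherwise
#' to the nearer flank). Repeats until every segment is at least the
#' threshold. Idempotent; conserves total labeled duration; never
#' introduces a class absent from its input.
#'
#' @param seq A [label_sequence()].
#' @param min_duration_ms Minimum segment duration in ms (default 30).
#' @param boundary_exempt If `TRUE`, segments truncated by the record edge
#'   are exempt from rejection (default `FALSE`: strict, every output
#'   segment meets the threshold).
#' @return The smoothed [label_sequence()].
#' @export
smooth_labels <- function(seq, min_duration_ms = 30, boundary_exempt = FALSE) {
  stopifnot(inherits(seq, "label_sequence"))
  min_samples <- ceiling(min_duration_ms / 1000 * seq$fs)
  labels <- seq$labels
  sim <- seq$similarity
  n <- length(labels)
  guard <- 10L * (nrow(seq$segments) + 1L)

  frozen <- integer(0)   # start indices of isolated short segments that
                         # have no labeled flank to merge into
  repeat {
    segs <- segments_from_labels(labels)
    if (!nrow(segs)) break
    short <- segs$length < min_samples & !(segs$start %in% frozen)
    if (boundary_exempt) {
      # A segment is edge-truncated if it starts at the first labeled sample
      # of its contiguous labeled run or ends at the last.
      first_lab <- segs$start == 1L |
        is.na(labels[pmax(segs$start - 1L, 1L)])
      last_lab <- (segs$start + segs$length - 1L) == n |
        is.na(labels[pmin(segs$start + segs$length, n)])
      short <- short & !(first_lab | last_lab)
    }
    if (!any(short)) break
    cand <- which(short)
    pick <- cand[order(segs$length[cand], segs$start[cand])][1]
    i0 <- segs$start[pick]; i1 <- i0 + segs$length[pick] - 1L
    prev_class <- if (pick > 1 &&
                      segs$start[pick - 1] + segs$length[pick - 1] == i0) {
      segs$class[pick - 1]
    } else NA_integer_
    next_class <- if (pick < nrow(segs) &&
                      segs$start[pick + 1] == i1 + 1L) {
      segs$class[pick + 1]
    } else NA_integer_
    if (is.na(prev_class) && is.na(next_class)) {
      warning("labeled run shorter than the smoothing threshold; ",
              "kept as a single segment")
      frozen <- c(frozen, i0)
      next
    }
    for (t in i0:i1) {
      if (is.na(prev_class)) {
        labels[t] <- next_class
      } else if (is.na(next_class)) {
        labels[t] <- prev_class
      } else if (is.null(sim)) {
        labels[t] <- if (t - i0 < i1 - t) prev_class else next_class
      } else {
        labels[t] <- if (sim[t, prev_class] >= sim[t, next_class]) {
          prev_class
        } else next_class
      }
    }
    guard <- guard - 1L
    if (guard <= 0L) stop("smoothing failed to converge")
  }
  label_sequence(labels, fs = seq$fs, k = seq$k, similarity = sim,
                 class_labels = seq$class_labels)
}

#' Serialize a label sequence as run-length segments
#'
#' Tab-delimited `class`, `label`, `start_ms`, `duration_ms`, one row per
#' segment — the compact interchange form of a microstate sequence.
#'
#' @param seq A [label_sequence()].
#' @param path Output file path.
#' @return `path` invisibly; `read_label_segments` returns the segment
#'   data frame.
#' @export
write_label_segments <- function(seq, path) {
  stopifnot(inherits(seq, "label_sequence"))
  segs <- seq$segments
  out <- data.frame(class = segs$class,
                    label = seq$class_labels[segs$class],
                    start_ms = (segs$start - 1) / seq$fs * 1000,
                    duration_ms = segs$length / seq$fs * 1000)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_label_segments
#' @export
read_label_segments <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}
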