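#' Microstate features from a label sequence
#'
#' Per-class features of a (smoothed) microstate sequence:
#' * `dur`: mean segment duration in ms,
#' * `occ`: segment onsets per second of labeled time,
#' * `cov`: fraction of labeled samples (sums to 1),
#' * `mean_gfp`: mean GFP over the class's samples (`NA` without a GFP
#'   series),
#' * `tp`: k x k transition-probability matrix over consecutive distinct
#'   segments, zero diagonal, each row summing to 1 (all-zero when a class
#'   never transitions).
#'
#' Unassigned (`NA`) samples are excluded from every denominator; an `NA`
#' run also breaks segment adjacency, so no transition is counted across
#' it. The identity `cov_c = occ_c * dur_c / 1000` holds exactly for every
#' class. Classes never observed get zero features and are listed in the
#' `absent` field.
#'
#' @param seq A [label_sequence()].
#' @param gfp Optional `gfp_series` of matching length for the mean-GFP
#'   feature.
#' @return A `microstate_features` object: list with `dur`, `occ`, `cov`,
#'   `mean_gfp` (named per-class vectors), `tp`, `k`, `class_labels`,
#'   `absent`, `labeled_seconds`.
#' @export
compute_features <- function(seq, gfp = NULL) {
  stopifnot(inherits(seq, "label_sequence"))
  if (!is.null(gfp)) {
    v <- if (inherits(gfp, "gfp_series")) gfp$values else as.numeric(gfp)
    if (length(v) != length(seq$labels)) {
      stop("GFP series length does not match the label sequence")
    }
  } else v <- NULL
  segs <- seq$segments
  if (!nrow(segs)) stop("empty label sequence: no labeled samples")
  mean_gfp <- if (is.null(v)) {
    rep(NA_real_, seq$k)
  } else {
    vapply(seq_len(seq$k), function(c) {
      sel <- !is.na(seq$labels) & seq$labels == c
      if (any(sel)) mean(v[sel]) else 0
    }, numeric(1))
  }
  feats <- features_from_segments(segs, fs = seq$fs, k = seq$k)
  feats$mean_gfp <- stats::setNames(mean_gfp, seq$class_labels)
  feats$class_labels <- seq$class_labels
  names(feats$dur) <- names(feats$occ) <- names(feats$cov) <- seq$class_labels
  dimnames(feats$tp) <- list(seq$class_labels, seq$class_labels)
  feats
}

# Core per-class feature computation from a run-length segment list.
# Used both by compute_features() and directly on generator ground truth.
features_from_segments <- function(segs, fs, k) {
  stopifnot(all(segs$class >= 1), all(segs$class <= k))
  labeled_samples <- sum(segs$length)
  labeled_seconds <- labeled_samples / fs
  dur <- occ <- cov <- numeric(k)
  for (c in seq_len(k)) {
    sel <- segs$class == c
    if (any(sel)) {
      dur[c] <- mean(segs$length[sel]) / fs * 1000
      occ[c] <- sum(sel) / labeled_seconds
      cov[c] <- sum(segs$length[sel]) / labeled_samples
    }
  }
  # Transitions only between consecutive *adjacent* segments (an NA gap
  # between runs breaks adjacency).
  tp <- matrix(0, k, k)
  if (nrow(segs) >= 2) {
    from <- segs$class[-nrow(segs)]
    to <- segs$class[-1]
    adjacent <- segs$start[-1] == segs$start[-nrow(segs)] +
      segs$length[-nrow(segs)]
    for (i in which(adjacent)) tp[from[i], to[i]] <- tp[from[i], to[i]] + 1
    rs <- rowSums(tp)
    nz <- rs > 0
    tp[nz, ] <- tp[nz, , drop = FALSE] / rs[nz]
  }
  structure(list(
    dur = dur, occ = occ, cov = cov,
    mean_gfp = rep(NA_real_, k), tp = tp, k = as.integer(k),
    class_labels = paste0("M", seq_len(k)),
    absent = which(!tabulate(segs$class, k)),
    labeled_seconds = labeled_seconds
  ), class = "microstate_features")
}

#' @export
print.microstate_features <- function(x, ...) {
  cat(sprintf("<microstate_features> %d classes over %.1f s labeled\n",
              x$k, x$labeled_seconds))
  m <- rbind(`Dur (ms)` = x$dur, `Occ (1/s)` = x$occ, Cov = x$cov,
             `mean GFP` = x$mean_gfp)
  colnames(m) <- x$class_labels
  print(round(m, 4))
  invisible(x)
}

#' Flatten features and metadata into one cohort-table row
#'
#' For the canonical k = 4 analysis: exactly 28 feature columns --
#' `GFP_A..GFP_D`, `Occ_A..Occ_D`, `Dur_A..Dur_D`, `Cov_A..Cov_D` and the
#' 12 off-diagonal transition probabilities in the order
#' `TP_AB, TP_AC, TP_AD, TP_BA, TP_BC, TP_BD, TP_CA, TP_CB, TP_CD, TP_DA,
#' TP_DB, TP_DC` -- followed by the metadata columns.
#'
#' @param features A `microstate_features` with k = 4 (classes labeled
#'   A-D).
#' @param meta One-row data frame (or named list) of subject metadata.
#' @return One-row data frame: 28 feature columns then metadata.
#' @export
features_to_row <- function(features, meta = NULL) {
  stopifnot(inherits(features, "microstate_features"))
  if (features$k != 4) {
    stop("features_to_row requires k = 4 (got k = ", features$k, ")")
  }
  cls <- c("A", "B", "C", "D")
  dur <- stats::setNames(features$dur, cls)
  occ <- stats::setNames(features$occ, cls)
  cov <- stats::setNames(features$cov, cls)
  gfp <- stats::setNames(features$mean_gfp, cls)
  out <- list()
  for (c in cls) out[[paste0("GFP_", c)]] <- unname(gfp[c])
  for (c in cls) out[[paste0("Occ_", c)]] <- unname(occ[c])
  for (c in cls) out[[paste0("Dur_", c)]] <- unname(dur[c])
  for (c in cls) out[[paste0("Cov_", c)]] <- unname(cov[c])
  for (i in 1:4) for (j in 1:4) {
    if (i != j) {
      out[[paste0("TP_", cls[i], cls[j])]] <- features$tp[i, j]
    }
  }
  row <- as.data.frame(out)
  if (!is.null(meta)) row <- cbind(row, as.data.frame(meta))
  row
}

#' The 28 canonical feature column names
#' @return Character vector of the 16 per-class features and 12 transition
#'   probabilities, in cohort-table order.
#' @export
feature_columns <- function() {
  cls <- c("A", "B", "C", "D")
  tp <- unlist(lapply(cls, function(i) {
    paste0("TP_", i, setdiff(cls, i))
  }))
  c(paste0("GFP_", cls), paste0("Occ_", cls), paste0("Dur_", cls),
    paste0("Cov_", cls), tp)
}
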