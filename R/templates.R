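#' Idealized electrode layout
#'
#' Approximately uniform 2-D electrode positions on the unit disk (sunflower
#' spiral), used to build the canonical class templates when no measured
#' montage is supplied. `x` runs left (-1) to right (+1), `y` posterior (-1)
#' to anterior (+1). This is an idealized stand-in for a 10-20 montage
#' geometry, adequate for defining large-scale gradient templates.
#'
#' @param n_channels Number of electrodes.
#' @return Data frame with columns `label`, `x`, `y`.
#' @export
electrode_layout <- function(n_channels) {
  i <- seq_len(n_channels)
  r <- sqrt((i - 0.5) / n_channels)
  theta <- i * pi * (3 - sqrt(5))            # golden angle
  data.frame(label = sprintf("Ch%02d", i),
             x = r * cos(theta), y = r * sin(theta))
}

#' Canonical microstate class templates A-D
#'
#' Idealized topographies of the four canonical resting-state classes,
#' defined on electrode coordinates: two opposing diagonal ("left-right")
#' gradients for A and B, an anterior-posterior gradient for C, and a
#' frontocentral maximum for D. Each template is channel-mean removed and
#' unit-normalized. Used for automated A-D labeling of fitted prototypes in
#' place of manual visual labeling; because labeling is polarity-ignorant,
#' each template's overall sign is irrelevant.
#'
#' @param layout Data frame with `x`, `y` electrode coordinates
#'   (see [electrode_layout()]).
#' @return A `prototype_set` with labels `A, B, C, D`.
#' @export
microstate_templates <- function(layout = electrode_layout(64)) {
  x <- layout$x; y <- layout$y
  maps <- rbind(
    A = (x + y) / sqrt(2),                       # right-anterior / left-posterior diagonal
    B = (-x + y) / sqrt(2),                      # left-anterior / right-posterior diagonal
    C = -y,                                      # anterior-posterior gradient
    D = exp(-((x^2 + (y - 0.2)^2) / (2 * 0.35^2)))  # frontocentral maximum
  )
  maps <- unit_rows(center_rows(maps))
  structure(list(
    maps = maps, k = 4L, labels = c("A", "B", "C", "D"),
    gev_per_class = rep(NA_real_, 4),
    diagnostics = list(gev_total = NA_real_),
    assignment = NULL,
    channel_labels = layout$label
  ), class = "prototype_set")
}

#' Group-level prototypes by two-stage clustering
#'
#' Per-subject prototype sets are fitted first; the pooled per-subject
#' prototypes are then clustered again to give group templates. This is the
#' aggregation used to compare group topographies and to define a common
#' label frame across subjects; single-stage pooling of all peak maps is
#' available via `stage = "pooled"`.
#'
#' @param peaks_list List of `peak_maps`, one per subject.
#' @param k Number of group prototypes (default 4).
#' @param stage `"two_stage"` (default) or `"pooled"`.
#' @param seed Integer seed.
#' @param ... Passed to [modified_kmeans()].
#' @return List with `group` (the group-level `prototype_set`) and
#'   `subject_fits` (per-subject sets; `NULL` for `stage = "pooled"`).
#' @export
group_prototypes <- function(peaks_list, k = 4, stage = c("two_stage", "pooled"),
                             seed, ...) {
  stage <- match.arg(stage)
  if (missing(seed)) stop("group_prototypes requires an explicit seed")
  if (stage == "pooled") {
    pooled <- pool_peak_maps(peaks_list)
    return(list(group = modified_kmeans(pooled, k, seed = seed, ...),
                subject_fits = NULL))
  }
  subject_fits <- lapply(seq_along(peaks_list), function(i) {
    modified_kmeans(peaks_list[[i]], k, seed = child_seed(seed, i), ...)
  })
  proto_maps <- do.call(rbind, lapply(subject_fits, `[[`, "maps"))
  pooled <- structure(list(
    maps = proto_maps,
    peak_indices = seq_len(nrow(proto_maps)),
    peak_gfp = rep(1, nrow(proto_maps)),       # prototypes weighted equally
    fs = peaks_list[[1]]$fs,
    channel_labels = peaks_list[[1]]$channel_labels
  ), class = "peak_maps")
  group <- modified_kmeans(pooled, k, seed = child_seed(seed, 0L), ...)
  list(group = group, subject_fits = subject_fits)
}
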