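#' Configuration for a synthetic microstate EEG recording
#'
#' Defaults emulate the acquisition conditions of a resting-state
#' microstate study: 64 channels at 250 Hz, at least 200 s per subject,
#' four prototype classes with mean dwell times in the canonical
#' 60-120 ms range, and sensor noise at a fixed amplitude ratio.
#'
#' @param n_channels Electrode count (default 64).
#' @param fs Sampling rate in Hz (default 250).
#' @param duration Recording length in seconds (default 200).
#' @param k_true Number of generating classes (default 4).
#' @param mean_durations_ms Per-class mean dwell times in ms (default
#'   `c(80, 85, 95, 70)`: class C longest, D shortest, matching the
#'   ordering typical of single-subject feature tables).
#' @param tp_true k x k stochastic transition matrix with zero diagonal
#'   (default mildly structured, C->D baseline 0.30).
#' @param gfp_level Mean amplitude of the clean signal (default 1,
#'   i.e. normalized units).
#' @param noise_sigma Sensor-noise amplitude as a ratio of the clean-signal
#'   RMS (default 0.3).
#' @param polarity_flip_prob Probability that the topography polarity flips
#'   at each new segment (default 0.5).
#' @param seed Integer master seed.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_channels = 64, fs = 250, duration = 200,
                             k_true = 4,
                             mean_durations_ms = c(80, 85, 95, 70),
                             tp_true = default_tp(k_true),
                             gfp_level = 1, noise_sigma = 0.3,
                             polarity_flip_prob = 0.5, seed = 1L) {
  cfg <- list(n_channels = n_channels, fs = fs, duration = duration,
              k_true = k_true, mean_durations_ms = mean_durations_ms,
              tp_true = tp_true, gfp_level = gfp_level,
              noise_sigma = noise_sigma,
              polarity_flip_prob = polarity_flip_prob, seed = seed)
  validate_tp(tp_true, k_true)
  stopifnot(fs > 0, duration > 0, all(mean_durations_ms > 0),
            length(mean_durations_ms) == k_true,
            noise_sigma >= 0, polarity_flip_prob >= 0,
            polarity_flip_prob <= 1)
  class(cfg) <- "synthetic_config"
  cfg
}

#' Default transition matrix for k classes
#'
#' Zero diagonal, rows summing to 1. For k = 4 a mildly structured matrix
#' with a C->D baseline of 0.30 (leaving headroom for planted couplings);
#' otherwise uniform off-diagonal.
#' @param k Number of classes.
#' @export
default_tp <- function(k = 4) {
  if (k == 4) {
    tp <- rbind(c(0, .35, .40, .25),
                c(.30, 0, .45, .25),
                c(.35, .35, 0, .30),
                c(.35, .40, .25, 0))
  } else {
    tp <- matrix(1 / (k - 1), k, k)
    diag(tp) <- 0
  }
  dimnames(tp) <- list(LETTERS[1:k], LETTERS[1:k])
  tp
}

validate_tp <- function(tp, k) {
  tp <- as.matrix(tp)
  if (!all(dim(tp) == c(k, k))) stop("tp must be ", k, " x ", k)
  if (any(diag(tp) != 0)) stop("tp diagonal must be exactly 0")
  if (any(tp < 0)) stop("tp entries must be non-negative")
  if (any(abs(rowSums(tp) - 1) > 1e-9)) {
    stop("each tp row must sum to 1 within 1e-9")
  }
  invisible(tp)
}

#' Generate well-separated random prototype topographies
#'
#' Draws k channel-mean-removed, unit-norm random maps, rejecting draws
#' until every pair satisfies |spatial correlation| <= `max_corr`, so the
#' clustering problem is nontrivial but identifiable.
#'
#' @param n_channels Electrode count (must allow k zero-mean maps,
#'   `n_channels > k` is required for separation).
#' @param k Number of prototypes (>= 1).
#' @param seed Integer seed.
#' @param max_corr Pairwise separation bound (default 0.5).
#' @param max_tries Bound on rejection sampling attempts per map.
#' @return A `prototype_set` labeled `A, B, ...`.
#' @export
make_prototypes <- function(n_channels, k, seed, max_corr = 0.5,
                            max_tries = 1000L) {
  if (k < 1) stop("k must be >= 1")
  if (n_channels < 2 || k > n_channels) {
    stop("cannot draw ", k, " zero-mean maps on ", n_channels, " channels")
  }
  maps <- with_seed(seed, {
    out <- matrix(NA_real_, k, n_channels)
    for (i in seq_len(k)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        m <- stats::rnorm(n_channels)
        m <- m - mean(m); m <- m / sqrt(sum(m^2))
        if (i == 1 ||
            all(abs(out[seq_len(i - 1), , drop = FALSE] %*% m) <= max_corr)) {
          out[i, ] <- m; ok <- TRUE; break
        }
      }
      if (!ok) {
        stop("failed to draw prototype ", i, " with pairwise |corr| <= ",
             max_corr, " after ", max_tries, " attempts")
      }
    }
    out
  })
  structure(list(
    maps = maps, k = as.integer(k), labels = LETTERS[seq_len(k)],
    gev_per_class = rep(NA_real_, k),
    diagnostics = list(gev_total = NA_real_), assignment = NULL,
    channel_labels = sprintf("Ch%02d", seq_len(n_channels))
  ), class = "prototype_set")
}

#' Simulate a semi-Markov microstate label sequence
#'
#' Segment classes follow a first-order Markov chain on the zero-diagonal
#' transition matrix (so successive segment classes always differ); dwell
#' times are geometric with the stated per-class mean (memoryless -- the
#' simplest law consistent with segment-level first-order transitions),
#' support starting at one sample. The initial class is uniform.
#'
#' @param tp k x k stochastic matrix, zero diagonal.
#' @param mean_durations_ms Per-class mean dwell in ms.
#' @param fs Sampling rate in Hz.
#' @param n_samples Sequence length (>= 1).
#' @param seed Integer seed.
#' @return A [label_sequence()]; its `segments` field is the ground-truth
#'   segment list (the final segment is truncated at `n_samples`).
#' @export
simulate_label_sequence <- function(tp, mean_durations_ms, fs, n_samples,
                                    seed) {
  k <- nrow(as.matrix(tp))
  validate_tp(tp, k)
  stopifnot(length(mean_durations_ms) == k, all(mean_durations_ms > 0),
            n_samples >= 1, fs > 0)
  mean_samples <- mean_durations_ms / 1000 * fs
  if (any(mean_samples < 1)) {
    stop("mean durations below one sample at fs = ", fs)
  }
  segs <- with_seed(seed, {
    simulate_segments(as.matrix(tp), mean_samples, n_samples)
  })
  labels <- rep.int(segs$class, segs$length)
  label_sequence(labels, fs = fs, k = k,
                 class_labels = LETTERS[seq_len(k)])
}

# Draw (class, length) segments until n_samples is covered; truncate last.
simulate_segments <- function(tp, mean_samples, n_samples) {
  k <- nrow(tp)
  cum <- lapply(seq_len(k), function(i) cumsum(tp[i, ]) / sum(tp[i, ]))
  p_geom <- 1 / mean_samples                  # dwell = 1 + rgeom(p)
  classes <- integer(0); lengths <- integer(0)
  total <- 0
  cls <- sample.int(k, 1)
  while (total < n_samples) {
    m <- max(32L, ceiling((n_samples - total) / min(mean_samples)) + 20L)
    u <- stats::runif(m)
    new_cls <- integer(m)
    cur <- cls
    for (j in seq_len(m)) {            # class chain is inherently sequential
      new_cls[j] <- cur
      cur <- findInterval(u[j], cum[[cur]]) + 1L
    }
    dw <- 1L + stats::rgeom(m, p_geom[new_cls])
    classes <- c(classes, new_cls)
    lengths <- c(lengths, dw)
    total <- total + sum(dw)
    cls <- cur
  }
  cut <- which(cumsum(lengths) >= n_samples)[1]
  classes <- classes[seq_len(cut)]
  lengths <- lengths[seq_len(cut)]
  lengths[cut] <- n_samples - sum(lengths[-cut])
  data.frame(class = classes,
             start = cumsum(lengths) - lengths + 1L,
             length = lengths)
}

#' Synthesize a multichannel EEG recording from a label sequence
#'
#' Sample t is `s(t) * a(t) * map_{L(t)} + noise`, where `s(t)` is a
#' per-segment polarity sign that flips with `polarity_flip_prob` at each
#' new segment, `a(t) > 0` is a smooth positive amplitude envelope
#' (rectified smoothed Gaussian noise, so GFP has genuine local maxima
#' inside segments), and the sensor noise is zero-mean Gaussian per channel
#' with sd `noise_sigma` times the clean-signal RMS. The output is common
#' average referenced.
#'
#' @param prototypes A `prototype_set` (generating maps).
#' @param labels A [label_sequence()] from [simulate_label_sequence()].
#' @param gfp_level Mean clean-signal GFP (default 1).
#' @param noise_sigma Noise-to-signal amplitude ratio (default 0.3).
#' @param polarity_flip_prob Per-segment polarity flip probability
#'   (default 0.5).
#' @param seed Integer seed.
#' @param subject_id Identifier for the recording.
#' @return An [eeg_recording()]; attribute `"polarity"` stores the
#'   per-segment signs.
#' @export
simulate_eeg <- function(prototypes, labels, gfp_level = 1,
                         noise_sigma = 0.3, polarity_flip_prob = 0.5,
                         seed = 1L, subject_id = "synthetic") {
  stopifnot(inherits(prototypes, "prototype_set"),
            inherits(labels, "label_sequence"))
  if (max(labels$labels, na.rm = TRUE) > prototypes$k) {
    stop("label sequence uses more classes than the prototype set")
  }
  nc <- ncol(prototypes$maps)
  ns <- length(labels$labels)
  segs <- labels$segments
  fs <- labels$fs

  with_seed(seed, {
    # Per-segment polarity: sign flips with the configured probability.
    flips <- stats::runif(nrow(segs)) < polarity_flip_prob
    signs <- cumprod(c(1, ifelse(flips[-1], -1, 1)))
    s_t <- rep.int(signs, segs$length)

    # Amplitude envelope: rectified moving-average Gaussian noise with a
    # ~40 ms correlation length, floored away from zero, unit mean.
    win <- max(3L, round(0.04 * fs))
    raw <- stats::rnorm(ns + win)
    env <- abs(stats::filter(raw, rep(1 / win, win), sides = 1)[-seq_len(win)])
    env <- env + 0.25
    a_t <- as.numeric(env / mean(env))

    # Map each sample to its (unit-norm, zero-mean) prototype row. A
    # zero-mean map with unit L2 norm has GFP = 1/sqrt(nc), so rescale to
    # make the mean clean GFP equal gfp_level.
    P <- unit_rows(center_rows(prototypes$maps))
    clean <- t(P[labels$labels, , drop = FALSE]) *
      rep(s_t * a_t * gfp_level * sqrt(nc), each = nc)
    if (noise_sigma > 0) {
      rms <- sqrt(mean(clean^2))
      noise <- matrix(stats::rnorm(nc * ns, sd = noise_sigma * rms), nc, ns)
      clean <- clean + noise
    }
    rec <- eeg_recording(clean, fs = fs,
                         channel_labels = prototypes$channel_labels,
                         subject_id = subject_id)
    rec <- common_average_reference(rec)
    attr(rec, "polarity") <- signs
    rec
  })
}

#' Simulate one subject end to end
#'
#' Convenience wrapper: label sequence plus EEG from one
#' [synthetic_config()], returning the ground truth alongside the
#' recording.
#'
#' @param cfg A [synthetic_config()].
#' @param prototypes Optional `prototype_set` (drawn from
#'   `cfg$seed` when omitted).
#' @param subject_id Identifier.
#' @return List with `recording`, `labels` (ground-truth
#'   [label_sequence()]), `prototypes`, `features` (ground-truth
#'   [compute_features()] of the generating sequence).
#' @export
simulate_subject <- function(cfg, prototypes = NULL,
                             subject_id = "synthetic") {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (is.null(prototypes)) {
    prototypes <- make_prototypes(cfg$n_channels, cfg$k_true,
                                  seed = child_seed(cfg$seed, 1L))
  }
  n_samples <- round(cfg$duration * cfg$fs)
  labels <- simulate_label_sequence(cfg$tp_true, cfg$mean_durations_ms,
                                    cfg$fs, n_samples,
                                    seed = child_seed(cfg$seed, 2L))
  rec <- simulate_eeg(prototypes, labels, gfp_level = cfg$gfp_level,
                      noise_sigma = cfg$noise_sigma,
                      polarity_flip_prob = cfg$polarity_flip_prob,
                      seed = child_seed(cfg$seed, 3L),
                      subject_id = subject_id)
  list(recording = rec, labels = labels, prototypes = prototypes,
       features = compute_features(labels))
}
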