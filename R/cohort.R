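#' Configuration for a two-group synthetic cohort
#'
#' Defines the planted effects of a patient-vs-healthy microstate study:
#' a group difference in the class-C mean duration, a positive coupling of
#' the C->D transition probability to an FMA-like motor score, and a
#' negative coupling of the class-A duration to a lower-limb-like score.
#'
#' Couplings are planted at the subject-parameter level: each patient's
#' true class-A duration and C->D probability are affine in their scale
#' score plus residual noise, with residual variances chosen so that the
#' total between-subject spread matches the healthy group (groups are
#' exchangeable when `dur_c_effect_ms` and both slopes are zero). With the
#' defaults the planted correlations are approximately +0.74 (C->D vs FMA
#' total) and -0.64 (Dur_A vs lower-limb score).
#'
#' @param n_per_group Subjects per group (default 12).
#' @param dur_c_effect_ms Reduction of the patients' class-C mean duration
#'   in ms (default 25).
#' @param tp_cd_slope Change in C->D probability per FMA-total point
#'   (default 0.003).
#' @param dur_a_slope Change in class-A duration (ms) per lower-limb point
#'   (default -1.664).
#' @param score_noise_sigma Measurement noise sd added to the reported
#'   scale scores, in scale points (default 1).
#' @param dur_between_sd_ms Between-subject sd of per-class mean durations
#'   (default 15).
#' @param tp_cd_sd Between-subject sd of the C->D probability
#'   (default 0.052).
#' @param age_range_patient,age_range_healthy Uniform age ranges (defaults
#'   40-80 and 20-40 years).
#' @param seed Integer master seed.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_per_group = 12, dur_c_effect_ms = 25,
                          tp_cd_slope = 0.003, dur_a_slope = -1.664,
                          score_noise_sigma = 1, dur_between_sd_ms = 15,
                          tp_cd_sd = 0.052,
                          age_range_patient = c(40, 80),
                          age_range_healthy = c(20, 40), seed = 1L) {
  stopifnot(n_per_group >= 2, dur_between_sd_ms >= 0, tp_cd_sd >= 0,
            score_noise_sigma >= 0, length(age_range_patient) == 2,
            length(age_range_healthy) == 2)
  structure(list(n_per_group = n_per_group,
                 dur_c_effect_ms = dur_c_effect_ms,
                 tp_cd_slope = tp_cd_slope, dur_a_slope = dur_a_slope,
                 score_noise_sigma = score_noise_sigma,
                 dur_between_sd_ms = dur_between_sd_ms,
                 tp_cd_sd = tp_cd_sd,
                 age_range_patient = age_range_patient,
                 age_range_healthy = age_range_healthy,
                 seed = seed),
            class = "cohort_config")
}

# sd of U(a, b)
unif_sd <- function(r) diff(r) / sqrt(12)

#' Simulate a two-group cohort with known microstate ground truth
#'
#' All subjects share one generating prototype set (classes A-D); each
#' subject gets their own mean durations and transition matrix with the
#' planted effects of the [cohort_config()], a semi-Markov label sequence,
#' ground-truth features computed from that sequence by the features
#' module, and (optionally) a synthesized EEG recording.
#'
#' Out-of-range planted C->D probabilities are clipped to `[0.02, 0.9]`
#' and the row renormalized, with a warning.
#'
#' @param cfg A [cohort_config()].
#' @param base A [synthetic_config()] giving the recording conditions and
#'   healthy-group baselines.
#' @param signals If `TRUE` (default), synthesize the EEG recordings;
#'   `FALSE` returns ground truth only (label sequences and features),
#'   which is sufficient for statistics-level simulations.
#' @return List with `meta` (metadata data frame), `truth_table` (one row
#'   per subject: 28 ground-truth feature columns then metadata),
#'   `features` (list of `microstate_features`), `label_seqs` (list),
#'   `recordings` (list of [eeg_recording()] or `NULL`s), `prototypes`
#'   (the shared generating set), `true_params` (per-subject planted
#'   durations and transition matrices), `cfg`, `base`.
#' @export
simulate_cohort <- function(cfg, base = synthetic_config(),
                            signals = TRUE) {
  stopifnot(inherits(cfg, "cohort_config"), inherits(base, "synthetic_config"))
  if (base$k_true != 4) stop("cohort simulation assumes k_true = 4 (A-D)")
  n <- cfg$n_per_group
  prototypes <- make_prototypes(base$n_channels, 4,
                                seed = child_seed(cfg$seed, 999L))

  # Score geometry (FMA-like): upper-limb U(20, 60), lower-limb U(10, 30),
  # total = upper + lower; IADL-like U(8, 31).
  sd_lower <- unif_sd(c(10, 30))
  sd_total <- sqrt(unif_sd(c(20, 60))^2 + sd_lower^2)

  sig_a <- abs(cfg$dur_a_slope) * sd_lower
  if (sig_a > cfg$dur_between_sd_ms) {
    warning("dur_a_slope implies more spread than dur_between_sd_ms; ",
            "residual variance floored at zero")
  }
  resid_a <- sqrt(max(0, cfg$dur_between_sd_ms^2 - sig_a^2))
  sig_cd <- abs(cfg$tp_cd_slope) * sd_total
  if (sig_cd > cfg$tp_cd_sd) {
    warning("tp_cd_slope implies more spread than tp_cd_sd; ",
            "residual variance floored at zero")
  }
  resid_cd <- sqrt(max(0, cfg$tp_cd_sd^2 - sig_cd^2))

  subjects <- list()
  idx <- 0L
  clipped <- FALSE
  for (grp in c("healthy", "patient")) {
    for (i in seq_len(n)) {
      idx <- idx + 1L
      sub <- with_seed(child_seed(cfg$seed, idx), {
        age_r <- if (grp == "patient") cfg$age_range_patient
                 else cfg$age_range_healthy
        age <- stats::runif(1, age_r[1], age_r[2])
        sex <- if (stats::runif(1) <
                   (if (grp == "patient") 0.75 else 2 / 3)) "M" else "F"
        durs <- base$mean_durations_ms
        jitter <- stats::rnorm(4, 0, cfg$dur_between_sd_ms)
        if (grp == "patient") {
          fma_upper <- stats::runif(1, 20, 60)
          fma_lower <- stats::runif(1, 10, 30)
          fma_total <- fma_upper + fma_lower
          iadl <- stats::runif(1, 8, 31)
          # planted couplings replace the generic class-A jitter
          jitter[1] <- cfg$dur_a_slope * (fma_lower - 20) +
            stats::rnorm(1, 0, resid_a)
          durs[3] <- durs[3] - cfg$dur_c_effect_ms
          tp_cd <- base$tp_true[3, 4] +
            cfg$tp_cd_slope * (fma_total - 60) +
            stats::rnorm(1, 0, resid_cd)
          scores <- c(fma_total, fma_upper, fma_lower, iadl) +
            stats::rnorm(4, 0, cfg$score_noise_sigma)
        } else {
          tp_cd <- base$tp_true[3, 4] + stats::rnorm(1, 0, cfg$tp_cd_sd)
          scores <- rep(NA_real_, 4)
        }
        durs <- pmax(durs + jitter, 40)
        tp_cd_clipped <- min(max(tp_cd, 0.02), 0.9)
        tp <- base$tp_true
        others <- setdiff(1:4, c(3, 4))
        tp[3, others] <- tp[3, others] *
          (1 - tp_cd_clipped) / sum(tp[3, others])
        tp[3, 4] <- tp_cd_clipped
        list(group = grp, age = age, sex = sex, scores = scores,
             durs = durs, tp = tp, clipped = tp_cd_clipped != tp_cd)
      })
      sub$id <- sprintf("S%02d_%s", idx, substr(grp, 1, 1))
      clipped <- clipped || sub$clipped
      subjects[[idx]] <- sub
    }
  }
  if (clipped) {
    warning("planted C->D probabilities out of [0.02, 0.9] were clipped ",
            "and the row renormalized")
  }

  n_samples <- round(base$duration * base$fs)
  label_seqs <- vector("list", length(subjects))
  features <- vector("list", length(subjects))
  recordings <- vector("list", length(subjects))
  rows <- vector("list", length(subjects))
  for (j in seq_along(subjects)) {
    s <- subjects[[j]]
    label_seqs[[j]] <- simulate_label_sequence(
      s$tp, s$durs, base$fs, n_samples,
      seed = child_seed(cfg$seed, 10000L + j))
    features[[j]] <- compute_features(label_seqs[[j]])
    if (signals) {
      recordings[[j]] <- simulate_eeg(
        prototypes, label_seqs[[j]], gfp_level = base$gfp_level,
        noise_sigma = base$noise_sigma,
        polarity_flip_prob = base$polarity_flip_prob,
        seed = child_seed(cfg$seed, 20000L + j), subject_id = s$id)
    }
    meta_row <- data.frame(subject_id = s$id, group = s$group,
                           age = s$age, sex = s$sex,
                           fma_total = s$scores[1], fma_upper = s$scores[2],
                           fma_lower = s$scores[3], iadl = s$scores[4])
    rows[[j]] <- features_to_row(features[[j]], meta_row)
  }

  meta <- do.call(rbind, lapply(rows, function(r) {
    r[c("subject_id", "group", "age", "sex",
        "fma_total", "fma_upper", "fma_lower", "iadl")]
  }))
  list(meta = meta,
       truth_table = do.call(rbind, rows),
       features = features,
       label_seqs = label_seqs,
       recordings = recordings,
       prototypes = prototypes,
       true_params = list(
         durs = t(vapply(subjects, `[[`, numeric(4), "durs")),
         tp = lapply(subjects, `[[`, "tp")),
       cfg = cfg, base = base)
}
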