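test_that("generated prototypes are zero-mean, unit-norm and separated", {
  p <- make_prototypes(64, 4, seed = 7)
  expect_equal(rowMeans(p$maps), rep(0, 4), tolerance = 1e-12)
  expect_equal(sqrt(rowSums(p$maps^2)), rep(1, 4), tolerance = 1e-12)
  cc <- abs(p$maps %*% t(p$maps))
  expect_true(all(cc[upper.tri(cc)] <= 0.5))

  one <- make_prototypes(4, 1, seed = 3)
  expect_equal(mean(one$maps), 0, tolerance = 1e-12)
  expect_equal(sum(one$maps^2), 1, tolerance = 1e-12)

  expect_error(make_prototypes(3, 4, seed = 1), "zero-mean maps")
  # unattainable separation must fail after bounded attempts
  expect_error(make_prototypes(6, 5, seed = 1, max_corr = 0.05,
                               max_tries = 25), "failed to draw")
})

test_that("a two-state chain with off-diagonal 1 strictly alternates", {
  tp <- rbind(c(0, 1), c(1, 0))
  s <- simulate_label_sequence(tp, c(60, 60), 250, 2000, seed = 5)
  segs <- s$segments
  expect_true(all(diff(segs$class) != 0))
  expect_equal(sort(unique(segs$class)), c(1L, 2L))
  # segments tile the record
  expect_equal(segs$start, cumsum(c(1, head(segs$length, -1))))
  expect_equal(sum(segs$length), 2000)
})

test_that("dwell means and transition frequencies converge to the generator", {
  tp <- default_tp(4)
  s <- simulate_label_sequence(tp, rep(80, 4), 250, 250000, seed = 1)
  f <- compute_features(s)
  expect_lt(max(abs(f$dur - 80) / 80), 0.05)
  expect_lt(max(abs(f$tp - tp)), 0.03)
})

test_that("synthesized EEG matches its generating prototypes sample-wise", {
  p <- make_prototypes(16, 3, seed = 2)
  s <- simulate_label_sequence(default_tp(3), c(80, 80, 80), 250, 1500,
                               seed = 3)
  corr_to_gen <- function(rec) {
    vapply(seq_along(s$labels), function(t) {
      spatial_corr(rec$data[, t], p$maps[s$labels[t], ])
    }, numeric(1))
  }

  clean <- simulate_eeg(p, s, noise_sigma = 0, polarity_flip_prob = 0,
                        seed = 4)
  expect_equal(corr_to_gen(clean), rep(1, 1500), tolerance = 1e-9)

  flipped <- simulate_eeg(p, s, noise_sigma = 0, polarity_flip_prob = 1,
                          seed = 4)
  cc <- corr_to_gen(flipped)
  expect_equal(abs(cc), rep(1, 1500), tolerance = 1e-9)
  seg_sign <- cc[s$segments$start]
  expect_true(all(abs(diff(sign(seg_sign))) == 2))  # alternating polarity

  noisy <- simulate_eeg(p, s, noise_sigma = 0.5, polarity_flip_prob = 0.5,
                        seed = 4)
  cn <- abs(corr_to_gen(noisy))
  expect_true(all(cn < 1))
  expect_gt(mean(cn), 0.6)   # class structure well above the noise floor
})

test_that("cohort planting: group effect and couplings hold by construction", {
  base <- synthetic_config(duration = 30, seed = 1)
  cfg <- cohort_config(dur_between_sd_ms = 0, score_noise_sigma = 0,
                       seed = 11)
  # zero between-subject jitter leaves only the planted slope for class A,
  # which the generator reports before flooring the residual variance
  expect_warning(co <- simulate_cohort(cfg, base, signals = FALSE),
                 "more spread")

  grp <- co$meta$group
  true_dur_c <- co$true_params$durs[, 3]
  expect_equal(mean(true_dur_c[grp == "healthy"]) -
                 mean(true_dur_c[grp == "patient"]), 25)

  tp_cd <- vapply(co$true_params$tp, function(m) m[3, 4], numeric(1))
  pat <- grp == "patient"
  expect_gt(cor(tp_cd[pat], co$meta$fma_total[pat]), 0)
  expect_lt(cor(co$true_params$durs[pat, 1], co$meta$fma_lower[pat]), 0)

  # every planted transition matrix stays stochastic with a zero diagonal
  for (m in co$true_params$tp) {
    expect_equal(unname(rowSums(m)), rep(1, 4), tolerance = 1e-9)
    expect_equal(diag(m), rep(0, 4),
                 ignore_attr = TRUE)
  }
  # healthy rows carry no scale scores; patient rows carry all four
  expect_true(all(is.na(co$meta$fma_total[grp == "healthy"])))
  expect_true(!anyNA(co$meta[pat, c("fma_total", "fma_upper",
                                    "fma_lower", "iadl")]))
})

test_that("out-of-range planted probabilities are clipped with a warning", {
  base <- synthetic_config(duration = 10, seed = 1)
  cfg <- cohort_config(tp_cd_slope = 0.05, tp_cd_sd = 0.65, seed = 2)
  expect_warning(co <- simulate_cohort(cfg, base, signals = FALSE),
                 "clipped")
  for (m in co$true_params$tp) {
    expect_equal(unname(rowSums(m)), rep(1, 4), tolerance = 1e-9)
    expect_true(all(m >= 0))
  }
})

test_that("ground-truth features equal an independent enumeration oracle", {
  s <- simulate_label_sequence(default_tp(4), c(80, 85, 95, 70), 250, 20000,
                               seed = 9)
  f <- compute_features(s)
  o <- features_oracle(s$labels, 250, 4)
  expect_equal(unname(f$dur), o$dur, tolerance = 1e-12)
  expect_equal(unname(f$occ), o$occ, tolerance = 1e-12)
  expect_equal(unname(f$cov), o$cov, tolerance = 1e-12)
  expect_equal(unname(f$tp), o$tp, ignore_attr = TRUE, tolerance = 1e-12)
})
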