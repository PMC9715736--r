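test_that("features match hand enumeration of a constructed 1 s sequence", {
  # 200 Hz so the 100/150 ms segments are whole samples:
  # A 100, B 150, A 100, C 150, A 100, B 150, A 100, C 150 (ms)
  ms <- c(100, 150, 100, 150, 100, 150, 100, 150)
  cls <- c(1L, 2L, 1L, 3L, 1L, 2L, 1L, 3L)
  labels <- rep.int(cls, ms / 1000 * 200)
  seq <- label_sequence(labels, fs = 200, k = 3,
                        class_labels = c("A", "B", "C"))
  f <- compute_features(seq)
  expect_equal(unname(f$dur), c(100, 150, 150))
  expect_equal(unname(f$occ), c(4, 2, 2))
  expect_equal(unname(f$cov), c(0.4, 0.3, 0.3))
  expect_equal(f$tp["A", ], c(A = 0, B = 0.5, C = 0.5))
  expect_equal(f$tp["B", ], c(A = 1, B = 0, C = 0))
  expect_equal(f$tp["C", ], c(A = 1, B = 0, C = 0))
})

test_that("a single segment yields occ = 1/T, cov = 1 and an all-zero TP", {
  seq <- label_sequence(rep(2L, 500), fs = 250, k = 3)
  f <- compute_features(seq)
  expect_equal(unname(f$occ), c(0, 0.5, 0))
  expect_equal(unname(f$cov), c(0, 1, 0))
  expect_true(all(f$tp == 0))
  expect_equal(f$absent, c(1L, 3L))
  expect_error(compute_features(label_sequence(rep(NA_integer_, 5),
                                               fs = 250, k = 2)),
               "empty label sequence")
})

test_that("coverage equals occurrence x duration for every class", {
  s <- simulate_label_sequence(default_tp(4), c(80, 85, 95, 70), 250, 30000,
                               seed = 51)
  f <- compute_features(s)
  expect_equal(unname(f$cov), unname(f$occ * f$dur / 1000),
               tolerance = 1e-9)
})

test_that("the example patient feature table satisfies the product identity", {
  tab <- read.delim(system.file("extdata", "example_patient_features.tsv",
                                package = "microstatr"), row.names = 1)
  recon <- unlist(tab["Occ", ]) * unlist(tab["Dur_ms", ]) / 1000
  expect_equal(round(unname(recon), 4), unname(unlist(tab["Cov", ])),
               tolerance = 5e-5)
})

test_that("mean GFP is averaged over each class's dominance samples", {
  labels <- c(rep(1L, 10), rep(2L, 10))
  gfp <- c(rep(2, 10), rep(4, 10))
  seq <- label_sequence(labels, fs = 250, k = 2)
  f <- compute_features(seq, gfp)
  expect_equal(unname(f$mean_gfp), c(2, 4))
  expect_error(compute_features(seq, gfp[1:5]), "length")
})

test_that("the cohort row export has the canonical 28-column layout", {
  s <- simulate_label_sequence(default_tp(4), rep(80, 4), 250, 10000,
                               seed = 52)
  f <- compute_features(s)
  meta <- data.frame(subject_id = "S1", group = "patient")
  row <- features_to_row(f, meta)
  expect_equal(names(row)[1:28], feature_columns())
  expect_equal(ncol(row), 30)
  expect_equal(row$Dur_B, unname(f$dur[2]))
  expect_equal(row$TP_CD, f$tp[3, 4])

  f3 <- compute_features(label_sequence(rep(1:3, each = 20), fs = 250, k = 3))
  expect_error(features_to_row(f3), "k = 4")
})

test_that("permuting class identities permutes the exported columns", {
  s <- simulate_label_sequence(default_tp(4), c(80, 85, 95, 70), 250, 20000,
                               seed = 53)
  f <- compute_features(s)
  perm <- c(3L, 1L, 4L, 2L)   # new order of the old classes
  s2 <- label_sequence(match(s$labels, perm), fs = 250, k = 4)
  f2 <- compute_features(s2)
  r1 <- features_to_row(f)
  r2 <- features_to_row(f2)
  cls <- c("A", "B", "C", "D")
  for (i in 1:4) {
    expect_equal(r2[[paste0("Dur_", cls[i])]],
                 r1[[paste0("Dur_", cls[perm[i]])]])
    expect_equal(r2[[paste0("Occ_", cls[i])]],
                 r1[[paste0("Occ_", cls[perm[i]])]])
  }
  expect_equal(r2$TP_AB, r1[[paste0("TP_", cls[perm[1]], cls[perm[2]])]])
})

test_that("NA gaps break transition counting and leave denominators clean", {
  labels <- c(rep(1L, 20), rep(2L, 20), rep(NA_integer_, 30), rep(3L, 20))
  seq <- label_sequence(labels, fs = 250, k = 3)
  f <- compute_features(seq)
  o <- features_oracle(labels, 250, 3)
  expect_equal(unname(f$dur), o$dur)
  expect_equal(unname(f$occ), o$occ)
  expect_equal(unname(f$tp), o$tp, ignore_attr = TRUE)
  expect_equal(f$tp[2, 3], 0)    # 2 -> 3 separated by the NA gap
  expect_equal(sum(f$cov), 1)
})
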