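proto_pair <- function() {
  structure(list(
    maps = rbind(c(1, -1, 1, -1) / 2, c(1, 1, -1, -1) / 2),
    k = 2L, labels = c("A", "B"), gev_per_class = c(NA, NA),
    diagnostics = list(), assignment = NULL,
    channel_labels = sprintf("Ch%02d", 1:4)
  ), class = "prototype_set")
}

test_that("winner-take-all labeling is polarity-ignorant with stable ties", {
  p <- proto_pair()
  cols <- cbind(p$maps[2, ],            # B
                -p$maps[2, ],           # -B -> still B
                p$maps[1, ],            # A
                p$maps[1, ] + p$maps[2, ],  # exact tie -> lowest index
                c(3, 3, 3, 3))          # flat -> unassigned
  seq <- assign_labels(rec_from_cols(cols, fs = 250), p)
  expect_equal(seq$labels, c(2L, 2L, 1L, 1L, NA))
  expect_false(is.null(seq$similarity))
  # flat sample excluded from segments
  expect_equal(sum(seq$segments$length), 4)
})

test_that("noiseless back-fit reproduces the generating sequence exactly", {
  p <- make_prototypes(24, 4, seed = 31)
  s <- simulate_label_sequence(default_tp(4), rep(85, 4), 250, 4000,
                               seed = 32)
  rec <- simulate_eeg(p, s, noise_sigma = 0, polarity_flip_prob = 0.5,
                      seed = 33)
  got <- assign_labels(rec, p)
  expect_equal(got$labels, s$labels)
})

test_that("a sub-threshold segment flanked by one class is absorbed into it", {
  p <- proto_pair()
  labels <- c(rep(1L, 10), rep(2L, 2), rep(1L, 10))
  sim <- cbind(matrix(c(.9, .1), 22, 2, byrow = TRUE))
  seq <- label_sequence(labels, fs = 250, k = 2, similarity = sim)
  sm <- smooth_labels(seq, 30)
  expect_equal(sm$labels, rep(1L, 22))
})

test_that("smoothing postconditions hold on rough random sequences", {
  set.seed(41)
  for (rep_i in 1:5) {
    labels <- sample(1:4, 600, replace = TRUE)  # deliberately fragmented
    sim <- matrix(runif(600 * 4), 600, 4)
    seq <- label_sequence(labels, fs = 250, k = 4, similarity = sim)
    sm <- smooth_labels(seq, 30)
    min_samples <- ceiling(30 / 1000 * 250)
    expect_true(all(sm$segments$length >= min_samples))
    # duration conserved, no new classes
    expect_equal(sum(is.na(sm$labels)), sum(is.na(seq$labels)))
    expect_true(all(unique(sm$labels) %in% unique(seq$labels)))
    # idempotent
    again <- smooth_labels(sm, 30)
    expect_identical(again$labels, sm$labels)
  }
})

test_that("already-smooth sequences pass through unchanged", {
  labels <- rep(c(1L, 2L, 3L), each = 25)   # 100 ms segments at 250 Hz
  seq <- label_sequence(labels, fs = 250, k = 3)
  expect_identical(smooth_labels(seq, 30)$labels, labels)
})

test_that("records shorter than the threshold collapse with a warning", {
  seq <- label_sequence(c(1L, 1L, 2L), fs = 250, k = 2,
                        similarity = matrix(0.5, 3, 2))
  expect_warning(sm <- smooth_labels(seq, 30), "single segment")
  expect_equal(length(unique(sm$labels)), 1)
})

test_that("edge-truncated segments survive when exempted", {
  labels <- c(rep(1L, 3), rep(2L, 40), rep(3L, 40), rep(1L, 2))
  sim <- matrix(runif(85 * 3), 85, 3)
  seq <- label_sequence(labels, fs = 250, k = 3, similarity = sim)
  strict <- smooth_labels(seq, 30)
  expect_true(all(strict$segments$length >= 8))
  exempt <- smooth_labels(seq, 30, boundary_exempt = TRUE)
  expect_equal(exempt$labels[1:3], rep(1L, 3))
  expect_equal(exempt$labels[84:85], rep(1L, 2))
})

test_that("label sequences round-trip through the run-length format", {
  s <- simulate_label_sequence(default_tp(4), rep(80, 4), 250, 2000,
                               seed = 71)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_label_segments(s, path)
  back <- read_label_segments(path)
  expect_equal(nrow(back), nrow(s$segments))
  expect_equal(back$class, s$segments$class)
  expect_equal(back$duration_ms, s$segments$length / 250 * 1000)
  expect_equal(back$label, LETTERS[s$segments$class])
})
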