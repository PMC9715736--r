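# Zero-mean orthogonal maps on 4 channels for exact small fixtures.
ortho4 <- list(v1 = c(1, -1, 1, -1) / 2,
               v2 = c(1, 1, -1, -1) / 2,
               v3 = c(1, -1, -1, 1) / 2)

test_that("polarity invariance forces a perfect single-prototype fit", {
  m <- ortho4$v1
  pm <- as_peak_maps(rbind(m, -m, 2 * m))
  fit <- modified_kmeans(pm, 1, n_restarts = 3, seed = 1)
  expect_equal(abs(spatial_corr(fit$maps[1, ], m)), 1, tolerance = 1e-12)
  expect_equal(fit$diagnostics$gev_total, 1, tolerance = 1e-12)
})

test_that("two orthogonal generators are recovered exactly from signed copies", {
  set.seed(2)
  n <- 200
  cls <- rep(1:2, each = n)
  sgn <- sample(c(-1, 1), 2 * n, replace = TRUE)
  gen <- rbind(ortho4$v1, ortho4$v2)
  pm <- as_peak_maps(gen[cls, ] * sgn)
  fit <- modified_kmeans(pm, 2, n_restarts = 10, seed = 3)
  cc <- abs(microstatr:::spatial_corr_matrix(fit$maps, gen))
  perm <- apply(cc, 1, which.max)
  expect_equal(sort(perm), 1:2)
  expect_equal(cc[cbind(1:2, perm)], c(1, 1), tolerance = 1e-9)
  # assignment accuracy 100% once fitted clusters are mapped to generators
  expect_equal(mean(perm[fit$assignment] == cls), 1)
})

test_that("GEV matches brute-force summation and its exact limits", {
  set.seed(4)
  pm <- as_peak_maps(matrix(rnorm(12 * 6), 12, 6))
  P <- matrix(rnorm(3 * 6), 3, 6)
  a <- sample(1:3, 12, replace = TRUE)
  got <- compute_gev(pm, P, a)
  # brute force from the definition
  num <- den <- 0
  for (i in 1:12) {
    x <- pm$maps[i, ]
    g2 <- sum((x - mean(x))^2)
    r <- spatial_corr(x, P[a[i], ])
    num <- num + g2 * r^2
    den <- den + g2
  }
  expect_equal(got$gev_total, num / den, tolerance = 1e-12)
  expect_equal(sum(got$gev_per_class), got$gev_total, tolerance = 1e-12)

  # every peak exactly +- a prototype -> GEV = 1
  exact <- as_peak_maps(rbind(ortho4$v1, -ortho4$v1, ortho4$v2))
  expect_equal(compute_gev(exact, rbind(ortho4$v1, ortho4$v2),
                           c(1L, 1L, 2L))$gev_total, 1, tolerance = 1e-12)
  # prototypes orthogonal to every peak -> GEV = 0
  expect_equal(compute_gev(as_peak_maps(rbind(ortho4$v1, ortho4$v1)),
                           rbind(ortho4$v2, ortho4$v3),
                           c(1L, 2L))$gev_total, 0, tolerance = 1e-12)
})

test_that("flipping the sign of any subset of peaks changes nothing", {
  p <- make_prototypes(16, 3, seed = 5)
  sim <- noisy_peak_maps(p, 150, 0.3, seed = 6)
  fit1 <- modified_kmeans(sim$peaks, 3, n_restarts = 5, seed = 7)

  flip <- rep(1, 150); flip[seq(1, 150, by = 3)] <- -1
  pm2 <- as_peak_maps(sim$peaks$maps * flip)
  fit2 <- modified_kmeans(pm2, 3, n_restarts = 5, seed = 7)

  expect_equal(fit1$diagnostics$gev_total, fit2$diagnostics$gev_total,
               tolerance = 1e-12)
  expect_equal(fit1$assignment, fit2$assignment)
  cc <- abs(microstatr:::spatial_corr_matrix(fit1$maps, fit2$maps))
  expect_equal(diag(cc), rep(1, 3), tolerance = 1e-9)
})

test_that("a 10-peak k=2 instance matches exhaustive partition search", {
  set.seed(8)
  pm <- as_peak_maps(matrix(rnorm(10 * 5), 10, 5))
  fit <- modified_kmeans(pm, 2, n_restarts = 25, seed = 9)

  # oracle: enumerate all 2-partitions; prototype of a part is the leading
  # eigenvector of its scatter; score by GEV
  X <- pm$maps - rowMeans(pm$maps)
  g2 <- rowSums(X^2)
  U <- X / sqrt(g2)
  best <- -Inf
  for (mask in 0:(2^10 - 1)) {
    a <- as.integer(intToBits(mask))[1:10] + 1L
    if (length(unique(a)) < 2) next
    gev <- 0
    for (c in 1:2) {
      M <- X[a == c, , drop = FALSE]
      v <- eigen(crossprod(M), symmetric = TRUE)$vectors[, 1]
      gev <- gev + sum(g2[a == c] * (U[a == c, , drop = FALSE] %*% v)^2)
    }
    best <- max(best, gev / sum(g2))
  }
  expect_equal(fit$diagnostics$gev_total, best, tolerance = 1e-9)
})

test_that("k-scan diagnostics behave on data with four true prototypes", {
  p <- make_prototypes(32, 4, seed = 10)
  sim <- noisy_peak_maps(p, 600, 0.3, seed = 11)
  sc <- scan_k(sim$peaks, k_range = 3:6, seed = 12, n_restarts = 8)

  expect_equal(sc$table$k, 3:6)
  expect_true(all(diff(sc$table$w) <= 0))          # dispersion shrinks with k
  expect_true(all(diff(sc$table$gev) >= -1e-9))    # GEV non-decreasing
  gain <- diff(sc$table$gev)
  expect_gt(gain[1], gain[2])                      # elbow at the true k = 4
  kl_known <- sc$table$kl[!is.na(sc$table$kl)]
  expect_equal(sc$table$kl[sc$table$k == 4], max(kl_known))
})

test_that("template labeling recovers permuted, sign-flipped prototypes", {
  templ <- microstate_templates(electrode_layout(64))
  shuffled <- templ
  ord <- c(3L, 1L, 4L, 2L)
  shuffled$maps <- templ$maps[ord, , drop = FALSE] * c(1, -1, 1, -1)
  shuffled$labels <- paste0("M", 1:4)
  shuffled$gev_per_class <- rep(0.25, 4)
  out <- label_prototypes(shuffled, templ)
  expect_equal(out$labels, c("A", "B", "C", "D"))
  expect_equal(attr(out, "matching"), match(1:4, ord))
  expect_equal(unname(attr(out, "match_corr")), rep(1, 4), tolerance = 1e-9)

  expect_error(label_prototypes(shuffled, templ$maps[1:3, ]), "equal k")
})

test_that("labeling survives template perturbation in nearly all seeds", {
  templ <- microstate_templates(electrode_layout(64))
  hits <- 0L
  for (s in 1:40) {
    set.seed(s)
    pert <- templ
    ord <- sample(4)
    pert$maps <- templ$maps[ord, , drop = FALSE] +
      matrix(rnorm(4 * 64, sd = 0.2 / sqrt(64)), 4, 64)
    pert$gev_per_class <- rep(0.25, 4)
    out <- label_prototypes(pert, templ)
    if (identical(attr(out, "matching"), match(1:4, ord))) hits <- hits + 1L
  }
  expect_gte(hits, 38L)   # >= 95% of seeds
})
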