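# Shared fixtures and independent oracles, built in code at test time.

# Recording whose columns (time samples) are given explicitly.
rec_from_cols <- function(cols, fs = 250, ...) {
  eeg_recording(as.matrix(cols), fs = fs, ...)
}

# Wrap a bare maps matrix (n x channels) as a peak_maps object.
as_peak_maps <- function(maps, fs = 250) {
  maps <- as.matrix(maps)
  structure(list(
    maps = maps,
    peak_indices = seq_len(nrow(maps)),
    peak_gfp = sqrt(rowMeans(sweep(maps, 1, rowMeans(maps))^2)),
    fs = fs,
    channel_labels = sprintf("Ch%02d", seq_len(ncol(maps)))
  ), class = "peak_maps")
}

# Peak maps drawn as signed prototypes plus channel noise (the clustering
# recovery fixture). noise_sigma is relative to the per-channel RMS of a
# unit-norm map.
noisy_peak_maps <- function(prototypes, n, noise_sigma, seed) {
  set.seed(seed)
  k <- prototypes$k
  nc <- ncol(prototypes$maps)
  cls <- sample.int(k, n, replace = TRUE)
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  maps <- prototypes$maps[cls, , drop = FALSE] * sgn +
    matrix(rnorm(n * nc, sd = noise_sigma / sqrt(nc)), n, nc)
  list(peaks = as_peak_maps(maps), classes = cls, signs = sgn)
}

# Independent enumeration oracle for microstate features: walks the label
# vector sample by sample (no rle, no shared code with the package).
features_oracle <- function(labels, fs, k) {
  n <- length(labels)
  seg_class <- integer(0); seg_len <- integer(0); seg_adj <- logical(0)
  cur <- NA_integer_; len <- 0L; gap <- TRUE
  for (t in seq_len(n + 1L)) {
    lab <- if (t <= n) labels[t] else NA_integer_
    if (!is.na(lab) && !is.na(cur) && lab == cur) {
      len <- len + 1L
    } else {
      if (!is.na(cur)) {
        seg_class <- c(seg_class, cur); seg_len <- c(seg_len, len)
        seg_adj <- c(seg_adj, !gap)
        gap <- FALSE
      }
      if (is.na(lab)) gap <- TRUE
      cur <- lab; len <- 1L
    }
  }
  labeled <- sum(seg_len)
  dur <- occ <- cov <- numeric(k)
  for (c in seq_len(k)) {
    lens <- seg_len[seg_class == c]
    if (length(lens)) {
      dur[c] <- mean(lens) / fs * 1000
      occ[c] <- length(lens) / (labeled / fs)
      cov[c] <- sum(lens) / labeled
    }
  }
  tp <- matrix(0, k, k)
  if (length(seg_class) >= 2) {
    for (i in 2:length(seg_class)) {
      if (seg_adj[i]) {
        tp[seg_class[i - 1], seg_class[i]] <-
          tp[seg_class[i - 1], seg_class[i]] + 1
      }
    }
    for (c in seq_len(k)) if (sum(tp[c, ]) > 0) tp[c, ] <- tp[c, ] / sum(tp[c, ])
  }
  list(dur = dur, occ = occ, cov = cov, tp = tp)
}

# Hand-coded Welch t-test (textbook formulas, independent of stats::t.test).
welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Hand-coded Pearson correlation with t-transform p.
pearson_oracle <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  n <- length(x)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

# Partial correlation via the residual-regression route: correlate the
# residuals of x ~ z and y ~ z.
partial_oracle <- function(x, y, z) {
  rx <- resid(lm(x ~ z)); ry <- resid(lm(y ~ z))
  pearson_oracle(rx, ry)$r
}

# Type-II sums of squares for a balanced two-factor design, by explicit
# model comparisons (no interaction, matching the package's additive fit).
anova2_oracle <- function(y, f1, f2) {
  rss <- function(fit) sum(resid(fit)^2)
  full <- lm(y ~ f1 + f2)
  ss1 <- rss(lm(y ~ f2)) - rss(full)
  ss2 <- rss(lm(y ~ f1)) - rss(full)
  df1 <- nlevels(factor(f1)) - 1; df2 <- nlevels(factor(f2)) - 1
  dfr <- length(y) - 1 - df1 - df2
  msr <- rss(full) / dfr
  list(F1 = (ss1 / df1) / msr, F2 = (ss2 / df2) / msr,
       p1 = pf((ss1 / df1) / msr, df1, dfr, lower.tail = FALSE),
       p2 = pf((ss2 / df2) / msr, df2, dfr, lower.tail = FALSE))
}

# Two-group one-feature table for the group-comparison tests.
cohort_df <- function(healthy, patient, feature = "Dur_C") {
  d <- data.frame(group = c(rep("healthy", length(healthy)),
                            rep("patient", length(patient))))
  d[[feature]] <- c(healthy, patient)
  d
}

# Small null / planted-effect cohort for statistics simulations.
null_cohort_config <- function(seed) {
  cohort_config(dur_c_effect_ms = 0, tp_cd_slope = 0, dur_a_slope = 0,
                seed = seed)
}
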