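test_that("Welch t equals the textbook formula and its degenerate limits", {
  x <- c(1, 2, 3); y <- c(1, 2, 3, 4, 5, 6)
  got <- welch_ttest_per_feature(cohort_df(x, y))
  o <- welch_oracle(x, y)
  expect_equal(got$statistic, o$t, tolerance = 1e-10)
  expect_equal(got$df, o$df, tolerance = 1e-10)
  expect_equal(got$p, o$p, tolerance = 1e-10)
  # Welch df never exceeds the pooled df
  expect_lte(got$df, length(x) + length(y) - 2)

  same <- welch_ttest_per_feature(cohort_df(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  const <- welch_ttest_per_feature(cohort_df(c(2, 2, 2), c(2, 2, 2)))
  expect_true(is.na(const$statistic))
  expect_match(const$note, "zero variance")
})

test_that("Welch reduces to Student's t for equal sizes and variances", {
  set.seed(61)
  x <- rnorm(10)
  y <- x + 0.7              # identical sample variance, shifted mean
  got <- welch_ttest_per_feature(cohort_df(x, y))
  st <- t.test(x, y, var.equal = TRUE)
  expect_equal(got$statistic, unname(st$statistic), tolerance = 1e-10)
  expect_equal(got$df, unname(st$parameter), tolerance = 1e-10)
  expect_equal(got$p, st$p.value, tolerance = 1e-10)
})

test_that("the BH flag adds adjusted p-values without changing raw ones", {
  set.seed(62)
  d <- data.frame(group = rep(c("healthy", "patient"), each = 6),
                  Dur_A = rnorm(12), Dur_B = rnorm(12), Dur_C = rnorm(12))
  raw <- welch_ttest_per_feature(d, c("Dur_A", "Dur_B", "Dur_C"))
  adj <- welch_ttest_per_feature(d, c("Dur_A", "Dur_B", "Dur_C"), fdr = TRUE)
  expect_equal(adj$p, raw$p)
  expect_equal(adj$p_adj, p.adjust(raw$p, "BH"))
})

test_that("Pearson correlation matches hand computation", {
  d <- data.frame(x = c(1, 2, 3, 4), y = c(2, 1, 4, 3))
  got <- pearson_corr(d, "x", "y")
  expect_equal(got$statistic, 0.6, tolerance = 1e-12)
  o <- pearson_oracle(d$x, d$y)
  expect_equal(got$p, o$p, tolerance = 1e-10)

  lin <- data.frame(x = 1:6, y = 2 * (1:6) + 3)
  expect_equal(pearson_corr(lin, "x", "y")$statistic, 1, tolerance = 1e-12)

  flagged <- pearson_corr(data.frame(x = c(1, 1, 1), y = 1:3), "x", "y")
  expect_true(is.na(flagged$statistic))
  expect_error(pearson_corr(data.frame(x = 1:2, y = 1:2), "x", "y"),
               "n >= 3")
})

test_that("partial correlation agrees with the residual-regression oracle", {
  set.seed(63)
  d <- data.frame(x = rnorm(20), z = rnorm(20))
  d$y <- 0.5 * d$x + 0.8 * d$z + rnorm(20, sd = 0.4)
  d$x <- d$x + 0.3 * d$z
  got <- partial_corr(d, "x", "y", "z")
  expect_equal(got$statistic, partial_oracle(d$x, d$y, d$z),
               tolerance = 1e-10)
  expect_equal(got$df, 17)

  # constant control reduces to the simple correlation
  d$const <- 5
  expect_equal(partial_corr(d, "x", "y", "const")$statistic,
               pearson_corr(d, "x", "y")$statistic, tolerance = 1e-12)
  # control collinear with y is undefined
  d$zcopy <- d$y
  expect_error(partial_corr(d, "x", "y", "zcopy"), "collinear")
})

test_that("uncorrelated controls leave the correlation nearly unchanged", {
  set.seed(64)
  n <- 2000
  d <- data.frame(x = rnorm(n), z = rnorm(n))
  d$y <- 0.6 * d$x + rnorm(n, sd = 0.8)
  simple <- pearson_corr(d, "x", "y")$statistic
  partial <- partial_corr(d, "x", "y", "z")$statistic
  expect_equal(partial, simple, tolerance = 0.02)
})

test_that("two-factor ANOVA matches a hand model-comparison oracle", {
  set.seed(65)
  d <- expand.grid(group = c("healthy", "patient"),
                   rep = 1:6, agebin = c("low", "high"))
  d$age <- ifelse(d$agebin == "low", 30, 60) + rnorm(nrow(d))
  d$Dur_C <- 90 + 12 * (d$group == "patient") + rnorm(nrow(d), sd = 5)
  got <- two_factor_anova(d, "Dur_C", c("group", "age"))
  f2 <- factor(ifelse(d$age <= median(d$age), "low", "high"),
               levels = c("low", "high"))
  o <- anova2_oracle(d$Dur_C, factor(d$group), f2)
  expect_equal(got$statistic, c(o$F1, o$F2), tolerance = 1e-10)
  expect_equal(got$p, c(o$p1, o$p2), tolerance = 1e-10)

  # constant response is flagged, not crashed
  d$flat <- 1
  flat <- two_factor_anova(d, "flat", c("group", "age"))
  expect_equal(flat$statistic, c(0, 0))
  expect_match(flat$note[1], "constant")

  # aliased factors are refused
  d2 <- data.frame(group = rep(c("healthy", "patient"), each = 6),
                   age = rep(c(25, 65), each = 6),
                   Dur_C = rnorm(12))
  expect_error(two_factor_anova(d2, "Dur_C", c("group", "age")), "aliased")
})

test_that("ANOVA separates a planted group effect from a null age factor", {
  set.seed(67)
  n <- 20
  rates <- rowMeans(vapply(1:200, function(i) {
    d <- data.frame(group = rep(c("healthy", "patient"), each = n / 2),
                    age = runif(n, 25, 75))   # overlapping age ranges
    d$Dur_C <- 90 + 10 * (d$group == "patient") + rnorm(n, sd = 5)
    res <- two_factor_anova(d, "Dur_C", c("group", "age"))
    c(group = res$p[1] < 0.05, age = res$p[2] < 0.05)
  }, logical(2)))
  expect_gte(rates["group"], 0.8)
  expect_lte(rates["age"], 0.12)    # ~nominal false-positive rate
})

test_that("the ANCOVA variant adjusts for continuous age", {
  set.seed(66)
  d <- data.frame(group = rep(c("healthy", "patient"), each = 12),
                  age = c(runif(12, 20, 40), runif(12, 40, 80)))
  d$Dur_C <- 95 - 0.1 * d$age - 20 * (d$group == "patient") +
    rnorm(24, sd = 8)
  got <- two_factor_anova(d, "Dur_C", c("group", "age"),
                          age_continuous = TRUE)
  a <- car::Anova(lm(Dur_C ~ group + age, data = d), type = 2)
  expect_equal(got$statistic, a[1:2, "F value"], tolerance = 1e-12)
  expect_equal(got$test, rep("ancova_F", 2))
})

test_that("simple regression recovers exact lines and the R2 = r2 identity", {
  d <- data.frame(x = c(0, 1, 2, 3.5, 7), y = 2 * c(0, 1, 2, 3.5, 7) + 1)
  fit <- linear_fit(d, "x", "y")
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  d2 <- data.frame(x = c(1, 2, 3, 4), y = c(2, 1, 4, 3))
  f2 <- linear_fit(d2, "x", "y")
  expect_equal(f2$r_squared, 0.36, tolerance = 1e-12)
  expect_equal(f2$r_squared, pearson_corr(d2, "x", "y")$statistic^2,
               tolerance = 1e-12)
  expect_error(linear_fit(data.frame(x = c(1, 1, 1), y = 1:3), "x", "y"),
               "zero variance")
})
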