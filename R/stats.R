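# Statistics layer over a cohort table (one row per subject: 28 feature
# columns + metadata). All p-values are two-tailed; the working
# significance level throughout the package is 0.05.

test_result <- function(feature, test, statistic, df, p, n,
                        ci_low = NA_real_, ci_high = NA_real_,
                        note = "") {
  data.frame(feature = feature, test = test, statistic = statistic,
             df = df, p = p, n = n, ci_low = ci_low, ci_high = ci_high,
             note = note, stringsAsFactors = FALSE)
}

#' Welch t-tests per feature between the two groups
#'
#' Unequal-variance two-sample t-test with Welch-Satterthwaite degrees of
#' freedom for each feature column, two-tailed. The statistic is
#' `mean(healthy) - mean(patient)` scaled by the Welch standard error. No
#' multiplicity correction is applied by default (each of the 28 features
#' is reported at its nominal p); Benjamini-Hochberg adjusted p-values are
#' added with `fdr = TRUE`.
#'
#' @param cohort Data frame with a `group` column (`healthy`/`patient`)
#'   and the feature columns.
#' @param feature_names Character vector of feature columns (default: the
#'   28 canonical columns present in `cohort`).
#' @param fdr Add a `p_adj` column (Benjamini-Hochberg).
#' @return Data frame of test results (one row per feature); features with
#'   zero variance in both groups are flagged in `note` with `NA`
#'   statistics.
#' @export
welch_ttest_per_feature <- function(cohort, feature_names = NULL,
                                    fdr = FALSE) {
  if (is.null(feature_names)) {
    feature_names <- intersect(feature_columns(), names(cohort))
  }
  stopifnot("group" %in% names(cohort), length(feature_names) >= 1)
  g <- cohort$group
  stopifnot(all(g %in% c("healthy", "patient")))
  out <- do.call(rbind, lapply(feature_names, function(f) {
    x <- cohort[[f]][g == "healthy"]
    y <- cohort[[f]][g == "patient"]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2) {
      return(test_result(f, "welch_t", NA_real_, NA_real_, NA_real_,
                         length(x) + length(y), note = "n < 2 in a group"))
    }
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      return(test_result(f, "welch_t", NA_real_, NA_real_, NA_real_,
                         length(x) + length(y),
                         note = "zero variance in both groups"))
    }
    tt <- stats::t.test(x, y, var.equal = FALSE)
    test_result(f, "welch_t", unname(tt$statistic),
                unname(tt$parameter), tt$p.value, length(x) + length(y),
                tt$conf.int[1], tt$conf.int[2])
  }))
  if (fdr) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Pearson correlation between a feature and a clinical scale
#'
#' Sample Pearson r with the two-tailed p from the t transform
#' (`df = n - 2`) and a 95% CI via the Fisher z transform. Rows with
#' missing values in either variable are dropped (healthy subjects carry
#' no scale scores, so scale correlations are effectively within the
#' patient group).
#'
#' @param cohort Cohort data frame.
#' @param feature,scale Column names.
#' @return One-row result data frame.
#' @export
pearson_corr <- function(cohort, feature, scale) {
  x <- cohort[[feature]]; y <- cohort[[scale]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  lab <- paste0(feature, "~", scale)
  if (n < 3) stop("pearson_corr needs n >= 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(test_result(lab, "pearson_r", NA_real_, n - 2, NA_real_, n,
                       note = "zero variance"))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  ci <- if (is.null(ct$conf.int)) c(NA_real_, NA_real_) else ct$conf.int
  test_result(lab, "pearson_r", unname(ct$estimate),
              unname(ct$parameter), ct$p.value, n, ci[1], ci[2])
}

#' Age-controlled partial correlation
#'
#' First-order partial correlation
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`
#' with the two-tailed p from the t transform at `df = n - 3` and a 95% CI
#' via Fisher z (`se = 1/sqrt(n - 4)`). With a constant control variable
#' it reduces to the simple correlation.
#'
#' @param cohort Cohort data frame.
#' @param feature,scale Column names to correlate.
#' @param control Control column (default `"age"`).
#' @return One-row result data frame.
#' @export
partial_corr <- function(cohort, feature, scale, control = "age") {
  x <- cohort[[feature]]; y <- cohort[[scale]]; z <- cohort[[control]]
  ok <- is.finite(x) & is.finite(y) & is.finite(z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  n <- length(x)
  lab <- paste0(feature, "~", scale, "|", control)
  if (n < 4) stop("partial_corr needs n >= 4 complete triples")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(test_result(lab, "partial_r", NA_real_, n - 3, NA_real_, n,
                       note = "zero variance"))
  }
  r_xy <- stats::cor(x, y)
  if (stats::var(z) == 0) {
    r_xz <- 0; r_yz <- 0   # constant control: partial == simple
  } else {
    r_xz <- stats::cor(x, z); r_yz <- stats::cor(y, z)
  }
  if (abs(r_xz) >= 1 - 1e-12 || abs(r_yz) >= 1 - 1e-12) {
    stop("partial correlation undefined: control is collinear with ",
         if (abs(r_xz) >= 1 - 1e-12) feature else scale)
  }
  r <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  r <- min(max(r, -1), 1)     # numeric guard
  df <- n - 3
  if (1 - r^2 < .Machine$double.eps) {
    p <- 0                    # perfect partial correlation
  } else {
    tval <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df)
  }
  ci <- c(NA_real_, NA_real_)
  if (n > 4 && abs(r) < 1) {
    zr <- atanh(r); se <- 1 / sqrt(n - 4)
    ci <- tanh(zr + c(-1, 1) * stats::qnorm(0.975) * se)
  }
  test_result(lab, "partial_r", r, df, p, n, ci[1], ci[2])
}

#' Two-factor ANOVA with type-II sums of squares
#'
#' Group-effect-on-feature analysis adjusting for age: either a two-factor
#' ANOVA with age binned at the cohort median (`age_continuous = FALSE`,
#' the default) or an ANCOVA with continuous age. Type-II sums of squares
#' (via [car::Anova()]) so factor order does not matter in unbalanced
#' designs; F and two-tailed p are reported per factor.
#'
#' @param cohort Cohort data frame.
#' @param response Response column name.
#' @param factors Length-2 character vector of factor columns (default
#'   `c("group", "age")`).
#' @param age_continuous Treat the second factor as a continuous covariate
#'   instead of a median-split bin.
#' @return Data frame with one row per factor.
#' @export
two_factor_anova <- function(cohort, response,
                             factors = c("group", "age"),
                             age_continuous = FALSE) {
  stopifnot(length(factors) == 2, response %in% names(cohort),
            all(factors %in% names(cohort)))
  d <- cohort[, c(response, factors)]
  d <- d[stats::complete.cases(d), ]
  f1 <- factor(d[[factors[1]]])
  v2 <- d[[factors[2]]]
  if (is.numeric(v2) && !age_continuous) {
    v2 <- factor(ifelse(v2 <= stats::median(v2), "low", "high"),
                 levels = c("low", "high"))
  } else if (!age_continuous) {
    v2 <- factor(v2)
  }
  if (nlevels(f1) < 2) stop("factor ", factors[1], " has a single level")
  if (!age_continuous && nlevels(factor(v2)) < 2) {
    stop("factor ", factors[2], " has a single level")
  }
  if (!age_continuous && all(rowSums(table(f1, v2) > 0) == 1)) {
    # every level of f1 falls entirely in one level of v2
    stop("factors ", factors[1], " and ", factors[2],
         " are aliased (confounded); the design cannot separate them")
  }
  dd <- data.frame(y = d[[response]], f1 = f1, f2 = v2)
  fit <- stats::lm(y ~ f1 + f2, data = dd)
  if (stats::var(dd$y) == 0) {
    return(do.call(rbind, lapply(factors, function(f) {
      test_result(f, "anova_F", 0, NA_real_, NA_real_, nrow(dd),
                  note = "constant response")
    })))
  }
  a <- car::Anova(fit, type = 2)
  out <- do.call(rbind, lapply(1:2, function(i) {
    test_result(factors[i], if (age_continuous) "ancova_F" else "anova_F",
                a[i, "F value"], a[i, "Df"], a[i, "Pr(>F)"], nrow(dd))
  }))
  attr(out, "residual_df") <- a[nrow(a), "Df"]
  out
}

#' Simple linear regression with R-squared
#'
#' Ordinary least squares `y ~ x`; for the single-predictor case
#' `R^2 = r^2` exactly (the identity used to report regression fits next
#' to correlations).
#'
#' @param cohort Cohort data frame.
#' @param x,y Column names (rows with missing values dropped).
#' @return List with `slope`, `intercept`, `r_squared`, `p` (slope,
#'   two-tailed), `n`.
#' @export
linear_fit <- function(cohort, x, y) {
  xv <- cohort[[x]]; yv <- cohort[[y]]
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3) stop("linear_fit needs n >= 3 complete pairs")
  if (stats::var(xv) == 0) stop("linear_fit undefined: x has zero variance")
  fit <- stats::lm(yv ~ xv)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared,
       p = s$coefficients[2, 4],
       n = length(xv))
}

#' Feature-scale correlation screen within the patient group
#'
#' Runs [pearson_corr()] and the age-controlled [partial_corr()] for every
#' feature x scale pair and returns the stacked results, the screen the
#' study design calls for after the group comparison.
#'
#' @param cohort Cohort data frame.
#' @param feature_names Feature columns (default the canonical 28).
#' @param scales Scale columns (default the four clinical scores).
#' @return Data frame of stacked results.
#' @export
scale_correlation_screen <- function(cohort, feature_names = NULL,
                                     scales = c("fma_total", "fma_upper",
                                                "fma_lower", "iadl")) {
  if (is.null(feature_names)) {
    feature_names <- intersect(feature_columns(), names(cohort))
  }
  out <- list()
  flagged <- function(lab, type, n, msg) {
    test_result(lab, type, NA_real_, NA_real_, NA_real_, n, note = msg)
  }
  for (f in feature_names) {
    for (s in scales) {
      out[[length(out) + 1L]] <- tryCatch(
        pearson_corr(cohort, f, s),
        error = function(e) flagged(paste0(f, "~", s), "pearson_r",
                                    nrow(cohort), conditionMessage(e)))
      out[[length(out) + 1L]] <- tryCatch(
        partial_corr(cohort, f, s),
        error = function(e) flagged(paste0(f, "~", s, "|age"), "partial_r",
                                    nrow(cohort), conditionMessage(e)))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
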