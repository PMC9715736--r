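#!/usr/bin/env Rscript
# Statistics over the cohort feature table from 02_microstates.R: Welch
# t-tests for all 28 features (16 per-class features + 12 transition
# probabilities), Pearson and age-controlled partial correlations of the
# features against the clinical scales within the patient group, the
# group-vs-age ANOVA / ANCOVA on Dur_C, and linear regressions for the
# significant scale correlations.
#
# Reads:  results/cohort_features.tsv
# Writes: results/welch_tests.tsv, results/scale_correlations.tsv,
#         results/anova.tsv, results/linear_fits.tsv

library(microstatr)

tab <- as.data.frame(data.table::fread("results/cohort_features.tsv",
                                       na.strings = "NA"))

welch <- welch_ttest_per_feature(tab)
data.table::fwrite(welch, "results/welch_tests.tsv", sep = "\t",
                   na = "NA", quote = FALSE)
sig_w <- welch[!is.na(welch$p) & welch$p < 0.05, ]
message("Group differences (Welch, p < 0.05): ",
        if (nrow(sig_w)) paste(sprintf("%s (t = %.3f, p = %.3f)",
                                       sig_w$feature, sig_w$statistic,
                                       sig_w$p), collapse = "; ")
        else "none")

corrs <- scale_correlation_screen(tab)
data.table::fwrite(corrs, "results/scale_correlations.tsv", sep = "\t",
                   na = "NA", quote = FALSE)
sig_c <- corrs[corrs$test == "pearson_r" & !is.na(corrs$p) &
                 corrs$p < 0.05, ]
message("Scale correlations (Pearson, p < 0.05): ",
        if (nrow(sig_c)) paste(sprintf("%s (r = %.3f, p = %.4f)",
                                       sig_c$feature, sig_c$statistic,
                                       sig_c$p), collapse = "; ")
        else "none")

# Age-adjusted analysis of the focal duration feature (the class labels of
# the data-driven frame are the pipeline's own; 04_recovery.R aligns them
# with the generator's classes).
durs <- welch[grepl("^Dur_", welch$feature), ]
focal <- durs$feature[which.min(durs$p)]
anova_bin <- tryCatch(
  two_factor_anova(tab, focal, c("group", "age")),
  error = function(e) {
    message("Median-split ANOVA not identifiable: ", conditionMessage(e))
    NULL
  })
anova_cont <- two_factor_anova(tab, focal, c("group", "age"),
                               age_continuous = TRUE)
data.table::fwrite(rbind(anova_bin, anova_cont), "results/anova.tsv",
                   sep = "\t", na = "NA", quote = FALSE)
message(sprintf("ANCOVA on %s: group F = %.3f (p = %.3f), age F = %.3f (p = %.3f)",
                focal, anova_cont$statistic[1], anova_cont$p[1],
                anova_cont$statistic[2], anova_cont$p[2]))

fits <- do.call(rbind, lapply(seq_len(nrow(sig_c)), function(i) {
  parts <- strsplit(sig_c$feature[i], "~", fixed = TRUE)[[1]]
  f <- linear_fit(tab, parts[1], parts[2])
  data.frame(feature = parts[1], scale = parts[2], slope = f$slope,
             intercept = f$intercept, r_squared = f$r_squared, p = f$p)
}))
if (!is.null(fits)) {
  data.table::fwrite(fits, "results/linear_fits.tsv", sep = "\t",
                     quote = FALSE)
  for (i in seq_len(nrow(fits))) {
    message(sprintf("Regression %s ~ %s: R^2 = %.4f", fits$feature[i],
                    fits$scale[i], fits$r_squared[i]))
  }
}
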