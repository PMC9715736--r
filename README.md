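# microstatr

Resting-state EEG **microstate analysis** in R, with a synthetic cohort
generator that provides known ground truth for every stage, and the
statistics layer used to compare a patient group against controls and to
relate microstate features to clinical scales (FMA, IADL).

Microstates are quasi-stable scalp potential topographies that recur in
resting EEG, each dominating for roughly 60–120 ms before yielding to the
next; resting recordings are conventionally described by four classes
A–D. The package is aimed at researchers who want the full pipeline —
segmentation, clustering, back-fitting, features, statistics — as tested,
scriptable R functions, plus a simulator to validate the pipeline end to
end where real recordings cannot be shared.

## The method

1. **Global field power.** For potentials $V_i(t)$ on $N$ electrodes,

   $$\mathrm{GFP}(t) = \sqrt{\tfrac{1}{N}\sum_{i=1}^{N}\big(V_i(t) - \bar V(t)\big)^2},$$

   the spatial standard deviation of the scalp map. Local maxima of
   GFP are the highest signal-to-noise topographies; the maps at those
   peaks ("original maps") are the clustering input
   (`compute_gfp()`, `find_gfp_peaks()`, `extract_peak_maps()`).

2. **Modified k-means** (`modified_kmeans()`): polarity-invariant
   clustering of the peak maps. Similarity between a map and a prototype
   is the squared spatial correlation, and each prototype update is the
   dominant eigenvector of its members' scatter rather than their mean.
   Fits are ranked by the global explained variance

   $$\mathrm{GEV} = \frac{\sum_p \mathrm{GFP}_p^2\,
     \mathrm{corr}^2(x_p, a_{(p)})}{\sum_p \mathrm{GFP}_p^2},$$

   with CV, dispersion (W) and Krzanowski–Lai diagnostics over
   k = 3..8 reported by `scan_k()`; k = 4 is the conventional choice for
   resting-state work and the package's default.

3. **Back-fitting** (`assign_labels()`): every sample gets the prototype
   with the highest absolute spatial correlation (winner-take-all), then
   segments shorter than 30 ms are absorbed into their flanks
   (`smooth_labels()`) — sub-stable states below that duration are not
   genuine microstates.

4. **Features** (`compute_features()`): per class, the mean duration
   (ms), occurrence rate (s⁻¹), coverage (time fraction) and mean GFP,
   plus the 4×4 transition-probability matrix with zero diagonal. The
   identity `cov = occ × dur` holds exactly.

5. **Statistics** (`welch_ttest_per_feature()`, `pearson_corr()`,
   `partial_corr()`, `two_factor_anova()`, `linear_fit()`): Welch
   t-tests over the 28 canonical features (16 per-class + 12 transition
   probabilities), Pearson and age-controlled partial correlations
   against clinical scales within the patient group, a group-vs-age
   ANOVA/ANCOVA, and simple regression with R².

The synthetic module (`make_prototypes()`, `simulate_label_sequence()`,
`simulate_eeg()`, `simulate_cohort()`) generates 64-channel, 250 Hz
recordings whose topography alternates among four separated prototype
maps by a semi-Markov process (geometric dwell times, zero-diagonal
transition matrix), with per-segment polarity flips, a smooth amplitude
envelope, and Gaussian sensor noise — plus two-group cohorts with a
planted class-C duration deficit and planted couplings between the C→D
transition probability and an FMA-like score and between the class-A
duration and a lower-limb-like score.

## Worked example

```r
library(microstatr)

cfg   <- synthetic_config(duration = 30, noise_sigma = 0.3, seed = 42)
sub   <- simulate_subject(cfg, subject_id = "demo")
rec   <- normalize_global(common_average_reference(sub$recording))
gfp   <- compute_gfp(rec)
peaks <- find_gfp_peaks(gfp, min_separation_ms = 10)   # 1564 peaks
fit   <- modified_kmeans(extract_peak_maps(rec, peaks), k = 4,
                         n_restarts = 20, seed = 1)
fit
#> <prototype_set> k = 4 (M1, M2, M3, M4), GEV = 0.9407

protos <- label_prototypes(fit, sub$prototypes)  # align to generators
seq    <- smooth_labels(assign_labels(rec, protos), min_duration_ms = 30)
compute_features(seq, gfp)
#> <microstate_features> 4 classes over 30.0 s labeled
#>                  A        B        C        D
#> Dur (ms)  101.2667 139.4783 132.4444 105.8667
#> Occ (1/s)   2.0000   2.3000   2.4000   1.5000
#> Cov         0.2025   0.3208   0.3179   0.1588
#> mean GFP    0.9630   1.0201   1.0338   0.9390
```

The four prototypes explain 94% of the GFP-weighted topographic variance
at the GFP peaks; after smoothing, each class dominates for ~100–140 ms
at a time, covers 16–32% of the recording, and (because the record was
normalized to unit mean GFP) has mean GFP near 1. Note that smoothing
raises mean durations above the generator's 60–120 ms dwell means: the
features of a smoothed sequence describe the *cleaned* segmentation.

## The analysis workflow

Numbered drivers under `analysis/` reproduce the full study on a
simulated cohort (12 patients + 12 controls):

```sh
Rscript analysis/01_simulate.R     # cohort EEG (scratch/) + ground truth
Rscript analysis/02_microstates.R  # features per subject, k-scan
Rscript analysis/03_stats.R        # Welch screen, scale correlations, ANCOVA
Rscript analysis/04_recovery.R     # estimated-vs-planted recovery checks
```

Small result tables are written under `results/`; bulky per-subject EEG
goes under `scratch/`.

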