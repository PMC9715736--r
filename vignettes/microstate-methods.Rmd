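---
title: "Microstate analysis: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate analysis: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microstatr)
```

## The model

Resting-state EEG topography does not drift continuously: it lingers in
one of a small set of quasi-stable scalp maps ("microstates") for tens of
milliseconds at a time and then switches abruptly. The analysis pipeline
operationalizes that picture in five steps: compute the global field
power (GFP), extract the scalp maps at GFP local maxima, cluster those
maps into k prototypes with a polarity-invariant k-means, back-fit every
sample to its best prototype, and summarize the resulting label sequence
as per-class features.

Two modelling commitments run through everything:

* **Polarity is ignored.** In resting EEG the generators oscillate, so a
  map and its sign reversal express the same configuration. Similarity
  is therefore `|spatial correlation|` (cosine similarity of channel-mean
  removed maps), the prototype update is the dominant eigenvector of the
  members' scatter (the polarity-invariant analogue of the mean), and
  back-fitting uses `|corr|` winner-take-all.
* **Segment-level first-order transitions.** The transition-probability
  feature conditions only on the current class, so the synthetic
  generator is the matching semi-Markov process: a first-order chain on
  segment classes (zero diagonal — self-transitions are meaningless)
  with per-class dwell distributions.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_separation_ms` (peak pruning) | 10 | ms | Below ~10 ms two GFP maxima sample the same topographic event; the larger peak survives. Configurable; 0 disables. |
| `k` (clusters) | 4 | – | The conventional resting-state choice; cross-study comparability outweighs per-dataset optimisation, so the k = 3..8 diagnostics (GEV, CV, W, KL) are reported but never auto-applied. |
| `n_restarts`, `max_iter`, `tol` | 20, 100, 1e-6 | –, –, rel. GEV | Best-of-restarts by GEV; convergence on the relative GEV change. 20 restarts make the 10-point k = 2 exhaustive-search check and the 4-generator recovery reproducible. |
| `min_duration_ms` (smoothing) | 30 | ms | Segments shorter than ~30 ms do not meet the sub-stability that defines a microstate; they are artifacts of noise at the winner-take-all step. |
| `noise_sigma` (generator) | 0.3 | ratio to clean-signal RMS | Sensor noise at which clustering recovery is still near-perfect but per-sample assignment is visibly degraded — a realistic regime for cleaned resting EEG. |
| `mean_durations_ms` (generator) | 80, 85, 95, 70 | ms | Inside the canonical 60–120 ms range, with class C longest and D shortest, the ordering typical of single-patient feature tables. |
| `dur_c_effect_ms`, `tp_cd_slope`, `dur_a_slope` | 25, 0.003, −1.664 | ms, prob/point, ms/point | Planted cohort effects; with the score geometry and between-subject spreads below, the slopes imply planted correlations ≈ +0.74 (C→D vs FMA-like total) and ≈ −0.64 (Dur_A vs lower-limb-like score). |
| `dur_between_sd_ms`, `tp_cd_sd` | 15, 0.052 | ms, prob | Between-subject spreads; 25 ms against a 15 ms sd puts the planted group effect at d ≈ 1.6, large but in line with a feature selected for significance at n = 12 + 12. |
| `score_noise_sigma` | 1 | scale points | Measurement noise of the clinical scales; it mildly attenuates the planted correlations, as rater noise would. |

## What the generator emulates — and what it does not

The generator reproduces the *structure* the pipeline relies on:
separated zero-mean unit-norm prototype maps (pairwise
`|corr| ≤ 0.5`, rejection-sampled), semi-Markov class dynamics,
per-segment polarity flips, a smooth positive amplitude envelope
(rectified moving-average Gaussian noise, ~40 ms correlation length,
floored at 0.25 before unit-mean scaling) so the GFP has genuine local
maxima *inside* segments, additive Gaussian sensor noise, and common
average referencing.

It deliberately does **not** emulate: 1/f spectral shape, ocular/muscle
artifacts, volume-conducted forward-model geometry, bad channels, or
line noise. Passing recovery tests therefore demonstrate that the
algorithms are correct and well-calibrated under the stated noise model;
they do not certify performance on uncleaned recordings — on real data
the upstream artifact pipeline (ICA-based cleaning, filtering) remains
the user's responsibility, of which only CAR, decimation, optional
band-pass and mean-GFP normalization are provided here.

Dwell times are geometric (memoryless, support from one sample),
parameterized by the per-class mean — the simplest law consistent with
segment-level first-order transitions. Its dispersion matters for test
design: the sd of a geometric dwell roughly equals its mean, so a 200 s
record at 80 ms mean dwell (~625 segments per class) estimates a class's
mean duration with ~3.2 ms sampling sd and each transition probability
with ~0.02 sd. Agreement much tighter than that needs longer records
(the convergence tests at 1000 s pass the 5% / ±0.03 bands comfortably;
at 200 s those same bands sit at ~1.3–1.6 sd and fail for many seeds
purely by sampling noise — a property of the estimator at that n, not a
defect of the implementation).

## Numerical choices

* **GFP** uses the population divisor N, exactly as the defining
  formula, not N−1.
* **Peak plateaus**: a flat run higher than both flanks counts once, at
  its first sample — deterministic and order-independent. Endpoints are
  never peaks. Pruning is greedy by descending amplitude (ties by
  earlier index), so within any close pair the larger peak survives.
* **Ties in winner-take-all** go to the lowest class index;
  spatially flat samples (zero variance) get an `NA` sentinel and are
  excluded from every feature denominator; `NA` runs also break
  transition adjacency.
* **Smoothing order**: the shortest sub-threshold segment is absorbed
  first (ties by earliest start); each of its samples moves to the flank
  whose prototype correlates better at that sample. The result is
  idempotent, conserves labeled duration, and never invents a class. By
  default edge-truncated segments are *not* exempt, so the output
  guarantee ("no segment below threshold") is unconditional; an
  exemption flag exists for users who prefer to keep truncated edge
  segments.
* **Empty clusters** re-seed from the worst-explained peak map.
* **Degenerate inputs** fail loudly: single-channel CAR, all-zero
  records, k exceeding the peak count, collinear partial-correlation
  controls, aliased ANOVA factors (the cohort pipeline catches the
  latter and reports a flagged row instead, see below).
* All randomness flows from explicit integer seeds; one master seed
  splits deterministically per subject and per restart, and the
  end-to-end pipeline is byte-reproducible from its config.

## Design choices where the convention is genuinely open

* **Normalization dialect.** "Normalize before segmentation" admits
  several readings; the package divides the whole record by its mean
  GFP. This removes global amplitude differences between subjects while
  preserving the relative GFP time course, so the per-class mean-GFP
  feature remains meaningful (per-sample unit-norm would destroy it).
  Downstream labels are invariant to global positive rescaling either way.
* **Occurrence** counts segment onsets per second of labeled time. This
  makes `cov = occ × dur` an exact identity, which published per-class
  feature tables satisfy to four decimals — the package ships one such
  single-patient table as `example_patient_features.tsv` and verifies
  the identity in its tests.
* **Class labeling.** Manual visual labeling is replaced by exact
  assignment (over all permutations, k ≤ 8) against either canonical
  layout templates — idealized A/B diagonal, anterior–posterior C and
  frontocentral D gradients on a sunflower-disk electrode layout — or a
  data-driven frame: two-stage group clustering (per-subject prototypes,
  then clustering of the pooled prototypes), GEV-ranked. For synthetic
  cohorts, whose generating maps are random, the data-driven frame is
  the default; it is internally consistent across subjects but is a
  permutation of the generator's classes, which the recovery driver
  aligns explicitly. The two "left-right" classes A and B are
  interpreted as the two opposing diagonals, the standard convention.
* **The group-vs-age analysis.** A two-factor ANOVA of group and age on
  a duration feature is ambiguous when the groups' age ranges barely
  overlap: the median-split design is then aliased and the package
  refuses it with an explicit error (the cohort pipeline reports the
  refusal as a flagged row). The ANCOVA variant (continuous age,
  type-II sums of squares) is reported alongside, and is the
  interpretable one under realistic stroke/control demographics.
* **No multiplicity correction by default** across the 28 Welch tests,
  matching common reporting practice for this design; Benjamini–Hochberg
  is available behind `fdr = TRUE` with the obvious caveat that a
  28-test screen at α = 0.05 expects one to two false positives.

## Problem sizes used by the tests and drivers

The packaged checks choose sizes that keep the whole suite fast while
leaving the statistics interpretable: clustering recovery uses 2000 peak
maps at `noise_sigma` 0.3; convergence checks use one 200 s and one
1000 s label sequence; the type-I/power calibration uses 1000 null and
500 planted-effect replicate cohorts of 12 + 12 subjects simulated at
the label-sequence level (60 s per subject — the Welch null calibration
is duration-independent, and the planted effect's detectability at that
duration was computed from the design, d ≈ 1.5); the planted-pattern
check runs 20 full-default cohorts (200 s). The analysis drivers
simulate 60 s recordings per subject; the EEG-level recovery checks run
single subjects at 20–30 s. Every such size is a deliberate choice of
the package, stated here so that users scaling up know which numbers
will tighten (estimator noise shrinks with record length as 1/√n_seg)
and which will not (type-I calibration).

## Known limitations

* The statistics layer reproduces a *design*, not any particular
  study's numbers: real patient EEG differs from the generator in all
  the ways listed above, and published t/r values from undeposited data
  are not reproducible targets.
* The smoothing estimator biases mean durations upward relative to the
  generator's dwell means (short segments are absorbed, not discarded);
  features of smoothed sequences describe the cleaned segmentation.
  Ground-truth comparisons therefore use unsmoothed sequences.
* Partial correlation is first-order only (one control variable).
* The EDF writer quantizes to 16 bits over the record's amplitude range
  and pads trailing partial seconds; round trips are exact only to
  quantization.
* With k > 8, template labeling would need a Hungarian solver; the
  exact permutation search is limited to the conventional range.
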