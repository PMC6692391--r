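---
title: "Methods: sleep phenotyping, locus subtyping and Mendelian randomization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep phenotyping, locus subtyping and Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleeptypes)
```

# Scope

`sleeptypes` implements the downstream, non-GWAS stages of a
daytime-sleepiness genetics analysis: extracting objective sleep and
circadian metrics from wrist accelerometry, scoring individuals with a
weighted genetic risk score (GRS), partitioning trait-associated loci into
biological subtypes by clustering their association signatures, combining
cohort evidence with Fisher's method, and interrogating causal hypotheses
with two-sample Mendelian randomization (MR). Genome-wide association
scanning itself (mixed-model GWAS, imputation, fine-mapping, enrichment) is
out of scope: the package starts from summary statistics, dosages and epoch
series.

Every stage has a seeded synthetic-data generator that plants a known
signal, so each method can be scored against ground truth.

# Actigraphy: the sleep-period-time window

## Model

The wrist z-angle (dorsal--ventral tilt, degrees) is near-constant while a
posture is held and jumps at posture changes. Sleep appears as a long block
of sustained postural stability. The detector therefore works entirely on
the absolute epoch-to-epoch change in z-angle:

1. `rolling_median_abs_change()` -- the absolute first difference of the
   z-angle (leading value repeated so the series keeps its length) is
   smoothed by a centered rolling median spanning 5 minutes. The median
   makes the statistic robust to isolated posture shifts.
2. `movement_threshold()` -- a data-driven threshold is taken as the 10th
   percentile (linear-interpolation quantile, `type = 7`) of the rolled
   series for the analysis day, scaled by a multiplier (below).
3. `detect_inactivity_bouts()` -- maximal runs of sub-threshold epochs of
   at least 30 minutes.
4. `merge_bouts_to_blocks()` -- bouts separated by strictly less than 60
   minutes merge transitively into blocks.
5. `detect_spt_window()` -- the longest block in the day is the
   sleep-period-time (SPT) window; ties go to the earliest block.
6. `detect_sleep_episodes()` -- inside the SPT window, maximal runs with
   rolled change below 5 degrees lasting at least 5 minutes are sleep
   episodes; episodes are separated by at least one non-stable epoch
   (5 seconds of wakefulness at the default epoch length).

Derived metrics per day (`compute_day_metrics()`): sleep duration (sum of
episode durations), sleep efficiency (sleep duration / SPT duration),
number of sleep bouts (episode count), sleep midpoint, L5 and M10 timing
(midpoints of the least-active 5-hour and most-active 10-hour
moving-average activity windows, reported as hours since the previous
midnight and midday respectively), and diurnal inactivity (inactivity-bout
time outside the SPT window). `summarize_person()` averages across days and
reports the sample SD (n − 1) of sleep duration; a single valid day yields
a missing SD.

## Numerical conventions

* **Analysis day.** Days run noon-to-noon so a nocturnal sleep window is
  never split; recordings are trimmed to the first noon.
* **Epoch grid.** Intervals are 1-based and half-open `[start, end)`.
  Durations are `end - start` epochs. The default epoch is 5 s, matching
  the episode-separation rule.
* **Rolling window.** The 5-minute window is rounded to an odd epoch count
  (61 at 5-s epochs) and centered; edge windows are truncated.
* **Threshold side.** Non-movement is `rolled <= threshold`. On a
  noiseless trace the rolled series is exactly zero through sleep and the
  10th percentile is zero; a strict inequality would classify nothing as
  still.
* **Threshold multiplier.** `run_actigraphy()` scales the 10th percentile
  by 15 by default (the calibration used by the heuristic's reference
  implementation), exposed as `threshold_multiplier`. The raw percentile
  cannot work under homoscedastic measurement noise: with ~8 h of sleep in
  a 24-h day, the 10th percentile of the rolled-change distribution falls
  *inside* the sleep-epoch noise distribution (its ~30th within-sleep
  percentile), so at most ~30% of sleep epochs can fall below it and no
  30-minute bout survives. The multiplier lifts the threshold clear of
  quiet-wear noise while staying far below waking movement. The primitive
  `movement_threshold()` itself defaults to multiplier 1 (it *is* the
  percentile).
* **One-epoch grid offset.** A change-based statistic can only certify
  stability from the *second* epoch of a constant-angle run: the entry
  transition occupies the first epoch's change value. Detected onset on a
  noiseless trace is therefore exactly one epoch (5 s) after the planted
  onset, and wake is exact. Tests assert this convention exactly.
* **Threshold scope.** The threshold is computed per analysis day by
  default (`threshold_scope = "day"`), with a per-recording option.

## What the generator emulates -- and what it does not

`gen_accel_trace()` plants one nocturnal sleep window per noon-to-noon day
(default 23:00--07:00): a constant posture angle with a configurable number
of discrete posture changes, optional daytime naps, independent
large-amplitude daytime wrist angles (SD 30 degrees), Gaussian measurement
noise everywhere (default 1 degree), and an activity channel (high by day,
near zero in planted stillness) for L5/M10. It does **not** emulate
non-wear, device miscalibration, gradual drowsy wind-down before sleep,
restless sleep with sustained movement, daylight-saving shifts, or
autocorrelated daytime behaviour. Passing recovery tests therefore show the
detector implements the heuristic correctly and tolerates the modelled
noise; they do not certify performance on real wear data with artefacts the
generator omits.

# Genetic risk scores and association

`compute_grs()` is the weighted allele score
$s_i = \sum_j w_j \, d_{ij}$ with dosages $d_{ij} \in [0, 2]$ coded on the
risk allele and weights from the discovery scan. Missing dosages are
mean-imputed per variant (logged) -- standard GRS practice. Orientation to
the risk allele (`orient_to_risk_allele()`) flips alleles so the primary
trait's beta is positive everywhere, complements the effect-allele
frequency, and flips companion-trait effects in tandem; it is an involution
and preserves $|z|$.

Association tests are ordinary least squares (`assoc_linear()`, two-sided
t-based p) and maximum-likelihood logistic regression (`assoc_logistic()`,
IRLS with tolerance 1e-8 and up to 50 iterations, Wald normal p, OR with
`exp(beta ± 1.96 se)` CI). Both adjust for caller-supplied covariates; the
usual set is age, sex, genotyping array and 10 principal components.
Short/long sleep indicators contrast < 7 h and > 8 h against the inclusive
7--8 h control band; frequent-insomnia cases are the "usually" responders.

`fisher_meta()` combines K independent cohort p-values as
$X = -2\sum_k \ln p_k \sim \chi^2_{2K}$. The package combines the
two-sided p-values as cohorts report them; direction consistency should be
checked separately on the betas. A zero p-value is rejected rather than
silently floored -- the caller chooses the floor. Bonferroni flags use the
strict `p < 0.05 / m` rule.

# Subtype clustering

Loci are points in the 4-dimensional space of association z-scores
(beta/SE) with accelerometer-derived sleep efficiency, sleep duration and
number of sleep bouts, and self-reported frequent insomnia -- all oriented
to the sleepiness-increasing allele. Distances are plain Euclidean on the
raw z-scores (no column standardisation: the z-scores already share a
scale). Agglomerative clustering (`stats::hclust`) is cut at k = 2;
**complete linkage is the default** since the published analysis does not
state a criterion, with average/single/Ward selectable -- the choice is
pinned for reproducibility and recorded in the output object.

`iterative_outlier_removal()` then loops: cluster, compute silhouette
coefficients $s_i = (b_i - a_i)/\max(a_i, b_i)$ (singletons score 0),
remove **all** loci with negative coefficients, recluster -- until every
coefficient is positive or 10 iterations. Removing all negatives per pass
matches an analysis that discards several misclustered loci in one
iteration. The full per-iteration audit trail (labels, silhouettes,
averages, removals) is retained and serialisable with
`write_cluster_audit()`.

`label_clusters()` names the two clusters semantically: the
sleep-propensity template over (efficiency, duration, bouts, insomnia) is
(+, +, −, −) -- risk alleles associated with *better*, longer, less
fragmented sleep; the inverse pattern is sleep fragmentation. A centroid
matching at least 3 of 4 template signs is propensity; ambiguous cases fall
back to total sign agreement with ties flagged.

The generator plants 10 propensity, 27 fragmentation and 5 off-template
loci by default with per-trait magnitude 3 and noise SD 1 -- the size and
composition of a 42-locus discovery set. Off-template outliers draw random
sign patterns distinct from both templates; those sharing three signs with
a template behave like noisy members and are legitimately absorbed rather
than removed, so the number of removed loci varies by seed. Median
adjusted Rand index against planted labels exceeds 0.9 across 100 seeds
under these conditions.

# Two-sample Mendelian randomization

`harmonize_instruments()` matches variants by ID, re-expresses outcome
effects on the exposure's effect allele (negating betas and complementing
EAF on swaps, resolving strand complements), and drops palindromic (A/T,
C/G) variants with exposure EAF in [0.42, 0.58] -- the conventional window
in which strand cannot be resolved from frequency.

With ratio estimates $\hat\beta_j = \hat\Gamma_j / \hat\gamma_j$ and
first-order weights $w_j = \hat\gamma_j^2 / \sigma_{\Gamma j}^2$
(`wald_weights()`; the exposure SE does not enter the weights, matching
the radial-plot x-axis of $\sqrt{w_j}$):

* **IVW** (`mr_ivw()`): fixed-effect estimate
  $\hat\beta = \sum w_j \hat\beta_j / \sum w_j$,
  $SE = (\sum w_j)^{-1/2}$, with Cochran's
  $Q = \sum w_j (\hat\beta_j - \hat\beta)^2$ on J − 1 df. Fixed-effect is
  the default (a multiplicative random-effects IVW is deliberately not
  duplicated here -- heterogeneity is handled by the Egger sensitivity
  analysis).
* **Radial MR-Egger** (`mr_radial_egger()`): least squares of
  $\hat\beta_j \sqrt{w_j}$ on $\sqrt{w_j}$ with a free intercept. The
  slope is the pleiotropy-adjusted causal estimate; the intercept captures
  directional pleiotropy. Rucker's Q is the residual sum of squares on
  J − 2 df, and SEs are scaled by the multiplicative overdispersion factor
  $\max(1, \sqrt{Q_R/(J-2)})$. Rucker's Q never exceeds Cochran's Q
  (nested models).
* **Diagnostics** (`instrument_strength()`): mean
  $F_j = \hat\gamma_j^2/\sigma_{\gamma j}^2$ and
  $I^2_{GX} = \max(0, (Q_{GX} - (J-1))/Q_{GX})$, the regression-dilution
  statistic for Egger.

`mr_analyze()` chains the stages, runs the Egger sensitivity analysis when
the Cochran Q p-value falls below 0.05 (heterogeneity indicating potential
horizontal pleiotropy), flags estimates at the multiple-testing-corrected
threshold (default 0.003), and with `reverse = TRUE` reruns the pipeline
with the tables swapped.

A caution on the reverse direction: swapping tables is only meaningful
when the instruments are relevant for the swapped exposure. On a simulated
null (zero causal slope) the swapped instruments have *no* effect on the
new exposure, and the reverse IVW estimate is a weak-instrument artefact,
not a null -- reverse analyses must use instruments selected for the
reverse exposure, as the package's tests do.

The instrument generator draws
$\gamma_j \sim N(0.068, 0.04)$, observed effects with SEs 0.014/0.01, and
a planted slope of 0.018 by default. These values put the simulated
instrument set in the strong-instrument regime reported for well-powered
anthropometric exposures -- mean F ≈ 33 and $I^2_{GX}$ ≈ 0.89 -- so the
recovery tests exercise the method where it is meant to operate. Pleiotropy
is planted as `none`, `balanced` (mean-zero) or `directional` (nonzero
mean), independent of $\gamma$ by default so the InSIDE condition Egger
relies on holds; an `inside_violation` switch correlates them, outside any
recovery guarantee. Binary cohort traits use a logistic link whose
intercept is solved numerically (`uniroot`, tolerance 1e-10) to hit the
requested baseline prevalence, keeping odds-ratio interpretation exact.

# Problem sizes and test design

The test-suite simulations use sizes chosen to make Monte-Carlo bounds
tight while keeping the default run fast on a single core: 50 seeds of
one-day traces for window recovery (±10 min in ≥95% of seeds), 500
replicates for IVW coverage (bound [0.92, 0.98]) and Cochran-Q size
(5% ± 3 binomial SEs), 200 for Egger intercept power, 100 random instances
per primitive for oracle equivalence at 1e-12, and 100 seeds for
clustering recovery. Every oracle is a definition-level brute-force
implementation kept independent of the package code; where an established
package implements the same statistic (`cluster::silhouette`,
`metafor::rma(method = "EE")`), it is used as an additional cross-check,
never as the implementation.

# Known limitations

* The actigraphy detector assumes calibrated z-angle input (or raw
  triaxial input converted via `z_angle_from_xyz()`); it performs no
  non-wear detection or device QC.
* The reproduction of the published 42-locus clustering (average
  silhouette 0.32 → 0.40, clusters of 10 and 27) requires the journal's
  supplementary locus-by-trait z-score table, which is not deposited in a
  programmatically retrievable archive; the corresponding test runs only
  when a user places that table at
  `inst/extdata/supp_data3_zscores.tsv`. Note the published counts leave
  one locus unaccounted for (42 − 4 removed = 38, but 10 + 27 = 37); the
  discrepancy is recorded, not resolved.
* Fixed-effect IVW and first-order weights are the only IVW variant;
  weighted-median/mode estimators, MR-PRESSO and multivariable MR are out
  of scope, and instruments are assumed pre-clumped (no LD handling).
* GRS effect scales from biobank-size cohorts are not reproducible at desk
  scale; the package implements the procedure and validates it on
  synthetic cohorts.
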