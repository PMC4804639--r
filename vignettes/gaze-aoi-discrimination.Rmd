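---
title: "Gaze AoI fixation metrics and count-over-cutoff discrimination: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaze AoI fixation metrics and count-over-cutoff discrimination: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeclass)
```

## The problem

Adolescents and adults with autism spectrum disorder (ASD) allocate gaze
differently from typically developing (TD) peers when viewing short social
movies: less time on eyes and on people, more on mouths and geometric
patterns. A two-minute battery of eight movies (five human-face clips, one
upright-vs-inverted biological-motion clip, two people-vs-geometry clips)
measured on a 1280 x 1024 display at 50 Hz summarises each participant by
*percentage fixation time* per named area of interest (AoI):

$$\mathrm{fix}_{s,a} = 100 \cdot
\frac{\#\{\text{valid samples in AoI } a \text{ of stimulus } s\}}
     {\#\{\text{scheduled samples of stimulus } s\}}.$$

The denominator is the full stimulus duration, *including* samples where
the tracker lost the eyes. That choice is deliberate: it matches how the
device reports its numbers and explains why per-stimulus columns do not sum
to 100 — the missing share is tracker dropout, not attention. A session's
*availability* is the valid share of all 4000 scheduled samples; a
participant below 80% (strict `<`) is excluded before any statistics.

The pipeline then runs, in order: independent t tests per AoI with
per-stimulus Bonferroni levels, pooled-SD Cohen's d effect sizes,
within-group correlations against SRS (social responsiveness, 0-195) and
FSIQ, rank-based ROC analysis with direction-aware Youden cutoffs, and a
count-over-cutoff panel classifier reported with sensitivity, specificity,
and likelihood ratios for every count threshold.

## Raw-sample dwell, not fixation events

"Fixation time" here is raw-sample dwell: no I-VT/I-DT event detection,
velocity filtering, blink interpolation, or gap filling. The percentages
come straight off the 50 Hz samples, which is both what the reference
device computes and the only quantity the downstream statistics consume.
Rectangles are half-open (`[x0, x1) x [y0, y1)`, origin top-left, pixel
units), so a sample on a shared edge can never be counted in two AoIs.

The AoI rectangles themselves are documented placeholders: the device's
exact geometry is proprietary. An eyes band and a mouth strip inside the
face region, inset left/right half-screens for the side-by-side movies,
and a lower-right window for the picture-in-picture movie. Geometry only
affects the simulator and the sample counting, never the statistics, and
is fully configurable through the battery JSON
(`system.file("extdata", "battery_default.json", package = "gazeclass")`).

## The synthetic cohort generator

No per-participant data are published, so every stage is exercised against
a seeded synthetic cohort whose *defaults are the study conditions*: 26 ASD
and 35 TD males; five ASD participants with session availabilities of
exactly 60, 58, 53, 52 and 31 percent (the published exclusion cases);
SRS 111.8 +/- 18.5 (ASD, four missing) and 53.6 +/- 16.9 (TD); FSIQ
99.8 +/- 13.5 in the ASD group; and per-AoI fixation targets equal to the
published group means and SDs.

The latent attention model, per participant x stimulus:

1. draw each AoI's dwell proportion from a normal with the item's group
   mean/SD, truncate to [0, 100];
2. if the within-stimulus sum exceeds the participant's valid share
   (100 - invalid%), rescale the proportions onto that ceiling; the
   remainder is out-of-AoI time;
3. emit every scheduled 20 ms sample independently: invalid with
   probability (1 - availability), otherwise landing in an AoI (uniform
   inside its rectangle) or the out-of-AoI region per the profile.

There is deliberately **no saccade or dwell-length model**: the analysis
consumes only time-aggregated percentages, so temporal autocorrelation
would add parameters the acceptance surface cannot constrain. Equally, the
AoI draws are independent across stimuli: nothing is published about a
participant's covariance across the battery, and the one knob that exists
(`srs_gaze_correlation`, default 0) reflects the near-null published
within-group correlations between gaze and SRS.

### Moment calibration

Truncation and sum-rescaling bias the realized moments away from the
configured targets — by up to six percentage points at the published
values if the latent normals are used naively. Because the generator's
contract is to reproduce the published group structure *in distribution*,
it calibrates the latent normal parameters per (group, stimulus) with a
damped fixed-point iteration (realized mean error feeds back into the
latent mean; realized/target SD ratio into the latent SD) on a private,
fixed-seed draw set, so calibration is deterministic, independent of the
user's seed, and memoised. With SD-0 targets the latent model is left
untouched, preserving the exact degenerate limit.

One stimulus is special: the biological-motion clip's published AoI means
sum to 97.4%, *above* the ~95.3% availability ceiling the per-sample
validity model imposes. Those targets are jointly unattainable; the
calibration shares the unavoidable deficit across the two AoIs in
proportion to their targets (about 2pp each for the ASD group, under 1pp
for TD). All other items recover their target means within 1.5pp and SDs
within 15% relative at n = 2000 per group, which is what the recovery
property test asserts (with the biological-motion exception held to a
measured 2.75pp bound).

### What the simulator does and does not establish

Passing tests on synthetic cohorts show that the *pipeline arithmetic* is
right and that cohorts with the published first and second moments yield
the published separability. They do not validate distributional shape
against real gaze data: the published AUC of .74 for the people region is
slightly below its binormal value (.755), while the calibrated
truncate-and-rescale model sits slightly above (~.79), because the
validity ceiling compresses the upper tail of the TD distribution. The
moments pin down everything the tables publish; the shapes remain a model
choice, and that residual gap (~0.05 on one AUC) is visible in the
acceptance checks rather than hidden by retuning.

## Statistical conventions

* **t tests.** Summary-level recomputation supports both the pooled
  (df = n1 + n2 - 2) and Welch variants; the published t column is a mix
  (the still-image eyes row matches pooled, the blinking eyes row matches
  Welch), so raw-data comparisons default to the classical convention: a
  centre-mean Levene test at 0.05 picks the variant per item
  (`variant_policy = "levene"`; explicit `"pooled"`/`"welch"` available).
* **Cohen's d** always uses the df-weighted pooled SD regardless of the t
  variant — every published d value matches that form — with d > 0.5
  medium and d > 0.8 large.
* **Bonferroni levels** are per stimulus: 0.05 / (number of AoIs), i.e.
  0.025 for two-AoI stimuli and 0.05 for the single-AoI one. The
  availability comparison is a preliminary test outside these families.
* **Correlations** are Pearson product-moment, uncorrected at 0.05,
  pairwise-complete — mirroring how the correlation table is starred.
* **AUC** is the Mann-Whitney statistic from midranks, oriented so the
  ASD-typical direction scores positive; confidence intervals use the
  Hanley-McNeil normal approximation (the published CI method is
  unstated, so the printed intervals are shipped as fixtures rather than
  asserted).
* **Cutoffs** maximise Youden's J over midpoints between adjacent distinct
  pooled values plus one candidate beyond each extreme; ties break toward
  higher specificity, then toward the more conservative threshold. The
  published integer cutoffs ("<81", ">31") are treated as report-level
  rounding and are also shipped as fixtures so the published classifier
  can be applied verbatim.

## The count-over-cutoff classifier

A participant is labelled ASD at threshold k when **at least k** panel
items meet their strict directional cutoff. The published threshold labels
">N" are implemented as "at least N": that is the only reading under which
the published breakdown counts reproduce every printed row (20/21 = 95.2%
sensitivity at N = 1), so the accompanying prose "more than N items" is
treated as loose wording. This is the single most consequential
interpretation in the package.

Reported likelihood ratios derive from the one-decimal-rounded
sensitivity/specificity percentages (half away from zero), which is how
such tables are printed — e.g. 81.0 / (100 - 80.0) = 4.05 -> 4.1, where
the unrounded proportions give 4.05 -> 4.0. Exact proportions are kept in
the same output row. A specificity of 1 yields an `Inf` PLR sentinel with
a warning, never an error.

The all-eight-item panel (`panel = "all-aoi1"`) runs through the same
sweep, but its published row is not numerically reproducible: no
per-participant eight-item breakdown is published, so that configuration
is covered by the procedure, not by value assertions.

```{r fixture-mode}
fm <- fixture_mode()
fm$panel
fm$metrics[c("k", "sensitivity_pct", "specificity_pct",
             "plr_report", "nlr_report")]
```

## Numerical and degenerate-input choices

* Availability draws for retained participants are truncated normals on
  [82, 100] (inverse-CDF, exact), so binomial sampling noise in a 4000-
  sample session cannot push a nominally retained participant under the
  80% line; the five low-availability cases are set to their published
  values exactly.
* Equal availability threshold is *retention* (`>= 80`); exclusion is
  strict `<`, as published.
* A t statistic with both SDs zero and equal means raises a classed
  `gf_undefined_statistic` error rather than returning NaN; zero-variance
  covariates do the same for correlations.
* Out-of-AoI samples are placed by rejection from the screen rectangle;
  a geometry whose AoIs tile the whole screen combined with nonzero
  out-of-AoI mass raises a generation error.
* All randomness flows from one root seed to per-participant substream
  seeds, so any participant's stream is reproducible in isolation and
  cohort CSVs are byte-identical across runs; the calibration RNG is
  private and restores the caller's RNG state.

## Problem sizes

The test suite exercises the study-scale cohort (26 + 35 participants,
244,000 gaze samples) end to end, and the distributional checks
(moment recovery, empirical AUC) at n = 2000 per group via the streaming
simulator, which reduces each participant's stream to its fixation record
immediately; both sizes were chosen as the smallest at which the
quantities under test are stable relative to their tolerances.

## Limitations

* In-sample only: cutoffs are derived and evaluated on the same cohort,
  exactly as in the source analysis. No cross-validation or resampled
  intervals for sensitivity/specificity are claimed.
* The simulator emulates marginal moments, validity, and missingness —
  not saccade dynamics, calibration error, head pose, or the true joint
  distribution across items.
* A screening panel of this kind is a supplementary signal, not a
  diagnostic instrument; the package's outputs should be read accordingly.
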