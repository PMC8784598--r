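---
title: "Methods: simulating and analyzing a smartphone digital-phenotyping cohort"
author: "phenocap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing a smartphone digital-phenotyping cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenocap)
```

## The scientific setting

phenocap models a four-week observational digital-phenotyping study of
college students with elevated stress, in which a smartphone app collects
two kinds of longitudinal data: *active* data (a biweekly battery of
standard psychometric instruments) and *passive* data (GPS fixes,
accelerometer activity, and screen on/off events). Participants state at
enrollment whether they believe they were exposed to COVID-19 ("Yes",
"No", or "Unsure, but I think so"); the analysis compares the
exposed-or-unsure group with the non-exposed group on survey totals,
individual survey items, and three passive behavioral features: daily home
time, nightly sleep duration, and daily screen duration.

Because the original raw data are not publicly deposited, the package is
built around a seeded synthetic cohort generator whose ground truth makes
every downstream stage testable: feature extractors are judged by
parameter recovery against the generator's truth, and the inference layer
is judged by Monte-Carlo calibration, while the handful of numbers that
*are* derivable from the published summaries (demographic percentages,
interval reconstructions, one-sided p-values, the ~30-minute sleep gap)
are reproduced exactly.

## The synthetic cohort

### Recruitment funnel and eligibility

`generate_cohort()` draws `n_recruited` students (default 695) and thins
them through three stages — app usage, biweekly-survey completion, and
response to the exposure question — with default retention ratios
612/695, 507/612 and 382/507. Two attrition modes exist: `"exact"`
retains `round(n * p)` participants per stage (a seeded random subset),
which reproduces the published stage counts 695 → 612 → 507 → 382
deterministically; `"bernoulli"` flips an independent coin per
participant, which is the realistic counterpart used in the funnel
monotonicity property tests.

Eligibility requires an enrollment Perceived Stress Scale (PSS) score of
at least 14 ("at least moderate stress"). Since the study screened before
enrollment, the generator draws enrollment PSS conditional on the gate by
default (discretized truncated normal, latent mean 20, SD 5);
`apply_eligibility()` exists as a standalone filter for unscreened
rosters.

The exposed-or-unsure proportion is never published. The interval widths
of the published item-level comparison table, however, pin it down: with
group sizes (54, 328) the pooled-variance t computed from the printed
"Meaning" means and SDs equals the printed 2.47 (we obtain 2.475). The
generator therefore defaults to `p_exposed_or_unsure = 54/382`.
Participants who never answer the exposure question still receive a
*latent* exposure group so that their sensor and survey behavior is drawn
from the same mixture; the raw answer string is retained alongside the
derived group for auditability.

### Behavioral ground truth

Each participant owns true parameters: sleep onset clock time
(N(23:30, 0.5 h), truncated to 21:00–02:00), true nightly sleep duration,
daily screen hours (truncated N(5, 1.5) on [0.5, 12]), and home fraction
(truncated N(0.70, 0.10) on [0.30, 0.95]). Sleep is parameterized as the
non-exposed mean (7.0 h) minus an exposed-group deficit (0.48 h, the
published ~30-minute shortfall), with between-participant SD 0.45 h
truncated to [3, 7.9] h. Two deliberate choices here:

* the *deficit*, not the printed group means (7.25/6.77 h), is the primary
  parameter: the printed values are means of the study's own capped
  estimator, not of true sleep;
* the upper truncation at 7.9 h keeps every true duration strictly inside
  the 8-h estimation window. A sleeper whose true duration fills the whole
  window leaves no awake epochs inside it, and no within-window threshold
  rule can then distinguish sleep from wake; keeping truth measurable
  separates "estimator wrong" from "estimand undefined" in the recovery
  tests, and the narrow truncation keeps the realized group gap close to
  the configured deficit.

Home and screen parameters carry no group effect, matching the null
findings they emulate (home time was hypothesized to differ and did not;
screen time was an explicit negative control).

### Raw streams

For each study date the generator emits (`generate_participant_streams()`):

* **GPS** fixes every 300 s across the day, at the home coordinate during
  the day's true home intervals and at one of two away coordinates
  otherwise, with 20 m Gaussian positional noise. Time away from home is a
  single contiguous block centered on 13:00 local, sized by the home
  fraction.
* **Accelerometer** 60-s activity epochs covering the night's overnight
  interval (18:00–10:00) — the only span the sleep feature reads. Activity
  is an abstract non-negative score: awake epochs draw from N(1.2, 0.35)
  and asleep epochs from N(0.05, 0.015), both floored at zero. The night's
  realized sleep interval jitters around the participant's true onset and
  duration (SD 0.15 h each) and is recorded as ground truth.
* **Screen** events as strictly alternating on/off pairs: 15 bouts per day
  inside 10:00–23:00 local, with exponential-stick-breaking bout and gap
  lengths normalized so bouts sum *exactly* to the participant's true daily
  screen hours (up to millisecond rounding of event times).

Timestamps are UTC epoch milliseconds; each participant carries a fixed
UTC offset (default −300 min) and all clock-time logic (overnight
intervals, day buckets) runs in local time. A per-participant RNG lane
derived from the config seed makes streams reproducible independently of
generation order. The generator deliberately does *not* model real-world
sampling jitter, battery-driven gaps, device heterogeneity, or travel
beyond two away locations; what passing recovery tests show is that the
estimators are correct on clean, well-covered streams, not that they are
robust to field data pathologies.

### Survey responses

Item responses are drawn from a discretized truncated normal: a latent
normal is rounded to the nearest scale point with tails absorbed at the
scale ends. Rounding and truncation shift the mean of the resulting
discrete distribution away from the latent location — for an item with
target mean 0.50 and dispersion 0.99 on a 0–3 scale, naive rounding of
N(0.50, 0.99) yields a mean near 0.7. `item_sampler()` therefore
calibrates the latent location by root finding until the discrete
expectation equals the configured target *exactly*; the published
item-level group means are then recovered by construction in expectation,
and the law-of-large-numbers tests check the sample mean against the
target at n = 10,000. The latent SD acts as a dispersion parameter; the
realized SD of the discrete distribution (`sd_analytic`) is what sample
SDs converge to. Participant item expectations equal their group means
(no extra between-person latent variance); one consequence is that
averaging over three administrations shrinks participant-level SDs by
about √3 relative to the published single-administration SDs, so group
effects reach significance more easily in the synthetic cohort than in
the published table — a feature to remember when reading the workflow
output, and irrelevant to the type-I calibration, which removes all
effects.

## Passive features

### Significant locations and home time

The GPS clustering the home-time feature needs is not specified in the
source beyond "weighted traveled regions of significance", so the package
uses the simplest deterministic, order-stable rule that is easy to verify
against an oracle: single-pass centroid agglomeration. Each fix, in time
order, joins the nearest existing cluster if that centroid is within
`eps_m` (haversine, default 100 m; chosen above the ~60 m spread of
noisy same-place fixes and below typical between-place distances),
otherwise it opens a new cluster; centroids are running means. Cluster
weights are fractions of all fixes, so they sum to one when every cluster
is reported; sub-threshold clusters are dropped from the report without
re-normalizing.

Home is the cluster holding the most fixes between 00:00 and 06:00 local
(ties to the earlier-formed cluster); with no overnight fixes the
highest-weight cluster is used and flagged. Daily home time accrues the
interval between consecutive home-assigned fixes no more than `gap_max_s`
(600 s) apart, split across the local dates it overlaps. Days with fixes
but no home presence score 0; days with no fixes are missing, never zero.

### Sleep duration

The sleep estimator follows the published two-stage design: first the
8-h window inside the 18:00–10:00 overnight interval minimizing mean
activity pooled across all usable nights (candidate starts every 10 min,
missing epochs excluded, ties to the earliest start; nights need ≥ 50%
epoch coverage); then a per-night refinement. The published description of
the nightly adjustment stops at "adjusted based on the accelerometer
activity", so the package commits to an explicit, testable rule: the
window may shift by up to ±2 h (same 10-min grid, clipped to the
interval) to minimize that night's mean activity, and the asleep
threshold is the midpoint of the means of the lower and upper halves of
the night's sorted in-window activities. Epochs strictly below the
threshold — or exactly zero, since perfect stillness is sleep regardless
of any threshold — count as asleep. The zero rule resolves the two
degenerate cases coherently: an all-zero window scores the full 8 h,
an all-equal positive window scores 0 h. Correctness is judged by
ground-truth recovery (nightly estimates within ±0.5 h of truth; group
means within sampling error), not by matching the original
implementation, which is not available.

The night of date *d* runs from 18:00 on *d−1* to 10:00 on *d* and its
sleep is attributed to *d*, fixing the midnight-crossing ambiguity.

### Screen duration

Each "on" is paired with the next "off"; repeated "on" keeps the first,
stray "off" is ignored, a trailing "on" is dropped, and malformed counts
are reported. Bout portions accrue to the local dates they overlap. The
published method sentence also mentions motion data in passing; the role
is unexplained and screen duration here is computed from screen state
alone. The pairing is verified against an independent interval-sweep
oracle on random event streams.

## Survey scoring

The battery and its scales: PHQ-9 (9 × 0–3), GAD-7 (7 × 0–3), PSS
(10 × 0–4, items 4, 5, 7, 8 reverse-keyed), UCLA Loneliness (20 × 1–4),
PQ-16 (16 × 0–3), PSQI (9 × 0–3) and D-WAI (6 × 1–7), all summed. Two
scales deserve comment. The standard PQ-16 is a binary endorsement
checklist, but the published item means reach 1.46 with SDs above 1 and
group totals near 11.8 — only an ordinal 0–3 per-item variant (max 48) is
consistent with those numbers, so that is what the package implements.
Likewise the published PSQI tabulates nine 0–3 frequency questions with
biweekly totals near 7 and 5.8, indicating a shortened frequency
adaptation (max 27) rather than the canonical 7-component instrument; the
package implements the 9-item variant under the explicit id `PSQI9`.

Normalization divides the raw score by the instrument maximum, the
simplest reading of putting surveys "on the same scale"; whether the
original analysis normalized by maximum or z-scored is not stated, and
the choice only rescales within-instrument comparisons, leaving t
statistics unchanged. Participant scores are means over the
administrations each participant completed; a participant with none is
missing for that instrument.

## Group inference

Comparisons are Student's pooled-variance two-sample t-tests computed
from group summaries,

t = (m₁ − m₂) / (s_p √(1/n₁ + 1/n₂)),  s_p² = ((n₁−1)s₁² + (n₂−1)s₂²) / (n₁+n₂−2),

with df = n₁ + n₂ − 2. Two conventions are fixed by reconstruction from
the published table rather than by its labels:

* **Sidedness.** The printed p-values 0.56 for t = −0.14 and 0.12 for
  t = 1.17 are only consistent with a one-sided upper-tail convention
  (exposed > non-exposed), so `one_sided_p(t, df) = P(T_df > t)` is the
  default; two-sided is available via configuration.
* **Intervals.** Reconstructing the self-consistent rows ("Sounds",
  "Meaning") from their printed means and t reproduces the printed bounds
  to two decimals with the 0.95 Student-t quantile — i.e. a 90%-wide
  interval despite the table's "95% CI" heading — so 0.95 is the default
  `ci_quantile`, configurable. Rows whose printed bounds are not centered
  on their printed mean differences ("Reality", "Voices", the
  footnote-ambiguous "Cough/Snore", and "Waking up" with its misprinted
  lower bound) are flagged `self_consistent = FALSE` in
  `reference_item_table()` and excluded from reconstruction checks.

No multiple-testing correction is applied by default, matching the
original analysis; a Benjamini–Hochberg option exists
(`inference_config(fdr = TRUE)`). Passive features are compared on
per-participant means over available days, the unit of analysis implied
by the published participant-level degrees of freedom. Stars follow the
published convention: one below 0.05, two below 0.001.

## Calibration design and problem sizes

Three layers of verification, in increasing scope:

1. **Oracle equality.** The window search is checked against an
   exhaustive candidate scan, screen pairing against an interval sweep,
   and summary-based t against a from-scratch two-pass computation (to
   1e−12) and against `t.test(var.equal = TRUE)`.
2. **Parameter recovery.** A 40-participant, 28-day cohort with a
   balanced exposure split and full raw streams (≈ 0.3 M fixes, ≈ 1 M
   epochs) is pushed through the entire extraction pipeline; the sleep
   comparison row must land within 2 pooled standard errors of the
   realized ground-truth gap, and home/screen estimates within fractions
   of an hour of truth. Forty participants keeps full-stream extraction
   around ten seconds while leaving the recovery bound meaningful.
3. **Monte-Carlo calibration.** With all group effects removed, the
   starred fraction over 400 replicate cohorts (100 per group; 35
   comparison rows each) must sit within ±0.02 of the nominal 0.05; with
   the published item effects at group sizes (54, 328), the strongly
   affected items ("Reality", "Seeing things") must be starred in at
   least 80% of 100 replicates. Calibration replicates draw survey
   responses from the same calibrated item samplers and daily features
   directly from the behavioral truth distributions, skipping raw-stream
   emission — raw-stream fidelity is already covered by layer 2, and this
   keeps 400 replicates near a minute.

Interval behavior is also checked directly: under equal true means the
default interval excludes zero in about 10% of replicates, as a 90%-wide
interval must.

## Known limitations

* The GPS clustering and nightly sleep adjustment are explicit,
  documented stand-ins for pipeline internals the source text does not
  specify; they reproduce the *published statistical conventions*, not a
  specific codebase.
* The generator's clean streams make recovery tests informative about
  estimator correctness, not about robustness to real-world missingness,
  multi-place mobility, or device differences.
* Group sizes (54, 328) are inferred from interval widths, not printed;
  analyses conditioning on them inherit that inference.
* The published passive sample (df = 425) exceeds the survey sample
  (n = 382); the package reproduces this possibility by letting the
  sensor and survey analysis sets differ, but the discrepancy itself is
  unexplained in the source material.
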