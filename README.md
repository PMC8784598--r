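# phenocap

Digital phenotyping of smartphone sensor and survey cohorts: a tested,
fully seeded re-implementation of a four-week college-student study of
perceived COVID-19 exposure, for methodologists and study teams who want
to prototype, validate, or power such analyses without access to raw
participant data.

The package covers the whole pipeline:

* **Synthetic cohort generator** — a recruitment/attrition funnel
  (695 → 612 → 507 → 382 by default), a PSS ≥ 14 stress-eligibility
  gate, exposure answers ("Yes" / "No" / "Unsure, but I think so"), and
  per-participant ground-truth behavior that drives raw GPS,
  accelerometer, and screen-state streams plus item-level survey
  responses (mean-calibrated discretized ordinal sampling).
* **Passive features** — *home time* via single-pass weighted
  significant-location clustering (haversine, 100 m radius, home = the
  cluster of 00:00–06:00 fixes); *sleep duration* via the 8-hour window
  of minimal accelerometer activity in the overnight interval
  [18:00, 10:00], shifted per night and thresholded at the
  halves-midpoint of the sorted in-window activities; *screen duration*
  via on → off bout pairing.
* **Survey scoring** — PHQ-9, GAD-7, PSS (reverse-keyed items 4, 5, 7,
  8), UCLA Loneliness, ordinal PQ-16 (16 × 0–3), a 9-item PSQI frequency
  variant, and D-WAI; raw sums normalized by each instrument's maximum.
* **Group inference** — Student's pooled-variance two-sample t-tests,

      t = (m1 − m2) / (sp · √(1/n1 + 1/n2)),
      sp² = ((n1−1)s1² + (n2−1)s2²) / (n1 + n2 − 2),  df = n1 + n2 − 2,

  with the one-sided upper-tail p-value P(T_df > t) and intervals
  mean_diff ± t₀.₉₅,df · se — the two conventions that reproduce the
  published comparison table, including its interval bounds to two
  decimals.

## Worked example

```r
library(phenocap)

cfg <- read_run_config(system.file("extdata", "demo-config.yaml",
                                   package = "phenocap"))
res <- run_pipeline(cfg, out_dir = tempdir())
res$funnel
#>         recruited          used_app completed_surveys answered_exposure
#>                12                12                12                12

sub <- res$comparison[res$comparison$variable %in%
                        c("PQ16", "PSQI9", "home_time_h",
                          "sleep_duration_h"), ]
format_comparison(sub)
#>          variable      exposed    unexposed     t    p ci_lower ci_upper marker
#>              PQ16  0.25 (0.02)  0.19 (0.04)  3.54 0.00     0.03     0.09      *
#>             PSQI9  0.27 (0.08)  0.22 (0.03)  1.67 0.06     0.00     0.11
#>       home_time_h 16.59 (2.47) 16.39 (3.25)  0.11 0.46    -2.95     3.34
#>  sleep_duration_h  6.53 (0.52)  6.93 (0.23) -1.84 0.95    -0.81    -0.01
```

Twelve simulated participants, seven days, no attrition. Survey rows are
normalized means (PQ-16: 0.25 × 48 ≈ 12 points, matching the elevated
exposed-group level the generator is calibrated to); passive rows are
hours per day. The exposed group sleeps ~0.4 h less (t = −1.84; under
the one-sided "exposed greater" convention that lands in the far upper
tail, p = 0.95), while home time shows no group difference — exactly the
pattern the generator encodes.

Reconstruction of a published interval from its printed mean difference
and t statistic:

```r
ci <- reconstruct_interval(0.84 - 0.48, t = 2.47, df = 380)
sprintf("(%.2f, %.2f)", ci$ci_lower, ci$ci_upper)
#> "(0.12, 0.60)"
```

The `analysis/` directory holds the same workflow as numbered narrative
scripts (`01_simulate.R` … `05_calibration.R`), each writing its tables
under `results/`.

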