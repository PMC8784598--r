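#!/usr/bin/env Rscript
# Stage 4 — group inference: exposed/unsure vs non-exposed.
#
# One-sided pooled-variance t-tests compare the groups on every instrument
# mean, every PQ-16 and PSQI item, and the three passive features
# (participant-level means over available days). Intervals use the
# 0.95 Student-t quantile, the convention that reproduces the published
# bounds.

suppressPackageStartupMessages(library(phenocap))

roster <- read.csv("results/roster_full.csv")
analysis <- roster[roster$in_analysis, ]
groups <- split_groups(analysis)
pm <- read.csv("results/participant_means.csv")
pm <- pm[pm$participant_id %in% analysis$participant_id, ]
im <- list(PQ16 = read.csv("results/item_matrix_PQ16.csv"),
           PSQI9 = read.csv("results/item_matrix_PSQI9.csv"))
im <- lapply(im, function(d) d[d$participant_id %in% analysis$participant_id, ])

survey_cmp <- compare_all(pm, im, NULL, groups)
write.csv(format_comparison(survey_cmp), "results/table1_style.csv",
          row.names = FALSE)
starred <- survey_cmp$variable[survey_cmp$marker != ""]
cat("Survey comparisons:", nrow(survey_cmp), "rows;",
    length(starred), "starred at p < 0.05:\n ",
    paste(starred, collapse = ", "), "\n")

gender <- cohort_summary(analysis)
write.csv(gender, "results/gender_summary.csv", row.names = FALSE)
cat("Gender:", paste(sprintf("%s %d (%d%%)", gender$gender, gender$n,
                             gender$pct), collapse = ", "), "\n")

sensor_roster <- read.csv("results/sensor_cohort/roster.csv")
fm <- read.csv("results/participant_feature_means.csv")
passive_cmp <- compare_all(NULL, NULL, fm, split_groups(sensor_roster))
write.csv(format_comparison(passive_cmp), "results/passive_comparison.csv",
          row.names = FALSE)
srow <- passive_cmp[passive_cmp$variable == "sleep_duration_h", ]
cat(sprintf(paste0("Passive sleep: exposed %.2f h vs unexposed %.2f h ",
                   "(diff %.2f h, t = %.2f, df = %d)\n"),
            srow$mean_exposed, srow$mean_unexposed, -srow$mean_diff,
            srow$t, srow$df))
cat("Home time and screen duration rows starred:",
    any(passive_cmp$marker[passive_cmp$variable != "sleep_duration_h"] != ""),
    "\n")
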