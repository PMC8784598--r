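#!/usr/bin/env Rscript
# Stage 3 — score the biweekly survey battery.
#
# Raw item responses (stage 1) are summed per administration with
# instrument-specific reverse-keying, normalized by each instrument's
# maximum so instruments of different lengths share one scale, then
# averaged over the administrations each participant completed. Item-level
# matrices are kept for the PQ-16 and PSQI question-level comparisons.

suppressPackageStartupMessages(library(phenocap))

surveys <- read.csv("results/survey_responses.csv")
scored <- score_administrations(surveys)
write.csv(scored, "results/scored_surveys.csv", row.names = FALSE)
cat("Scored", nrow(scored), "administrations of",
    length(unique(scored$instrument_id)), "instruments\n")

pm <- participant_mean(scored)
write.csv(pm, "results/participant_means.csv", row.names = FALSE)

for (ins in c("PQ16", "PSQI9")) {
  im <- item_matrix(surveys, ins)
  write.csv(im, sprintf("results/item_matrix_%s.csv", ins), row.names = FALSE)
}

roster <- read.csv("results/roster_full.csv")
exposed <- split_groups(roster)$exposed
pq <- pm[pm$instrument_id == "PQ16", ]
cat(sprintf("PQ-16 totals (0-48 scale): exposed %.2f, unexposed %.2f\n",
            48 * mean(pq$mean_normalized[pq$participant_id %in% exposed]),
            48 * mean(pq$mean_normalized[!pq$participant_id %in% exposed])))
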