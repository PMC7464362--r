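#!/usr/bin/env Rscript

## Stage 5: metabolic syndrome z-score.
##
## Averages the five SBP readings, derives HOMA-IR, standardizes the five
## components against the external (here: simulated null-population)
## sex/age(/height) reference tables, and averages them with HDL reversed.

library(mimnet)

cohort <- read_cohort("results/cohort")
dir.create("results/mets", showWarnings = FALSE, recursive = TRUE)

z <- compute_mets_z(cohort$components, cohort$reference)
write.csv(z, "results/mets/mets_z.csv", row.names = FALSE)

cat("subjects scored:", nrow(z), "\n")
cat(sprintf("composite MetS z: mean %.3f, SD %.3f\n",
            mean(z$mets_z), sd(z$mets_z)))
cat("component z means (should sit near 0 against a matched reference):\n")
print(round(colMeans(z[, c("z_waist", "z_sbp", "z_hdl", "z_tg",
                           "z_homa")]), 3))
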