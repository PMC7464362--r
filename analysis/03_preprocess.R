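#!/usr/bin/env Rscript

## Stage 3: metabolomics preprocessing.
##
## Endogenous filter, half-minimum imputation of below-detection values,
## log10 transform, Pareto scaling.

library(mimnet)

cohort <- read_cohort("results/cohort")
dir.create("results/preprocess", showWarnings = FALSE, recursive = TRUE)

prep <- preprocess_metabolites(cohort$abundance, cohort$meta)
out <- data.frame(sample_id = rownames(prep$matrix), prep$matrix,
                  check.names = FALSE)
write.csv(out, "results/preprocess/metabolites_processed.csv",
          row.names = FALSE)
jsonlite::write_json(prep$report[c("n_input_metabolites", "n_endogenous",
                                   "n_samples", "n_imputed_values")],
                     "results/preprocess/preprocess_report.json",
                     auto_unbox = TRUE, digits = NA)

cat("metabolites:", prep$report$n_input_metabolites, "->",
    prep$report$n_endogenous, "endogenous\n")
cat("imputed values:", prep$report$n_imputed_values,
    sprintf("(%.1f%% of the endogenous matrix)\n",
            100 * prep$report$n_imputed_values /
              (prep$report$n_endogenous * prep$report$n_samples)))
cat("processed matrix written; columns are mean-centered, Pareto-scaled log10 abundances\n")
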