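#!/usr/bin/env Rscript
# Sample the synthetic study cohort: 46 colorectal cancer cases contributing
# 54 single-pattern ROIs with the study's exact pattern / grade / mutation /
# MSI margins, and per-ROI mean stiffness drawn from the mutation-group
# distributions (mutant 967 +/- 145 kPa, wild type 751 +/- 92 kPa, truncated
# at the 520 kPa tumor-cell floor).

suppressPackageStartupMessages(library(elastoce))

seed <- 1L
dir.create("results", showWarnings = FALSE)

cohort <- sample_cohort(seed = seed)
write_cohort_csv(cohort, "results/cohort.csv")
write.csv(cohort_case_table(cohort), "results/cases.csv", row.names = FALSE)

tab <- table(cohort$pattern, ifelse(cohort$mutation == "wt", "wt", "mutant"))
cat("ROI counts by pattern and mutation status:\n")
print(tab)
cat(sprintf("\n%d / %d ROIs carry a driver mutation; %d / %d cases do.\n",
            sum(cohort$mutation != "wt"), nrow(cohort),
            sum(cohort_case_table(cohort)$mutation != "wt"), 46))
cat("Cohort written to results/cohort.csv\n")
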