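#!/usr/bin/env Rscript
# Cohort statistics: stiffness summaries per morphological pattern and per
# mutation status with pairwise Mann-Whitney U tests (Bonferroni corrected),
# and Fisher's exact tests of the two mutation-frequency contrasts (tumor
# grade at the case level, solid vs complex tubular at the ROI level).

suppressPackageStartupMessages(library(elastoce))

seed <- 1L
dir.create("results", showWarnings = FALSE)
cohort <- if (file.exists("results/cohort.csv"))
  read_cohort_csv("results/cohort.csv") else sample_cohort(seed = seed)

by_pattern <- summarize_groups(cohort, "pattern")
by_mutation <- summarize_groups(cohort, "mutation")
write.csv(by_pattern$summary, "results/summary_by_pattern.csv",
          row.names = FALSE)
write.csv(by_pattern$tests, "results/utests_by_pattern.csv",
          row.names = FALSE)
write.csv(by_mutation$summary, "results/summary_by_mutation.csv",
          row.names = FALSE)

p_grade <- fisher_exact(grade_mutation_table(cohort))
p_pattern <- fisher_exact(pattern_mutation_table(cohort, "solid",
                                                 "complex_tubular"))
write.csv(data.frame(contrast = c("high_vs_low_grade_cases",
                                  "solid_vs_tubular_rois"),
                     p_two_sided = c(p_grade, p_pattern)),
          "results/fisher_tests.csv", row.names = FALSE)

cat("Stiffness by mutation status (kPa):\n")
print(by_mutation$summary, digits = 4)
mw <- mann_whitney(cohort$stiffness_kpa[cohort$mutation != "wt"],
                   cohort$stiffness_kpa[cohort$mutation == "wt"])
cat(sprintf("\nMutant vs wild type: U = %.0f, p = %.2g (%s)\n",
            mw$u_statistic, mw$p_two_sided, mw$method))
cat(sprintf("Fisher grade contrast p = %.4f; pattern contrast p = %.4f\n",
            p_grade, p_pattern))
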