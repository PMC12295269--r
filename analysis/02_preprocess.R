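#!/usr/bin/env Rscript
# Stage 2 — clean the cohort.
#
# Applies the three filters in order: the two named low-quality samples
# are dropped outright, then samples with excess below-LOD missingness
# and samples with > 10% of a family's metabolites beyond 3 SD are
# removed per family. Writes the filtered cohort and the filter report.

library(metabolda)

coh <- read_cohort("results/cohort.csv", "results/family_map.csv")
res <- preprocess_cohort(coh, names = c("PX009", "PX025"),
                         max_missing_frac = 0.2,
                         sd_mult = 3, max_outlier_frac = 0.10)

write_cohort(res$cohort, "results/cohort_clean.csv",
             "results/family_map.csv")
write_filter_report(res$reports, "results/filter_report.json")

cat("samples:", nrow(coh$samples), "->", nrow(res$cohort$samples),
    "after named exclusion\n")
cat("per-family removals (low quality / outliers):\n")
print(rbind(res$reports$low_quality$removed_samples,
            res$reports$outliers$removed_samples))
cat("\nper-family tallies after cleaning:\n")
print(family_counts(res$cohort))
cat("wrote results/cohort_clean.csv, results/filter_report.json\n")
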