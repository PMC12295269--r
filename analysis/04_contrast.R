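#!/usr/bin/env Rscript
# Stage 4 — group contrasts and residual correlation structure.
#
# For every non-concomitant metabolite: direction of change in AD, the
# Group coefficient's p-value and its BH-adjusted value (per family), and
# a significance tier. Then the per-family Pearson correlation matrices
# of the with-Group residuals, the computational content behind the
# family heatmaps (rendered as PNGs when pheatmap is available).

library(metabolda)

coh <- read_cohort("results/cohort_clean.csv", "results/family_map.csv")
fams <- unique(coh$family_map)
scores <- lapply(fams, function(f) score_concomitants(coh, f))
conc <- select_concomitants(scores)

contr <- group_contrasts(coh, conc, scope = "per_family")
utils::write.csv(contr, "results/group_contrasts.csv", row.names = FALSE)

cat("significance tiers:\n")
print(table(contr$family, contr$significance_tier))
cat("\nadjusted-significant metabolites:\n")
print(contr[contr$significance_tier == "adjusted",
            c("metabolite", "family", "direction", "group_p_adjusted")],
      digits = 3)

res_wg <- compute_residuals(coh, conc, include_group = TRUE)
for (f in fams) {
  if (sum(res_wg$family_map == f) < 2) next
  cm <- residual_correlations(res_wg, f)
  slug <- gsub("[^A-Za-z0-9]+", "_", f)
  utils::write.csv(cm$r, sprintf("results/correlations_%s.csv", slug))
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    plot_family_heatmap(cm, contr,
                        filename = sprintf("results/heatmap_%s.png", slug))
  }
}
cat("wrote group contrasts, correlation matrices and heatmaps under results/\n")
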