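#!/usr/bin/env Rscript
# Stage 3 — group-level degeneration patterns and clinical associations.
#
# Decomposes the 17 predicted atrophy maps (each at its patient's t_max)
# into principal spatial components, then tests whether model fit (R^2)
# increases with time since injury after controlling for age, and whether
# the model's peak time tracks time since injury. Outputs land under
# results/group/.
#
# Usage: Rscript analysis/03_group.R

suppressMessages(library(ndmtbi))
cfg <- pipeline_config(verbose = TRUE)
grp <- run_group(cfg)

frac <- grp$pca$explained_variance_fraction
cat(sprintf("First %d principal components explain %s%% of the variance (total %.0f%%)\n",
            grp$pca$k,
            paste(sprintf("%.0f", 100 * frac[seq_len(grp$pca$k)]),
                  collapse = "/"),
            100 * sum(frac[seq_len(grp$pca$k)])))
cat("\nFit (R^2) vs time since injury, controlling for age:\n  ")
print(grp$fit_vs_tsi)
cat("Peak time (t_max) vs time since injury:\n  ")
print(grp$peaktime_vs_tsi)
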