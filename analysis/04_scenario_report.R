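#!/usr/bin/env Rscript

# Summarize the covariate cascade and the mechanism-scenario
# classification of the full run produced by 03_group_inference.R:
# which of the six sign-pattern scenarios have support, how the estimated
# map compares with the planted ground truth, the Pearson correlations of
# region mean Z values with T2LL/MSSS, and the overlap of the subgroup
# contrast maps with each mechanism.

suppressPackageStartupMessages(library(fcmech))

run <- readRDS("results/run_object.rds")

cat("scenarios present:", paste(run$report$present, collapse = ", "), "\n\n")
cat("voxel counts per scenario:\n")
print(run$report$counts, row.names = FALSE)

gt <- run$ground_truth$scenario_map
est <- run$scenario_map$labels
inreg <- gt != 0
cat(sprintf("\nlabel accuracy inside planted regions: %.1f%% (%d voxels)\n",
            100 * mean(est[inreg] == gt[inreg]), sum(inreg)))

pearson <- do.call(rbind, lapply(run$cascades, function(cs) cs$pearson))
if (!is.null(pearson)) {
  cat("\nPearson correlations of region mean Z with the covariates:\n")
  pearson$r <- round(pearson$r, 3)
  pearson$p_bonferroni <- signif(pearson$p_bonferroni, 3)
  print(pearson[, c("region", "covariate", "r", "p_bonferroni", "n")],
        row.names = FALSE)
}

if (!is.null(run$report$overlaps)) {
  ov <- run$report$overlaps
  ov <- ov[ov$percent > 0, ]
  cat("\nsubgroup-contrast overlap with mechanism maps (%):\n")
  if (nrow(ov)) print(ov, row.names = FALSE) else cat("  none\n")
}
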