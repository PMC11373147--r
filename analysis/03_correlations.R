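#!/usr/bin/env Rscript
# Stage 3: association of each physiological metric with the pilot
# inceptor workload baseline.
#
# Pearson correlation across the 60 participant-by-condition rows plus the
# repeated-measures correlation (ANCOVA with per-participant intercepts),
# and the inter-pilot variability of every metric across conditions.

suppressPackageStartupMessages(library(vrcogload))

tab <- utils::read.csv("results/metric_table.csv")
class(tab) <- c("metric_table", "data.frame")

ct <- correlate_with_piw(tab)
vt <- pilot_variability(tab)

utils::write.csv(ct, "results/correlations.csv", row.names = FALSE)
utils::write.csv(vt, "results/pilot_variability.csv", row.names = FALSE)
report <- format_correlation_report(ct)
writeLines(report, "results/correlation_report.txt")
cat(report, sep = "\n")

cat("\nmost consistent pilot (lowest mean variability rank):\n")
ranks <- apply(vt[, -1], 2, rank)
best <- vt$participant[which.min(rowMeans(ranks))]
cat(sprintf("  participant %d\n", best))
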