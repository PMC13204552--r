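#!/usr/bin/env Rscript
# Runs the mitochondrial morphometry pipeline (Frangi tubeness sigmas 1-4,
# one batch-global Otsu threshold across both conditions, 1-20 um skeleton
# length filter) over the simulated tube fields, then checks that the two
# designed conditions (fragmented ~2 um vs fused ~6 um mean length) are
# recovered and that per-object skeleton lengths track the ground truth.
#
# Input:  results/sim/ (from 01_simulate.R)
# Output: results/morpho/ (objects, per-condition summary, recovery table)

suppressMessages(library(fluoquant))

man <- read_manifest("results/sim/manifest_tubes.csv")
out <- "results/morpho"

res <- run_batch(man, "morpho", config = list(channel = "mito"),
                 out_dir = out)
summ <- res$tables$summary

cat("per-condition summaries (global Otsu threshold shared):\n")
print(summ, row.names = FALSE)
designed <- c(short = 2, long = 6)
for (cd in names(designed)) {
  m <- summ$mean_length_um[summ$condition == cd]
  cat(sprintf("%-6s designed %.1f um, recovered %.2f um (%.1f%% off)\n",
              cd, designed[cd], m, 100 * abs(m - designed[cd]) / designed[cd]))
}
cat(sprintf("ordering preserved: %s\n",
            summ$mean_length_um[summ$condition == "long"] >
              summ$mean_length_um[summ$condition == "short"]))
cat(sprintf("objects excluded by the 1-20 um filter: %d small, %d large\n",
            res$tables$threshold$n_too_small,
            res$tables$threshold$n_too_large))
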