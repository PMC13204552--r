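#!/usr/bin/env Rscript
# Runs the two-channel colocalization pipeline (Otsu+closing masks,
# optimized scan line, PCC / Manders / ICQ) over the simulated punctate
# fields and compares the recovered Manders M1 with the designed overlap
# fraction of each field.
#
# Input:  results/sim/ (from 01_simulate.R)
# Output: results/coloc/ (per-image statistics + recovery summary)

suppressMessages(library(fluoquant))

man <- read_manifest("results/sim/manifest_coloc.csv")
truth <- read.csv("results/sim/truth_coloc.csv")
out <- "results/coloc"

res <- run_batch(man, "coloc",
                 config = list(channel_a = "red", channel_b = "green"),
                 out_dir = out)
tab <- res$tables$results
tab$designed_f <- truth$designed_f[match(tab$source_id, truth$path)]

rec <- do.call(rbind, lapply(split(tab, tab$designed_f), function(g)
  data.frame(designed_f = g$designed_f[1], n = nrow(g),
             mean_m1 = mean(g$m1), sd_m1 = sd(g$m1),
             mean_m2 = mean(g$m2), mean_pcc_pixel = mean(g$pcc_pixel),
             mean_icq = mean(g$icq))))
write_records(rec, file.path(out, "m1_recovery.csv"))

cat("Manders M1 recovery of the designed overlap fraction:\n")
print(rec[, c("designed_f", "mean_m1", "sd_m1", "mean_pcc_pixel",
              "mean_icq")], row.names = FALSE)
cat(sprintf("\nmax |mean M1 - designed f| = %.3f; monotone: %s\n",
            max(abs(rec$mean_m1 - rec$designed_f)),
            all(diff(rec$mean_m1[order(rec$designed_f)]) > 0)))
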