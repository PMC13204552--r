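#!/usr/bin/env Rscript
# Builds the synthetic study used by the downstream analyses: punctate
# two-channel fields with designed colocalization fractions, tube fields
# for two morphometric conditions (short, fragmented vs long, fused), and
# dual-channel JC-1 fields in the three axial-potential modes. Images are
# written as 16-bit TIFFs with manifests so every later step runs from
# files, exactly as it would on real exported microscope data.
#
# Output: results/sim/ (images + manifests + ground-truth tables)

suppressMessages(library(fluoquant))

seed0 <- 20260901L
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## colocalization fields: 5 designed overlap fractions x 5 replicates ----
coloc_entries <- list()
truth_rows <- list()
for (f in c(0, 0.25, 0.5, 0.75, 1)) {
  for (rep in 1:5) {
    seed <- seed0 + round(1000 * f) + rep
    fld <- make_coloc_field(n_spots = 200, overlap_fraction = f,
                            seed = seed,
                            condition = sprintf("f%.2f", f))
    p <- file.path(out, sprintf("coloc_f%03d_r%d.tif", round(100 * f), rep))
    save_image(fld$image, p)
    coloc_entries[[length(coloc_entries) + 1]] <- data.frame(
      path = basename(p), condition = fld$image$condition,
      channels = "red;green", pixel_size_um = 0.1)
    truth_rows[[length(truth_rows) + 1]] <- data.frame(
      path = basename(p), designed_f = f,
      analytic_m1 = fld$truth$analytic_m1,
      analytic_m2 = fld$truth$analytic_m2, seed = seed)
  }
}
write_manifest(do.call(rbind, coloc_entries),
               file.path(out, "manifest_coloc.csv"))
write_records(do.call(rbind, truth_rows),
              file.path(out, "truth_coloc.csv"))
cat(sprintf("coloc: %d fields written\n", length(coloc_entries)))

## tube fields: two conditions with designed mean lengths 2 vs 6 um ------
tube_entries <- list()
tube_truth <- list()
conds <- list(short = list(n = 6, range = c(1.2, 2.8), base = 100L),
              long  = list(n = 5, range = c(4, 8),    base = 200L))
for (cd in names(conds)) {
  for (rep in 1:20) {
    seed <- seed0 + conds[[cd]]$base * 100 + rep
    fld <- make_tube_field(n_tubes = conds[[cd]]$n,
                           length_um_range = conds[[cd]]$range,
                           size = 256L, seed = seed, condition = cd,
                           source_id = sprintf("%s_%02d", cd, rep))
    p <- file.path(out, sprintf("tubes_%s_%02d.tif", cd, rep))
    save_image(fld$image, p)
    tube_entries[[length(tube_entries) + 1]] <- data.frame(
      path = basename(p), condition = cd, channels = "mito",
      pixel_size_um = 0.1)
    tube_truth[[length(tube_truth) + 1]] <- data.frame(
      path = basename(p), condition = cd,
      tube = seq_along(fld$truth$true_lengths_um),
      true_length_um = fld$truth$true_lengths_um, seed = seed)
  }
}
write_manifest(do.call(rbind, tube_entries),
               file.path(out, "manifest_tubes.csv"))
write_records(do.call(rbind, tube_truth),
              file.path(out, "truth_tubes.csv"))
cat(sprintf("tubes: %d fields written (2 um and 6 um conditions)\n",
            length(tube_entries)))

## JC-1 fields: three designed axial-potential modes ----------------------
jc1_entries <- list()
for (mode in c("uniform", "half-half", "gradient")) {
  for (rep in 1:5) {
    seed <- seed0 + 900 + 10 * rep + match(mode, c("uniform", "half-half",
                                                   "gradient"))
    fld <- make_jc1_field(n_objects = 8, mosaic_mode = mode, seed = seed,
                          condition = mode)
    p <- file.path(out, sprintf("jc1_%s_%d.tif", gsub("-", "", mode), rep))
    save_image(fld$image, p)
    jc1_entries[[length(jc1_entries) + 1]] <- data.frame(
      path = basename(p), condition = mode, channels = "red;green",
      pixel_size_um = 0.1)
  }
}
write_manifest(do.call(rbind, jc1_entries),
               file.path(out, "manifest_jc1.csv"))
cat(sprintf("jc1: %d fields written (uniform / half-half / gradient)\n",
            length(jc1_entries)))
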