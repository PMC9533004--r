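#!/usr/bin/env Rscript
# Generate the synthetic study: a small cohort of participants, each with
# one discrete and one rhythmic block, written as wide-TSV marker files so
# the downstream stages run from files exactly as they would on a real
# export. Ground truth goes alongside as CSV for the closed-loop checks.

library(whipkin)

out_dir <- "results/study"
dir.create(file.path(out_dir), showWarnings = FALSE, recursive = TRUE)

set.seed(20260925)
study <- simulate_study(n_participants = 3, n_blocks = 1,
                        discrete_duration = 60, rhythmic_duration = 40,
                        seed = 42)

manifest <- list()
for (pid in names(study)) {
  for (style in names(study[[pid]])) {
    for (b in seq_along(study[[pid]][[style]])) {
      blk <- study[[pid]][[style]][[b]]
      stem <- sprintf("%s_%s_block%d", pid, style, b)
      write_markers(blk$dataset, file.path(out_dir, paste0(stem, ".tsv")))
      write.csv(blk$truth$trials, file.path(out_dir, paste0(stem, "_truth.csv")),
                row.names = FALSE)
      manifest[[length(manifest) + 1]] <- data.frame(
        participant = pid, style = style, block = b,
        file = paste0(stem, ".tsv"), n_trials = nrow(blk$truth$trials))
    }
  }
}
manifest <- do.call(rbind, manifest)
write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)

cat(sprintf("wrote %d blocks for %d participants to %s\n",
            nrow(manifest), length(study), out_dir))
print(manifest)
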