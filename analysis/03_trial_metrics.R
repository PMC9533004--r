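#!/usr/bin/env Rscript
# Per-trial outcome metrics (error, hit, extension, azimuths, peak speeds,
# inter-trial interval) and block-level summaries, plus the participant
# ranking by median error used to order the performance figures.

library(whipkin)

manifest <- read.csv("results/study/manifest.csv")
trial_rows <- list()
block_rows <- list()
for (i in seq_len(nrow(manifest))) {
  m <- manifest[i, ]
  ds <- read_markers(file.path("results/study", m$file))
  res <- analyze_block(ds, m$style)
  tm <- cbind(participant = m$participant, block = m$block, res$trials)
  trial_rows[[i]] <- tm
  block_rows[[i]] <- cbind(participant = m$participant, style = m$style,
                           block = m$block, res$summary)
}
metrics <- do.call(rbind, trial_rows)
blocks <- do.call(rbind, block_rows)
write.csv(metrics, "results/trial_metrics.csv", row.names = FALSE)
write.csv(blocks, "results/block_summaries.csv", row.names = FALSE)

cat("block summaries:\n")
print(blocks[, c("participant", "style", "n_trials", "success_rate",
                 "error_median", "extension_median", "whip_azimuth_mean",
                 "peak_hand_speed_mean", "peak_tip_speed_mean", "rhythmicity")])

rk <- rank_participants(metrics)
write.csv(rk, "results/participant_ranking.csv", row.names = FALSE)
cat("\nparticipants ranked by median error across both styles:\n")
print(rk)
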