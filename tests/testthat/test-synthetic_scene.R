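test_that("scene parameters validate their invariants", {
  expect_error(scene_params("discrete", hand_peak1 = 7, hand_peak2 = 6),
               "second")
  expect_error(scene_params("discrete", planted_extension = 1.7), "extension")
  expect_error(scene_params("discrete", noise_sd = -1), "noise")
  expect_error(scene_params("discrete", nonsense = 1), "unknown")
})

test_that("the generator is deterministic under a fixed seed", {
  p <- fx_params("discrete")
  a <- simulate_trial(p)
  b <- simulate_trial(p)
  expect_identical(a$dataset$positions, b$dataset$positions)
  b1 <- simulate_block(p, duration = 30, seed = 2)
  b2 <- simulate_block(p, duration = 30, seed = 2)
  expect_identical(b1$dataset$positions, b2$dataset$positions)
  b3 <- simulate_block(p, duration = 30, seed = 3)
  expect_false(identical(b1$dataset$positions, b3$dataset$positions))
})

test_that("adjacent whip markers keep their arclength spacing before noise", {
  p <- scene_params("discrete", noise_sd = 0)
  tr <- simulate_trial(p)
  pos <- tr$dataset$positions
  lens <- whipkin:::whip_segment_lengths(p$schema)
  chain <- c("h1", paste0("w", 10:1))
  for (k in seq_along(lens)) {
    d <- whipkin:::vnorm(pos[, chain[k + 1], ] - pos[, chain[k], ])
    expect_lt(max(abs(d - lens[k])), 1e-6)
  }
})

test_that("the noise-free closed loop recovers every planted quantity", {
  p <- scene_params("discrete", noise_sd = 0, planted_error = 0.05,
                    planted_azimuth = 28, planted_extension = 1.43)
  tr <- simulate_trial(p)
  res <- analyze_block(tr$dataset, "discrete")
  tm <- res$trials
  expect_equal(nrow(tm), 1L)
  expect_lt(abs(tm$error - 0.05), 1e-3)
  expect_lt(abs(tm$whip_azimuth - 28), 1)
  expect_lt(abs(tm$extension - 1.43), 0.01)
  expect_lt(abs(tm$hand_azimuth - p$planted_hand_azimuth), 1)
  expect_frames_close(tm$onset_frame, tr$truth$onset_frame, 1)
  expect_frames_close(tm$peak_frame, tr$truth$peak_frame, 1)
  expect_frames_close(tm$md_frame, tr$truth$md_frame, 1)
  expect_lt(abs(tm$peak_hand_speed - tr$truth$peak_hand_speed), 0.05)
  expect_lt(abs(tm$peak_tip_speed - tr$truth$peak_tip_speed), 0.3)
  # tip peak exceeds hand peak by construction of the cascade
  expect_gt(tm$peak_tip_speed, tm$peak_hand_speed)
})

test_that("an infeasible strike geometry raises a parameter error", {
  p <- fx_params("discrete")
  p$target_t1 <- c(2.2, 0, 3.5)  # target far above the chain's reach
  expect_error(simulate_trial(p), "infeasible")
})

test_that("a zero-variability rhythmic block has rhythmicity zero", {
  p <- scene_params("rhythmic", interval_cov = 0, noise_sd = 0)
  blk <- simulate_block(p, duration = 20, seed = 1)
  iv <- blk$truth$trials$interval
  expect_lt(rhythmicity(iv[!is.na(iv)]), 1e-6)
  res <- analyze_block(blk$dataset, "rhythmic")
  tm <- res$trials
  expect_lt(rhythmicity(tm$inter_trial_interval[!tm$excluded]), 1e-3)
})

test_that("block durations yield the study trial counts", {
  pd <- fx_params("discrete")
  blk <- simulate_block(pd, duration = 180, seed = 2)
  expect_gte(nrow(blk$truth$trials), 30)
  expect_lte(nrow(blk$truth$trials), 36)
  pr <- fx_params("rhythmic")
  blk2 <- simulate_block(pr, duration = 40, seed = 2)
  expect_gte(nrow(blk2$truth$trials), 31)
  expect_lte(nrow(blk2$truth$trials), 33)
})

test_that("cohort simulation plants the generative effects it reports", {
  cp <- cohort_params(seed = 9)
  sim <- simulate_cohort(cp)
  expect_equal(nrow(sim$table), 16 * 2 * 5 * 33)
  expect_identical(sim$truth, cp$metrics)
  # two seeds -> different tables, same planted effects
  sim2 <- simulate_cohort(cohort_params(seed = 10))
  expect_false(identical(sim$table$error, sim2$table$error))
  expect_identical(sim$truth, sim2$truth)
  # null plants give near-nominal rejection: checked in the acceptance suite
})

test_that("gap schedules are applied after noise, as specified", {
  p <- scene_params("discrete",
                    gap_schedule = data.frame(marker = "w5", start = 50,
                                              length = 70), seed = 2)
  tr <- simulate_trial(p)
  expect_true(all(tr$dataset$gap_mask[50:119, "w5"]))
  expect_true(all(is.na(tr$dataset$positions[50:119, "w5", ])))
  expect_false(any(tr$dataset$gap_mask[, "w4"]))
})
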