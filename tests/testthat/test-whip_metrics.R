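test_that("segment-segment minimum distance matches closed-form toys", {
  # collinear static toy: whip points (0,0,0),(0.06,0,0),(0.25,0,0); target
  # segment from (0.10,0.05,0) to (0.10,0.15,0) -> 0.05 m
  schema <- whip_schema()
  cfg <- straight_whip_config()
  cfg["w1", ] <- c(0, 0, 0)
  cfg["w2", ] <- c(0.06, 0, 0)
  cfg["w3", ] <- c(0.25, 0, 0)
  cfg["t1", ] <- c(0.10, 0.05, 0)
  cfg["t2", ] <- c(0.10, 0.15, 0)
  ds <- static_dataset(cfg)
  d <- whipkin:::whip_target_distance(ds, 1)
  expect_equal(d, 0.05, tolerance = 1e-12)
  # tip passing exactly through the target point -> 0
  cfg["w1", ] <- cfg["t1", ]
  expect_equal(whipkin:::whip_target_distance(static_dataset(cfg), 1), 0,
               tolerance = 1e-12)
})

test_that("minimum distance equals the dense-sampling brute force", {
  set.seed(10)
  devs <- replicate(100, {
    w <- matrix(runif(9, -0.1, 0.1), 3)
    w[2, ] <- w[1, ] + runif(3, -0.05, 0.05)
    w[3, ] <- w[2, ] + runif(3, -0.05, 0.05)
    tt <- matrix(runif(6, -0.1, 0.1), 2)
    p1 <- rbind(w[1, ], w[2, ])
    impl <- min(whipkin:::segment_segment_distance(
      rbind(w[1, ], w[2, ]), rbind(w[2, ], w[3, ]),
      rbind(tt[1, ], tt[1, ]), rbind(tt[2, ], tt[2, ])))
    oracle <- whipkin:::polyline_min_dist_dense(w, tt, step = 1e-4)
    abs(impl - oracle)
  })
  expect_lt(max(devs), 1e-4)
})

test_that("the error never exceeds any raw whip-target marker distance", {
  fx <- fx_block("discrete")
  ds <- fx$res$proc$dataset
  for (i in head(seq_len(nrow(fx$trials)), 3)) {
    tr <- fx$trials[i, ]
    frames <- tr$onset_frame:tr$end_frame
    raw <- Inf
    for (wm in c("w1", "w2", "w3")) for (tm in c("t1", "t2"))
      raw <- min(raw, min(whipkin:::vnorm(
        ds$positions[frames, wm, ] - ds$positions[frames, tm, ]), na.rm = TRUE))
    expect_lte(minimum_distance_error(ds, tr, "throw"), raw + 1e-12)
  }
})

test_that("error and extension are invariant under rigid transforms", {
  p <- scene_params("discrete", noise_sd = 0)
  tr <- simulate_trial(p)
  ds <- tr$dataset
  res <- analyze_block(ds, "discrete")
  # rotate the whole scene about the vertical axis and translate it
  R <- whipkin:::rot_z(33)
  shift <- c(0.7, -0.4, 0.2)
  pos2 <- ds$positions
  for (k in seq_len(dim(pos2)[2]))
    pos2[, k, ] <- sweep(pos2[, k, ] %*% t(R), 2, -shift)
  ds2 <- marker_dataset(pos2, ds$sampling_rate, ds$schema)
  tr1 <- res$trials[1, ]
  e1 <- minimum_distance_error(ds, tr1, "throw")
  e2 <- minimum_distance_error(ds2, tr1, "throw")
  expect_equal(e1, e2, tolerance = 1e-9)
  x1 <- whip_extension(ds, tr1$peak_frame)
  x2 <- whip_extension(ds2, tr1$peak_frame)
  expect_equal(x1$extension, x2$extension, tolerance = 1e-9)
})

test_that("whip azimuth follows the sign convention and is equivariant", {
  # straight whip pointing directly away from the target -> 0 deg
  cfg <- straight_whip_config(azimuth = 0)
  ds <- static_dataset(cfg)
  expect_equal(whip_azimuth(ds, 1), 0, tolerance = 1e-9)
  # rotating the scene 30 deg toward the participant's right adds 30 deg
  cfg30 <- rotate_config(cfg, 30, center = cfg["h1", ])
  cfg30[c("t1", "t2", "t3"), ] <- cfg[c("t1", "t2", "t3"), ]  # target fixed
  expect_equal(whip_azimuth(static_dataset(cfg30), 1), 30, tolerance = 1e-9)
})

test_that("planted azimuths and extension are recovered under 5 mm noise", {
  set.seed(21)
  az_err <- ext_err <- haz_err <- numeric(60)
  for (r in 1:60) {
    cfg <- straight_whip_config(azimuth = 28)
    noisy <- cfg + matrix(rnorm(length(cfg), 0, 0.005), nrow(cfg))
    ds <- static_dataset(noisy)
    az_err[r] <- whip_azimuth(ds, 1) - 28
    ext_err[r] <- whip_extension(ds, 1)$extension - 1.60
    haz_err[r] <- hand_azimuth(ds, 1) - 28
  }
  expect_lt(mean(abs(az_err)), 1)
  expect_lt(mean(abs(ext_err)), 0.01)
  expect_lt(abs(mean(haz_err)), 1)
})

test_that("extension reports both marker-pair variants", {
  cfg <- straight_whip_config(azimuth = 10)
  ds <- static_dataset(cfg)
  ex <- whip_extension(ds, 1)
  expect_equal(ex$extension, 1.60, tolerance = 1e-9)   # h1 -> w1, straight
  expect_equal(ex$extension_ratio, 1.0, tolerance = 1e-9)
  expect_equal(ex$extension_w1w10, 1.58, tolerance = 1e-9)
  # folded exactly in half at w5: w1 coincides with the fold symmetry
  schema <- whip_schema()
  lens <- whipkin:::whip_segment_lengths(schema)
  u <- c(1, 0, 0)
  pos <- cfg
  cur <- pos["h1", ]
  for (k in seq_along(lens)) {
    dir <- if (k <= 5) u else -u  # fold back after w6
    cur <- cur + lens[k] * dir
    pos[paste0("w", 11 - k), ] <- cur
  }
  exf <- whip_extension(static_dataset(pos), 1)
  # folded: |h1 - w1| = |sum of segment vectors| = 2*(first 5) - total
  expected <- abs(2 * sum(lens[1:5]) - sum(lens))
  expect_equal(exf$extension, expected, tolerance = 1e-9)
  expect_lt(exf$extension_ratio, 0.2)
})

test_that("degenerate marker clouds are rejected with a diagnostic", {
  schema <- whip_schema()
  cfg <- straight_whip_config()
  for (m in c("h1", paste0("w", 1:10))) cfg[m, ] <- c(0.5, 0.05, 1.0)
  ds <- static_dataset(cfg)
  expect_warning(az <- whip_azimuth(ds, 1), "degenerate|coincident")
  expect_true(is.na(az))
})

test_that("hand azimuth is equivariant and aligned with the sagittal line", {
  cfg <- straight_whip_config(azimuth = 0)
  expect_equal(hand_azimuth(static_dataset(cfg), 1), 0, tolerance = 1e-9)
  cfg36 <- rotate_config(cfg, 36, center = cfg["hand_MC5", ])
  cfg36[c("t1", "t2", "t3"), ] <- cfg[c("t1", "t2", "t3"), ]
  expect_equal(hand_azimuth(static_dataset(cfg36), 1), 36, tolerance = 1e-9)
})

test_that("hit detection responds to planted target oscillations", {
  p0 <- scene_params("discrete", noise_sd = 3e-4, hit = FALSE, seed = 5)
  trial0 <- simulate_trial(p0)
  res0 <- analyze_block(trial0$dataset, "discrete")
  expect_false(res0$trials$hit[1])           # static target -> miss
  p1 <- scene_params("discrete", noise_sd = 3e-4, hit = TRUE, seed = 5)
  trial1 <- simulate_trial(p1)
  res1 <- analyze_block(trial1$dataset, "discrete")
  expect_true(res1$trials$hit[1])            # 5 cm decaying oscillation -> hit
  # sub-threshold wobble (0.5 mm) -> miss
  p2 <- scene_params("discrete", noise_sd = 3e-4, hit = TRUE, osc_amp = 5e-4,
                     seed = 5)
  trial2 <- simulate_trial(p2)
  res2 <- analyze_block(trial2$dataset, "discrete")
  expect_false(res2$trials$hit[1])
})

test_that("success rate recovers the planted contact fraction", {
  fx <- fx_block("rhythmic")
  tm <- fx$trials[!fx$trials$excluded, ]
  gt <- fx$truth
  expect_equal(100 * mean(tm$hit), 100 * mean(gt$hit))
  expect_equal(block_metrics(fx$trials)$success_rate, 100 * mean(gt$hit))
})

test_that("rhythmicity matches hand-computed coefficients of variation", {
  expect_equal(rhythmicity(rep(1.2, 10)), 0)
  # {1.0, 1.0, 2.0}: sample SD sqrt(1/3), mean 4/3 -> 0.43301...
  expect_equal(rhythmicity(c(1, 1, 2)), sqrt(1 / 3) / (4 / 3), tolerance = 1e-12)
  expect_equal(round(rhythmicity(c(1, 1, 2)), 4), 0.4330)
  expect_true(is.na(rhythmicity(1.2)))
  # planted lognormal-style CoV 0.06 recovered over ~30 trials
  set.seed(9)
  iv <- whipkin:::standardize_intervals(30, 1.2, 0.06)
  expect_lt(abs(rhythmicity(iv) - 0.06), 0.01)
})

test_that("peak speeds pick the trial hand maximum and throw tip maximum", {
  hand <- c(rep(0.2, 50), seq(0.2, 3, length.out = 30), rep(0.5, 40),
            seq(0.5, 6.1, length.out = 30), seq(6.1, 0.3, length.out = 50))
  tip <- c(rep(1, 120), seq(1, 25, length.out = 60), rep(2, 20))
  trial <- data.frame(start_frame = 1, end_frame = 200, onset_frame = 110)
  ps <- peak_speeds(trial, hand, tip)
  expect_equal(ps$peak_hand_speed, 6.1)
  expect_equal(ps$peak_tip_speed, 25)
  expect_equal(ps$peak_frame, which.max(hand))
  # constant speed -> that constant
  ps2 <- peak_speeds(data.frame(start_frame = 1, end_frame = 100,
                                onset_frame = 10),
                     rep(2.5, 100), rep(4, 100))
  expect_equal(ps2$peak_hand_speed, 2.5)
})
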