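test_that("minimum-distance events are found at planted minima", {
  fs <- 500
  t <- seq(0, 3, by = 1 / fs)
  # two clean minima 1 s apart in a synthetic distance series
  d <- 2 - 1.9 * exp(-((t - 1) / 0.08)^2) - 1.9 * exp(-((t - 2) / 0.08)^2)
  ev <- detect_minimum_distance_events(d, pipeline_config(), distance = TRUE)
  expect_length(ev, 2)
  expect_frames_close(ev, c(which.min(abs(t - 1)), which.min(abs(t - 2))), 1)
  # monotone distance -> no events
  expect_length(detect_minimum_distance_events(seq(2, 0.2, length.out = 1000),
                                               pipeline_config(),
                                               distance = TRUE), 0)
  # noisy series with planted minima: events within +-2 frames of the
  # noise-free twin's argmins
  set.seed(4)
  dn <- d + rnorm(length(d), 0, 0.003)
  evn <- detect_minimum_distance_events(dn, pipeline_config(), distance = TRUE)
  expect_length(evn, 2)
  expect_frames_close(evn, ev, 2)
})

test_that("discrete parsing finds exactly the planted throws", {
  fx <- fx_block("discrete")
  expect_equal(nrow(fx$trials), nrow(fx$truth))
  expect_frames_close(fx$trials$start_frame, fx$truth$start_frame, 1)
  expect_frames_close(fx$trials$lift_frame, fx$truth$lift_frame, 3)
  # inter-trial floor phases keep w1-w3 below the 2 cm lift threshold
  ds <- fx$block$dataset
  between <- setdiff(seq_len(dim(ds$positions)[1]),
                     unlist(mapply(seq, fx$truth$start_frame - 250,
                                   fx$truth$md_frame + 500)))
  between <- between[between > 0 & between <= dim(ds$positions)[1]]
  z3 <- ds$positions[between, c("w1", "w2", "w3"), 3]
  expect_lt(max(z3, na.rm = TRUE), 0.02)
})

test_that("a block without whip lift yields no trials", {
  cfg <- straight_whip_config()
  cfg[paste0("w", 1:10), 3] <- 0.005  # whip flat on the floor
  ds <- static_dataset(cfg, n_frames = 2000)
  trials <- parse_discrete(ds, hand_speed = rep(0, 2000), events = integer(0))
  expect_equal(nrow(trials), 0L)
})

test_that("rhythmic trials tile the span between events", {
  ev <- c(500, 1000, 1500, 2000, 2500)
  tr <- parse_rhythmic(NULL, events = ev)
  expect_equal(nrow(tr), 4L)
  expect_equal(tr$start_frame, ev[1:4])
  expect_equal(tr$end_frame, ev[2:5])
  expect_true(all(tr$start_frame[-1] == tr$end_frame[-4]))  # no gaps/overlap
  # events at 1, 2, 3 s -> inter-trial intervals of 1 s
  tr2 <- parse_rhythmic(NULL, events = c(500, 1000, 1500))
  expect_equal(diff(tr2$start_frame) / 500, 1.0)
  expect_equal(nrow(parse_rhythmic(NULL, events = 1000L)), 0L)
})

test_that("a 40 s rhythmic block at ~1.2 s period parses to the planted count", {
  fx <- fx_block("rhythmic")
  expect_equal(nrow(fx$trials), nrow(fx$truth))
  expect_gte(nrow(fx$trials), 31)
  expect_lte(nrow(fx$trials), 33)
})

test_that("landmarks are recovered within two frames on synthetic blocks", {
  for (style in c("discrete", "rhythmic")) {
    fx <- fx_block(style)
    expect_frames_close(fx$trials$onset_frame, fx$truth$onset_frame, 2)
    expect_frames_close(fx$trials$peak_frame, fx$truth$peak_frame, 2)
    expect_frames_close(fx$trials$md_frame, fx$truth$md_frame, 2)
    # ordering invariant on every accepted trial
    ok <- !fx$trials$excluded
    expect_true(all(fx$trials$onset_frame[ok] <= fx$trials$peak_frame[ok]))
    expect_true(all(fx$trials$peak_frame[ok] <= fx$trials$md_frame[ok]))
  }
})

test_that("landmark detection rejects degenerate input and picks the higher peak", {
  # stationary hand -> landmark error
  hand_pos <- matrix(rep(c(0.3, 0.05, 1.0), each = 200), 200)
  expect_error(find_landmarks(data.frame(start_frame = 1, end_frame = 200),
                              hand_pos, rep(0, 200), c(2.2, 0, 1.45)),
               "landmark error")
  # two-peak speed profile: the landmark is the higher, second peak
  sp <- c(seq(0, 3, length.out = 50), seq(3, 0.2, length.out = 50),
          seq(0.2, 6, length.out = 50), seq(6, 0.1, length.out = 50))
  hp <- cbind(seq(0, -1, length.out = 200), 0, 1)  # drifting back then
  hp[101:200, 1] <- seq(-1, 0.5, length.out = 100)
  lm <- find_landmarks(data.frame(start_frame = 1, end_frame = 200),
                       hp, sp, c(2.2, 0, 1.45))
  expect_equal(lm$peak_hand_speed, 100 + which.max(sp[101:200]))
})

test_that("exclusion rules follow the simultaneous-gap and long-gap limits", {
  trials <- data.frame(trial = 1:3, start_frame = c(1, 501, 1001),
                       end_frame = c(500, 1000, 1500),
                       excluded = FALSE, excl_reason = NA_character_)
  n_missing <- integer(1500)
  n_missing[250] <- 6L  # > 5 markers gone in trial 1
  report <- list(
    gaps = data.frame(marker = c("w4", "w6"),
                      start_frame = c(600, 1100), length = c(150, 201)),
    n_missing = n_missing)
  out <- apply_exclusions(trials, report)
  expect_true(out$excluded[1])
  expect_false(out$excluded[2])     # 150-frame gap: kept everywhere
  expect_false(out$profile_excluded[2])
  expect_false(out$excluded[3])     # 201-frame gap: metrics kept,
  expect_true(out$profile_excluded[3])  # profiles excluded
})
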