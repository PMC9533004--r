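#' Minimum-distance error of a trial
#'
#' The error is the minimum distance between the whip and the target over
#' the trial: the distal whip polyline (through w1, w2, w3) against the
#' target segment (through t1, t2), minimised over all frames of the trial.
#' The distance is the exact continuous minimum between the interpolated
#' polylines (the limit of sampling them at arbitrarily fine spacing). The
#' `span = "throw"` variant restricts the minimum to the throw interval
#' (onset to minimum distance).
#'
#' @param dataset filtered [marker_dataset()].
#' @param trial one-row trial record with frames (and `onset_frame` for the
#'   throw span).
#' @param span `"trial"` (default) or `"throw"`.
#' @return minimum distance in metres; `NA` when the distal markers are
#'   gapped throughout the span.
#' @export
minimum_distance_error <- function(dataset, trial, span = c("trial", "throw")) {
  span <- match.arg(span)
  from <- if (span == "throw" && !is.na(trial$onset_frame)) trial$onset_frame
          else trial$start_frame
  frames <- from:trial$end_frame
  d <- whip_target_distance(dataset, frames)
  if (all(is.na(d))) return(NA_real_)
  min(d, na.rm = TRUE)
}

# Band-passed oscillation amplitude of the target marker t1 around the
# spring frequency, per frame (NA-safe; gaps propagate).
target_oscillation_envelope <- function(dataset, config) {
  fs <- dataset$sampling_rate
  x <- marker_xyz(dataset, "t1")
  lo <- max(0.5, config$hit_freq_hz - config$hit_band_hz)
  hi <- config$hit_freq_hz + config$hit_band_hz
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  bp <- matrix(NA_real_, nrow(x), 3)
  ok <- rowSums(is.na(x)) == 0
  spans <- valid_spans(ok)
  edge <- round(0.25 * fs)
  for (i in seq_len(nrow(spans))) {
    idx <- spans$start[i]:(spans$start[i] + spans$length[i] - 1)
    if (length(idx) < 12) next
    for (j in 1:3)  # demean first: edge transients scale with the offset
      bp[idx, j] <- signal::filtfilt(bf, x[idx, j] - mean(x[idx, j]))
    if (length(idx) > 2 * edge) {  # blank the filter warm-up at span edges
      bp[head(idx, edge), ] <- NA_real_
      bp[tail(idx, edge), ] <- NA_real_
    }
  }
  vnorm(bp)
}

#' Detect whether a trial hit the target
#'
#' Oscillations of the sprung target caused by contact are the hit
#' indicator: the t1 marker trajectory is band-passed around the spring's
#' free frequency and a hit is declared when the post-trial oscillation
#' amplitude exceeds the calibrated threshold above the pre-trial baseline.
#' Trials whose target was still oscillating before the trial end (e.g. from
#' the previous rhythmic hit) are flagged `ambiguous`.
#'
#' @param dataset filtered [marker_dataset()].
#' @param trial one-row trial record.
#' @param config a [pipeline_config()].
#' @param envelope optional precomputed [target_oscillation_envelope] series.
#' @return list with logical `hit` and `ambiguous`.
#' @export
detect_hit <- function(dataset, trial, config = pipeline_config(),
                       envelope = NULL) {
  fs <- dataset$sampling_rate
  if (is.null(envelope)) envelope <- target_oscillation_envelope(dataset, config)
  w <- round(config$hit_window * fs)
  post <- trial$end_frame:min(length(envelope), trial$end_frame + w)
  pre_hi <- max(trial$start_frame,
                trial$end_frame - round(0.1 * fs))
  pre <- max(1, pre_hi - w):pre_hi
  amp_post <- suppressWarnings(max(envelope[post], na.rm = TRUE))
  amp_pre <- suppressWarnings(max(envelope[pre], na.rm = TRUE))
  if (!is.finite(amp_post)) return(list(hit = NA, ambiguous = TRUE))
  if (!is.finite(amp_pre)) amp_pre <- 0
  list(hit = amp_post > config$hit_threshold &&
         amp_post > amp_pre + config$hit_threshold / 2,
       ambiguous = amp_pre > config$hit_threshold)
}

# Nearest frame to `frame` (within +/- window) at which all `markers` are
# valid; NA when none.
nearest_valid_frame <- function(dataset, frame, markers, window = 5) {
  cand <- unique(pmax(1L, pmin(n_frames(dataset), frame + seq(-window, window))))
  cand <- cand[order(abs(cand - frame), cand)]
  for (f in cand) {
    if (!any(dataset$gap_mask[f, markers])) return(f)
  }
  NA_integer_
}

#' Whip extension at a frame
#'
#' Euclidean distance between the distal handle marker h1 and the whip tip
#' w1 (primary definition, metres), with the ratio to the whip arc length;
#' the alternative tip-to-base variant (w1 to w10, as a ratio) is also
#' returned. Evaluated at the peak-hand-speed landmark in the pipeline; if a
#' needed marker is gapped there the nearest valid frame within +/-5 frames
#' is used.
#'
#' @param dataset filtered [marker_dataset()].
#' @param frame frame index (typically the peak-hand-speed landmark).
#' @param config a [pipeline_config()].
#' @return list with `extension`, `extension_ratio`, `extension_w1w10`,
#'   `extension_ratio_w1w10`.
#' @export
whip_extension <- function(dataset, frame, config = pipeline_config()) {
  f <- nearest_valid_frame(dataset, frame, c("h1", "w1"), config$landmark_fallback)
  out <- list(extension = NA_real_, extension_ratio = NA_real_,
              extension_w1w10 = NA_real_, extension_ratio_w1w10 = NA_real_)
  L <- dataset$schema$whip_arclength
  if (!is.na(f)) {
    e <- sqrt(sum((dataset$positions[f, "h1", ] - dataset$positions[f, "w1", ])^2))
    out$extension <- e
    out$extension_ratio <- e / L
  }
  f2 <- nearest_valid_frame(dataset, frame, c("w10", "w1"), config$landmark_fallback)
  if (!is.na(f2)) {
    e2 <- sqrt(sum((dataset$positions[f2, "w10", ] - dataset$positions[f2, "w1", ])^2))
    out$extension_w1w10 <- e2
    out$extension_ratio_w1w10 <- e2 / L
  }
  out
}

#' Whip azimuth at a frame
#'
#' Fits a line by SVD through the whip and distal-handle markers (w1..w10
#' and h1), oriented handle-to-tip, projects it to the horizontal plane and
#' measures its angle against the target direction: 0 deg points straight
#' backward from the target, positive angles toward the participant's right.
#'
#' @inheritParams whip_extension
#' @return azimuth in degrees, `NA` (with a warning) when degenerate.
#' @export
whip_azimuth <- function(dataset, frame, config = pipeline_config()) {
  mk <- c("h1", paste0("w", 10:1))
  f <- nearest_valid_frame(dataset, frame, mk, config$landmark_fallback)
  if (is.na(f)) {
    # allow a partial cloud (>= 3 valid markers) at the exact frame
    f <- frame
    if (sum(!dataset$gap_mask[f, mk]) < 3) return(NA_real_)
  }
  pts <- dataset$positions[f, mk, ]
  fit_line_azimuth(pts, from = 1, to = length(mk))
}

#' Hand-handle azimuth at a frame
#'
#' Orientation of the hand-handle rigid body's long axis: the direction from
#' the proximal end (mean of h2 and the hand marker) to the distal end (mean
#' of w10 and h1), projected to the horizontal plane, with the same sign
#' convention as [whip_azimuth()] (0 deg along the sagittal line pointing
#' backward from the target).
#'
#' @inheritParams whip_extension
#' @return azimuth in degrees, `NA` when construction markers are missing.
#' @export
hand_azimuth <- function(dataset, frame, config = pipeline_config()) {
  mk <- c("w10", "h1", "h2", "hand_MC5")
  f <- nearest_valid_frame(dataset, frame, mk, config$landmark_fallback)
  if (is.na(f)) return(NA_real_)
  distal <- (dataset$positions[f, "w10", ] + dataset$positions[f, "h1", ]) / 2
  proximal <- (dataset$positions[f, "h2", ] + dataset$positions[f, "hand_MC5", ]) / 2
  d <- distal - proximal
  if (sqrt(sum(d[1:2]^2)) < 1e-9) return(NA_real_)
  azimuth_deg(d)
}

#' Peak hand and tip speeds of a trial
#'
#' The peak hand speed is the maximum of the hand tangential speed over the
#' trial interval (the peak-hand-speed landmark frame); the peak tip speed
#' is the maximum of the w2 marker speed over the throw interval (onset to
#' minimum distance), matching the interval over which the whip speed
#' profiles are analysed. w2 stands in for the tip, whose own marker is too
#' noisy to differentiate reliably.
#'
#' @param trial one-row trial record (with `onset_frame` when available).
#' @param hand_speed,tip_speed block-long speed series.
#' @return list with `peak_hand_speed`, `peak_tip_speed`, `peak_frame`.
#' @export
peak_speeds <- function(trial, hand_speed, tip_speed) {
  idx <- trial$start_frame:trial$end_frame
  hs <- hand_speed[idx]
  from <- if (!is.null(trial$onset_frame) && !is.na(trial$onset_frame))
    trial$onset_frame else trial$start_frame
  ts <- tip_speed[from:trial$end_frame]
  if (all(is.na(hs)))
    return(list(peak_hand_speed = NA_real_, peak_tip_speed = NA_real_,
                peak_frame = NA_integer_))
  list(peak_hand_speed = max(hs, na.rm = TRUE),
       peak_tip_speed = if (all(is.na(ts))) NA_real_ else max(ts, na.rm = TRUE),
       peak_frame = idx[which.max(hs)])
}

#' Rhythmicity of a block
#'
#' Coefficient of variation (sample SD over mean) of the inter-trial
#' intervals — start-to-start times, which equal trial durations in the
#' rhythmic style.
#'
#' @param intervals numeric vector of inter-trial intervals in seconds, or a
#'   trial data.frame (with `start_frame`) plus `sampling_rate`.
#' @param sampling_rate needed when `intervals` is a trial table.
#' @return CoV (dimensionless); `NA` when fewer than two intervals.
#' @export
rhythmicity <- function(intervals, sampling_rate = NULL) {
  if (is.data.frame(intervals)) {
    stopifnot(!is.null(sampling_rate))
    intervals <- diff(intervals$start_frame) / sampling_rate
  }
  intervals <- intervals[!is.na(intervals)]
  if (length(intervals) < 2) return(NA_real_)
  sd(intervals) / mean(intervals)
}

#' Compute all per-trial metrics for one block
#'
#' @param dataset filtered [marker_dataset()] of the block.
#' @param trials trial table from [segment_block()].
#' @param hand_speed,tip_speed optional precomputed speed series.
#' @param config a [pipeline_config()].
#' @return data.frame, one row per trial, with the trial bookkeeping plus
#'   error, error_throw, hit, ambiguous, extension columns, whip/hand
#'   azimuths, peak speeds and inter-trial interval.
#' @export
trial_metrics <- function(dataset, trials, hand_speed = NULL, tip_speed = NULL,
                          config = pipeline_config()) {
  if (is.null(hand_speed) || is.null(tip_speed)) {
    vel <- differentiate(dataset, 1)
    sp <- tangential_speed(vel)
    if (is.null(hand_speed)) hand_speed <- sp[, "hand_MC5"]
    if (is.null(tip_speed)) tip_speed <- sp[, "w2"]
  }
  fs <- dataset$sampling_rate
  env <- target_oscillation_envelope(dataset, config)
  n <- nrow(trials)
  add <- data.frame(error = rep(NA_real_, n), error_trial = NA_real_,
                    hit = NA, ambiguous = NA,
                    extension = NA_real_, extension_ratio = NA_real_,
                    extension_w1w10 = NA_real_, extension_ratio_w1w10 = NA_real_,
                    whip_azimuth = NA_real_, hand_azimuth = NA_real_,
                    peak_hand_speed = NA_real_, peak_tip_speed = NA_real_,
                    inter_trial_interval = NA_real_)
  for (i in seq_len(n)) {
    tr <- trials[i, ]
    add$error[i] <- minimum_distance_error(dataset, tr, "throw")
    add$error_trial[i] <- minimum_distance_error(dataset, tr, "trial")
    h <- detect_hit(dataset, tr, config, env)
    add$hit[i] <- h$hit
    add$ambiguous[i] <- h$ambiguous
    ps <- peak_speeds(tr, hand_speed, tip_speed)
    add$peak_hand_speed[i] <- ps$peak_hand_speed
    add$peak_tip_speed[i] <- ps$peak_tip_speed
    pf <- if (!is.na(tr$peak_frame)) tr$peak_frame else ps$peak_frame
    if (!is.na(pf)) {
      ex <- whip_extension(dataset, pf, config)
      add$extension[i] <- ex$extension
      add$extension_ratio[i] <- ex$extension_ratio
      add$extension_w1w10[i] <- ex$extension_w1w10
      add$extension_ratio_w1w10[i] <- ex$extension_ratio_w1w10
      add$whip_azimuth[i] <- suppressWarnings(whip_azimuth(dataset, pf, config))
      add$hand_azimuth[i] <- hand_azimuth(dataset, pf, config)
    }
  }
  if (n >= 2)
    add$inter_trial_interval[seq_len(n - 1)] <- diff(trials$start_frame) / fs
  cbind(trials, add)
}

#' Block-level summary of trial metrics
#'
#' Success rate (percentage of non-excluded trials that hit), rhythmicity
#' (CoV of inter-trial intervals), medians and IQRs for the skewed metrics
#' (error, extension) and means and SDs for the rest.
#'
#' @param tm trial-metrics data.frame from [trial_metrics()].
#' @return one-row data.frame of block statistics.
#' @export
block_metrics <- function(tm) {
  ok <- !tm$excluded
  t_ok <- tm[ok, , drop = FALSE]
  iqr <- function(x) diff(quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE))
  data.frame(
    n_trials = nrow(tm), n_excluded = sum(tm$excluded),
    success_rate = if (any(ok)) 100 * mean(t_ok$hit, na.rm = TRUE) else NA_real_,
    rhythmicity = rhythmicity(t_ok$inter_trial_interval),
    interval_mean = mean(t_ok$inter_trial_interval, na.rm = TRUE),
    error_median = median(t_ok$error, na.rm = TRUE),
    error_iqr = iqr(t_ok$error),
    extension_median = median(t_ok$extension, na.rm = TRUE),
    extension_iqr = iqr(t_ok$extension),
    whip_azimuth_mean = mean(t_ok$whip_azimuth, na.rm = TRUE),
    whip_azimuth_sd = sd(t_ok$whip_azimuth, na.rm = TRUE),
    hand_azimuth_mean = mean(t_ok$hand_azimuth, na.rm = TRUE),
    hand_azimuth_sd = sd(t_ok$hand_azimuth, na.rm = TRUE),
    peak_hand_speed_mean = mean(t_ok$peak_hand_speed, na.rm = TRUE),
    peak_hand_speed_sd = sd(t_ok$peak_hand_speed, na.rm = TRUE),
    peak_tip_speed_mean = mean(t_ok$peak_tip_speed, na.rm = TRUE),
    peak_tip_speed_sd = sd(t_ok$peak_tip_speed, na.rm = TRUE))
}
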