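#' Pipeline configuration defaults
#'
#' All thresholds of the segmentation and metric stages in one flat list,
#' with defaults equal to the study's stated values: hand-speed threshold
#' 0.5 m/s, whip-lift height 2 cm, exclusion limits of 5 simultaneously
#' missing markers and 200-frame (0.4 s) gaps, filter cutoffs 20 Hz (body)
#' and 40 Hz (whip/handle/target). Repo-chosen values: 1.0 s search window
#' for the speed crossing before lift, 0.3 s refractory period between
#' minimum-distance events, 1.0 m ceiling for event minima, 50-frame gap
#' bridging limit, 500-sample profile grid, hit-detection band around the
#' target spring frequency.
#'
#' @param ... overrides for any default, by name.
#' @return named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    speed_threshold = 0.5,     # m/s, discrete trial start
    lift_height = 0.02,        # m, whip lift off the floor
    lift_debounce = 25,        # frames a lift must persist
    search_window = 1.0,       # s, window before lift for the speed crossing
    refractory = 0.3,          # s, between minimum-distance events
    event_max_distance = 1.0,  # m, ceiling for a credible approach minimum
    max_missing_markers = 5,   # simultaneous-gap exclusion limit
    long_gap_frames = 200,     # frames; longer gaps exclude from profiles
    bridge_max_gap = 50,       # frames bridged by interpolation
    cutoff_body = 20,          # Hz
    cutoff_whip = 40,          # Hz
    profile_samples = 500,
    min_profile_span = 10,     # frames
    landmark_fallback = 5,     # frames, nearest-valid window at a landmark
    hit_band_hz = 2,           # half-width of the hit-detection band
    hit_freq_hz = 4,           # target spring free frequency
    hit_threshold = 0.005,     # m, oscillation amplitude for a hit
    hit_window = 1.0           # s, post-trial window examined for a hit
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config option(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  cfg
}

#' Detect minimum-distance events between whip and target
#'
#' Local minima of the instantaneous whip-to-target distance (distal whip
#' polyline w1-w3 against target segment t1-t2, the same computation as the
#' error metric), separated by a refractory period and below a distance
#' ceiling so that far-from-target wiggles are ignored. One event terminates
#' each throw/cycle.
#'
#' @param dataset a (filtered) [marker_dataset()], or a numeric distance
#'   series when `distance = TRUE`.
#' @param config a [pipeline_config()].
#' @param distance set `TRUE` when `dataset` is already a distance series.
#' @return integer vector of event frames (possibly empty), ordered.
#' @export
detect_minimum_distance_events <- function(dataset, config = pipeline_config(),
                                           distance = FALSE) {
  if (distance) {
    d <- as.numeric(dataset)
    fs <- config$fs %||% 500
  } else {
    d <- whip_target_distance(dataset)
    fs <- dataset$sampling_rate
  }
  dmax <- max(d, na.rm = TRUE) + 1
  dfil <- ifelse(is.na(d), dmax, d)
  pk <- pracma::findpeaks(-dfil,
                          minpeakheight = -config$event_max_distance,
                          minpeakdistance = max(1L, round(config$refractory * fs)))
  if (is.null(pk)) return(integer(0))
  sort(as.integer(pk[, 2]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Upward crossings of `x` through `thr`: frames i with x[i-1] < thr <= x[i].
upward_crossings <- function(x, thr) {
  x <- as.numeric(x)
  which(c(FALSE, x[-1] >= thr & x[-length(x)] < thr))
}

#' Parse a discrete-style block into trials
#'
#' A discrete trial starts at the last upward crossing of hand speed through
#' the 0.5 m/s threshold preceding the lift of the whip from the floor (all
#' of w1, w2, w3 above 2 cm), and ends at the next minimum-distance event.
#'
#' @param dataset a filtered [marker_dataset()].
#' @param hand_speed hand tangential-speed series (from
#'   [tangential_speed()]); computed from the dataset when missing.
#' @param events minimum-distance event frames; detected when missing.
#' @param config a [pipeline_config()].
#' @return data.frame of trials: trial, start_frame, end_frame, lift_frame,
#'   excluded, excl_reason.
#' @export
parse_discrete <- function(dataset, hand_speed = NULL, events = NULL,
                           config = pipeline_config()) {
  fs <- dataset$sampling_rate
  if (is.null(hand_speed)) {
    vel <- differentiate(dataset, 1)
    hand_speed <- tangential_speed(vel[, "hand_MC5", ])
  }
  if (is.null(events)) events <- detect_minimum_distance_events(dataset, config)
  empty <- data.frame(trial = integer(), start_frame = integer(),
                      end_frame = integer(), lift_frame = integer(),
                      excluded = logical(), excl_reason = character())
  if (!length(events)) return(empty)
  z <- dataset$positions[, c("w1", "w2", "w3"), 3]
  lifted <- rowSums(z > config$lift_height, na.rm = TRUE) == 3 &
    rowSums(is.na(z)) == 0
  runs <- true_runs(lifted)
  runs <- runs[runs$length >= config$lift_debounce, , drop = FALSE]
  if (!nrow(runs)) return(empty)
  out <- list()
  prev_event <- 0L
  for (i in seq_along(events)) {
    ev <- events[i]
    cand <- runs$start[runs$start <= ev & runs$start > prev_event]
    prev_event <- ev
    if (!length(cand)) next
    lift <- max(cand)
    w0 <- max(1L, lift - round(config$search_window * fs))
    cross <- upward_crossings(hand_speed[w0:lift], config$speed_threshold)
    if (length(cross)) {
      start <- w0 + max(cross) - 1L
      out[[length(out) + 1]] <- data.frame(
        start_frame = start, end_frame = ev, lift_frame = lift,
        excluded = FALSE, excl_reason = NA_character_)
    } else {
      out[[length(out) + 1]] <- data.frame(
        start_frame = lift, end_frame = ev, lift_frame = lift,
        excluded = TRUE, excl_reason = "no hand-speed crossing before lift")
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  cbind(trial = seq_len(nrow(res)), res)
}

#' Parse a rhythmic-style block into trials
#'
#' Consecutive minimum-distance events bound consecutive trials; trials tile
#' the inter-event span with no overlap (each start is the previous end).
#'
#' @inheritParams parse_discrete
#' @return data.frame of trials as in [parse_discrete()] (`lift_frame` is
#'   `NA` for rhythmic trials).
#' @export
parse_rhythmic <- function(dataset, events = NULL, config = pipeline_config()) {
  if (is.null(events)) events <- detect_minimum_distance_events(dataset, config)
  if (length(events) < 2)
    return(data.frame(trial = integer(), start_frame = integer(),
                      end_frame = integer(), lift_frame = integer(),
                      excluded = logical(), excl_reason = character()))
  n <- length(events) - 1
  data.frame(trial = seq_len(n),
             start_frame = as.integer(events[seq_len(n)]),
             end_frame = as.integer(events[seq_len(n) + 1]),
             lift_frame = NA_integer_,
             excluded = FALSE, excl_reason = NA_character_)
}

#' Locate the three temporal landmarks of a trial
#'
#' Throw onset is the frame of maximum hand-to-target distance within the
#' trial (hand pointing backward), peak hand speed the frame of maximum hand
#' tangential speed, and minimum distance the trial end. Ties break to the
#' earliest frame. The ordering onset <= peak <= minimum-distance is
#' enforced.
#'
#' @param trial one-row trial record with `start_frame`, `end_frame`.
#' @param hand_pos frames x 3 hand marker positions for the whole block.
#' @param hand_speed hand tangential-speed series for the whole block.
#' @param target_pos length-3 target reference position (e.g. mean t1).
#' @return list with `throw_onset`, `peak_hand_speed`, `minimum_distance`
#'   (block frame indices).
#' @export
find_landmarks <- function(trial, hand_pos, hand_speed, target_pos) {
  idx <- trial$start_frame:trial$end_frame
  sp <- hand_speed[idx]
  if (all(is.na(sp)) || diff(range(sp, na.rm = TRUE)) < 1e-9)
    stop("landmark error: hand speed is missing or constant over the trial")
  dist <- vnorm(sweep(hand_pos[idx, , drop = FALSE], 2, target_pos))
  t_on <- idx[which.max(dist)]
  t_pk <- idx[which.max(sp)]
  t_md <- trial$end_frame
  if (!(t_on <= t_pk && t_pk <= t_md))
    stop(sprintf(paste0("landmark error: ordering violated (onset %d, peak %d, ",
                        "minimum distance %d)"), t_on, t_pk, t_md))
  list(throw_onset = t_on, peak_hand_speed = t_pk, minimum_distance = t_md)
}

#' Apply the trial-exclusion rules
#'
#' A trial is excluded from all analyses when more than
#' `config$max_missing_markers` markers have simultaneous gaps at any of its
#' frames, and excluded from profile averaging (only) when any single gap
#' longer than `config$long_gap_frames` frames overlaps it.
#'
#' @param trials trial data.frame (from the parsers).
#' @param report a [gap_report()] of the unbridged dataset.
#' @param config a [pipeline_config()].
#' @return the trials with `excluded`, `excl_reason`, `profile_excluded`
#'   updated.
#' @export
apply_exclusions <- function(trials, report, config = pipeline_config()) {
  if (!"profile_excluded" %in% names(trials)) trials$profile_excluded <- FALSE
  if (!nrow(trials)) return(trials)
  nmiss <- report$n_missing
  long <- report$gaps[report$gaps$length > config$long_gap_frames, , drop = FALSE]
  for (i in seq_len(nrow(trials))) {
    idx <- trials$start_frame[i]:trials$end_frame[i]
    if (any(nmiss[idx] > config$max_missing_markers, na.rm = TRUE)) {
      trials$excluded[i] <- TRUE
      trials$excl_reason[i] <- sprintf("more than %d markers simultaneously missing",
                                       config$max_missing_markers)
    }
    if (nrow(long)) {
      overlap <- long$start_frame <= trials$end_frame[i] &
        (long$start_frame + long$length - 1) >= trials$start_frame[i]
      if (any(overlap)) trials$profile_excluded[i] <- TRUE
    }
  }
  trials
}

#' Segment one block into trials with landmarks and exclusion flags
#'
#' Convenience wrapper: detects events, parses trials for the given style,
#' locates landmarks (trials whose landmarks are degenerate or out of order
#' are flagged excluded, never dropped silently), and applies the exclusion
#' rules.
#'
#' @param dataset filtered [marker_dataset()] of one block.
#' @param style `"discrete"` or `"rhythmic"`.
#' @param hand_speed optional precomputed hand speed series.
#' @param report optional [gap_report()] of the raw dataset (defaults to the
#'   report of `dataset`).
#' @param config a [pipeline_config()].
#' @return trial data.frame with landmark frame columns `onset_frame`,
#'   `peak_frame`, `md_frame`.
#' @export
segment_block <- function(dataset, style = c("discrete", "rhythmic"),
                          hand_speed = NULL, report = NULL,
                          config = pipeline_config()) {
  style <- match.arg(style)
  if (is.null(hand_speed)) {
    vel <- differentiate(dataset, 1)
    hand_speed <- tangential_speed(vel[, "hand_MC5", ])
  }
  if (is.null(report)) report <- gap_report(dataset)
  events <- detect_minimum_distance_events(dataset, config)
  trials <- if (style == "discrete")
    parse_discrete(dataset, hand_speed, events, config)
  else parse_rhythmic(dataset, events, config)
  trials$onset_frame <- NA_integer_
  trials$peak_frame <- NA_integer_
  trials$md_frame <- trials$end_frame
  if (nrow(trials)) {
    hand_pos <- marker_xyz(dataset, "hand_MC5")
    tpos <- colMeans(marker_xyz(dataset, "t1"), na.rm = TRUE)
    for (i in seq_len(nrow(trials))) {
      lm <- tryCatch(find_landmarks(trials[i, ], hand_pos, hand_speed, tpos),
                     error = function(e) e)
      if (inherits(lm, "error")) {
        trials$excluded[i] <- TRUE
        trials$excl_reason[i] <- conditionMessage(lm)
      } else {
        trials$onset_frame[i] <- lm$throw_onset
        trials$peak_frame[i] <- lm$peak_hand_speed
      }
    }
  }
  trials <- apply_exclusions(trials, report, config)
  trials$style <- style
  trials
}
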