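#' Preprocess one recording block
#'
#' The standard preprocessing chain: gap report on the raw data, bridging
#' of short gaps, zero-lag low-pass filtering (20 Hz for the hand marker,
#' 40 Hz for whip, handle and target markers), differentiation and
#' tangential speeds.
#'
#' @param dataset raw [marker_dataset()].
#' @param config a [pipeline_config()].
#' @return list with `dataset` (filtered), `report` (raw-data
#'   [gap_report()]), `speed` (frames x markers tangential-speed matrix),
#'   `velocity`.
#' @export
process_block <- function(dataset, config = pipeline_config()) {
  report <- gap_report(dataset)
  ds <- bridge_gaps(dataset, config$bridge_max_gap)
  fs <- ds$sampling_rate
  spec_body <- design_lowpass(config$cutoff_body, fs)
  spec_whip <- design_lowpass(config$cutoff_whip, fs)
  labs <- dimnames(ds$positions)[[2]]
  body <- intersect("hand_MC5", labs)
  whip <- setdiff(labs, body)
  ds <- filter_zero_lag(ds, spec_body, body)
  ds <- filter_zero_lag(ds, spec_whip, whip)
  vel <- differentiate(ds, 1)
  list(dataset = ds, report = report, velocity = vel,
       speed = tangential_speed(vel))
}

#' Analyse one block end to end
#'
#' Preprocess, segment, compute per-trial metrics and the block summary.
#'
#' @param dataset raw [marker_dataset()] of one block.
#' @param style `"discrete"` or `"rhythmic"`.
#' @param config a [pipeline_config()].
#' @return list with `trials` (trial metrics table), `summary`
#'   (one-row block summary), `proc` (the [process_block()] result).
#' @export
analyze_block <- function(dataset, style, config = pipeline_config()) {
  proc <- process_block(dataset, config)
  trials <- segment_block(proc$dataset, style,
                          hand_speed = proc$speed[, "hand_MC5"],
                          report = proc$report, config = config)
  tm <- trial_metrics(proc$dataset, trials,
                      hand_speed = proc$speed[, "hand_MC5"],
                      tip_speed = proc$speed[, "w2"], config = config)
  list(trials = tm, summary = block_metrics(tm), proc = proc)
}

#' Run the full analysis over a study layout
#'
#' Orchestrates preprocessing, segmentation, metrics, profiles and the
#' mixed-model stage over a nested study layout (participants, styles,
#' blocks of datasets or file paths, as produced by [simulate_study()] or
#' assembled from [read_markers()] calls). Deterministic given inputs and
#' config; every excluded trial is kept in the tables with its reason.
#'
#' @param layout nested list: participant -> style -> list of blocks; each
#'   block either a [marker_dataset()], a list with a `dataset` element, or
#'   a file path.
#' @param config a [pipeline_config()].
#' @param profiles compute ensemble speed profiles per participant/style.
#' @param models fit the style-by-block mixed models (needs >= 2
#'   participants and both styles).
#' @return list with `trials` (all trial metrics), `blocks` (block
#'   summaries), `profiles` (long-format profile table), `models`,
#'   `log` (character vector), `config`.
#' @export
run_study <- function(layout, config = pipeline_config(), profiles = TRUE,
                      models = TRUE) {
  all_trials <- list()
  all_blocks <- list()
  prof_rows <- list()
  log <- character()
  for (pid in names(layout)) {
    for (style in names(layout[[pid]])) {
      blocks <- layout[[pid]][[style]]
      for (b in seq_along(blocks)) {
        blk <- blocks[[b]]
        ds <- if (inherits(blk, "marker_dataset")) blk
              else if (is.list(blk) && !is.null(blk$dataset)) blk$dataset
              else if (is.character(blk)) read_markers(blk)
              else stop("unrecognised block entry for ", pid, "/", style)
        res <- analyze_block(ds, style, config)
        tm <- res$trials
        if (nrow(tm)) {
          tm <- cbind(participant = pid, block = b,
                      tm[, setdiff(names(tm), c("participant", "block"))])
          for (i in which(tm$excluded))
            log <- c(log, sprintf("%s %s block %d trial %d excluded: %s",
                                  pid, style, b, tm$trial[i], tm$excl_reason[i]))
          for (i in which(tm$profile_excluded))
            log <- c(log, sprintf("%s %s block %d trial %d excluded from profiles (long gap)",
                                  pid, style, b, tm$trial[i]))
        } else {
          log <- c(log, sprintf("%s %s block %d: no trials parsed", pid, style, b))
        }
        all_trials[[length(all_trials) + 1]] <- tm
        all_blocks[[length(all_blocks) + 1]] <-
          cbind(participant = pid, style = style, block = b, res$summary)
        if (profiles && nrow(tm)) {
          for (mk in c("hand_MC5", paste0("w", 1:10))) {
            span <- if (mk == "hand_MC5") "trial" else "throw"
            pr <- average_profiles(res$proc$dataset, tm, mk, span,
                                   speed = res$proc$speed[, mk], config = config)
            if (attr(pr, "n_trials") > 0)
              prof_rows[[length(prof_rows) + 1]] <- data.frame(
                participant = pid, style = style, block = b, marker = mk,
                span = span, normalized_time = pr$normalized_time,
                mean = pr$mean, sd = pr$sd, n_trials = attr(pr, "n_trials"))
          }
        }
      }
    }
  }
  trials <- do.call(rbind, all_trials)
  blocks <- do.call(rbind, all_blocks)
  mdl <- NULL
  if (models && !is.null(trials) &&
      length(unique(trials$participant)) >= 2 &&
      length(unique(trials$style)) == 2) {
    ok <- trials[!trials$excluded, , drop = FALSE]
    mdl <- list(
      error = tryCatch(fit_style_block_model(ok, "error", "gaussian"),
                       error = function(e) conditionMessage(e)),
      hit = tryCatch(fit_style_block_model(ok, "hit", "binomial"),
                     error = function(e) conditionMessage(e)),
      peak_hand_speed = tryCatch(
        fit_style_block_model(ok, "peak_hand_speed", "gaussian"),
        error = function(e) conditionMessage(e)))
  }
  list(trials = trials, blocks = blocks,
       profiles = if (length(prof_rows)) do.call(rbind, prof_rows) else NULL,
       models = mdl, log = log, config = config)
}

#' Rank participants by median error
#'
#' Participants ordered by ascending median error across both styles (the
#' ordering used to number participants in the performance figures); ties
#' break by participant label.
#'
#' @param trials trial-metrics table with `participant` and `error`.
#' @return data.frame with participant, median_error and rank.
#' @export
rank_participants <- function(trials) {
  ok <- trials[!is.na(trials$error), , drop = FALSE]
  if (!is.null(ok$excluded)) ok <- ok[!ok$excluded, , drop = FALSE]
  med <- tapply(ok$error, ok$participant, median)
  out <- data.frame(participant = names(med), median_error = as.numeric(med))
  out <- out[order(out$median_error, out$participant), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
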