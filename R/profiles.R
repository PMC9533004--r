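#' Time-normalise a speed series onto a fixed sample grid
#'
#' Linear resampling of the series over the span onto `n_samples` uniformly
#' spaced points; endpoint values are preserved. A fixed grid is equivalent
#' to normalising every trial to the mean span duration up to a relabelling
#' of the time axis, and makes cross-trial averaging immediate.
#'
#' @param x numeric series defined over the span.
#' @param n_samples number of output samples.
#' @return numeric vector of length `n_samples`.
#' @export
time_normalize <- function(x, n_samples = 500) {
  n <- length(x)
  stopifnot(n >= 2)
  approx(seq_len(n), x, xout = seq(1, n, length.out = n_samples))$y
}

#' Ensemble-average speed profiles aligned at minimum distance
#'
#' For every eligible trial, the speed series of the chosen marker over the
#' chosen span (throw interval: onset to minimum distance; trial interval:
#' start to minimum distance) is time-normalised to a common grid whose last
#' sample is the minimum-distance landmark; the per-sample mean and sample
#' SD across trials form the profile. Trials flagged `profile_excluded`,
#' trials with missing landmarks or samples, and spans shorter than
#' `config$min_profile_span` frames are skipped.
#'
#' @param dataset filtered [marker_dataset()].
#' @param trials trial table from [segment_block()].
#' @param marker marker whose tangential speed is profiled (`"hand_MC5"`,
#'   `"w1"`..`"w10"`).
#' @param span `"throw"` or `"trial"`.
#' @param speed optional precomputed speed series for `marker`.
#' @param config a [pipeline_config()].
#' @return object of class `speed_profile`: data.frame with
#'   `normalized_time` on \[-1, 0\] (0 = minimum distance), `mean`, `sd`, and
#'   attributes `n_trials`, `marker`, `span`.
#' @export
average_profiles <- function(dataset, trials, marker = "hand_MC5",
                             span = c("throw", "trial"), speed = NULL,
                             config = pipeline_config()) {
  span <- match.arg(span)
  n_s <- config$profile_samples
  if (is.null(speed)) {
    vel <- differentiate(dataset, 1)
    speed <- tangential_speed(vel[, marker, ])
  }
  rows <- list()
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    if (isTRUE(tr$excluded) || isTRUE(tr$profile_excluded)) next
    from <- if (span == "throw") tr$onset_frame else tr$start_frame
    if (is.na(from) || is.na(tr$md_frame)) next
    idx <- from:tr$md_frame
    if (length(idx) < config$min_profile_span) next
    s <- speed[idx]
    if (anyNA(s)) next  # gapped beyond the interpolation limit
    rows[[length(rows) + 1]] <- time_normalize(s, n_s)
  }
  n_tr <- length(rows)
  if (!n_tr) {
    prof <- data.frame(normalized_time = seq(-1, 0, length.out = n_s),
                       mean = NA_real_, sd = NA_real_)
  } else {
    M <- do.call(rbind, rows)
    prof <- data.frame(normalized_time = seq(-1, 0, length.out = n_s),
                       mean = colMeans(M),
                       sd = if (n_tr > 1) apply(M, 2, sd) else rep(0, n_s))
  }
  structure(prof, class = c("speed_profile", "data.frame"),
            n_trials = n_tr, marker = marker, span = span)
}

#' Per-marker peak times of the whip unfolding cascade
#'
#' Index (on the normalised grid) of the maximum of each whip marker's mean
#' speed profile, ordered from the handle-adjacent marker (w10) to the tip
#' (w1). A strictly increasing sequence is the proximal-to-distal cascade
#' signature of the unfolding whip.
#'
#' @param dataset filtered [marker_dataset()].
#' @param trials trial table.
#' @param markers whip markers, proximal first.
#' @param span profile span.
#' @param config a [pipeline_config()].
#' @return named integer vector of argmax sample indices.
#' @export
cascade_peak_times <- function(dataset, trials, markers = paste0("w", 10:1),
                               span = "throw", config = pipeline_config()) {
  vel <- differentiate(dataset, 1)
  sp <- tangential_speed(vel)
  vapply(markers, function(m) {
    pr <- average_profiles(dataset, trials, m, span, speed = sp[, m],
                           config = config)
    if (attr(pr, "n_trials") == 0) return(NA_integer_)
    which.max(pr$mean)
  }, integer(1))
}
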