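# Cohort-level generators: trial-metric tables drawn directly from the
# mixed-model generative form (fixed style/block/covariate effects plus
# per-participant random coefficients), used for parameter-recovery and
# calibration checks of the statistical stage.

default_metric_plants <- function() {
  # beta = (intercept, style, block, style x block); style dummy rhythmic=1.
  list(
    error = list(beta = c(0.15, 0.10, -0.003, -0.006),
                 sd_re = c(0.06, 0.04, 0.005), sd_resid = 0.08),
    hit = list(beta = c(-0.8, -1.11, 0.05, 0.10),
               sd_re = c(0.8, 0.4, 0.05), sd_resid = NA),
    interval = list(beta = c(5.4, -4.16, -0.05, 0.04),
                    sd_re = c(0.6, 0.55, 0.03), sd_resid = 0.8),
    extension = list(beta = c(1.444, 0.037, 0.002, 0.006),
                     sd_re = c(0.05, 0.03, 0.003), sd_resid = 0.10),
    whip_azimuth = list(beta = c(-10.9, 39.43, -0.230, 0),
                        sd_re = c(12, 10, 1), sd_resid = 18),
    hand_azimuth = list(beta = c(20.1, 16.6, 1.4, -1.6),
                        sd_re = c(10, 8, 1), sd_resid = 15),
    peak_hand_speed = list(beta = c(5.83, -1.24, 0.09, -0.11),
                           sd_re = c(1.0, 0.6, 0.05), sd_resid = 0.9),
    peak_tip_speed = list(beta = c(28.4, -5.02, 0.448, -0.215),
                          sd_re = c(5, 3, 0.3), sd_resid = 5))
}

#' Parameters of a simulated cohort
#'
#' Study-scale defaults: 16 participants, 5 blocks per style, about 33
#' trials per block, with fixed-effect plants taken from the reported
#' style/block coefficients of each metric and plausible random-effect and
#' residual spreads.
#'
#' @param n_participants number of participants.
#' @param n_blocks blocks per style.
#' @param trials_per_block trials per block.
#' @param metrics named list of plants per metric: `beta` (intercept,
#'   style, block, interaction), `sd_re` (random intercept/style/block
#'   SDs), `sd_resid`.
#' @param seed RNG seed.
#' @return object of class `cohort_params`.
#' @export
cohort_params <- function(n_participants = 16, n_blocks = 5,
                          trials_per_block = 33,
                          metrics = default_metric_plants(), seed = 1) {
  stopifnot(n_participants >= 1, n_blocks >= 1, trials_per_block >= 1)
  for (m in metrics) {
    stopifnot(length(m$beta) == 4, length(m$sd_re) == 3, all(m$sd_re >= 0))
  }
  structure(list(n_participants = n_participants, n_blocks = n_blocks,
                 trials_per_block = trials_per_block, metrics = metrics,
                 seed = seed),
            class = "cohort_params")
}

#' Simulate a trial-level metric table from the mixed-model generative form
#'
#' Each metric is drawn independently as
#' `Y = (b0 + P0i) + (bS + PSi) S + (bB + PBi) B + bSB S B + eps`,
#' with participant random coefficients `P ~ N(0, sd_re)`; the `hit` metric
#' is drawn as a Bernoulli response with that linear predictor on the logit
#' scale.
#'
#' @param params a [cohort_params()].
#' @return list with `table` (trial-level data.frame: participant, style,
#'   block, trial, one column per metric) and `truth` (the planted
#'   parameters).
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  with_seed(params$seed, {
    grid <- expand.grid(trial = seq_len(params$trials_per_block),
                        block = seq_len(params$n_blocks),
                        style = c("discrete", "rhythmic"),
                        participant = sprintf("P%02d", seq_len(params$n_participants)),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    S <- as.numeric(grid$style == "rhythmic")
    B <- as.numeric(grid$block)
    pid <- match(grid$participant, unique(grid$participant))
    np <- params$n_participants
    for (mn in names(params$metrics)) {
      m <- params$metrics[[mn]]
      P <- cbind(rnorm(np, 0, m$sd_re[1]), rnorm(np, 0, m$sd_re[2]),
                 rnorm(np, 0, m$sd_re[3]))
      eta <- (m$beta[1] + P[pid, 1]) + (m$beta[2] + P[pid, 2]) * S +
        (m$beta[3] + P[pid, 3]) * B + m$beta[4] * S * B
      grid[[mn]] <- if (mn == "hit") rbinom(nrow(grid), 1, plogis(eta))
                    else eta + rnorm(nrow(grid), 0, m$sd_resid)
    }
    list(table = grid, truth = params$metrics)
  })
}

#' Simulate an error-covariate cohort
#'
#' Generates trial-level (covariate, error) pairs from
#' `E = (b0 + P0i) + (bS + PSi) S + (bX + PXi) X + bSX S X + eps`, the
#' generative form matched by [fit_error_correlation()]: per-style covariate
#' distributions, participant random intercepts and style/covariate slopes.
#'
#' @param n_participants participants.
#' @param trials_per_style trials per participant per style.
#' @param beta fixed effects `c(b0, bS, bX, bSX)`.
#' @param sd_re random-effect SDs `c(intercept, style, covariate slope)`.
#' @param sd_resid residual SD.
#' @param x_mean per-style covariate means `c(discrete, rhythmic)`.
#' @param x_sd covariate SD.
#' @param covariate,response column names in the output table.
#' @param seed RNG seed.
#' @return list with `table` and `truth`.
#' @export
simulate_covariate_cohort <- function(n_participants = 16,
                                      trials_per_style = 150,
                                      beta = c(0.35, 0.1, -0.04, -0.113),
                                      sd_re = c(0.05, 0.03, 0.02),
                                      sd_resid = 0.08,
                                      x_mean = c(1.45, 1.43), x_sd = 0.08,
                                      covariate = "extension",
                                      response = "error", seed = 1) {
  with_seed(seed, {
    grid <- expand.grid(trial = seq_len(trials_per_style),
                        style = c("discrete", "rhythmic"),
                        participant = sprintf("P%02d", seq_len(n_participants)),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    S <- as.numeric(grid$style == "rhythmic")
    pid <- match(grid$participant, unique(grid$participant))
    P <- cbind(rnorm(n_participants, 0, sd_re[1]),
               rnorm(n_participants, 0, sd_re[2]),
               rnorm(n_participants, 0, sd_re[3]))
    X <- rnorm(nrow(grid), x_mean[1] + (x_mean[2] - x_mean[1]) * S, x_sd)
    E <- (beta[1] + P[pid, 1]) + (beta[2] + P[pid, 2]) * S +
      (beta[3] + P[pid, 3]) * X + beta[4] * S * X +
      rnorm(nrow(grid), 0, sd_resid)
    grid[[covariate]] <- X
    grid[[response]] <- E
    list(table = grid,
         truth = list(beta = beta, sd_re = sd_re, sd_resid = sd_resid,
                      slope_discrete = beta[3],
                      slope_rhythmic = beta[3] + beta[4]))
  })
}

#' Simulate a full-scene multi-participant study
#'
#' Routes the cohort through the kinematic scene generator: each
#' participant gets per-participant draws of skill level (error scale, hand
#' peaks, azimuths, extension, interval variability) around the study
#' means, and each style x block is generated with [simulate_block()]. The
#' result is a study layout consumable by [run_study()], with full ground
#' truth.
#'
#' @param n_participants participants (scale down for quick runs).
#' @param n_blocks blocks per style.
#' @param discrete_duration,rhythmic_duration block durations in seconds.
#' @param noise_sd marker noise, metres.
#' @param seed RNG seed.
#' @return list of participants; each participant is a list of styles; each
#'   style a list of blocks, each with `dataset` and `truth`.
#' @export
simulate_study <- function(n_participants = 2, n_blocks = 1,
                           discrete_duration = 60, rhythmic_duration = 40,
                           noise_sd = 3e-4, seed = 1) {
  with_seed(seed, {
    out <- list()
    for (i in seq_len(n_participants)) {
      id <- sprintf("P%02d", i)
      clamp <- function(x, lo, hi) min(max(x, lo), hi)
      err_med <- exp(rnorm(1, log(0.10), 0.45))
      peak_d <- clamp(rnorm(1, 6.1, 0.8), 5.2, 7.3)
      peak_r <- clamp(rnorm(1, 4.5, 0.6), 3.8, 5.4)
      az_d <- clamp(rnorm(1, -10.9, 12), -32, 12)
      az_r <- clamp(rnorm(1, 28.4, 10), 8, 50)
      ext_d <- clamp(rnorm(1, 1.45, 0.05), 1.30, 1.50)
      ext_r <- clamp(rnorm(1, 1.43, 0.04), 1.30, 1.50)
      cov_d <- max(rnorm(1, 0.12, 0.04), 0.02)
      cov_r <- max(rnorm(1, 0.06, 0.02), 0.01)
      styles <- list()
      for (st in c("discrete", "rhythmic")) {
        d <- st == "discrete"
        pk2 <- if (d) peak_d else peak_r
      sp <- scene_params(st,
                           hand_peak2 = pk2,
                           hand_peak1 = 0.57 * pk2,
                           planted_azimuth = if (d) az_d else az_r,
                           planted_extension = if (d) ext_d else ext_r,
                           planted_error = err_med,
                           interval_cov = if (d) cov_d else cov_r,
                           noise_sd = noise_sd)
        blocks <- list()
        for (b in seq_len(n_blocks)) {
          blocks[[b]] <- simulate_block(
            sp, duration = if (d) discrete_duration else rhythmic_duration,
            seed = sample.int(.Machine$integer.max, 1))
        }
        styles[[st]] <- blocks
      }
      out[[id]] <- styles
    }
    out
  })
}
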