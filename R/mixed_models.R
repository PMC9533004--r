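# Coerce the trial table to the model coding: participant factor, style
# dummy S (discrete = 0, rhythmic = 1), numeric block B (1..5).
mm_prepare <- function(data) {
  stopifnot(all(c("participant", "style") %in% names(data)))
  data$participant <- factor(data$participant)
  if (is.numeric(data$style)) data$S <- as.numeric(data$style)
  else data$S <- as.numeric(data$style == "rhythmic")
  if ("block" %in% names(data)) data$B <- as.numeric(data$block)
  data
}

mm_coef_table <- function(fit) {
  s <- summary(fit)$coefficients
  out <- data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
                    row.names = NULL)
  pcol <- grep("^Pr", colnames(s))
  out$statistic <- s[, ncol(s) - 1]
  out$p <- if (length(pcol)) s[, pcol[1]] else NA_real_
  out
}

# Fit with a decreasing ladder of random-effect structures, stepping down on
# singular fits or errors; returns fit + trace of attempts.
fit_with_reduction <- function(formula_fixed, random_terms, data, family,
                               REML = TRUE) {
  trace <- character()
  for (rt in random_terms) {
    f <- as.formula(paste(formula_fixed, "+", rt))
    fit <- tryCatch({
      if (family == "gaussian")
        lmerTest::lmer(f, data = data, REML = REML)
      else
        lme4::glmer(f, data = data, family = stats::binomial("logit"),
                    control = lme4::glmerControl(optimizer = "bobyqa"))
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      trace <- c(trace, sprintf("%s: error (%s)", rt, conditionMessage(fit)))
      next
    }
    if (lme4::isSingular(fit, tol = 1e-4)) {
      trace <- c(trace, sprintf("%s: singular fit, reducing", rt))
      next
    }
    trace <- c(trace, sprintf("%s: retained", rt))
    return(list(fit = fit, random = rt, trace = trace))
  }
  # last resort: accept the simplest structure even if singular
  rt <- random_terms[length(random_terms)]
  f <- as.formula(paste(formula_fixed, "+", rt))
  fit <- if (family == "gaussian") lmerTest::lmer(f, data = data, REML = REML)
         else lme4::glmer(f, data = data, family = stats::binomial("logit"))
  trace <- c(trace, sprintf("%s: accepted despite singularity", rt))
  list(fit = fit, random = rt, trace = trace)
}

whip_mm_result <- function(res, data, family, response) {
  fit <- res$fit
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(response = response, family = family,
                 coefficients = mm_coef_table(fit),
                 random = res$random,
                 varcor = vc,
                 logLik = as.numeric(logLik(fit)),
                 n_obs = nrow(data),
                 n_participants = nlevels(data$participant),
                 trace = res$trace,
                 df_method = if (family == "gaussian") "Satterthwaite" else "Wald z",
                 fit = fit),
            class = "whip_mm")
}

#' @export
print.whip_mm <- function(x, ...) {
  cat(sprintf("<whip_mm> %s (%s), %d obs / %d participants, random: %s\n",
              x$response, x$family, x$n_obs, x$n_participants, x$random))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Fit the style-by-block mixed-effects model
#'
#' The 2 x 5 design model of a per-trial metric: fixed effects for style
#' (discrete = 0, rhythmic = 1, so a positive style coefficient means the
#' metric is larger in the rhythmic style), numeric block (1..5) and their
#' interaction, with per-participant random intercepts and random style and
#' block slopes. Hit/miss responses use a binomial family with logit link;
#' all other metrics a Gaussian LMM (REML for reported estimates). Singular
#' random-effect fits step down to simpler random structures, recorded in
#' the trace.
#'
#' @param data trial-level data.frame with columns `participant`, `style`,
#'   `block` and the response.
#' @param response response column name (e.g. `"error"`, `"hit"`).
#' @param family `"gaussian"` or `"binomial"`.
#' @return a `whip_mm` result (coefficients, random-effect variances,
#'   log-likelihood, reduction trace, and the underlying fit).
#' @export
fit_style_block_model <- function(data, response,
                                  family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  data <- mm_prepare(data)
  if (nlevels(data$participant) < 2)
    stop("need at least 2 participants")
  if (length(unique(data$S)) < 2)
    stop("both styles must be present")
  data$.y <- if (family == "binomial") as.numeric(data[[response]] > 0)
             else as.numeric(data[[response]])
  data <- data[!is.na(data$.y) & !is.na(data$B), , drop = FALSE]
  if (length(unique(data$B)) < 2) {
    # single-block designs: the block terms are unidentifiable
    res <- fit_with_reduction(".y ~ S",
                              c("(1 + S | participant)", "(1 | participant)"),
                              data, family)
    res$trace <- c("single block: style-only fixed effects", res$trace)
  } else {
    res <- fit_with_reduction(".y ~ S * B",
                              c("(1 + S + B | participant)",
                                "(1 + S | participant)",
                                "(1 | participant)"),
                              data, family)
  }
  whip_mm_result(res, data, family, response)
}

#' Fit the error-covariate correlation model
#'
#' Tests whether a whip/hand variable measured at the trial's initial
#' conditions correlates with the trial's error in each style: response
#' regressed on style, the covariate and their interaction, with
#' per-participant random intercepts and covariate slopes. The per-style
#' slopes are the covariate coefficient (discrete) and its sum with the
#' interaction (rhythmic). With a single participant the model drops to a
#' fixed-effects regression with a logged warning.
#'
#' @param data trial-level data.frame.
#' @param covariate covariate column name (whip extension, whip azimuth,
#'   peak hand or tip speed, ...).
#' @param response response column (default `"error"`; use
#'   `"peak_tip_speed"` with covariate `"peak_hand_speed"` for the
#'   speed-speed correlation).
#' @return a `whip_mm` result with extra fields `slope_discrete`,
#'   `slope_rhythmic`.
#' @export
fit_error_correlation <- function(data, covariate, response = "error") {
  data <- mm_prepare(data)
  data$.y <- as.numeric(data[[response]])
  data$X <- as.numeric(data[[covariate]])
  data <- data[!is.na(data$.y) & !is.na(data$X), , drop = FALSE]
  if (var(data$X) < .Machine$double.eps)
    stop("degenerate covariate: zero variance")
  if (nlevels(droplevels(data$participant)) < 2) {
    warning("single participant: dropping random effects, fitting fixed-only model")
    fit <- stats::lm(.y ~ S * X, data = data)
    s <- summary(fit)$coefficients
    co <- data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
                     statistic = s[, 3], p = s[, 4], row.names = NULL)
    out <- structure(list(response = response, family = "gaussian",
                          coefficients = co, random = "none (single participant)",
                          varcor = NULL, logLik = as.numeric(logLik(fit)),
                          n_obs = nrow(data), n_participants = 1,
                          trace = "single participant: fixed-effects only",
                          df_method = "t", fit = fit),
                     class = "whip_mm")
  } else {
    res <- fit_with_reduction(".y ~ S * X",
                              c("(1 + S + X | participant)",
                                "(1 + X | participant)",
                                "(1 | participant)"),
                              data, "gaussian")
    out <- whip_mm_result(res, data, "gaussian", response)
  }
  est <- setNames(out$coefficients$estimate, out$coefficients$term)
  out$covariate <- covariate
  out$slope_discrete <- unname(est["X"])
  out$slope_rhythmic <- unname(est["X"] + ifelse(is.na(est["S:X"]), 0, est["S:X"]))
  out
}

#' Likelihood-ratio model selection over a nested ladder
#'
#' Compares an ordered list of nested model fits (simplest first, same data)
#' by chi-squared likelihood-ratio tests, refitting with maximum likelihood
#' where needed; a term is retained when its test rejects at `alpha`. The
#' returned trace records every comparison.
#'
#' @param fits named list of fitted models (`lmerMod`/`glmerMod`/`lm`),
#'   nested and ordered by increasing complexity. `whip_mm` results are
#'   accepted and unwrapped.
#' @param alpha retention level (default 0.05).
#' @return data.frame trace: comparison, added term, statistic, df, p,
#'   retained.
#' @export
likelihood_ratio_select <- function(fits, alpha = 0.05) {
  fits <- lapply(fits, function(f) if (inherits(f, "whip_mm")) f$fit else f)
  if (length(fits) < 2) stop("need at least two nested fits")
  nms <- names(fits)
  if (is.null(nms)) nms <- paste0("M", seq_along(fits))
  refit_ml <- function(f) {
    if (inherits(f, "lmerMod") && lme4::isREML(f)) update(f, REML = FALSE) else f
  }
  fits <- lapply(fits, refit_ml)
  nobs_all <- vapply(fits, stats::nobs, numeric(1))
  if (length(unique(nobs_all)) != 1)
    stop("non-nested comparison: models fitted to different data")
  npar <- vapply(fits, function(f) attr(logLik(f), "df"), numeric(1))
  if (any(diff(npar) < 0))
    stop("non-nested comparison: parameter counts must be non-decreasing")
  out <- list()
  for (i in seq_len(length(fits) - 1)) {
    ll0 <- as.numeric(logLik(fits[[i]]))
    ll1 <- as.numeric(logLik(fits[[i + 1]]))
    df <- npar[i + 1] - npar[i]
    stat <- max(0, 2 * (ll1 - ll0))
    p <- if (df > 0) pchisq(stat, df, lower.tail = FALSE) else NA_real_
    out[[i]] <- data.frame(comparison = paste(nms[i], "->", nms[i + 1]),
                           statistic = stat, df = df, p = p,
                           retained = isTRUE(p < alpha))
  }
  do.call(rbind, out)
}

#' Iterative selection of the style-by-block model
#'
#' Forward selection of the fixed terms (style, block, interaction) by
#' maximum-likelihood LRT at `alpha`, on a participant random-intercept
#' base, followed by an LRT test of the random style/block slopes; the final
#' retained model is refit by REML (Gaussian case). The full selection trace
#' is returned alongside the final `whip_mm`.
#'
#' @inheritParams fit_style_block_model
#' @param alpha retention level.
#' @return list with `model` (final `whip_mm`) and `selection` (trace
#'   data.frame).
#' @export
select_style_block_model <- function(data, response,
                                     family = c("gaussian", "binomial"),
                                     alpha = 0.05) {
  family <- match.arg(family)
  data <- mm_prepare(data)
  data$.y <- if (family == "binomial") as.numeric(data[[response]] > 0)
             else as.numeric(data[[response]])
  data <- data[!is.na(data$.y) & !is.na(data$B), , drop = FALSE]
  fit1 <- function(fixed, random, REML = FALSE) {
    f <- as.formula(paste(".y ~", fixed, "+", random))
    if (family == "gaussian") lmerTest::lmer(f, data = data, REML = REML)
    else lme4::glmer(f, data = data, family = stats::binomial("logit"))
  }
  terms_seq <- c("S", "B", "S:B")
  kept <- character()
  base <- "1"
  trace <- list()
  cur <- fit1(base, "(1 | participant)")
  for (tm in terms_seq) {
    cand_fixed <- paste(c(base, kept, tm), collapse = " + ")
    cand <- fit1(cand_fixed, "(1 | participant)")
    lr <- likelihood_ratio_select(setNames(list(cur, cand),
                                           c("without", paste("with", tm))), alpha)
    lr$comparison <- paste("fixed:", tm)
    trace[[length(trace) + 1]] <- lr
    if (lr$retained[1]) {
      kept <- c(kept, tm)
      cur <- cand
    }
  }
  fixed_final <- paste(c(base, kept), collapse = " + ")
  # random slopes for retained main effects, tested against intercept-only
  slope_terms <- intersect(kept, c("S", "B"))
  random_final <- "(1 | participant)"
  if (length(slope_terms)) {
    rnd <- sprintf("(1 + %s | participant)", paste(slope_terms, collapse = " + "))
    cand <- tryCatch(fit1(fixed_final, rnd), error = function(e) NULL)
    if (!is.null(cand) && !lme4::isSingular(cand, tol = 1e-4)) {
      lr <- likelihood_ratio_select(setNames(list(cur, cand),
                                             c("intercept only", "with slopes")), alpha)
      lr$comparison <- paste("random:", paste(slope_terms, collapse = "+"))
      trace[[length(trace) + 1]] <- lr
      if (lr$retained[1]) random_final <- rnd
    }
  }
  final <- fit1(fixed_final, random_final, REML = TRUE)
  res <- list(fit = final, random = random_final,
              trace = sprintf("selected fixed: %s; random: %s",
                              fixed_final, random_final))
  list(model = whip_mm_result(res, data, family, response),
       selection = do.call(rbind, trace))
}
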