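test_that("a balanced Gaussian LMM reproduces the OLS fixed effects", {
  set.seed(2)
  d <- expand.grid(participant = sprintf("P%02d", 1:8),
                   style = c("discrete", "rhythmic"), block = 1:5)
  S <- as.numeric(d$style == "rhythmic")
  d$y <- 0.2 + 0.1 * S - 0.01 * d$block + 0.005 * S * d$block + rnorm(nrow(d), 0, 0.05)
  m <- fit_style_block_model(d, "y", "gaussian")
  ols <- coef(lm(y ~ I(as.numeric(style == "rhythmic")) * block, data = d))
  expect_equal(unname(m$coefficients$estimate), unname(ols), tolerance = 1e-6)
})

test_that("planted style/block effects are recovered within their CIs", {
  sim <- simulate_cohort(cohort_params(seed = 14))
  truth <- sim$truth$error$beta
  m <- fit_style_block_model(sim$table, "error", "gaussian")
  est <- m$coefficients$estimate
  se <- m$coefficients$se
  for (i in 1:4)
    expect_lt(abs(est[i] - truth[i]) / se[i], 1.96 * 1.5)
  # binomial-logit for hit/miss
  mh <- fit_style_block_model(sim$table, "hit", "binomial")
  expect_equal(mh$family, "binomial")
  bS <- mh$coefficients$estimate[mh$coefficients$term == "S"]
  seS <- mh$coefficients$se[mh$coefficients$term == "S"]
  expect_lt(abs(bS - sim$truth$hit$beta[2]), 1.96 * 2 * seS)
})

test_that("preconditions are enforced", {
  sim <- simulate_cohort(cohort_params(n_participants = 4, seed = 1))
  one_style <- sim$table[sim$table$style == "discrete", ]
  expect_error(fit_style_block_model(one_style, "error"), "both styles")
  one_p <- sim$table[sim$table$participant == "P01", ]
  expect_error(fit_style_block_model(one_p, "error"), "participants")
})

test_that("error-covariate slopes are recovered per style", {
  cc <- simulate_covariate_cohort(beta = c(0.35, 0.1, 0, -0.153), seed = 8)
  fit <- fit_error_correlation(cc$table, "extension")
  co <- fit$coefficients
  bX <- co$estimate[co$term == "X"]; seX <- co$se[co$term == "X"]
  bSX <- co$estimate[co$term == "S:X"]; seSX <- co$se[co$term == "S:X"]
  expect_lt(abs(bX - 0), 1.96 * 1.5 * seX)
  expect_lt(abs(bSX - (-0.153)), 1.96 * 1.5 * seSX)
  expect_equal(fit$slope_rhythmic, bX + bSX)
  # uncorrelated covariate stays non-significant most of the time: single
  # representative cohort here (rates are covered by the acceptance suite)
  expect_gt(co$p[co$term == "X"], 0.001)
})

test_that("degenerate covariates and groupings are handled", {
  cc <- simulate_covariate_cohort(seed = 3)
  tab <- cc$table
  tab$extension <- 1.45
  expect_error(fit_error_correlation(tab, "extension"), "zero variance")
  single <- cc$table[cc$table$participant == "P01", ]
  expect_warning(fit1 <- fit_error_correlation(single, "extension"),
                 "single participant")
  expect_equal(fit1$n_participants, 1)
  expect_true(is.finite(fit1$slope_discrete))
})

test_that("likelihood-ratio selection retains only supported terms", {
  sim <- simulate_cohort(cohort_params(seed = 6))
  d <- whipkin:::mm_prepare(sim$table)
  d$.y <- d$error
  m0 <- lme4::lmer(.y ~ S + B + (1 | participant), d, REML = FALSE)
  m1 <- lme4::lmer(.y ~ S * B + (1 | participant), d, REML = FALSE)
  tr <- likelihood_ratio_select(list(additive = m0, interaction = m1))
  expect_equal(nrow(tr), 1L)
  expect_gt(tr$statistic, 0)
  expect_equal(tr$df, 1)
  # identical models -> statistic 0, term dropped
  tr0 <- likelihood_ratio_select(list(a = m0, b = m0))
  expect_equal(tr0$statistic, 0)
  expect_false(tr0$retained)
  # non-nested comparison -> error
  half <- d[seq_len(nrow(d) / 2), ]
  m2 <- lme4::lmer(.y ~ S + (1 | participant), half, REML = FALSE)
  expect_error(likelihood_ratio_select(list(m0, m2)), "non-nested")
})

test_that("iterative selection keeps a strongly planted interaction", {
  cp <- cohort_params(seed = 31)
  cp$metrics <- list(error = list(beta = c(0.15, 0.1, -0.01, -0.03),
                                  sd_re = c(0.05, 0.03, 0.004), sd_resid = 0.08))
  sim <- simulate_cohort(cp)
  sel <- select_style_block_model(sim$table, "error")
  expect_true(any(grepl("S:B", sel$selection$comparison) & sel$selection$retained))
  expect_s3_class(sel$model, "whip_mm")
})
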