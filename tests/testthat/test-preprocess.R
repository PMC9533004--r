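fs <- 500

make_series_dataset <- function(x, y = 0 * x, z = 0 * x) {
  schema <- whip_schema()
  n <- length(x)
  pos <- array(0, c(n, 16, 3), dimnames = list(NULL, schema$marker_names, NULL))
  pos[, "hand_MC5", 1] <- x
  pos[, "hand_MC5", 2] <- y
  pos[, "hand_MC5", 3] <- z
  marker_dataset(pos, fs, schema)
}

test_that("filter designs meet the stated band specs", {
  for (fc in c(20, 40)) {
    fd <- design_lowpass(fc, fs)
    expect_equal(fd$passband_edge, fc - 1)
    expect_equal(fd$stopband_edge, fc + 1)
    # symmetric coefficients: exactly linear phase
    expect_equal(fd$coef, rev(fd$coef), tolerance = 1e-12)
    H <- abs(fir_response(fd$coef, c(fc - 1, fc + 1), fs))
    expect_lte(H[2], 10^(-60 / 20))
    expect_lte(abs(H[1] - 1), fd$passband_ripple)
  }
  expect_error(design_lowpass(260, fs), "infeasible")
})

test_that("a stopband sinusoid is attenuated by at least 60 dB", {
  fd <- design_lowpass(40, fs)
  t <- seq(0, 10, by = 1 / fs)
  for (f0 in c(41, 45)) {
    ds <- make_series_dataset(sin(2 * pi * f0 * t))
    out <- filter_zero_lag(ds, fd)
    core <- out$positions[1000:4000, "hand_MC5", 1]
    expect_lte(max(abs(core)), 10^(-60 / 20) * 1.05)
  }
})

test_that("passband signals pass unchanged and DC is preserved", {
  fd <- design_lowpass(20, fs)
  t <- seq(0, 6, by = 1 / fs)
  ds <- make_series_dataset(rep(0.75, length(t)))
  out <- filter_zero_lag(ds, fd)
  expect_lt(max(abs(out$positions[, "hand_MC5", 1] - 0.75)), 1e-9)
  ds2 <- make_series_dataset(sin(2 * pi * 2 * t))
  out2 <- filter_zero_lag(ds2, fd)
  core <- 1500:2500
  dev <- max(abs(out2$positions[core, "hand_MC5", 1] - sin(2 * pi * 2 * t)[core]))
  expect_lte(dev, fd$passband_ripple)
})

test_that("filtering is zero phase: a symmetric pulse keeps its peak frame", {
  fd <- design_lowpass(40, fs)
  t <- seq(0, 4, by = 1 / fs)
  pulse <- exp(-((t - 2) / 0.05)^2)
  ds <- make_series_dataset(pulse)
  out <- filter_zero_lag(ds, fd)
  expect_equal(which.max(out$positions[, "hand_MC5", 1]), which.max(pulse))
  # cross-correlation peak of a band-limited signal at lag 0
  set.seed(1)
  x <- as.numeric(stats::filter(rnorm(4000), rep(1 / 30, 30), sides = 2))
  x[is.na(x)] <- 0
  dsn <- make_series_dataset(x)
  y <- filter_zero_lag(dsn, fd)$positions[, "hand_MC5", 1]
  cc <- stats::ccf(x[500:3500], y[500:3500], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("white-noise power above the stopband edge drops by >= 60 dB", {
  fd <- design_lowpass(40, fs)
  set.seed(7)
  x <- rnorm(2^14)
  y <- filter_zero_lag(make_series_dataset(x), fd)$positions[, "hand_MC5", 1]
  px <- spec.pgram(ts(x, frequency = fs), plot = FALSE, taper = 0.2,
                   spans = c(31, 31))
  py <- spec.pgram(ts(y, frequency = fs), plot = FALSE, taper = 0.2,
                   spans = c(31, 31))
  hi <- px$freq > 42 & px$freq < 240
  drop_db <- 10 * log10(mean(px$spec[hi]) / mean(py$spec[hi]))
  expect_gte(drop_db, 60)
})

test_that("double filtering changes passband signals by less than 2x ripple", {
  fd <- design_lowpass(20, fs)
  t <- seq(0, 6, by = 1 / fs)
  ds <- make_series_dataset(sin(2 * pi * 3 * t))
  once <- filter_zero_lag(ds, fd)
  twice <- filter_zero_lag(once, fd)
  core <- 1500:2500
  dev <- max(abs(twice$positions[core, "hand_MC5", 1] -
                   ds$positions[core, "hand_MC5", 1]))
  expect_lte(dev, 2 * fd$passband_ripple)
})

test_that("gap bridging interpolates short gaps and leaves long ones", {
  t <- seq(0, 2, by = 1 / fs)
  ds <- make_series_dataset(0.1 * t)
  ds$positions[101:130, "hand_MC5", ] <- NA_real_
  ds$gap_mask[101:130, "hand_MC5"] <- TRUE
  ds$positions[301:400, "hand_MC5", ] <- NA_real_
  ds$gap_mask[301:400, "hand_MC5"] <- TRUE
  out <- bridge_gaps(ds, max_gap = 50)
  expect_false(any(out$gap_mask[101:130, "hand_MC5"]))
  expect_equal(as.numeric(out$positions[115, "hand_MC5", 1]), 0.1 * t[115],
               tolerance = 1e-9)
  expect_true(all(out$gap_mask[301:400, "hand_MC5"]))
})

test_that("differentiation matches closed forms", {
  t <- seq(0, 2, by = 1 / fs)
  schema <- whip_schema()
  n <- length(t)
  pos <- array(0, c(n, 16, 3), dimnames = list(NULL, schema$marker_names, NULL))
  pos[, "hand_MC5", 1] <- t           # 1 m/s along x
  pos[, "w1", 3] <- 0.5 * 9.81 * t^2  # gravity-like quadratic
  pos[, "w2", 2] <- sin(2 * pi * 3 * t)
  ds <- marker_dataset(pos, fs, schema)
  v <- differentiate(ds, 1)
  expect_lt(max(abs(v[, "hand_MC5", 1] - 1)), 1e-9)
  a <- differentiate(ds, 2)
  interior <- 10:(n - 10)
  expect_lt(max(abs(a[interior, "w1", 3] - 9.81)), 1e-6)
  vy <- v[interior, "w2", 2]
  expect_lt(max(abs(vy - 2 * pi * 3 * cos(2 * pi * 3 * t[interior]))) /
              (2 * pi * 3), 1e-3)
  # masked frames propagate
  ds$positions[50, "w2", ] <- NA_real_
  ds$gap_mask[50, "w2"] <- TRUE
  v2 <- differentiate(ds, 1)
  expect_true(is.na(v2[50, "w2", 2]))
  # no span long enough for the stencil
  short <- marker_dataset(array(0, c(1, 16, 3)), fs, schema)
  expect_error(differentiate(short, 1), "stencil")
})

test_that("tangential speed is the per-frame norm and rotation invariant", {
  expect_equal(tangential_speed(matrix(c(3, 4, 0), 1)), 5)
  expect_equal(tangential_speed(matrix(0, 1, 3)), 0)
  set.seed(3)
  v <- matrix(rnorm(300), 100, 3)
  expect_equal(tangential_speed(v), sqrt(rowSums(v^2)))
  R <- whipkin:::rot_z(37)
  expect_equal(tangential_speed(v %*% t(R)), tangential_speed(v), tolerance = 1e-12)
})
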