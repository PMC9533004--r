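# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Calibrated scene parameter sets (calibration is deterministic but not
# instant, so share them).
fx_params <- function(style, ...) {
  key <- paste0("params_", style, "_", paste(deparse(substitute(list(...))), collapse = ""))
  fixture(key, function() scene_params(style, ...))
}

# One analysed synthetic block per style: dataset + truth + pipeline output.
fx_block <- function(style, seed = 11) {
  fixture(paste0("block_", style, "_", seed), function() {
    p <- fixture(paste0("params_", style), function() scene_params(style))
    dur <- if (style == "discrete") 60 else 40
    blk <- simulate_block(p, duration = dur, seed = seed)
    res <- analyze_block(blk$dataset, style)
    list(params = p, block = blk, res = res,
         trials = res$trials, truth = blk$truth$trials)
  })
}

# A static single-configuration dataset: positions is markers x 3.
static_dataset <- function(positions, n_frames = 3, fs = 500,
                           schema = whip_schema()) {
  pos <- array(NA_real_, c(n_frames, nrow(positions), 3),
               dimnames = list(NULL, rownames(positions), c("x", "y", "z")))
  for (i in seq_len(n_frames)) pos[i, , ] <- positions
  marker_dataset(pos, fs, schema)
}

# Marker layout of a straight whip at a given azimuth/elevation, handle at
# `origin`; returns the full 16-marker configuration (target at default
# study position).
straight_whip_config <- function(azimuth = 0, origin = c(0.3, 0.05, 1.0),
                                 schema = whip_schema()) {
  u <- as.numeric(whipkin:::dir_from_azel(azimuth, 0))
  lens <- whipkin:::whip_segment_lengths(schema)
  pos <- matrix(NA_real_, length(schema$marker_names), 3,
                dimnames = list(schema$marker_names, c("x", "y", "z")))
  pos["hand_MC5", ] <- origin
  pos["h2", ] <- origin + 0.02 * u
  pos["h1", ] <- pos["h2", ] + 0.24 * u
  cur <- pos["h1", ]
  for (k in seq_along(lens)) {
    cur <- cur + lens[k] * u
    pos[paste0("w", 11 - k), ] <- cur
  }
  pos["t1", ] <- c(2.2, 0, 1.45)
  pos["t2", ] <- c(2.2, 0.15, 1.45)
  pos["t3", ] <- c(2.2, 0.30, 1.45)
  pos
}

# Rotate a configuration about the vertical axis through `center` by `deg`
# (positive toward the participant's right, i.e. adds to azimuths).
rotate_config <- function(pos, deg, center = c(0, 0, 0)) {
  R <- whipkin:::rot_z(deg)
  swept <- sweep(pos, 2, center)
  sweep(swept %*% t(R), 2, -center)
}

expect_frames_close <- function(a, b, tol = 2) {
  expect_true(all(abs(a - b) <= tol),
              label = sprintf("frame deviations %s within %d",
                              paste(abs(a - b), collapse = ","), tol))
}
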