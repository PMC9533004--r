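test_that("schema validation enforces the marker-set invariants", {
  s <- whip_schema()
  expect_length(s$marker_names, 16)
  expect_error(whip_schema(marker_names = c("a", "a", "b")), "unique")
  expect_error(whip_schema(whip_arclength = -1), "positive")
  # implied chain longer than the thong
  expect_error(whip_schema(inter_marker_spacing = 0.25), "exceeds")
  # chain length h1 -> w1 equals the thong arclength
  expect_equal(sum(whipkin:::whip_segment_lengths(s)), s$whip_arclength)
})

test_that("TSV round trip is lossless for positions, mask and rate", {
  p <- scene_params("discrete",
                    gap_schedule = data.frame(marker = c("w5", "w3"),
                                              start = c(100, 400),
                                              length = c(30, 260)),
                    seed = 3)
  tr <- simulate_trial(p)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_markers(tr$dataset, f)
  ds2 <- read_markers(f)
  expect_equal(ds2$sampling_rate, 500)
  expect_lt(max(abs(ds2$positions - tr$dataset$positions), na.rm = TRUE), 1e-9)
  expect_identical(ds2$gap_mask, tr$dataset$gap_mask)
})

test_that("reading rejects files that do not cover the schema", {
  p <- fx_params("discrete")
  tr <- simulate_trial(p)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_markers(tr$dataset, f)
  txt <- readLines(f)
  txt[2] <- gsub("w1_", "q1_", txt[2])
  writeLines(txt, f)
  expect_error(read_markers(f), "w1")
  expect_error(read_markers("missing_file.tsv"), "not found")
  expect_error(read_markers("recording.c3d"), "not supported|not found")
})

test_that("blank coordinates become gaps for that frame and marker only", {
  p <- fx_params("discrete")
  tr <- simulate_trial(scene_params("discrete", noise_sd = 0))
  ds <- tr$dataset
  ds$positions[5, "w5", ] <- NA_real_
  ds$gap_mask[5, "w5"] <- TRUE
  f <- withr::local_tempfile(fileext = ".tsv")
  write_markers(ds, f)
  ds2 <- read_markers(f)
  expect_true(ds2$gap_mask[5, "w5"])
  expect_equal(sum(ds2$gap_mask), 1L)
})

test_that("gap_report matches a run-length-encoding oracle", {
  set.seed(42)
  n <- 400
  schema <- whip_schema()
  pos <- array(rnorm(n * 16 * 3), c(n, 16, 3),
               dimnames = list(NULL, schema$marker_names, NULL))
  mask <- matrix(FALSE, n, 16, dimnames = list(NULL, schema$marker_names))
  # plant 5 runs across markers
  runs <- data.frame(marker = c("w1", "w1", "w7", "t1", "hand_MC5"),
                     start = c(10, 200, 55, 300, 390), len = c(4, 30, 1, 90, 11))
  for (i in seq_len(nrow(runs)))
    mask[runs$start[i]:(runs$start[i] + runs$len[i] - 1), runs$marker[i]] <- TRUE
  pos[mask] <- NA  # recycles over coordinates? set explicitly instead
  for (m in colnames(mask)) pos[mask[, m], m, ] <- NA_real_
  ds <- marker_dataset(pos, 500, schema, mask)
  rep <- gap_report(ds)
  expect_equal(nrow(rep$gaps), 5L)
  expect_setequal(rep$gaps$length, runs$len)
  # total masked frames equals the sum of run lengths
  expect_equal(sum(rep$gaps$length), sum(mask))
  # per-frame simultaneous count
  expect_equal(rep$n_missing, as.integer(rowSums(mask)))
  # gap-free dataset -> empty table
  ds0 <- marker_dataset(array(0, c(5, 16, 3)), 500, schema)
  expect_equal(nrow(gap_report(ds0)$gaps), 0L)
})

test_that("a long single gap is reported as one run", {
  schema <- whip_schema()
  pos <- array(0, c(500, 16, 3), dimnames = list(NULL, schema$marker_names, NULL))
  pos[101:300, "w3", ] <- NA_real_
  ds <- marker_dataset(pos, 500, schema)
  g <- gap_report(ds)$gaps
  expect_equal(nrow(g), 1L)
  expect_equal(g$length, 200L)
  expect_equal(g$start_frame, 101L)
})
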