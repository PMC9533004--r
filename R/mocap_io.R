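#' Marker-set schema for the whip task
#'
#' Describes the labelled marker set used throughout the pipeline: one hand
#' marker (5th metacarpal head), ten whip markers `w1`..`w10` ordered from the
#' tip (`w1`) to the thong base (`w10`), two handle markers `h1` (distal, at
#' the thong base) and `h2` (proximal, near the hand), and three target
#' markers `t1`..`t3` with `t1` on the free end of the target spring.
#'
#' @param marker_names character vector of marker labels.
#' @param whip_arclength thong arc length in metres.
#' @param handle_length rigid handle length in metres.
#' @param inter_marker_spacing spacing of adjacent whip markers w10..w3 (and
#'   w3-w2), metres.
#' @param distal_spacing spacing between the two most distal markers w2 and
#'   w1, metres.
#' @param target_direction unit 3-vector from the participant toward the
#'   target in the lab frame (defaults to +x).
#' @return an object of class `whip_schema`.
#' @export
whip_schema <- function(marker_names = c("hand_MC5", paste0("w", 1:10),
                                         "h1", "h2", "t1", "t2", "t3"),
                        whip_arclength = 1.60,
                        handle_length = 0.24,
                        inter_marker_spacing = 0.19,
                        distal_spacing = 0.06,
                        target_direction = c(1, 0, 0)) {
  if (anyDuplicated(marker_names))
    stop("marker names must be unique")
  if (whip_arclength <= 0 || handle_length <= 0 ||
      inter_marker_spacing <= 0 || distal_spacing <= 0)
    stop("lengths and spacings must be positive")
  # w10..w3 has 7 gaps at inter_marker_spacing, then w3-w2 at the same
  # spacing and w2-w1 at distal_spacing.
  chain <- 8 * inter_marker_spacing + distal_spacing
  if (chain > whip_arclength + 1e-9)
    stop(sprintf("implied marker chain (%.3f m) exceeds whip arclength (%.3f m)",
                 chain, whip_arclength))
  td <- target_direction / sqrt(sum(target_direction^2))
  structure(list(marker_names = marker_names,
                 whip_arclength = whip_arclength,
                 handle_length = handle_length,
                 inter_marker_spacing = inter_marker_spacing,
                 distal_spacing = distal_spacing,
                 target_direction = td),
            class = "whip_schema")
}

# Segment lengths of the whip chain h1 -> w10 -> ... -> w1 (11 segments).
whip_segment_lengths <- function(schema) {
  c(schema$whip_arclength - (8 * schema$inter_marker_spacing + schema$distal_spacing),
    rep(schema$inter_marker_spacing, 8),
    schema$distal_spacing)
}

#' Construct a marker dataset
#'
#' @param positions numeric array, frames x markers x 3, in metres. Missing
#'   samples are `NA` (and flagged in `gap_mask`), never zeros.
#' @param sampling_rate sampling rate in Hz.
#' @param schema a [whip_schema()].
#' @param gap_mask optional frames x markers logical matrix (`TRUE` =
#'   missing); derived from non-finite positions when omitted.
#' @return an object of class `marker_dataset`.
#' @export
marker_dataset <- function(positions, sampling_rate, schema = whip_schema(),
                           gap_mask = NULL) {
  stopifnot(length(dim(positions)) == 3, dim(positions)[3] == 3)
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  nm <- dimnames(positions)[[2]]
  if (is.null(nm)) {
    if (dim(positions)[2] != length(schema$marker_names))
      stop("positions must carry marker names or match the schema size")
    dimnames(positions) <- list(NULL, schema$marker_names, c("x", "y", "z"))
  }
  if (is.null(gap_mask)) {
    gap_mask <- apply(positions, c(1, 2), function(p) any(!is.finite(p)))
  }
  storage.mode(gap_mask) <- "logical"
  if (!all(dim(gap_mask) == dim(positions)[1:2]))
    stop("gap_mask must be frames x markers")
  # masked samples are NA; unmasked samples must be finite
  for (k in seq_len(dim(positions)[2])) {
    bad <- gap_mask[, k]
    positions[bad, k, ] <- NA_real_
    ok <- positions[!bad, k, , drop = FALSE]
    if (length(ok) && any(!is.finite(ok)))
      stop("positions must be finite wherever gap_mask is FALSE")
  }
  structure(list(positions = positions, sampling_rate = sampling_rate,
                 gap_mask = gap_mask, schema = schema),
            class = "marker_dataset")
}

#' @export
print.marker_dataset <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf("<marker_dataset> %d frames x %d markers @ %g Hz (%.1f s), %.2f%% gaps\n",
              d[1], d[2], x$sampling_rate, d[1] / x$sampling_rate,
              100 * mean(x$gap_mask)))
  invisible(x)
}

n_frames <- function(ds) dim(ds$positions)[1]

# frames x 3 trajectory of one marker (NA where masked)
marker_xyz <- function(ds, marker) {
  ds$positions[, marker, , drop = TRUE]
}

#' Read marker trajectories from a wide TSV file
#'
#' The wide-TSV dialect has one header row with columns `<label>_X`,
#' `<label>_Y`, `<label>_Z` per marker and one row per frame, units metres.
#' An optional leading comment line `# sampling_rate_hz: <value>` carries the
#' sampling rate; otherwise `sampling_rate` is used. Blank or non-finite
#' coordinates become gaps. The binary C3D dialect is not supported by this
#' implementation; convert C3D exports to wide TSV first.
#'
#' @param path file path.
#' @param schema a [whip_schema()]; every schema marker must appear in the
#'   file (extra columns are ignored).
#' @param sampling_rate fallback sampling rate in Hz when the file carries
#'   none.
#' @return a [marker_dataset()].
#' @export
read_markers <- function(path, schema = whip_schema(), sampling_rate = 500) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.c3d$", path, ignore.case = TRUE))
    stop("C3D input is not supported; export the recording as wide TSV ",
         "(columns <label>_X/_Y/_Z) and use that file instead")
  first <- readLines(path, n = 1L)
  fs <- sampling_rate
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("sampling_rate_hz:\\s*([0-9.eE+-]+)", first))[[1]]
    if (length(m) == 2) fs <- as.numeric(m[2])
  }
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = c("", "NA", "NaN"))
  cols <- names(dt)
  need <- as.vector(t(outer(schema$marker_names, c("_X", "_Y", "_Z"), paste0)))
  missing_lab <- schema$marker_names[!vapply(schema$marker_names, function(m)
    all(paste0(m, c("_X", "_Y", "_Z")) %in% cols), logical(1))]
  if (length(missing_lab))
    stop("file is missing required marker label(s): ",
         paste(missing_lab, collapse = ", "))
  nfr <- nrow(dt)
  nmk <- length(schema$marker_names)
  pos <- array(NA_real_, c(nfr, nmk, 3),
               dimnames = list(NULL, schema$marker_names, c("x", "y", "z")))
  for (k in seq_len(nmk)) {
    sub <- as.matrix(dt[, paste0(schema$marker_names[k], c("_X", "_Y", "_Z")),
                        with = FALSE])
    storage.mode(sub) <- "double"
    sub[!is.finite(sub)] <- NA_real_
    # a frame with any absent coordinate is a gap for that marker
    bad <- rowSums(is.na(sub)) > 0
    sub[bad, ] <- NA_real_
    pos[, k, ] <- sub
  }
  marker_dataset(pos, fs, schema)
}

#' Write marker trajectories to a wide TSV file
#'
#' Inverse of [read_markers()]: positions survive a round trip to within
#' 1e-9 m and the gap mask exactly (gaps are written as empty fields).
#'
#' @param dataset a [marker_dataset()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_markers <- function(dataset, path) {
  stopifnot(inherits(dataset, "marker_dataset"))
  nmk <- dim(dataset$positions)[2]
  labs <- dimnames(dataset$positions)[[2]]
  cols <- vector("list", 3 * nmk)
  nms <- character(3 * nmk)
  for (k in seq_len(nmk)) for (j in 1:3) {
    cols[[3 * (k - 1) + j]] <- dataset$positions[, k, j]
    nms[3 * (k - 1) + j] <- paste0(labs[k], c("_X", "_Y", "_Z")[j])
  }
  dt <- data.table::setDT(setNames(cols, nms))
  con <- file(path, "w")
  ok <- FALSE
  tryCatch({
    writeLines(sprintf("# sampling_rate_hz: %.10g", dataset$sampling_rate), con)
    close(con)
    ok <- TRUE
  }, error = function(e) stop("cannot write to ", path, ": ", conditionMessage(e)))
  if (!ok) stop("cannot write to ", path)
  data.table::fwrite(dt, path, sep = "\t", na = "", append = TRUE,
                     col.names = TRUE, scipen = 0)
  invisible(path)
}

#' Tabulate gaps in a marker dataset
#'
#' Run-length encodes the gap mask: one row per maximal run of missing frames
#' per marker, plus the per-frame count of simultaneously missing markers
#' (used by the trial-exclusion rules).
#'
#' @param dataset a [marker_dataset()].
#' @return list with `gaps` (data.frame: marker, start_frame, length) and
#'   `n_missing` (integer vector, simultaneously missing markers per frame).
#' @export
gap_report <- function(dataset) {
  stopifnot(inherits(dataset, "marker_dataset"))
  labs <- dimnames(dataset$positions)[[2]]
  out <- lapply(seq_along(labs), function(k) {
    r <- true_runs(dataset$gap_mask[, k])
    if (!nrow(r)) return(NULL)
    data.frame(marker = labs[k], start_frame = r$start, length = r$length)
  })
  gaps <- do.call(rbind, out)
  if (is.null(gaps))
    gaps <- data.frame(marker = character(), start_frame = integer(),
                       length = integer())
  list(gaps = gaps, n_missing = as.integer(rowSums(dataset$gap_mask)))
}
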