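#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx median quantile sd rnorm runif rbinom setNames
#'   coef logLik pchisq plogis qnorm anova update as.formula rlnorm var
#' @importFrom utils head tail
NULL

# Run code with a private, restored RNG stream seeded from `seed`.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

vnorm <- function(x) sqrt(rowSums(x^2))

#' Signed azimuth of a lab-frame direction
#'
#' The lab frame has x pointing from the participant toward the target and z
#' vertical; azimuth 0 deg is the horizontal direction pointing straight
#' backward (away from the target) and positive angles turn toward the
#' participant's right (-y). Returns angles in (-180, 180].
#'
#' @param d numeric vector of length 3, or an n x 3 matrix of directions.
#' @return azimuth in degrees.
#' @export
azimuth_deg <- function(d) {
  if (is.null(dim(d))) d <- matrix(d, nrow = 1)
  a <- atan2(-d[, 2], -d[, 1]) * 180 / pi
  a[a <= -180] <- a[a <= -180] + 360
  if (length(a) == 1) a <- as.numeric(a)
  a
}

# Inverse of azimuth_deg (with elevation): unit lab-frame direction.
dir_from_azel <- function(az_deg, el_deg = 0) {
  az <- az_deg * pi / 180
  el <- el_deg * pi / 180
  cbind(-cos(az) * cos(el), -sin(az) * cos(el), sin(el))
}

# Rotation about the vertical axis by `deg` degrees toward the participant's
# right (i.e. the rotation that adds `deg` to an azimuth).
rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

# Cubic Hermite smooth step on [0,1] with S(0)=0, S'(0)=0, S(1)=1, S'(1)=s.
# Monotone for 0 <= s <= 2. Evaluated (and extrapolated) for any u.
smoothstep_end <- function(u, s = 1) {
  a <- 3 - s
  b <- s - 2
  out <- a * u^2 + b * u^3
  out[u <= 0] <- 0
  out
}

# Maximal runs of TRUE in a logical vector: data.frame(start, length).
true_runs <- function(x) {
  r <- rle(as.logical(x))
  ends <- cumsum(r$lengths)
  keep <- !is.na(r$values) & r$values
  data.frame(start = (ends - r$lengths + 1L)[keep], length = r$lengths[keep])
}

# Contiguous runs of valid (non-NA / unmasked) samples.
valid_spans <- function(valid) true_runs(valid)
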