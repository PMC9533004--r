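#' Design the zero-lag low-pass FIR filter
#'
#' Kaiser-window FIR low-pass design with passband/stopband edges 1 Hz below
#' and above the cutoff, 60 dB stopband attenuation and 0.1 passband ripple
#' bound. The order is the automatic minimum for those constraints (Kaiser
#' order estimate, then increased if the realized response falls short of the
#' stopband spec). Coefficients are symmetric, so the filter has exactly
#' linear phase; [filter_zero_lag()] removes the constant group delay.
#'
#' @param cutoff cutoff frequency, Hz (20 for body markers, 40 for whip
#'   markers in the study configuration).
#' @param sampling_rate sampling rate, Hz.
#' @param stopband_atten_db stopband attenuation, dB.
#' @param passband_ripple passband deviation bound (linear units).
#' @return object of class `filter_spec` with realized coefficients `coef`.
#' @export
design_lowpass <- function(cutoff, sampling_rate,
                           stopband_atten_db = 60, passband_ripple = 0.1) {
  f_pass <- cutoff - 1
  f_stop <- cutoff + 1
  if (!(f_pass > 0 && f_stop < sampling_rate / 2))
    stop(sprintf("infeasible band edges: need 0 < %g < %g < %g",
                 f_pass, f_stop, sampling_rate / 2))
  dev_stop <- 10^(-stopband_atten_db / 20)
  ko <- signal::kaiserord(c(f_pass, f_stop), c(1, 0),
                          c(passband_ripple, dev_stop), sampling_rate)
  n <- ko$n + ko$n %% 2  # even order -> odd length, integer group delay
  realized_ok <- function(h) {
    fr <- abs(fir_response(h, c(f_pass, f_stop), sampling_rate))
    fr[2] <= dev_stop && abs(fr[1] - 1) <= passband_ripple
  }
  h <- NULL
  for (i in 0:20) {  # bump order a little if the estimate undershoots
    h <- signal::fir1(n, ko$Wc, "low", signal::kaiser(n + 1, ko$beta),
                      scale = TRUE)
    h <- h / sum(h)  # exact unit DC gain
    if (realized_ok(h)) break
    n <- n + 2
  }
  if (!realized_ok(h)) stop("filter design failed to meet the response spec")
  structure(list(cutoff = cutoff, sampling_rate = sampling_rate,
                 passband_edge = f_pass, stopband_edge = f_stop,
                 stopband_atten_db = stopband_atten_db,
                 passband_ripple = passband_ripple,
                 window = "kaiser", beta = ko$beta, order = n,
                 coef = as.numeric(h)),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> low-pass %g Hz @ %g Hz (edges %g/%g Hz, -%g dB, Kaiser beta %.2f, order %d)\n",
              x$cutoff, x$sampling_rate, x$passband_edge, x$stopband_edge,
              x$stopband_atten_db, x$beta, x$order))
  invisible(x)
}

#' Complex frequency response of an FIR filter
#'
#' Direct evaluation of `H(f) = sum h_k exp(-2 pi i f k / fs)` at the
#' requested frequencies.
#'
#' @param h FIR coefficients.
#' @param f frequencies, Hz.
#' @param fs sampling rate, Hz.
#' @return complex response values.
#' @export
fir_response <- function(h, f, fs) {
  k <- seq_along(h) - 1
  vapply(f, function(fi) sum(h * exp(-2i * pi * fi * k / fs)), complex(1))
}

# Zero-phase filtering of one series (no NAs): symmetric FIR applied once
# with group-delay compensation, odd-reflection padding at the edges.
zero_lag_filter_vec <- function(x, h) {
  n <- length(x)
  L <- length(h)
  d <- (L - 1) / 2
  if (n < 2) return(x)
  P <- min(L, n - 1)
  left <- 2 * x[1] - x[seq(P + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - P)]
  xp <- c(left, x, right, rep(0, max(0, d - P + 1)))
  y <- signal::fftfilt(h, xp)
  y[(P + d + 1):(P + d + n)]
}

#' Bridge short gaps by linear interpolation
#'
#' Interior gaps of at most `max_gap` frames are filled by linear
#' interpolation (and cleared from the gap mask); longer gaps and
#' leading/trailing gaps are left missing, which splits the series into
#' separately filtered spans.
#'
#' @param dataset a [marker_dataset()].
#' @param max_gap largest bridgeable gap, frames (default 50, i.e. 0.1 s at
#'   500 Hz).
#' @return the dataset with short gaps filled.
#' @export
bridge_gaps <- function(dataset, max_gap = 50) {
  pos <- dataset$positions
  mask <- dataset$gap_mask
  for (k in seq_len(dim(pos)[2])) {
    gk <- true_runs(mask[, k])
    if (!nrow(gk)) next
    n <- dim(pos)[1]
    for (i in seq_len(nrow(gk))) {
      s <- gk$start[i]; len <- gk$length[i]; e <- s + len - 1
      if (len > max_gap || s == 1 || e == n) next
      idx <- s:e
      for (j in 1:3) {
        pos[idx, k, j] <- approx(c(s - 1, e + 1),
                                 c(pos[s - 1, k, j], pos[e + 1, k, j]),
                                 xout = idx)$y
      }
      mask[idx, k] <- FALSE
    }
  }
  dataset$positions <- pos
  dataset$gap_mask <- mask
  dataset
}

#' Apply a zero-lag low-pass filter to a marker dataset
#'
#' Each marker coordinate is filtered over every contiguous valid span
#' (bridge short gaps first with [bridge_gaps()]); masked frames stay
#' missing. The realization is a single pass of the symmetric FIR with
#' group-delay compensation — numerically equivalent to forward-backward
#' filtering for a linear-phase filter — with odd-reflection padding of one
#' filter length at span edges.
#'
#' @param dataset a [marker_dataset()].
#' @param spec a [design_lowpass()] filter spec (its sampling rate must match).
#' @param markers markers to filter (default all).
#' @return the filtered dataset.
#' @export
filter_zero_lag <- function(dataset, spec, markers = NULL) {
  stopifnot(inherits(spec, "filter_spec"))
  if (abs(spec$sampling_rate - dataset$sampling_rate) > 1e-9)
    stop("filter spec sampling rate does not match the dataset")
  labs <- dimnames(dataset$positions)[[2]]
  if (is.null(markers)) markers <- labs
  pos <- dataset$positions
  for (m in markers) {
    k <- match(m, labs)
    if (is.na(k)) stop("unknown marker: ", m)
    spans <- valid_spans(!dataset$gap_mask[, k])
    for (i in seq_len(nrow(spans))) {
      idx <- spans$start[i]:(spans$start[i] + spans$length[i] - 1)
      if (length(idx) < 2) next
      for (j in 1:3) pos[idx, k, j] <- zero_lag_filter_vec(pos[idx, k, j], spec$coef)
    }
  }
  dataset$positions <- pos
  dataset
}

#' Differentiate marker trajectories
#'
#' Second-order central differences on span interiors, one-sided differences
#' at span boundaries; masked frames propagate as missing. Apply after
#' filtering.
#'
#' @param dataset a [marker_dataset()] (typically filtered).
#' @param order 1 for velocity (m/s), 2 for acceleration (m/s^2).
#' @return array frames x markers x 3 of derivatives, `NA` where undefined.
#' @export
differentiate <- function(dataset, order = 1) {
  stopifnot(order %in% c(1, 2))
  pos <- dataset$positions
  dt <- 1 / dataset$sampling_rate
  out <- array(NA_real_, dim(pos), dimnames = dimnames(pos))
  min_len <- order + 1
  any_ok <- FALSE
  for (k in seq_len(dim(pos)[2])) {
    spans <- valid_spans(!dataset$gap_mask[, k])
    for (i in seq_len(nrow(spans))) {
      idx <- spans$start[i]:(spans$start[i] + spans$length[i] - 1)
      if (length(idx) < min_len) next
      any_ok <- TRUE
      for (j in 1:3) {
        v <- pracma::gradient(pos[idx, k, j], h1 = dt)
        if (order == 2) v <- pracma::gradient(v, h1 = dt)
        out[idx, k, j] <- v
      }
    }
  }
  if (!any_ok)
    stop(sprintf("no span long enough for the order-%d stencil (need %d frames)",
                 order, min_len))
  out
}

#' Tangential speed of marker velocities
#'
#' Euclidean norm of the velocity per frame and marker.
#'
#' @param velocity frames x markers x 3 array from [differentiate()], or a
#'   frames x 3 matrix for a single marker.
#' @return frames x markers matrix of speeds (m/s), or a vector for a single
#'   marker.
#' @export
tangential_speed <- function(velocity) {
  if (length(dim(velocity)) == 2) return(vnorm(velocity))
  out <- sqrt(apply(velocity^2, c(1, 2), sum))
  dimnames(out) <- dimnames(velocity)[1:2]
  out
}
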