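# Minimum distance between segments P1-Q1 and P2-Q2, vectorized over rows.
# Standard clamped closest-point algorithm (robust to degenerate segments).
segment_segment_distance <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1
  d2 <- q2 - p2
  r <- p1 - p2
  a <- rowSums(d1 * d1)
  e <- rowSums(d2 * d2)
  f <- rowSums(d2 * r)
  c_ <- rowSums(d1 * r)
  b <- rowSums(d1 * d2)
  denom <- a * e - b * b
  s <- ifelse(denom > .Machine$double.eps, (b * f - c_ * e) / denom, 0)
  s <- pmin(1, pmax(0, s))
  # both segments may be points
  t <- ifelse(e > .Machine$double.eps, (b * s + f) / e, 0)
  tcl <- pmin(1, pmax(0, t))
  # re-clamp s when t was clamped
  s <- ifelse(t != tcl,
              pmin(1, pmax(0, ifelse(a > .Machine$double.eps,
                                     (b * tcl - c_) / a, 0))),
              s)
  t <- tcl
  cp1 <- p1 + d1 * s
  cp2 <- p2 + d2 * t
  sqrt(rowSums((cp1 - cp2)^2))
}

# Per-frame minimum distance between the distal whip polyline (w1-w2-w3) and
# the target segment (t1-t2). Frames with any required marker missing -> NA.
whip_target_distance <- function(dataset, frames = NULL,
                                 whip_markers = c("w1", "w2", "w3"),
                                 target_markers = c("t1", "t2")) {
  if (is.null(frames)) frames <- seq_len(n_frames(dataset))
  P <- dataset$positions
  w1 <- P[frames, whip_markers[1], , drop = FALSE]; dim(w1) <- c(length(frames), 3)
  w2 <- P[frames, whip_markers[2], , drop = FALSE]; dim(w2) <- c(length(frames), 3)
  w3 <- P[frames, whip_markers[3], , drop = FALSE]; dim(w3) <- c(length(frames), 3)
  t1 <- P[frames, target_markers[1], , drop = FALSE]; dim(t1) <- c(length(frames), 3)
  t2 <- P[frames, target_markers[2], , drop = FALSE]; dim(t2) <- c(length(frames), 3)
  d <- pmin(segment_segment_distance(w1, w2, t1, t2),
            segment_segment_distance(w2, w3, t1, t2))
  d[!is.finite(d)] <- NA_real_
  d
}

# Dense-sampling oracle: both polylines resampled at `step` metres, minimum
# pairwise point distance. Used as the independent check of the closed form.
polyline_min_dist_dense <- function(whip_pts, target_pts, step = 1e-4) {
  densify <- function(pts) {
    out <- list()
    for (i in seq_len(nrow(pts) - 1)) {
      len <- sqrt(sum((pts[i + 1, ] - pts[i, ])^2))
      n <- max(2L, ceiling(len / step) + 1L)
      u <- seq(0, 1, length.out = n)
      out[[i]] <- cbind(pts[i, 1] + u * (pts[i + 1, 1] - pts[i, 1]),
                        pts[i, 2] + u * (pts[i + 1, 2] - pts[i, 2]),
                        pts[i, 3] + u * (pts[i + 1, 3] - pts[i, 3]))
    }
    do.call(rbind, out)
  }
  A <- densify(whip_pts)
  B <- densify(target_pts)
  cross <- A %*% t(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * cross
  sqrt(max(0, min(d2)))
}

#' First-principal-direction azimuth of a marker cloud
#'
#' Fits a line through 3-D points by singular value decomposition, orients it
#' from the handle end toward the tip end, projects it to the horizontal
#' plane, and returns its [azimuth_deg()] relative to the backward direction.
#'
#' @param points n x 3 matrix of marker positions (rows with NA are dropped).
#' @param from,to row indices (in the full matrix) used only to orient the
#'   fitted direction (`from` = handle side, `to` = tip side).
#' @return azimuth in degrees, or `NA` with a warning for a degenerate fit.
#' @export
fit_line_azimuth <- function(points, from = 1, to = nrow(points)) {
  ok <- rowSums(is.na(points)) == 0
  if (sum(ok) < 3) return(NA_real_)
  X <- points[ok, , drop = FALSE]
  ctr <- colMeans(X)
  sv <- svd(sweep(X, 2, ctr))
  if (sv$d[1] < 1e-6 || sv$d[1] < 3 * sv$d[2]) {
    warning("degenerate line fit: markers nearly coincident or not line-like")
    if (sv$d[1] < 1e-6) return(NA_real_)
  }
  v <- sv$v[, 1]
  ref <- points[to, ] - points[from, ]
  if (all(is.finite(ref)) && sum(v * ref) < 0) v <- -v
  if (sqrt(sum(v[1:2]^2)) < 1e-9) {
    warning("fitted direction is vertical; azimuth undefined")
    return(NA_real_)
  }
  azimuth_deg(v)
}
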