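#' Reference trajectories of the evaluation protocol
#'
#' \code{linearReference} is the cross-shaped path through the seven
#' waypoints (0,0), (0,10), (0,-10), (0,0), (10,0), (-10,0), (0,0) in
#' millimetres: an out-and-back sweep along y followed by one along x,
#' returning to the origin (total polyline length 80 mm).
#' \code{spiralReference} is the 26-waypoint polygonal spiral
#' \deqn{c_n = \left(\tfrac{10n}{50}\sin\tfrac{8\pi n}{50},\;
#'   \tfrac{10n}{50}\cos\tfrac{8\pi n}{50}\right), \quad n = 0, \ldots, 25,}
#' four turns growing to radius 5 mm. Both are traversed at a constant
#' speed, 2 mm/s by default (the reference robot's maximum).
#'
#' @param speed traversal speed in mm/s.
#' @return a \linkS4class{ReferenceTrajectory}.
#' @export
linearReference <- function(speed = 2) {
  wp <- matrix(c(0, 0, 0, 10, 0, -10, 0, 0, 10, 0, -10, 0, 0, 0),
               ncol = 2, byrow = TRUE)
  colnames(wp) <- c("x", "y")
  new("ReferenceTrajectory", waypoints = wp, speed = speed)
}

#' @rdname linearReference
#' @export
spiralReference <- function(speed = 2) {
  n <- 0:25
  wp <- cbind(x = 10 * n / 50 * sin(4 * 2 * pi * n / 50),
              y = 10 * n / 50 * cos(4 * 2 * pi * n / 50))
  new("ReferenceTrajectory", waypoints = wp, speed = speed)
}

#' Build a reference trajectory from explicit waypoints
#' @param waypoints n x 2 matrix of (x, y) waypoints in mm.
#' @param speed traversal speed in mm/s.
#' @return a \linkS4class{ReferenceTrajectory}.
#' @export
referenceTrajectory <- function(waypoints, speed = 2) {
  wp <- as.matrix(waypoints)
  colnames(wp) <- c("x", "y")
  new("ReferenceTrajectory", waypoints = wp, speed = speed)
}

#' Waypoints of a reference trajectory
#' @param ref a \linkS4class{ReferenceTrajectory}.
#' @return its n x 2 waypoint matrix (mm).
#' @export
referenceWaypoints <- function(ref) ref@waypoints

#' Total polyline length of a reference trajectory
#' @param ref a \linkS4class{ReferenceTrajectory}.
#' @return summed segment lengths in mm.
#' @export
referenceLength <- function(ref) {
  sum(sqrt(rowSums(diff(ref@waypoints)^2)))
}

#' Total traversal duration of a reference trajectory
#' @param ref a \linkS4class{ReferenceTrajectory}.
#' @return length / speed, in seconds.
#' @export
referenceDuration <- function(ref) referenceLength(ref) / ref@speed

#' Sample a reference trajectory at given times
#'
#' Walks the waypoint polyline at the trajectory's constant speed and
#' returns the position at each requested time by linear interpolation
#' within the segment reached. Times past the total duration clamp to the
#' final waypoint (no extrapolation).
#'
#' @param ref a \linkS4class{ReferenceTrajectory}.
#' @param times non-negative, non-decreasing times in seconds.
#' @return length(times) x 2 matrix of (x, y) positions in mm.
#' @export
sampleReference <- function(ref, times) {
  if (any(times < 0)) .stopf("negative time")
  if (is.unsorted(times)) .stopf("times must be non-decreasing")
  wp <- ref@waypoints
  seg <- sqrt(rowSums(diff(wp)^2))
  cum <- c(0, cumsum(seg))
  dist <- pmin(times * ref@speed, cum[length(cum)])
  # segment index for each distance (zero-length segments skipped)
  idx <- findInterval(dist, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, length(seg))
  frac <- ifelse(seg[idx] > 0, (dist - cum[idx]) / seg[idx], 0)
  out <- wp[idx, , drop = FALSE] + frac * (wp[idx + 1, , drop = FALSE] -
                                             wp[idx, , drop = FALSE])
  colnames(out) <- c("x", "y")
  out
}

setMethod("show", "ReferenceTrajectory", function(object) {
  cat(sprintf(
    "ReferenceTrajectory  %d waypoints, length %.2f mm, speed %.2f mm/s (%.1f s)\n",
    nrow(object@waypoints), referenceLength(object), object@speed,
    referenceDuration(object)))
})

#' Frame-to-frame translation errors against a reference
#'
#' For each pair of consecutive trajectory records, the tracked increment
#' \eqn{\Delta x_{trk}} (from the millimetre position columns) is compared
#' with the reference increment \eqn{\Delta x_{ref}} obtained by sampling
#' the reference trajectory at the same two timestamps:
#' \deqn{E = \Delta x_{trk} - \Delta x_{ref}.}
#' The summary reports the mean absolute error distance
#' \eqn{\mu = \frac{1}{n}\sum_n \|E_n\|} and the population standard
#' deviation of the norms.
#'
#' @param records trajectory record data.frame (>= 2 rows; see
#'   \code{\link{trackSequence}}).
#' @param ref a \linkS4class{ReferenceTrajectory}.
#' @return an \linkS4class{ErrorSummary}.
#' @export
frameErrors <- function(records, ref) {
  if (nrow(records) < 2L) .stopf("need at least 2 records")
  measured <- cbind(records$x_mm, records$y_mm)
  refPos <- sampleReference(ref, records$timestamp)
  dMeas <- diff(measured)
  dRef <- diff(refPos)
  errs <- dMeas - dRef
  colnames(errs) <- c("ex", "ey")
  norms <- sqrt(rowSums(errs^2))
  n <- nrow(errs)
  new("ErrorSummary", errors = errs,
      times = cbind(t0 = records$timestamp[-nrow(records)],
                    t1 = records$timestamp[-1]),
      mu = mean(norms), std = sqrt(mean((norms - mean(norms))^2)),
      n = as.integer(n))
}

#' Summary statistics of an ErrorSummary
#' @param summary an \linkS4class{ErrorSummary}.
#' @return named list with mu, std, n (mu and std in mm).
#' @export
errorStats <- function(summary) {
  list(mu = summary@mu, std = summary@std, n = summary@n)
}

#' Per-pair error vectors of an ErrorSummary
#' @param summary an \linkS4class{ErrorSummary}.
#' @return n x 2 matrix of (ex, ey) in mm.
#' @export
errorVectors <- function(summary) summary@errors

#' Export the per-pair error distribution
#'
#' Writes one CSV row per consecutive-frame pair (columns
#' \code{pair_index,t0,t1,ex_mm,ey_mm,norm_mm}) and, optionally, a 2D
#' scatter figure of the error distribution.
#'
#' @param summary a non-empty \linkS4class{ErrorSummary}.
#' @param path output CSV path.
#' @param plotPath optional PNG path for the scatter figure.
#' @return invisibly, \code{path}.
#' @export
exportErrorDistribution <- function(summary, path, plotPath = NULL) {
  if (summary@n == 0L) .stopf("empty error summary")
  norms <- sqrt(rowSums(summary@errors^2))
  df <- data.frame(pair_index = seq_len(summary@n) - 1L,
                   t0 = summary@times[, "t0"], t1 = summary@times[, "t1"],
                   ex_mm = summary@errors[, "ex"],
                   ey_mm = summary@errors[, "ey"], norm_mm = norms)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(plotPath)) {
    grDevices::png(plotPath, width = 600, height = 600)
    on.exit(grDevices::dev.off())
    lim <- max(abs(summary@errors), 1e-6)
    plot(summary@errors[, "ex"], summary@errors[, "ey"],
         xlim = c(-lim, lim), ylim = c(-lim, lim), asp = 1,
         xlab = "Ex [mm]", ylab = "Ey [mm]",
         main = "Frame-to-frame error distribution", pch = 19,
         col = grDevices::rgb(0.8, 0.1, 0.1, 0.5))
    graphics::abline(h = 0, v = 0, col = "gray")
  }
  invisible(path)
}

setMethod("show", "ErrorSummary", function(object) {
  cat(sprintf("ErrorSummary  n = %d pairs  mu = %.4f mm  std = %.4f mm\n",
              object@n, object@mu, object@std))
})

#' Align a measured trajectory to a reference (rotation + scale)
#'
#' Utility for externally recorded data whose image axes are not aligned to
#' the reference axes: finds the rotation angle and isotropic scale
#' minimizing the squared distance between the measured increments and the
#' reference increments (closed-form Procrustes on increments). Synthetic
#' evaluations do not need it (axes agree exactly by construction).
#'
#' @param records trajectory record data.frame.
#' @param ref a \linkS4class{ReferenceTrajectory}.
#' @return list with \code{angle} (radians), \code{scale}, and
#'   \code{records} with rotated/scaled mm position columns.
#' @export
alignTrajectory <- function(records, ref) {
  M <- diff(cbind(records$x_mm, records$y_mm))
  R <- diff(sampleReference(ref, records$timestamp))
  # Procrustes: rotation from the SVD of cross-covariance, scale from traces
  H <- t(M) %*% R
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  Rot <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
  sc <- sum(diag(t(R) %*% M %*% t(Rot))) / sum(M^2)
  out <- records
  aligned <- sc * cbind(records$x_mm, records$y_mm) %*% t(Rot)
  out$x_mm <- aligned[, 1]; out$y_mm <- aligned[, 2]
  list(angle = atan2(Rot[2, 1], Rot[1, 1]), scale = sc, records = out)
}
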