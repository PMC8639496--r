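#' Robust affine estimation between matched keypoint sets
#'
#' Seeded RANSAC over the matched correspondences: each iteration draws
#' \code{ransac_min_samples} distinct matches uniformly without replacement,
#' fits the exact affine interpolant, and counts the matches whose Euclidean
#' reprojection residual is at most \code{ransac_residual_threshold} pixels.
#' The largest consensus set wins, with ties resolved in favour of the
#' earlier iteration; the returned transform is the least-squares refit
#' (\code{\link{fitAffineLsq}}) on all inliers of the winning set. Degenerate
#' (collinear) minimal samples are skipped but still consume an iteration.
#'
#' If the best consensus is smaller than \code{min_inliers} the result is a
#' fallback: identity transform, status \code{"fallback_identity"}, zero
#' inliers.
#'
#' @param kpA,kpB keypoint data.frames (columns \code{x}, \code{y}) of the
#'   two frames, as returned by \code{\link{detectFeatures}}.
#' @param matches match data.frame from \code{\link{matchDescriptors}}.
#' @param config a \linkS4class{TrackerConfig} (residual threshold,
#'   iteration count, seed, minimal consensus).
#' @return a \linkS4class{StepResult}. The estimated transform maps keypoint
#'   coordinates in the first frame to coordinates in the second.
#' @export
ransacAffine <- function(kpA, kpB, matches, config = trackerConfig()) {
  nm <- nrow(matches)
  if (nm < config@ransacMinSamples)
    .stopf("insufficient matches: %d < %d", nm, config@ransacMinSamples)
  src <- cbind(kpA$x[matches$index_a], kpA$y[matches$index_a])
  dst <- cbind(kpB$x[matches$index_b], kpB$y[matches$index_b])
  thr2 <- config@ransacResidualThreshold^2
  s <- config@ransacMinSamples

  bestCount <- -1L
  bestInl <- logical(nm)
  .withSeed(config@ransacSeed, {
    for (it in seq_len(config@ransacMaxIterations)) {
      pick <- sample.int(nm, s)
      X <- cbind(src[pick, 1], src[pick, 2], 1)
      qrX <- qr(X)
      if (qrX$rank < 3L) next
      cf <- qr.coef(qrX, dst[pick, , drop = FALSE])
      px <- src[, 1] * cf[1, 1] + src[, 2] * cf[2, 1] + cf[3, 1]
      py <- src[, 1] * cf[1, 2] + src[, 2] * cf[2, 2] + cf[3, 2]
      inl <- (px - dst[, 1])^2 + (py - dst[, 2])^2 <= thr2
      cnt <- sum(inl)
      if (cnt > bestCount) {
        bestCount <- cnt
        bestInl <- inl
      }
    }
  })

  if (bestCount < config@minInliers)
    return(new("StepResult", transform = identityTransform(),
               inliers = logical(nm), nFeaturesA = nrow(kpA),
               nFeaturesB = nrow(kpB), nMatches = nm, nInliers = 0L,
               status = "fallback_identity"))

  fit <- fitAffineLsq(src[bestInl, , drop = FALSE],
                      dst[bestInl, , drop = FALSE])
  new("StepResult", transform = fit, inliers = bestInl,
      nFeaturesA = nrow(kpA), nFeaturesB = nrow(kpB),
      nMatches = nm, nInliers = as.integer(bestCount), status = "ok")
}

setMethod("show", "StepResult", function(object) {
  p <- transformParams(object@transform)
  cat(sprintf(
    "StepResult [%s]  features %d/%d  matches %d  inliers %d  b=(%.3f, %.3f)\n",
    object@status, object@nFeaturesA, object@nFeaturesB, object@nMatches,
    object@nInliers, p["b0"], p["b1"]))
})
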