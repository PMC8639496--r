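# Per-frame orchestration of the tracking pipeline:
# mask -> detect -> match -> RANSAC -> cascade, with identity fallback on
# estimation failure and optional keyframe re-anchoring.

.frameFeatures <- function(frame, config) {
  mask <- computeValidityMask(frame, config@tau1, config@tau2)
  d <- dim(frame@image)
  detectFeatures(frame, mask, k = .effectiveK(config@k, d[1], d[2]))
}

# Estimate the step transform between two feature sets; never errors.
# stepSeed perturbs the configured RANSAC seed so successive steps do not
# reuse the identical sampling sequence while staying deterministic.
.estimateStep <- function(featA, featB, config, stepSeed = 0L) {
  matches <- matchDescriptors(featA$descriptors, featB$descriptors,
                              config@matchCrossCheck)
  nA <- nrow(featA$keypoints); nB <- nrow(featB$keypoints)
  if (nrow(matches) < config@ransacMinSamples)
    return(new("StepResult", transform = identityTransform(),
               inliers = logical(nrow(matches)),
               nFeaturesA = as.integer(nA), nFeaturesB = as.integer(nB),
               nMatches = nrow(matches), nInliers = 0L,
               status = "fallback_identity"))
  cfg <- config
  if (!is.na(cfg@ransacSeed))
    cfg@ransacSeed <- as.integer((cfg@ransacSeed + stepSeed) %% .Machine$integer.max)
  ransacAffine(featA$keypoints, featB$keypoints, matches, cfg)
}

#' Estimate the motion between one pair of frames
#'
#' Runs the full single-step pipeline: reflection masks for both frames,
#' masked feature detection, descriptor matching, and RANSAC affine
#' estimation. If fewer matches than the minimal sample size are found, or
#' the best consensus is below \code{min_inliers}, the step degrades to the
#' identity transform with status \code{"fallback_identity"} instead of
#' failing.
#'
#' @param frameA,frameB \linkS4class{Frame}s of identical dimensions.
#' @param config a \linkS4class{TrackerConfig}.
#' @return a \linkS4class{StepResult}; its transform maps pixel coordinates
#'   in \code{frameA} to coordinates in \code{frameB}.
#' @export
trackPair <- function(frameA, frameB, config = trackerConfig()) {
  if (!identical(dim(frameA@image), dim(frameB@image)))
    .stopf("frame dimension mismatch")
  .estimateStep(.frameFeatures(frameA, config), .frameFeatures(frameB, config),
                config)
}

.zeroRecord <- function(frame, nFeatures, config) {
  data.frame(frame = frame@index, timestamp = frame@timestamp,
             a00 = 1, a01 = 0, a10 = 0, a11 = 1, b0 = 0, b1 = 0,
             x_px = 0, y_px = 0, x_mm = 0, y_mm = 0,
             n_features = as.integer(nFeatures), n_matches = 0L,
             n_inliers = 0L, status = "ok")
}

#' Track a whole frame sequence
#'
#' Folds \code{\link{trackPair}} over all consecutive frame pairs (features
#' are detected once per frame and reused), cascading the step transforms
#' into the accumulated pose. Fallback steps contribute the identity, i.e.
#' the position is held. One trajectory record is emitted per frame; the
#' first is the zero record of frame 0.
#'
#' With \code{keyframe_interval = K >= 1} in the configuration (or via
#' \code{trackSequenceKeyframed}), every K-th frame is additionally
#' registered against the last stored keyframe; when that wider-baseline
#' estimate succeeds, the cumulative transform is replaced by
#' (keyframe cumulative) composed with (keyframe-to-current transform),
#' bounding the drift of the incremental chain, and the current frame
#' becomes the new keyframe. A failed keyframe estimate leaves the
#' incremental chain untouched.
#'
#' @param frames list of \linkS4class{Frame}s (>= 2, equal dimensions).
#' @param config a \linkS4class{TrackerConfig}.
#' @return a \linkS4class{TrackingRun}.
#' @export
trackSequence <- function(frames, config = trackerConfig()) {
  n <- length(frames)
  if (n < 2L) .stopf("need at least 2 frames")
  kf <- config@keyframeInterval

  featPrev <- .frameFeatures(frames[[1]], config)
  pose <- initialPose()
  records <- vector("list", n)
  records[[1]] <- .zeroRecord(frames[[1]], nrow(featPrev$keypoints), config)
  keyFeat <- featPrev
  keyPose <- pose
  fallbacks <- 0L
  inlierRatios <- numeric(0)

  for (i in 2:n) {
    feat <- .frameFeatures(frames[[i]], config)
    step <- .estimateStep(featPrev, feat, config, stepSeed = i)
    if (step@status == "fallback_identity") fallbacks <- fallbacks + 1L
    else if (step@nMatches > 0L)
      inlierRatios <- c(inlierRatios, step@nInliers / step@nMatches)
    pose <- accumulatePose(pose, step@transform)

    if (kf >= 1L && (i - 1L) %% kf == 0L) {
      anchor <- .estimateStep(keyFeat, feat, config, stepSeed = 100000L + i)
      if (anchor@status == "ok") {
        cum <- composeTransforms(anchor@transform, keyPose@cumulative)
        pose <- new("PoseState", cumulative = cum,
                    position = as.numeric(cum@m[1:2, 3]), index = pose@index)
      }
      keyFeat <- feat
      keyPose <- pose
    }

    p <- transformParams(step@transform)
    records[[i]] <- data.frame(
      frame = frames[[i]]@index, timestamp = frames[[i]]@timestamp,
      a00 = p[["a00"]], a01 = p[["a01"]], a10 = p[["a10"]], a11 = p[["a11"]],
      b0 = p[["b0"]], b1 = p[["b1"]],
      x_px = pose@position[1], y_px = pose@position[2],
      x_mm = pose@position[1] * config@mmPerPixel,
      y_mm = pose@position[2] * config@mmPerPixel,
      n_features = as.integer(nrow(feat$keypoints)),
      n_matches = step@nMatches, n_inliers = step@nInliers,
      status = step@status)
    featPrev <- feat
  }

  new("TrackingRun", config = config,
      records = do.call(rbind, records),
      summary = list(framesProcessed = n, fallbacks = fallbacks,
                     meanInlierRatio = if (length(inlierRatios))
                       mean(inlierRatios) else NA_real_))
}

#' @rdname trackSequence
#' @export
trackSequenceKeyframed <- function(frames, config = trackerConfig()) {
  trackSequence(frames, config)
}

#' Records of a tracking run
#' @param run a \linkS4class{TrackingRun}.
#' @return the trajectory record data.frame (see
#'   \code{\link{writeTrajectoryCSV}} for the schema).
#' @export
trackingRecords <- function(run) run@records

#' Summary counts of a tracking run
#' @param run a \linkS4class{TrackingRun}.
#' @return list with framesProcessed, fallbacks, meanInlierRatio.
#' @export
trackingSummary <- function(run) run@summary

setMethod("show", "TrackingRun", function(object) {
  s <- object@summary
  last <- object@records[nrow(object@records), ]
  cat(sprintf(paste0(
    "TrackingRun  %d frames, %d fallbacks, mean inlier ratio %.3f\n",
    "  final position (%.3f, %.3f) px\n"),
    s$framesProcessed, s$fallbacks, s$meanInlierRatio, last$x_px, last$y_px))
})
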