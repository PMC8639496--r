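#' @import methods
NULL

#' Frame: one timestamped RGB raster from the image stream
#'
#' A single frame of the microscope image stream. The raster is stored as an
#' H x W x 3 numeric array in RGB channel order with values on the 8-bit scale
#' [0, 255]. The pixel coordinate convention shared by all of ScopeTrack is
#' 0-based, x rightward (columns), y downward (rows), origin at the top-left
#' pixel center.
#'
#' @slot index non-negative integer position of the frame in its sequence.
#' @slot timestamp acquisition time in seconds.
#' @slot image H x W x 3 numeric array, values in [0, 255], RGB order.
#' @exportClass Frame
setClass("Frame",
  representation(index = "integer", timestamp = "numeric", image = "array"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@image)
    if (length(d) != 3L || d[3] != 3L)
      msg <- c(msg, "image must be an H x W x 3 array")
    else {
      if (d[1] < 1L || d[2] < 1L)
        msg <- c(msg, "frame dimensions must be positive")
      rng <- range(object@image)
      if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
        msg <- c(msg, "channel values must lie in [0, 255]")
    }
    if (length(object@index) != 1L || is.na(object@index) || object@index < 0L)
      msg <- c(msg, "index must be a single non-negative integer")
    if (length(object@timestamp) != 1L || is.na(object@timestamp))
      msg <- c(msg, "timestamp must be a single number")
    if (is.null(msg)) TRUE else msg
  })

#' TrackerConfig: all tunable parameters of the tracking pipeline
#'
#' Thresholds of the reflection mask (tau1, tau2), the feature budget k (the
#' reference budget at 1080p; it is rescaled by pixel count for other frame
#' sizes), RANSAC parameters, the matching mode, the metric scale, and the
#' optional keyframe re-anchoring interval.
#'
#' @slot tau1 intensity threshold factor, fraction in (0, 1].
#' @slot tau2 saturation threshold factor, fraction in [0, 1).
#' @slot k feature budget at 1080p resolution (positive integer).
#' @slot ransacMinSamples minimal sample size for the affine model (>= 3).
#' @slot ransacResidualThreshold inlier residual threshold in pixels.
#' @slot ransacMaxIterations number of RANSAC iterations.
#' @slot ransacSeed integer seed for the RANSAC sampler (NA = unseeded).
#' @slot matchCrossCheck keep only mutual nearest-neighbour matches.
#' @slot minInliers minimal consensus size below which a step falls back to
#'   the identity transform.
#' @slot mmPerPixel metric scale, millimetres per pixel.
#' @slot keyframeInterval re-anchoring interval in frames (0 disables it).
#' @slot fps frame rate used to synthesize timestamps when no timing sidecar
#'   is present.
#' @exportClass TrackerConfig
setClass("TrackerConfig",
  representation(
    tau1 = "numeric", tau2 = "numeric", k = "integer",
    ransacMinSamples = "integer", ransacResidualThreshold = "numeric",
    ransacMaxIterations = "integer", ransacSeed = "integer",
    matchCrossCheck = "logical", minInliers = "integer",
    mmPerPixel = "numeric", keyframeInterval = "integer", fps = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!(object@tau1 > 0 && object@tau1 <= 1))
      msg <- c(msg, "tau1 must lie in (0, 1]")
    if (!(object@tau2 >= 0 && object@tau2 < 1))
      msg <- c(msg, "tau2 must lie in [0, 1)")
    if (object@k < 1L) msg <- c(msg, "k must be positive")
    if (object@ransacMinSamples < 3L)
      msg <- c(msg, "ransacMinSamples must be >= 3")
    if (object@ransacResidualThreshold <= 0)
      msg <- c(msg, "ransacResidualThreshold must be positive")
    if (object@ransacMaxIterations < 1L)
      msg <- c(msg, "ransacMaxIterations must be positive")
    if (object@minInliers < 3L) msg <- c(msg, "minInliers must be >= 3")
    if (object@mmPerPixel <= 0) msg <- c(msg, "mmPerPixel must be positive")
    if (object@keyframeInterval < 0L)
      msg <- c(msg, "keyframeInterval must be >= 0")
    if (object@fps <= 0) msg <- c(msg, "fps must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' ValidityMask: per-pixel usability raster for feature detection
#'
#' Boolean raster marking the pixels usable for feature detection. A pixel is
#' valid iff (I < tau1 * Imax) OR (S > tau2 * Smax), where I is the HSV value
#' channel, S the saturation channel, and Imax/Smax the frame maxima; the
#' complement (bright AND unsaturated) is the specular reflection artifact
#' set excluded from detection.
#'
#' @slot mask logical H x W matrix; TRUE = usable pixel.
#' @slot iMax maximum intensity (HSV value in [0, 1]) observed in the frame.
#' @slot sMax maximum saturation (in [0, 1]) observed in the frame.
#' @slot tau1,tau2 thresholds the mask was built with.
#' @exportClass ValidityMask
setClass("ValidityMask",
  representation(mask = "matrix", iMax = "numeric", sMax = "numeric",
                 tau1 = "numeric", tau2 = "numeric"),
  validity = function(object) {
    if (!is.logical(object@mask)) return("mask must be a logical matrix")
    TRUE
  })

#' AffineTransform2D: 6-parameter planar transform in homogeneous form
#'
#' The planar affine map with linear part (a00, a01; a10, a11) and translation
#' (b0, b1), stored as a homogeneous 3 x 3 matrix whose last row is exactly
#' (0, 0, 1). Composition of two transforms is again an AffineTransform2D;
#' the transform is invertible iff the determinant of its linear part is
#' non-zero.
#'
#' @slot m homogeneous 3 x 3 matrix, last row (0, 0, 1).
#' @exportClass AffineTransform2D
setClass("AffineTransform2D",
  representation(m = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@m), c(3L, 3L)))
      return("homogeneous matrix must be 3 x 3")
    if (!identical(object@m[3, ], c(0, 0, 1)))
      return("last row must be exactly (0, 0, 1)")
    if (any(!is.finite(object@m[1:2, ])))
      return("transform parameters must be finite")
    TRUE
  })

#' PoseState: accumulated pose after cascading step transforms
#'
#' Running product of the per-step transforms together with the tracked
#' position, which is always the image of the homogeneous origin (0, 0, 1)
#' under the cumulative transform.
#'
#' @slot cumulative the running product of step transforms.
#' @slot position numeric length-2: cumulative transform applied to (0, 0).
#' @slot index frame index of the state.
#' @exportClass PoseState
setClass("PoseState",
  representation(cumulative = "AffineTransform2D", position = "numeric",
                 index = "integer"),
  validity = function(object) {
    p <- object@cumulative@m[1:2, 3]
    if (max(abs(p - object@position)) > 1e-9)
      return("position must equal cumulative transform applied to the origin")
    TRUE
  })

#' StepResult: outcome of one frame-pair motion estimate
#'
#' @slot transform the estimated step transform (identity on fallback).
#' @slot inliers logical flags, one per match, marking the RANSAC consensus.
#' @slot nFeaturesA,nFeaturesB keypoint counts in the two frames.
#' @slot nMatches number of descriptor matches.
#' @slot nInliers consensus size (0 on fallback).
#' @slot status "ok" or "fallback_identity".
#' @exportClass StepResult
setClass("StepResult",
  representation(transform = "AffineTransform2D", inliers = "logical",
                 nFeaturesA = "integer", nFeaturesB = "integer",
                 nMatches = "integer", nInliers = "integer",
                 status = "character"),
  validity = function(object) {
    if (!object@status %in% c("ok", "fallback_identity"))
      return("status must be 'ok' or 'fallback_identity'")
    TRUE
  })

#' ReferenceTrajectory: piecewise-linear waypoint path at constant speed
#'
#' An ordered polyline of waypoints in millimetres, traversed at a constant
#' speed (default 2 mm/s, the reference robot's maximum). Sampling at time t
#' walks the polyline by arc length; times beyond the total duration clamp to
#' the final waypoint.
#'
#' @slot waypoints n x 2 numeric matrix of (x, y) waypoints in mm, n >= 2.
#' @slot speed traversal speed in mm/s.
#' @exportClass ReferenceTrajectory
setClass("ReferenceTrajectory",
  representation(waypoints = "matrix", speed = "numeric"),
  validity = function(object) {
    if (ncol(object@waypoints) != 2L || nrow(object@waypoints) < 2L)
      return("waypoints must be an n x 2 matrix with n >= 2")
    if (object@speed <= 0) return("speed must be positive")
    TRUE
  })

#' ErrorSummary: frame-to-frame translation errors and their summary
#'
#' Per-pair error vectors E = dx_tracked - dx_reference (in mm), the mean of
#' their Euclidean norms mu, and the population standard deviation of the
#' norms.
#'
#' @slot errors n x 2 matrix of per-pair error vectors (mm).
#' @slot times n x 2 matrix of the (t0, t1) timestamps of each pair.
#' @slot mu mean absolute error distance (mm).
#' @slot std population standard deviation of the error norms (mm).
#' @slot n number of consecutive-frame pairs.
#' @exportClass ErrorSummary
setClass("ErrorSummary",
  representation(errors = "matrix", times = "matrix", mu = "numeric",
                 std = "numeric", n = "integer"),
  validity = function(object) {
    if (nrow(object@errors) != object@n)
      return("n must equal the number of error vectors")
    if (object@n > 0 && object@mu < 0) return("mu must be >= 0")
    TRUE
  })

#' TrackingRun: full result of tracking a frame sequence
#'
#' @slot config the TrackerConfig used.
#' @slot records data.frame of trajectory records, one per frame (the first
#'   is the zero record of frame 0).
#' @slot summary list with framesProcessed, fallbacks, meanInlierRatio.
#' @exportClass TrackingRun
setClass("TrackingRun",
  representation(config = "TrackerConfig", records = "data.frame",
                 summary = "list"))

#' SceneSpec: parameters of the synthetic microscope scene generator
#'
#' Describes a bone-like textured scene: multi-octave value noise with dark
#' drilled cavities and fine speckle, bright low-saturation specular ellipses
#' rendered AFTER warping (so they move independently of the scene, like real
#' lamp reflections), multiplicative illumination drift and additive Gaussian
#' sensor noise. The same spec always renders a bit-identical sequence.
#'
#' @slot seed integer master seed; all randomness derives from it.
#' @slot height,width frame dimensions in pixels.
#' @slot margin canvas margin in pixels; the background canvas is
#'   (height + 2 margin) x (width + 2 margin) so no border content is invented.
#' @slot octaves,persistence multi-octave noise parameters of the texture.
#' @slot blobDensity dark cavity blobs per 10000 pixels.
#' @slot speckleDensity fine dark speckle dots per 100 pixels.
#' @slot reflectionCount number of specular ellipses (0 disables them).
#' @slot reflectionRadius mean ellipse radius in pixels.
#' @slot reflectionPeak peak added brightness in 8-bit counts.
#' @slot reflectionJitter per-frame centre jitter of the ellipses in pixels.
#' @slot noiseSigma additive Gaussian sensor noise sigma in 8-bit counts.
#' @slot illuminationDrift half-range of the per-frame multiplicative gain.
#' @slot pxPerMm scale linking trajectory millimetres to pixel warps.
#' @exportClass SceneSpec
setClass("SceneSpec",
  representation(
    seed = "integer", height = "integer", width = "integer",
    margin = "integer", octaves = "integer", persistence = "numeric",
    blobDensity = "numeric", speckleDensity = "numeric",
    reflectionCount = "integer", reflectionRadius = "numeric",
    reflectionPeak = "numeric", reflectionJitter = "numeric",
    noiseSigma = "numeric", illuminationDrift = "numeric",
    pxPerMm = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@height < 32L || object@width < 32L)
      msg <- c(msg, "frames must be at least 32 x 32")
    if (object@margin < 0L) msg <- c(msg, "margin must be >= 0")
    if (object@pxPerMm <= 0) msg <- c(msg, "pxPerMm must be positive")
    if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
    if (is.null(msg)) TRUE else msg
  })
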