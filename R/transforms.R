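#' Construct a planar affine transform
#'
#' Builds an \linkS4class{AffineTransform2D} from its six parameters or from a
#' homogeneous 3 x 3 matrix. The map sends a point (x, y) to
#' (a00 x + a01 y + b0, a10 x + a11 y + b1).
#'
#' @param a00,a01,a10,a11 linear part (unitless).
#' @param b0,b1 translation in pixels.
#' @param m alternatively, a homogeneous 3 x 3 matrix with last row (0, 0, 1).
#' @return an \code{AffineTransform2D}.
#' @examples
#' affineTransform2D(b0 = 3, b1 = -4)
#' @export
affineTransform2D <- function(a00 = 1, a01 = 0, a10 = 0, a11 = 1,
                              b0 = 0, b1 = 0, m = NULL) {
  if (is.null(m))
    m <- matrix(c(a00, a10, 0, a01, a11, 0, b0, b1, 1), 3, 3)
  new("AffineTransform2D", m = m)
}

#' Identity transform
#' @return the identity \code{AffineTransform2D}.
#' @export
identityTransform <- function() affineTransform2D()

#' Homogeneous matrix of a transform
#' @param t an \code{AffineTransform2D}.
#' @return its 3 x 3 homogeneous matrix.
#' @export
transformMatrix <- function(t) t@m

#' Named parameter vector of a transform
#' @param t an \code{AffineTransform2D}.
#' @return named numeric vector (a00, a01, a10, a11, b0, b1).
#' @export
transformParams <- function(t) {
  c(a00 = t@m[1, 1], a01 = t@m[1, 2], a10 = t@m[2, 1], a11 = t@m[2, 2],
    b0 = t@m[1, 3], b1 = t@m[2, 3])
}

#' Compose two transforms
#'
#' Returns the transform applying \code{tInner} first, then \code{tOuter}
#' (the homogeneous matrix product outer \%*\% inner). Composition is
#' associative with the identity as neutral element.
#'
#' @param tOuter,tInner \code{AffineTransform2D} objects.
#' @return their composition.
#' @export
composeTransforms <- function(tOuter, tInner) {
  m <- tOuter@m %*% tInner@m
  m[3, ] <- c(0, 0, 1)  # guard against rounding in the affine row
  affineTransform2D(m = m)
}

#' Invert a transform
#' @param t an \code{AffineTransform2D} with non-singular linear part.
#' @return the inverse transform.
#' @export
invertTransform <- function(t) {
  if (abs(det(t@m[1:2, 1:2])) < .Machine$double.xmin)
    .stopf("non-invertible transform")
  m <- solve(t@m)
  m[3, ] <- c(0, 0, 1)
  affineTransform2D(m = m)
}

#' Apply a transform to points
#' @param t an \code{AffineTransform2D}.
#' @param pts n x 2 matrix (or length-2 vector) of (x, y) coordinates.
#' @return n x 2 matrix of transformed coordinates.
#' @export
applyTransform <- function(t, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, 1)
  out <- cbind(pts, 1) %*% t(t@m[1:2, ])
  colnames(out) <- c("x", "y")
  out
}

#' Initial pose state
#'
#' The pose before any step has been applied: identity cumulative transform,
#' position (0, 0), frame index 0.
#' @return a \linkS4class{PoseState}.
#' @export
initialPose <- function() {
  new("PoseState", cumulative = identityTransform(), position = c(0, 0),
      index = 0L)
}

#' Accumulate a step transform into a pose
#'
#' The cascaded pose after frame n is the left product of all step transforms
#' applied to the initial pose: new cumulative = step o old cumulative, and
#' the tracked position is the cumulative transform's image of the origin.
#'
#' @param state a \linkS4class{PoseState}.
#' @param step the \code{AffineTransform2D} of the next frame pair.
#' @return the updated \code{PoseState}.
#' @export
accumulatePose <- function(state, step) {
  cum <- composeTransforms(step, state@cumulative)
  new("PoseState", cumulative = cum,
      position = as.numeric(cum@m[1:2, 3]), index = state@index + 1L)
}

#' Least-squares affine fit between point sets
#'
#' Finds the affine transform minimizing the summed squared residuals
#' \eqn{\sum_i \| T \, src_i - dst_i \|^2}. With exactly three non-collinear
#' pairs the fit interpolates them exactly. The x and y target coordinates
#' decouple into two independent 3-parameter least-squares problems solved by
#' QR decomposition.
#'
#' @param src,dst n x 2 matrices of corresponding (x, y) points, n >= 3.
#' @return the fitted \code{AffineTransform2D}.
#' @export
fitAffineLsq <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) != nrow(dst)) .stopf("src and dst must have equal length")
  if (nrow(src) < 3L) .stopf("underdetermined: need at least 3 point pairs")
  X <- cbind(src[, 1], src[, 2], 1)
  qrX <- qr(X)
  if (qrX$rank < 3L) .stopf("degenerate configuration: collinear src points")
  cf <- qr.coef(qrX, dst)
  affineTransform2D(a00 = cf[1, 1], a01 = cf[2, 1], b0 = cf[3, 1],
                    a10 = cf[1, 2], a11 = cf[2, 2], b1 = cf[3, 2])
}

#' @describeIn affineTransform2D display method
#' @param object an \code{AffineTransform2D}.
#' @export
setMethod("show", "AffineTransform2D", function(object) {
  p <- transformParams(object)
  cat(sprintf(
    "AffineTransform2D  linear [%.6g %.6g; %.6g %.6g]  translation (%.6g, %.6g)\n",
    p["a00"], p["a01"], p["a10"], p["a11"], p["b0"], p["b1"]))
})

setMethod("show", "PoseState", function(object) {
  cat(sprintf("PoseState  frame %d  position (%.4f, %.4f) px\n",
              object@index, object@position[1], object@position[2]))
})
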