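#' Compute the reflection validity mask of a frame
#'
#' Specular lamp reflections in microscope images appear as pixels that are
#' simultaneously very bright and nearly colorless. The mask keeps a pixel
#' for feature detection iff
#' \deqn{I < \tau_1 I_{max} \quad \lor \quad S > \tau_2 S_{max}}
#' where I is the HSV value (intensity) channel, S the saturation channel
#' (both scaled to [0, 1]) and \eqn{I_{max}}, \eqn{S_{max}} the frame maxima.
#' The complement — bright AND unsaturated — is treated as a reflection
#' artifact and excluded. Inequalities are strict exactly as written.
#'
#' Degenerate case: on a pure grayscale frame \eqn{S_{max} = 0}, so the
#' saturation branch is unsatisfiable; the mask then falls back to the
#' intensity-only rule \eqn{I < \tau_1 I_{max}} so grayscale imagery remains
#' trackable.
#'
#' @param frame a \linkS4class{Frame}.
#' @param tau1 intensity threshold factor in (0, 1] (default 0.8).
#' @param tau2 saturation threshold factor in [0, 1) (default 0.2).
#' @return a \linkS4class{ValidityMask}.
#' @export
computeValidityMask <- function(frame, tau1 = 0.8, tau2 = 0.2) {
  stopifnot(tau1 > 0, tau1 <= 1, tau2 >= 0, tau2 < 1)
  d <- dim(frame@image)
  if (d[1] < 1 || d[2] < 1) .stopf("zero-sized frame")
  ch <- .hsvChannels(frame@image)
  iMax <- max(ch$v); sMax <- max(ch$s)
  valid <- if (sMax == 0 && iMax > 0) ch$v < tau1 * iMax
           else (ch$v < tau1 * iMax) | (ch$s > tau2 * sMax)
  new("ValidityMask", mask = valid, iMax = iMax, sMax = sMax,
      tau1 = tau1, tau2 = tau2)
}

#' Fraction of usable pixels in a mask
#' @param mask a \linkS4class{ValidityMask}.
#' @return number of valid pixels divided by H * W, in [0, 1].
#' @export
maskFraction <- function(mask) mean(mask@mask)

#' Logical matrix of a validity mask
#' @param mask a \linkS4class{ValidityMask}.
#' @return the H x W logical matrix (TRUE = usable).
#' @export
maskMatrix <- function(mask) mask@mask

#' Write a mask as an 8-bit PNG (255 = valid), for debugging
#' @param mask a \linkS4class{ValidityMask}.
#' @param path output PNG path.
#' @export
writeMaskPNG <- function(mask, path) {
  png::writePNG(mask@mask * 1.0, path)
  invisible(path)
}

setMethod("show", "ValidityMask", function(object) {
  cat(sprintf(
    "ValidityMask  %d x %d  %.1f%% valid  (Imax=%.3f Smax=%.3f tau1=%.2f tau2=%.2f)\n",
    ncol(object@mask), nrow(object@mask), 100 * mean(object@mask),
    object@iMax, object@sMax, object@tau1, object@tau2))
})
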