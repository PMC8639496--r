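# Synthetic microscope scene generator.
#
# Emulates the evaluation rig (textured bone-like situs moved under a static
# microscope by a precision robot) so the tracker can be benchmarked against
# exact ground truth. The background is rendered once on an oversized canvas
# (frame + 2 x margin) and frames are cut out of it by bilinear sampling, so
# no border content is ever invented. Specular highlights, illumination
# drift and sensor noise are applied AFTER warping: like real lamp
# reflections they stay put / jitter independently while the scene moves.

#' Create a synthetic scene specification
#'
#' Defaults describe the study conditions used throughout the package's
#' benchmarks: 512 x 512 frames cut from a canvas with a 48 px margin, a
#' bone-like multi-octave texture with drilled dark cavities and fine
#' speckle (feature-rich by construction), three specular ellipses of ~14 px
#' radius jittering by 2 px per frame, sensor noise of 2 counts, mild
#' illumination drift, and a scale of 4 px/mm linking trajectory millimetres
#' to pixel warps (so the reference speed of 2 mm/s is 8 px/s).
#'
#' @param seed integer master seed.
#' @param height,width frame size in pixels.
#' @param margin canvas margin in pixels; trajectories must stay within it.
#' @param octaves,persistence multi-octave texture noise parameters.
#' @param blobDensity dark cavity blobs per 10000 canvas pixels.
#' @param speckleDensity fine speckle dots per 100 canvas pixels.
#' @param reflectionCount number of specular ellipses (0 = none).
#' @param reflectionRadius mean ellipse radius in pixels.
#' @param reflectionPeak peak brightness the highlight pulls pixels toward
#'   (8-bit counts).
#' @param reflectionJitter per-frame centre jitter sd in pixels.
#' @param noiseSigma additive Gaussian sensor noise sd in 8-bit counts.
#' @param illuminationDrift half-range of the per-frame multiplicative gain.
#' @param pxPerMm pixels per millimetre of commanded motion.
#' @return a \linkS4class{SceneSpec}.
#' @export
sceneSpec <- function(seed = 1L, height = 512L, width = 512L, margin = 48L,
                      octaves = 4L, persistence = 0.55, blobDensity = 1.5,
                      speckleDensity = 1.5, reflectionCount = 3L,
                      reflectionRadius = 14, reflectionPeak = 250,
                      reflectionJitter = 2, noiseSigma = 2,
                      illuminationDrift = 0.02, pxPerMm = 4) {
  new("SceneSpec", seed = as.integer(seed), height = as.integer(height),
      width = as.integer(width), margin = as.integer(margin),
      octaves = as.integer(octaves), persistence = as.numeric(persistence),
      blobDensity = as.numeric(blobDensity),
      speckleDensity = as.numeric(speckleDensity),
      reflectionCount = as.integer(reflectionCount),
      reflectionRadius = as.numeric(reflectionRadius),
      reflectionPeak = as.numeric(reflectionPeak),
      reflectionJitter = as.numeric(reflectionJitter),
      noiseSigma = as.numeric(noiseSigma),
      illuminationDrift = as.numeric(illuminationDrift),
      pxPerMm = as.numeric(pxPerMm))
}

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(paste0(
    "SceneSpec  %d x %d px (+%d margin)  seed %d\n",
    "  reflections: %d x r=%.0f px jitter %.1f px   noise sd %.1f   %.3g px/mm\n"),
    object@width, object@height, object@margin, object@seed,
    object@reflectionCount, object@reflectionRadius, object@reflectionJitter,
    object@noiseSigma, object@pxPerMm))
})

# bilinearly upsample a coarse grid to h x w
.upsampleGrid <- function(grid, h, w) {
  gy <- seq(0, nrow(grid) - 1, length.out = h)
  gx <- seq(0, ncol(grid) - 1, length.out = w)
  coords <- expand.grid(y = gy, x = gx)
  matrix(.bilinearSample(grid, coords$x, coords$y), h, w)
}

#' Generate the oversized background canvas of a scene
#'
#' Renders the bone-like texture: multi-octave value noise shaded with a
#' base bone colour, dark elliptical cavities (drill sites), and fine dark
#' speckle that provides dense, well-localized corners. Output is the canvas
#' of size (height + 2 margin) x (width + 2 margin) x 3 on the 8-bit scale;
#' identical for identical specs.
#'
#' @param spec a \linkS4class{SceneSpec}.
#' @return numeric array, values in [0, 255].
#' @export
generateBackground <- function(spec) {
  h <- spec@height + 2L * spec@margin
  w <- spec@width + 2L * spec@margin
  .withSeed(spec@seed, {
    tex <- matrix(0, h, w)
    amp <- 1
    total <- 0
    cell <- 64
    for (o in seq_len(spec@octaves)) {
      gh <- max(2L, ceiling(h / cell) + 1L)
      gw <- max(2L, ceiling(w / cell) + 1L)
      tex <- tex + amp * .upsampleGrid(matrix(stats::runif(gh * gw), gh, gw),
                                       h, w)
      total <- total + amp
      amp <- amp * spec@persistence
      cell <- cell / 2
    }
    tex <- tex / total                       # in [0, 1], broadband
    shade <- 0.55 + 0.4 * tex                # keep background below the
                                             # reflection intensity band

    # dark drilled cavities: soft-edged ellipses
    nBlob <- round(spec@blobDensity * h * w / 10000)
    if (nBlob > 0) {
      for (b in seq_len(nBlob)) {
        cx <- stats::runif(1, 10, w - 11); cy <- stats::runif(1, 10, h - 11)
        rx <- stats::runif(1, 4, 18); ry <- stats::runif(1, 4, 18)
        ang <- stats::runif(1, 0, pi)
        depth <- stats::runif(1, 0.35, 0.7)
        ext <- ceiling(max(rx, ry)) + 1L
        xs <- max(1, floor(cx) - ext):min(w, ceiling(cx) + ext)
        ys <- max(1, floor(cy) - ext):min(h, ceiling(cy) + ext)
        dx <- outer(rep(1, length(ys)), xs - 1 - cx)
        dy <- outer(ys - 1 - cy, rep(1, length(xs)))
        u <- (dx * cos(ang) + dy * sin(ang)) / rx
        v <- (-dx * sin(ang) + dy * cos(ang)) / ry
        r2 <- u^2 + v^2
        wgt <- pmin(pmax(1.6 * (1 - r2), 0), 1)
        shade[ys, xs] <- shade[ys, xs] * (1 - wgt * depth)
      }
    }

    # fine speckle: 2 px radius dark dots (drilling debris), dense corners
    nSpeck <- round(spec@speckleDensity * h * w / 100)
    if (nSpeck > 0) {
      cx <- stats::runif(nSpeck, 3, w - 4)
      cy <- stats::runif(nSpeck, 3, h - 4)
      depth <- stats::runif(nSpeck, 0.3, 0.6)
      for (sdx in -2:2) for (sdy in -2:2) {
        if (sdx^2 + sdy^2 > 4) next
        ix <- round(cx) + sdx; iy <- round(cy) + sdy
        shade[cbind(iy, ix)] <- shade[cbind(iy, ix)] * (1 - depth)
      }
    }

    # slight low-frequency saturation variation so Smax is representative
    satMod <- 0.9 + 0.2 * .upsampleGrid(matrix(stats::runif(25), 5, 5), h, w)
    base <- c(205, 180, 148)                 # bone-like RGB
    img <- array(0, c(h, w, 3))
    gray <- mean(base)
    for (ch in 1:3)
      img[, , ch] <- shade * (gray + (base[ch] - gray) * satMod)
    pmin(pmax(img, 0), 255)
  })
}

# Cut one frame out of the canvas: frame(x) = canvas(x + margin - shift) for
# a pure translation, or canvas(Cinv %*% x + margin) for a general cumulative
# transform. Bilinear interpolation; coordinates must stay inside the canvas.
.cutFrame <- function(canvas, spec, cinv = NULL, shift = c(0, 0)) {
  h <- spec@height; w <- spec@width; m <- spec@margin
  xg <- rep(0:(w - 1), each = h)
  yg <- rep(0:(h - 1), times = w)
  if (is.null(cinv)) {
    sx <- xg + m - shift[1]
    sy <- yg + m - shift[2]
  } else {
    sx <- cinv[1, 1] * xg + cinv[1, 2] * yg + cinv[1, 3] + m
    sy <- cinv[2, 1] * xg + cinv[2, 2] * yg + cinv[2, 3] + m
  }
  if (min(sx) < 0 || min(sy) < 0 || max(sx) > ncol(canvas) - 1 ||
      max(sy) > nrow(canvas) - 1)
    .stopf("scene leaves canvas: enlarge the margin")
  img <- array(0, c(h, w, 3))
  for (ch in 1:3)
    img[, , ch] <- matrix(.bilinearSample(canvas[, , ch], sx, sy), h, w)
  img
}

# Post-warp effects: illumination gain, specular ellipses, sensor noise.
# Deterministic per (spec, frame index). Returns the frame image and the
# logical core mask of the rendered highlights.
.applyEffects <- function(img, spec, frameIdx, baseCenters) {
  h <- spec@height; w <- spec@width
  core <- matrix(FALSE, h, w)
  .withSeed((spec@seed + 7919 * (frameIdx + 1)) %% 2147483647, {
    if (spec@illuminationDrift > 0) {
      gain <- 1 + stats::runif(1, -1, 1) * spec@illuminationDrift
      img <- img * gain
    }
    if (spec@reflectionCount > 0) {
      for (r in seq_len(nrow(baseCenters))) {
        cx <- baseCenters[r, "cx"] + stats::rnorm(1, 0, spec@reflectionJitter)
        cy <- baseCenters[r, "cy"] + stats::rnorm(1, 0, spec@reflectionJitter)
        rx <- baseCenters[r, "rx"]; ry <- baseCenters[r, "ry"]
        ext <- ceiling(max(rx, ry)) + 2L
        xs <- max(1, floor(cx) - ext):min(w, ceiling(cx) + ext)
        ys <- max(1, floor(cy) - ext):min(h, ceiling(cy) + ext)
        if (!length(xs) || !length(ys)) next
        dx <- outer(rep(1, length(ys)), xs - 1 - cx) / rx
        dy <- outer(ys - 1 - cy, rep(1, length(xs))) / ry
        r2 <- dx^2 + dy^2
        # saturated plateau with a narrow penumbra, like a blown-out
        # specular highlight
        wgt <- pmin(pmax(2.2 * (1 - r2), 0), 1)
        for (ch in 1:3)
          img[ys, xs, ch] <- img[ys, xs, ch] * (1 - wgt) +
            wgt * spec@reflectionPeak
        core[ys, xs] <- core[ys, xs] | (r2 < 0.6)
      }
    }
    if (spec@noiseSigma > 0)
      img <- img + stats::rnorm(length(img), 0, spec@noiseSigma)
  })
  list(image = pmin(pmax(img, 0), 255), core = core)
}

# Base geometry of the specular ellipses, drawn once per spec (frame coords).
.reflectionCenters <- function(spec) {
  if (spec@reflectionCount == 0) return(NULL)
  .withSeed((spec@seed + 104729) %% 2147483647, {
    cbind(cx = stats::runif(spec@reflectionCount, 0.15 * spec@width,
                            0.85 * spec@width),
          cy = stats::runif(spec@reflectionCount, 0.15 * spec@height,
                            0.85 * spec@height),
          rx = spec@reflectionRadius * stats::runif(spec@reflectionCount,
                                                    0.7, 1.4),
          ry = spec@reflectionRadius * stats::runif(spec@reflectionCount,
                                                    0.7, 1.4))
  })
}

#' Render a frame sequence following a reference trajectory
#'
#' Samples the reference at the given times, converts millimetres to pixels
#' with the scene scale, and cuts each frame out of the oversized canvas
#' translated accordingly, so the rendered scene moves exactly as commanded.
#' Specular highlights, illumination drift and sensor noise are applied
#' after the warp. The exact per-step ground-truth transforms (pure
#' translations in pixel units) are returned alongside the frames.
#'
#' @param spec a \linkS4class{SceneSpec}.
#' @param ref a \linkS4class{ReferenceTrajectory}.
#' @param times non-decreasing sample times in seconds.
#' @return list with \code{frames} (list of \linkS4class{Frame}),
#'   \code{steps} (list of ground-truth \linkS4class{AffineTransform2D},
#'   one per consecutive pair), \code{positionsPx} (commanded positions in
#'   pixels), and \code{reflectionCores} (per-frame logical mask of the
#'   rendered highlight cores).
#' @export
renderSequence <- function(spec, ref, times) {
  posMm <- sampleReference(ref, times)
  posPx <- posMm * spec@pxPerMm
  if (max(abs(posPx)) > spec@margin - 1)
    .stopf("scene leaves canvas: trajectory needs %.1f px, margin is %d px",
           max(abs(posPx)), spec@margin)
  canvas <- generateBackground(spec)
  centers <- .reflectionCenters(spec)
  n <- length(times)
  frames <- vector("list", n)
  cores <- vector("list", n)
  for (i in seq_len(n)) {
    img <- .cutFrame(canvas, spec, shift = posPx[i, ])
    fx <- .applyEffects(img, spec, i - 1L, centers)
    frames[[i]] <- newFrame(fx$image, index = i - 1L, timestamp = times[i])
    cores[[i]] <- fx$core
  }
  steps <- lapply(seq_len(n - 1), function(i)
    affineTransform2D(b0 = posPx[i + 1, 1] - posPx[i, 1],
                      b1 = posPx[i + 1, 2] - posPx[i, 2]))
  list(frames = frames, steps = steps, positionsPx = posPx,
       reflectionCores = cores)
}

#' Render a frame sequence under arbitrary affine motion
#'
#' Exercises the full 6-parameter motion model beyond the rig's pure
#' translations: frame i is the background warped by the cumulative product
#' of the supplied step transforms (frame 0 is unwarped). Each step must be
#' well-conditioned (|det(linear part) - 1| <= 0.5).
#'
#' @param spec a \linkS4class{SceneSpec}.
#' @param transforms list of step \linkS4class{AffineTransform2D}; frame
#'   count is length(transforms) + 1.
#' @param fps frame rate used for the synthesized timestamps.
#' @return list with \code{frames}, \code{steps} (the input transforms) and
#'   \code{reflectionCores}, as in \code{\link{renderSequence}}.
#' @export
renderAffineSequence <- function(spec, transforms, fps = 25) {
  for (t in transforms)
    if (abs(det(t@m[1:2, 1:2]) - 1) > 0.5)
      .stopf("ill-conditioned transform: |det - 1| > 0.5")
  canvas <- generateBackground(spec)
  centers <- .reflectionCenters(spec)
  n <- length(transforms) + 1L
  frames <- vector("list", n)
  cores <- vector("list", n)
  cum <- identityTransform()
  for (i in seq_len(n)) {
    cinv <- invertTransform(cum)@m
    img <- .cutFrame(canvas, spec, cinv = cinv)
    fx <- .applyEffects(img, spec, i - 1L, centers)
    frames[[i]] <- newFrame(fx$image, index = i - 1L,
                            timestamp = (i - 1) / fps)
    cores[[i]] <- fx$core
    if (i < n) cum <- composeTransforms(transforms[[i]], cum)
  }
  list(frames = frames, steps = transforms, reflectionCores = cores)
}
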