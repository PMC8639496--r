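# Shared fixtures, memoized so expensive renders happen once per test run.

.fixtureCache <- new.env(parent = emptyenv())

memoFixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache)) {
    assign(name, builder(), envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

# clean 256 x 256 textured frame (no reflections, no noise)
richFrame <- function() memoFixture("richFrame", function() {
  spec <- sceneSpec(seed = 11, height = 256, width = 256, margin = 16,
                    reflectionCount = 0L, noiseSigma = 0,
                    illuminationDrift = 0)
  newFrame(generateBackground(spec)[17:272, 17:272, ])
})

# clean feature-rich 512 x 512 scene spec
cleanSpec512 <- function(seed = 7) {
  sceneSpec(seed = seed, reflectionCount = 0L, noiseSigma = 0,
            illuminationDrift = 0)
}

# random RGB frame with integer 8-bit values
randomFrame <- function(h = 16, w = 16) {
  newFrame(array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3)))
}

# build a frame directly from per-pixel HSV value/saturation matrices
# (hue fixed; used by the mask tests)
frameFromVS <- function(v, s) {
  h <- nrow(v); w <- ncol(v)
  img <- array(0, c(h, w, 3))
  img[, , 1] <- 255 * v              # max channel
  img[, , 2] <- 255 * v * (1 - s)    # min channels
  img[, , 3] <- 255 * v * (1 - s)
  newFrame(img)
}

# independent oracle for the mask predicate: own HSV arithmetic, no shared
# code with computeValidityMask
maskOracle <- function(frame, tau1, tau2) {
  img <- frameImage(frame)
  mx <- pmax(img[, , 1], img[, , 2], img[, , 3])
  mn <- pmin(img[, , 1], img[, , 2], img[, , 3])
  V <- mx / 255
  S <- ifelse(mx > 0, 1 - mn / mx, 0)
  iMax <- max(V); sMax <- max(S)
  if (sMax == 0 && iMax > 0) V < tau1 * iMax
  else (V < tau1 * iMax) | (S > tau2 * sMax)
}

# rotation (degrees) and scale about a centre point, as a step transform
rotScaleAbout <- function(deg, scale = 1, centre) {
  th <- deg * pi / 180
  lin <- affineTransform2D(scale * cos(th), -scale * sin(th),
                           scale * sin(th), scale * cos(th))
  composeTransforms(affineTransform2D(b0 = centre[1], b1 = centre[2]),
                    composeTransforms(lin,
                      affineTransform2D(b0 = -centre[1], b1 = -centre[2])))
}

# random trajectory record table
randomRecords <- function(n) {
  data.frame(frame = 0:(n - 1), timestamp = sort(runif(n, 0, 100)),
             a00 = rnorm(n), a01 = rnorm(n), a10 = rnorm(n), a11 = rnorm(n),
             b0 = rnorm(n, 0, 10), b1 = rnorm(n, 0, 10),
             x_px = rnorm(n, 0, 100), y_px = rnorm(n, 0, 100),
             x_mm = rnorm(n), y_mm = rnorm(n),
             n_features = sample.int(500, n), n_matches = sample.int(300, n),
             n_inliers = sample.int(200, n),
             status = sample(c("ok", "fallback_identity"), n, replace = TRUE))
}

# exhaustive RANSAC consensus oracle: max inlier count over all C(n,3)
# minimal samples (exact affine fit per triple)
consensusOracle <- function(src, dst, threshold) {
  n <- nrow(src)
  best <- 0L
  combs <- utils::combn(n, 3)
  for (j in seq_len(ncol(combs))) {
    pick <- combs[, j]
    X <- cbind(src[pick, 1], src[pick, 2], 1)
    qrX <- qr(X)
    if (qrX$rank < 3) next
    cf <- qr.coef(qrX, dst[pick, , drop = FALSE])
    px <- src[, 1] * cf[1, 1] + src[, 2] * cf[2, 1] + cf[3, 1]
    py <- src[, 1] * cf[1, 2] + src[, 2] * cf[2, 2] + cf[3, 2]
    cnt <- sum((px - dst[, 1])^2 + (py - dst[, 2])^2 <= threshold^2)
    if (cnt > best) best <- cnt
  }
  best
}

# seeded instance of 12 correspondences with nOut outliers
ransacInstance <- function(seed, nOut) {
  set.seed(seed)
  gt <- affineTransform2D(1 + rnorm(1, 0, 0.05), rnorm(1, 0, 0.05),
                          rnorm(1, 0, 0.05), 1 + rnorm(1, 0, 0.05),
                          runif(1, -5, 5), runif(1, -5, 5))
  src <- cbind(runif(12, 0, 100), runif(12, 0, 100))
  dst <- applyTransform(gt, src)
  if (nOut > 0)
    dst[seq_len(nOut), ] <- cbind(runif(nOut, 0, 100), runif(nOut, 0, 100))
  list(src = src, dst = dst)
}

# per-step tracking errors (px) of a run against ground-truth positions
stepErrors <- function(records, positionsPx) {
  dx <- diff(records$x_px) - diff(positionsPx[, 1])
  dy <- diff(records$y_px) - diff(positionsPx[, 2])
  sqrt(dx^2 + dy^2)
}
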