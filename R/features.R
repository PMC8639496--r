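# Oriented FAST + rotated BRIEF feature pipeline.
#
# FAST-9/16 corners are detected on the luma channel, ranked by a
# sum-of-absolute-differences corner score, non-maximum suppressed, restricted
# to the validity mask, and localized to subpixel precision by a quadratic fit
# of the score surface. Each keypoint gets an orientation from the intensity
# centroid of a radius-15 disc and a 256-bit BRIEF descriptor sampled from a
# fixed pseudo-random pattern rotated to that orientation on a Gaussian-blurred
# copy of the frame.

# Bresenham circle of radius 3: the 16 (dx, dy) ring offsets, clockwise.
.fastRing <- cbind(
  dx = c(0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3, -3, -3, -2, -1),
  dy = c(-3, -3, -2, -1, 0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3))

# Patch geometry: BRIEF offsets live in [-13, 13]; rotating them stays within
# radius 13 * sqrt(2) < 19, and the orientation disc has radius 15, so any
# keypoint at least .featureMargin pixels from the border samples in-bounds.
.featureMargin <- 20L
.briefBits <- 256L

# 256 fixed (x1, y1, x2, y2) sampling offsets drawn once from an isotropic
# Gaussian (sd = patch/5) via a private linear congruential generator, so the
# pattern is identical in every session without touching R's RNG.
.briefPattern <- local({
  state <- 20210742
  lcg <- function() {
    state <<- (1103515245 * state + 12345) %% 2147483648
    state / 2147483648
  }
  n <- 2L * 4L * .briefBits   # two uniforms per normal deviate
  u <- numeric(n)
  for (i in seq_len(n)) u[i] <- lcg()
  # Box-Muller from consecutive uniform pairs
  z <- sqrt(-2 * log(pmax(u[seq(1, n, 2)], 1e-12))) * cos(2 * pi * u[seq(2, n, 2)])
  off <- matrix(pmin(pmax(round(z * 31 / 5), -13), 13), ncol = 4)
  colnames(off) <- c("x1", "y1", "x2", "y2")
  off
})

# Offsets of the orientation disc (radius 15), as columns dx, dy.
.orientDisc <- local({
  r <- 15L
  g <- expand.grid(dx = -r:r, dy = -r:r)
  as.matrix(g[g$dx^2 + g$dy^2 <= r^2, ])
})

# FAST-9/16 segment test on a luma matrix. Returns a score matrix (0 where
# not a corner): score = sum over the ring of |I_ring - I_center| - t, over
# the pixels exceeding the threshold in the majority direction.
.fastScore <- function(gray, threshold) {
  h <- nrow(gray); w <- ncol(gray)
  if (h < 8L || w < 8L) return(matrix(0, h, w))
  rows <- 4:(h - 3); cols <- 4:(w - 3)
  ctr <- gray[rows, cols]
  np <- length(ctr)
  bright <- matrix(FALSE, np, 16L)
  dark <- matrix(FALSE, np, 16L)
  sad <- 0
  for (j in 1:16) {
    s <- gray[rows + .fastRing[j, "dy"], cols + .fastRing[j, "dx"]]
    d <- s - ctr
    bright[, j] <- d > threshold
    dark[, j] <- d < -threshold
    sad <- sad + pmax(abs(d) - threshold, 0)
  }
  run9 <- function(f) {
    # TRUE where some circular run of >= 9 consecutive ring pixels is set
    fp <- cbind(f, f[, 1:8, drop = FALSE])
    a <- fp[, 1:23, drop = FALSE] & fp[, 2:24, drop = FALSE]   # runs of 2
    a <- a[, 1:21, drop = FALSE] & a[, 3:23, drop = FALSE]     # runs of 4
    a <- a[, 1:17, drop = FALSE] & a[, 5:21, drop = FALSE]     # runs of 8
    a <- a[, 1:16, drop = FALSE] & fp[, 9:24, drop = FALSE]    # runs of 9
    rowSums(a) > 0
  }
  corner <- run9(bright) | run9(dark)
  score <- matrix(0, h, w)
  score[rows, cols] <- ifelse(corner, as.vector(sad), 0)
  score
}

# 3 x 3 strict non-maximum suppression of a score matrix; returns (row, col)
# indices of surviving maxima.
.nonMaxSuppress <- function(score) {
  h <- nrow(score); w <- ncol(score)
  rows <- 2:(h - 1); cols <- 2:(w - 1)
  c0 <- score[rows, cols]
  keep <- c0 > 0
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0) next
    keep <- keep & (c0 > score[rows + dy, cols + dx])
  }
  idx <- which(keep, arr.ind = TRUE)
  cbind(row = idx[, 1] + 1L, col = idx[, 2] + 1L)
}

#' Detect oriented keypoints with binary descriptors inside a mask
#'
#' Runs the FAST-9 segment test on the luma channel, suppresses non-maxima of
#' the corner score, drops keypoints whose center pixel is invalid in
#' \code{mask} or closer than 20 px to the border, keeps the \code{k}
#' highest-scoring corners (ties broken by row then column, so the output is
#' fully deterministic), refines each position by a quadratic fit of the
#' score surface (bounded to the same pixel, so the center stays on a valid
#' pixel), assigns an intensity-centroid orientation, and samples a 256-bit
#' rotated BRIEF descriptor on a Gaussian-blurred (sigma = 2) copy.
#'
#' @param frame a \linkS4class{Frame}.
#' @param mask a \linkS4class{ValidityMask} of the same size (NULL = all
#'   pixels valid).
#' @param k maximum number of keypoints to return.
#' @param fastThreshold FAST center-vs-ring contrast threshold in 8-bit
#'   counts (default 20).
#' @return list with \code{keypoints} (data.frame x, y, response,
#'   orientation, octave — x, y subpixel, 0-based) and \code{descriptors}
#'   (n x 256 logical matrix, rows aligned with keypoints). A featureless
#'   frame yields zero rows, not an error.
#' @export
detectFeatures <- function(frame, mask = NULL, k = 500L, fastThreshold = 20) {
  stopifnot(k >= 1L)
  gray <- .grayscale(frame@image)
  h <- nrow(gray); w <- ncol(gray)
  if (!is.null(mask) && !identical(dim(mask@mask), dim(gray)))
    .stopf("mask shape does not match frame")
  empty <- list(
    keypoints = data.frame(x = numeric(0), y = numeric(0),
                           response = numeric(0), orientation = numeric(0),
                           octave = integer(0)),
    descriptors = matrix(FALSE, 0, .briefBits))

  score <- .fastScore(gray, fastThreshold)
  pk <- .nonMaxSuppress(score)
  if (nrow(pk) == 0L) return(empty)

  m <- .featureMargin
  inb <- pk[, "row"] > m & pk[, "row"] <= h - m &
         pk[, "col"] > m & pk[, "col"] <= w - m
  pk <- pk[inb, , drop = FALSE]
  if (!is.null(mask) && nrow(pk))
    pk <- pk[mask@mask[pk], , drop = FALSE]
  if (nrow(pk) == 0L) return(empty)

  resp <- score[pk]
  ord <- order(-resp, pk[, "row"], pk[, "col"])
  ord <- ord[seq_len(min(k, length(ord)))]
  pk <- pk[ord, , drop = FALSE]
  resp <- resp[ord]
  n <- nrow(pk)

  # subpixel refinement: 1-D quadratic through the 3 score samples per axis;
  # offsets are clamped inside the pixel so the center pixel stays valid
  refine <- function(sm, sc, sp) {
    den <- sm - 2 * sc + sp
    off <- ifelse(abs(den) > 1e-12, 0.5 * (sm - sp) / den, 0)
    pmin(pmax(off, -0.499), 0.499)
  }
  dxs <- refine(score[cbind(pk[, 1], pk[, 2] - 1L)], resp,
                score[cbind(pk[, 1], pk[, 2] + 1L)])
  dys <- refine(score[cbind(pk[, 1] - 1L, pk[, 2])], resp,
                score[cbind(pk[, 1] + 1L, pk[, 2])])

  # orientation by intensity centroid over the disc (at integer centers)
  lin <- pk[, "row"] + (pk[, "col"] - 1L) * h
  discLin <- outer(lin, .orientDisc[, "dy"] + .orientDisc[, "dx"] * h, "+")
  vals <- matrix(gray[discLin], n)
  m10 <- as.vector(vals %*% .orientDisc[, "dx"])
  m01 <- as.vector(vals %*% .orientDisc[, "dy"])
  theta <- atan2(m01, m10) %% (2 * pi)

  # rotated BRIEF on the blurred luma
  blurred <- .gaussianBlur(gray, 2)
  ct <- cos(theta); st <- sin(theta)
  sampleLin <- function(ox, oy) {
    rx <- round(outer(ct, ox) - outer(st, oy))
    ry <- round(outer(st, ox) + outer(ct, oy))
    lin + (ry + rx * h)
  }
  p1 <- matrix(blurred[sampleLin(.briefPattern[, "x1"], .briefPattern[, "y1"])],
               n)
  p2 <- matrix(blurred[sampleLin(.briefPattern[, "x2"], .briefPattern[, "y2"])],
               n)
  desc <- p1 < p2

  list(keypoints = data.frame(x = pk[, "col"] - 1 + dxs,
                              y = pk[, "row"] - 1 + dys,
                              response = resp, orientation = theta,
                              octave = 0L),
       descriptors = desc)
}

#' Match binary descriptor sets by Hamming distance
#'
#' Brute-force nearest neighbour from \code{descA} to \code{descB} under
#' Hamming distance. With \code{crossCheck} only mutual nearest neighbours
#' are kept, so the mapping is injective in both directions. Ties are broken
#' by the lowest index in \code{descB}; the result is sorted by ascending
#' distance, then by \code{index_a}, making the output fully deterministic.
#'
#' @param descA,descB logical matrices (n x 256), rows are descriptors.
#' @param crossCheck logical; mutual nearest-neighbour filtering.
#' @return data.frame with columns \code{index_a}, \code{index_b} (1-based
#'   row indices) and \code{distance} (integer Hamming distance in [0, 256]).
#' @export
matchDescriptors <- function(descA, descB, crossCheck = TRUE) {
  emptyRes <- data.frame(index_a = integer(0), index_b = integer(0),
                         distance = integer(0))
  if (NROW(descA) == 0L || NROW(descB) == 0L) return(emptyRes)
  A <- matrix(as.numeric(descA), nrow(descA))
  B <- matrix(as.numeric(descB), nrow(descB))
  # Hamming distance = #(a & !b) + #(!a & b)
  D <- A %*% t(1 - B) + (1 - A) %*% t(B)
  nnB <- max.col(-D, ties.method = "first")
  ia <- seq_len(nrow(A))
  if (crossCheck) {
    nnA <- max.col(-t(D), ties.method = "first")
    keep <- nnA[nnB] == ia
    ia <- ia[keep]
  }
  ib <- nnB[ia]
  dist <- as.integer(round(D[cbind(ia, ib)]))
  ord <- order(dist, ia)
  data.frame(index_a = ia[ord], index_b = ib[ord], distance = dist[ord])
}

# Effective feature budget: the configured k is referenced to 1080p and
# rescaled proportionally to the pixel count, with a floor of 100.
.effectiveK <- function(k, h, w) {
  max(100L, as.integer(round(k * (h * w) / (1920 * 1080))))
}
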