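# Shared raster helpers. All coordinates follow the package convention:
# 0-based, x rightward (matrix columns), y downward (matrix rows), origin at
# the top-left pixel center. Matrices are indexed [row, col] = [y + 1, x + 1].

# Luma of an RGB frame array (0..255) as an H x W matrix.
.grayscale <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# HSV saturation and value channels (both in [0, 1]) of an RGB array (0..255).
.hsvChannels <- function(img) {
  d <- dim(img)
  px <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
              as.vector(img[, , 3]))
  hsv <- grDevices::rgb2hsv(px, maxColorValue = 255)
  list(s = matrix(hsv[2, ], d[1], d[2]),
       v = matrix(hsv[3, ], d[1], d[2]))
}

# Bilinear sample of matrix `m` at 0-based fractional coordinates (x, y).
# Coordinates outside the raster are clamped to the border pixel.
.bilinearSample <- function(m, x, y) {
  h <- nrow(m); w <- ncol(m)
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- y0 + 1 + x0 * h; i10 <- y1 + 1 + x0 * h
  i01 <- y0 + 1 + x1 * h; i11 <- y1 + 1 + x1 * h
  m[i00] * (1 - fx) * (1 - fy) + m[i01] * fx * (1 - fy) +
    m[i10] * (1 - fx) * fy + m[i11] * fx * fy
}

# Separable Gaussian blur with replicated borders, exact (non-FFT): the 1-D
# kernel is applied as banded row/column matrix products with the boundary
# weights renormalized, so output is deterministic to the last bit.
.gaussianBlur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  band <- function(n) {
    B <- matrix(0, n, n)
    for (d in seq(-r, r)) {
      idx <- seq_len(n - abs(d))
      if (d >= 0) B[cbind(idx, idx + d)] <- k[d + r + 1]
      else B[cbind(idx - d, idx)] <- k[d + r + 1]
    }
    B / rowSums(B)
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. seed = NA runs expr with the current stream.
.withSeed <- function(seed, expr) {
  if (is.na(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
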