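#' Create a Frame
#'
#' @param image H x W x 3 numeric array in RGB order. Values may be on the
#'   [0, 1] or the 8-bit [0, 255] scale; [0, 1] input is rescaled to 8-bit.
#'   Grayscale matrices are replicated across the three channels.
#' @param index non-negative integer sequence position.
#' @param timestamp time in seconds.
#' @return a \linkS4class{Frame}.
#' @export
newFrame <- function(image, index = 0L, timestamp = 0) {
  if (is.matrix(image)) image <- array(rep(image, 3), c(dim(image), 3))
  if (length(dim(image)) == 3 && dim(image)[3] > 3)
    image <- image[, , 1:3, drop = FALSE]
  if (max(image) <= 1 && min(image) >= 0) image <- image * 255
  new("Frame", index = as.integer(index), timestamp = as.numeric(timestamp),
      image = image)
}

#' @rdname newFrame
#' @param frame a \code{Frame}.
#' @export
frameImage <- function(frame) frame@image

#' @rdname newFrame
#' @export
frameIndex <- function(frame) frame@index

#' @rdname newFrame
#' @export
frameTimestamp <- function(frame) frame@timestamp

setMethod("show", "Frame", function(object) {
  d <- dim(object@image)
  cat(sprintf("Frame %d  %d x %d px  t = %.4f s\n",
              object@index, d[2], d[1], object@timestamp))
})

.readImageFile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    .stopf("unsupported image format: %s", path))
  if (is.matrix(img)) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Read an ordered image sequence
#'
#' Reads a directory of numbered PNG/TIFF frames into a list of
#' \linkS4class{Frame} objects, ordered by the number embedded in each
#' filename (lexicographic order where no number is present). Timestamps are
#' taken from a sidecar \code{timestamps.csv} (columns \code{frame,timestamp})
#' if one exists in the directory, otherwise synthesized as index / fps.
#'
#' @param path directory containing the frames, or a glob pattern.
#' @param fps frame rate used to synthesize timestamps (default 25).
#' @return list of \code{Frame}s with consecutive indices from 0.
#' @export
readFrameSequence <- function(path, fps = 25) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
  } else {
    files <- Sys.glob(path)
  }
  if (length(files) < 2L) .stopf("no frames: need at least 2 image files")
  key <- suppressWarnings(as.numeric(gsub("\\D", "", basename(files))))
  ord <- if (anyNA(key)) order(basename(files)) else order(key, basename(files))
  files <- files[ord]

  ts <- NULL
  sidecar <- file.path(if (dir.exists(path)) path else dirname(files[1]),
                       "timestamps.csv")
  if (file.exists(sidecar)) {
    tt <- utils::read.csv(sidecar)
    if (!all(c("frame", "timestamp") %in% names(tt)))
      .stopf("timestamps.csv must have columns frame,timestamp")
    ts <- tt$timestamp[order(tt$frame)]
    if (length(ts) != length(files))
      .stopf("timestamps.csv has %d rows for %d frames", length(ts),
             length(files))
  }

  frames <- vector("list", length(files))
  for (i in seq_along(files)) {
    img <- .readImageFile(files[i])
    if (i > 1L && !identical(dim(img)[1:2], dim(frames[[1]]@image)[1:2]))
      .stopf("inconsistent frame size: %s", basename(files[i]))
    frames[[i]] <- newFrame(img, index = i - 1L,
                            timestamp = if (is.null(ts)) (i - 1) / fps
                                        else ts[i])
  }
  frames
}

#' Write a frame sequence as numbered PNGs
#'
#' Inverse of \code{\link{readFrameSequence}}: writes \code{frames} into
#' \code{dir} as zero-padded PNGs plus a \code{timestamps.csv} sidecar.
#'
#' @param frames list of \linkS4class{Frame}s.
#' @param dir output directory (created if absent).
#' @return invisibly, the written file paths.
#' @export
writeFrameSequence <- function(frames, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(frames))
  for (i in seq_along(frames)) {
    paths[i] <- file.path(dir, sprintf("%05d.png", frames[[i]]@index))
    png::writePNG(frames[[i]]@image / 255, paths[i])
  }
  utils::write.csv(
    data.frame(frame = vapply(frames, frameIndex, 0L),
               timestamp = vapply(frames, frameTimestamp, 0)),
    file.path(dir, "timestamps.csv"), row.names = FALSE, quote = FALSE)
  invisible(paths)
}

.configDefaults <- list(
  tau1 = 0.8, tau2 = 0.2, k = 2000L,
  ransac_min_samples = 3L, ransac_residual_threshold = 3.0,
  ransac_max_iterations = 1000L, ransac_seed = NA_integer_,
  match_cross_check = TRUE, min_inliers = 10L,
  mm_per_pixel = 1.0, keyframe_interval = 0L, fps = 25)

#' Create a tracker configuration
#'
#' All arguments default to the documented pipeline defaults: mask thresholds
#' tau1 = 0.8 and tau2 = 0.2, feature budget k = 2000 (at 1080p; rescaled by
#' pixel count for other sizes), RANSAC with minimal samples of 3, a 3 px
#' residual threshold and 1000 iterations, mutual cross-check matching, a
#' minimum consensus of 10 inliers, identity metric scale, and keyframe
#' re-anchoring disabled.
#'
#' @param tau1 intensity threshold factor in (0, 1].
#' @param tau2 saturation threshold factor in [0, 1).
#' @param k feature budget at 1080p.
#' @param ransac_min_samples minimal sample size (>= 3).
#' @param ransac_residual_threshold inlier threshold in pixels.
#' @param ransac_max_iterations RANSAC iteration count.
#' @param ransac_seed integer seed for RANSAC sampling, or NA.
#' @param match_cross_check logical, mutual nearest-neighbour filtering.
#' @param min_inliers minimal consensus size before identity fallback.
#' @param mm_per_pixel metric scale (mm per pixel).
#' @param keyframe_interval keyframe re-anchoring interval (0 = off).
#' @param fps frame rate for synthesized timestamps.
#' @return a \linkS4class{TrackerConfig}.
#' @export
trackerConfig <- function(tau1 = 0.8, tau2 = 0.2, k = 2000L,
                          ransac_min_samples = 3L,
                          ransac_residual_threshold = 3.0,
                          ransac_max_iterations = 1000L,
                          ransac_seed = NA_integer_,
                          match_cross_check = TRUE, min_inliers = 10L,
                          mm_per_pixel = 1.0, keyframe_interval = 0L,
                          fps = 25) {
  new("TrackerConfig", tau1 = as.numeric(tau1), tau2 = as.numeric(tau2),
      k = as.integer(k), ransacMinSamples = as.integer(ransac_min_samples),
      ransacResidualThreshold = as.numeric(ransac_residual_threshold),
      ransacMaxIterations = as.integer(ransac_max_iterations),
      ransacSeed = as.integer(ransac_seed),
      matchCrossCheck = as.logical(match_cross_check),
      minInliers = as.integer(min_inliers),
      mmPerPixel = as.numeric(mm_per_pixel),
      keyframeInterval = as.integer(keyframe_interval),
      fps = as.numeric(fps))
}

#' Load a tracker configuration from YAML or JSON
#'
#' Absent keys take the documented defaults; unknown keys are rejected by
#' name. An empty file yields the all-defaults configuration.
#'
#' @param path a YAML (.yml/.yaml) or JSON (.json) mapping file.
#' @return a validated \linkS4class{TrackerConfig}.
#' @export
loadTrackerConfig <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext == "json") jsonlite::fromJSON(path)
          else yaml::yaml.load_file(path)
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) .stopf("config must be a key-value mapping")
  unknown <- setdiff(names(vals), names(.configDefaults))
  if (length(unknown))
    .stopf("unknown config key: %s", paste(unknown, collapse = ", "))
  do.call(trackerConfig, vals)
}

setMethod("show", "TrackerConfig", function(object) {
  cat(sprintf(paste0(
    "TrackerConfig  tau1=%.2f tau2=%.2f k=%d\n",
    "  RANSAC: min_samples=%d residual<=%.2f px iters=%d seed=%s\n",
    "  matching: cross_check=%s  min_inliers=%d  mm/px=%.4g  keyframe=%d\n"),
    object@tau1, object@tau2, object@k, object@ransacMinSamples,
    object@ransacResidualThreshold, object@ransacMaxIterations,
    ifelse(is.na(object@ransacSeed), "unset", object@ransacSeed),
    object@matchCrossCheck, object@minInliers, object@mmPerPixel,
    object@keyframeInterval))
})

.trajColumns <- c("frame", "timestamp", "a00", "a01", "a10", "a11",
                  "b0", "b1", "x_px", "y_px", "x_mm", "y_mm",
                  "n_features", "n_matches", "n_inliers", "status")

#' Write and read trajectory CSV files
#'
#' The trajectory record table has one row per processed frame (the first row
#' is the zero record of frame 0), with the step transform parameters, the
#' cascaded position in pixels and millimetres, per-step diagnostics and the
#' step status. Numeric columns are written with full precision so a
#' write/read round trip reproduces the records to at least 12 significant
#' digits.
#'
#' @param records data.frame of trajectory records (see
#'   \code{\link{trackSequence}}).
#' @param path CSV file path.
#' @return \code{writeTrajectoryCSV}: invisibly, \code{path};
#'   \code{readTrajectoryCSV}: the records data.frame.
#' @export
writeTrajectoryCSV <- function(records, path) {
  if (nrow(records) == 0L) .stopf("no records")
  out <- records[, .trajColumns]
  for (nm in .trajColumns) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]]))
      out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTrajectoryCSV
#' @export
readTrajectoryCSV <- function(path) {
  if (!file.exists(path)) .stopf("trajectory file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) < 2L) .stopf("no records")
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  missing <- setdiff(.trajColumns, header)
  if (length(missing))
    .stopf("parse error at line 1: missing column %s",
           paste(missing, collapse = ", "))
  nf <- lengths(strsplit(lines[-1], ",", fixed = TRUE))
  bad <- which(nf != length(header))
  if (length(bad))
    .stopf("parse error at line %d: expected %d fields, found %d",
           bad[1] + 1L, length(header), nf[bad[1]])
  df <- utils::read.csv(path, colClasses = c(
    frame = "integer", timestamp = "numeric", a00 = "numeric",
    a01 = "numeric", a10 = "numeric", a11 = "numeric", b0 = "numeric",
    b1 = "numeric", x_px = "numeric", y_px = "numeric", x_mm = "numeric",
    y_mm = "numeric", n_features = "integer", n_matches = "integer",
    n_inliers = "integer", status = "character"))
  df[, .trajColumns]
}
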