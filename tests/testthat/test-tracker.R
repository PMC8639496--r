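# Tracker-level tests run on small (256 px) synthetic scenes to keep the
# suite fast; the acceptance suite exercises the full 512 px study size.

smallSpec <- function(seed = 19, ...) {
  sceneSpec(seed = seed, height = 256, width = 256, margin = 24,
            reflectionCount = 0L, noiseSigma = 0, illuminationDrift = 0, ...)
}

test_that("self-registration returns the identity", {
  f <- richFrame()
  res <- trackPair(f, f, trackerConfig(ransac_seed = 3))
  p <- transformParams(res@transform)
  expect_lt(sqrt(p[["b0"]]^2 + p[["b1"]]^2), 0.1)
  expect_lt(max(abs(p[1:4] - c(1, 0, 0, 1))), 1e-3)
  expect_equal(res@status, "ok")
})

test_that("a known translation between two frames is recovered", {
  spec <- smallSpec()
  ref <- referenceTrajectory(rbind(c(0, 0), c(4, -2)), speed = 2)
  # time at which the commanded pixel shift is exactly (4, -2) px:
  # distance |(1, -0.5)| mm at 2 mm/s and 4 px/mm
  sim <- renderSequence(spec, ref, times = c(0, sqrt(20) / 8))
  res <- trackPair(sim$frames[[1]], sim$frames[[2]],
                   trackerConfig(ransac_seed = 4))
  gt <- transformParams(sim$steps[[1]])
  p <- transformParams(res@transform)
  expect_lt(sqrt((p[["b0"]] - gt[["b0"]])^2 + (p[["b1"]] - gt[["b1"]])^2),
            0.3)
})

test_that("featureless or noise pairs fall back to identity", {
  set.seed(2)
  a <- newFrame(array(runif(128 * 128 * 3, 0, 255), c(128, 128, 3)))
  b <- newFrame(array(runif(128 * 128 * 3, 0, 255), c(128, 128, 3)))
  res <- trackPair(a, b, trackerConfig(ransac_seed = 5))
  expect_equal(res@status, "fallback_identity")
  expect_equal(transformMatrix(res@transform), diag(3))
  expect_error(trackPair(a, newFrame(array(0, c(64, 64, 3)))), "mismatch")
})

test_that("identical frames track to a zero trajectory", {
  f <- richFrame()
  frames <- lapply(0:4, function(i) newFrame(frameImage(f), index = i,
                                             timestamp = i))
  run <- trackSequence(frames, trackerConfig(ransac_seed = 6))
  rec <- trackingRecords(run)
  expect_equal(nrow(rec), 5)
  expect_true(all(abs(rec$x_px) < 0.1) && all(abs(rec$y_px) < 0.1))
  expect_equal(trackingSummary(run)$fallbacks, 0)
})

test_that("a staircase of unit steps accumulates to the commanded end point", {
  spec <- smallSpec(seed = 29)
  # 10 steps of (1, 0) px: 0.25 mm per step at 4 px/mm
  ref <- referenceTrajectory(rbind(c(0, 0), c(2.5, 0)), speed = 2)
  times <- seq(0, 1.25, length.out = 11)
  sim <- renderSequence(spec, ref, times)
  run <- trackSequence(sim$frames, trackerConfig(ransac_seed = 7))
  rec <- trackingRecords(run)
  expect_equal(nrow(rec), 11)
  expect_lt(abs(rec$x_px[11] - 10), 0.5)
  expect_lt(abs(rec$y_px[11]), 0.5)
})

test_that("an all-black frame causes exactly two fallbacks and resumes", {
  spec <- smallSpec(seed = 37)
  ref <- referenceTrajectory(rbind(c(0, 0), c(2, 0)), speed = 2)
  times <- seq(0, 1, length.out = 5)
  sim <- renderSequence(spec, ref, times)
  frames <- sim$frames
  frames[[3]] <- newFrame(array(0, c(256, 256, 3)), index = 2L,
                          timestamp = frames[[3]]@timestamp)
  run <- trackSequence(frames, trackerConfig(ransac_seed = 8))
  rec <- trackingRecords(run)
  expect_equal(sum(rec$status == "fallback_identity"), 2)
  expect_equal(rec$status[3:4], rep("fallback_identity", 2))
  # position frozen across the black frame, then resumes accumulating
  expect_equal(rec$x_px[4], rec$x_px[2])
  expect_gt(rec$x_px[5], rec$x_px[4])
})

test_that("tracking out and back returns near the starting point", {
  spec <- smallSpec(seed = 41)
  ref <- referenceTrajectory(rbind(c(0, 0), c(4, 2), c(0, 0)), speed = 2)
  times <- seq(0, referenceDuration(ref), length.out = 13)
  sim <- renderSequence(spec, ref, times)
  run <- trackSequence(sim$frames, trackerConfig(ransac_seed = 9))
  rec <- trackingRecords(run)
  endErr <- sqrt(rec$x_px[13]^2 + rec$y_px[13]^2)
  expect_lt(endErr, 0.5)
})

test_that("tracking is deterministic given config and seed", {
  spec <- smallSpec(seed = 43)
  ref <- referenceTrajectory(rbind(c(0, 0), c(3, 1)), speed = 2)
  sim <- renderSequence(spec, ref, seq(0, 1.5, 0.5))
  cfg <- trackerConfig(ransac_seed = 10)
  r1 <- trackingRecords(trackSequence(sim$frames, cfg))
  r2 <- trackingRecords(trackSequence(sim$frames, cfg))
  expect_identical(r1, r2)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeTrajectoryCSV(r1, p1); writeTrajectoryCSV(r2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("keyframe interval zero reproduces plain tracking", {
  spec <- smallSpec(seed = 47)
  ref <- referenceTrajectory(rbind(c(0, 0), c(2, 1)), speed = 2)
  sim <- renderSequence(spec, ref, seq(0, 1, 0.25))
  plain <- trackSequence(sim$frames, trackerConfig(ransac_seed = 11))
  kf0 <- trackSequenceKeyframed(sim$frames,
                                trackerConfig(ransac_seed = 11,
                                              keyframe_interval = 0L))
  expect_identical(trackingRecords(plain), trackingRecords(kf0))
})

test_that("keyframed and plain tracking agree on a drift-free sequence", {
  spec <- smallSpec(seed = 53)
  ref <- referenceTrajectory(rbind(c(0, 0), c(3, 0)), speed = 2)
  sim <- renderSequence(spec, ref, seq(0, 1.5, 0.25))
  plain <- trackingRecords(trackSequence(sim$frames,
                                         trackerConfig(ransac_seed = 12)))
  kf <- trackingRecords(trackSequence(sim$frames,
                                      trackerConfig(ransac_seed = 12,
                                                    keyframe_interval = 3L)))
  expect_lt(max(abs(kf$x_px - plain$x_px)), 0.5)
  expect_lt(max(abs(kf$y_px - plain$y_px)), 0.5)
})

test_that("record schema and bookkeeping are exact", {
  spec <- smallSpec(seed = 59)
  ref <- referenceTrajectory(rbind(c(0, 0), c(1, 0)), speed = 2)
  sim <- renderSequence(spec, ref, c(0, 0.25, 0.5))
  cfg <- trackerConfig(ransac_seed = 13, mm_per_pixel = 0.25)
  run <- trackSequence(sim$frames, cfg)
  rec <- trackingRecords(run)
  expect_named(rec, c("frame", "timestamp", "a00", "a01", "a10", "a11",
                      "b0", "b1", "x_px", "y_px", "x_mm", "y_mm",
                      "n_features", "n_matches", "n_inliers", "status"))
  expect_equal(rec$frame, 0:2)
  expect_equal(rec$x_mm, rec$x_px * 0.25)
  expect_equal(rec$b0[1], 0)  # zero record
  expect_error(trackSequence(sim$frames[1], cfg), "at least 2")
})
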