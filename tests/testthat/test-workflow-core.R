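test_that("interval semantics: phases, transitions, non-phase and pauses", {
  ann <- phase_annotation(
    data.frame(phase_id = c(1, 1, 2, 2),
               event = c("start", "end", "start", "end"),
               time_s = c(0, 10, 12, 20)),
    video_duration_s = 20)
  f <- intervals_to_frame_labels(ann, fps = 1)
  expect_equal(as.integer(unclass(f)), c(rep(1L, 10), 6L, 6L, rep(2L, 8)))
  expect_length(f, floor(20 * 1))

  # degenerate: no events at all
  empty <- phase_annotation(
    data.frame(phase_id = integer(), event = character(), time_s = numeric()),
    video_duration_s = 5)
  expect_equal(as.integer(unclass(intervals_to_frame_labels(empty, 1))),
               rep(0L, 5))

  # paused span maps to transition
  paused <- phase_annotation(
    data.frame(phase_id = 1, event = c("start", "pause", "resume", "end"),
               time_s = c(0, 4, 6, 10)),
    video_duration_s = 10)
  expect_equal(as.integer(unclass(intervals_to_frame_labels(paused, 1))),
               c(rep(1L, 4), 6L, 6L, rep(1L, 4)))
})

test_that("frame-label count matches active durations and fps scaling", {
  ann <- phase_annotation(
    data.frame(phase_id = c(1, 1, 2, 2),
               event = c("start", "end", "start", "end"),
               time_s = c(3.5, 103.5, 110, 250)),
    video_duration_s = 300)
  for (fps in c(1, 2.4)) {
    f <- intervals_to_frame_labels(ann, fps = fps)
    expect_length(f, floor(300 * fps))
    counts <- table(factor(unclass(f), levels = 0:6))
    durs <- phase_durations(ann)
    # frame count / fps recovers active duration within one frame per boundary
    expect_lt(abs(counts[["1"]] / fps - durs[["1"]]), 2 / fps + 1e-9)
    expect_lt(abs(counts[["2"]] / fps - durs[["2"]]), 2 / fps + 1e-9)
  }
})

test_that("overlapping active phases are rejected with a useful error", {
  ann <- phase_annotation(
    data.frame(phase_id = c(1, 2, 1, 2),
               event = c("start", "start", "end", "end"),
               time_s = c(0, 5, 10, 15)),
    video_duration_s = 15)
  expect_error(intervals_to_frame_labels(ann, 1), "overlapping active phases")
  expect_error(intervals_to_frame_labels(ann, 1), "phase 2")
})

test_that("annotation validation enforces the event state machine", {
  expect_error(phase_annotation(
    data.frame(phase_id = 1, event = c("start", "resume"), time_s = c(0, 5)),
    10), "not valid")
  expect_error(phase_annotation(
    data.frame(phase_id = 1, event = "start", time_s = 0), 10),
    "not closed")
  expect_error(phase_annotation(
    data.frame(phase_id = 1, event = c("start", "end"), time_s = c(5, 1)),
    10), "time-sorted")
})

test_that("clip labels are modal frame labels with stated tie/truncation rules", {
  f <- frame_labels(c(rep(1L, 9), rep(2L, 7)))
  expect_equal(as.integer(unclass(frames_to_clips(f, 16))), 1L)
  # exact tie broken by lowest code
  tie <- frame_labels(c(rep(1L, 8), rep(2L, 8)))
  expect_equal(as.integer(unclass(frames_to_clips(tie, 16))), 1L)
  # trailing partial block dropped
  f3 <- frame_labels(rep(3L, 40))
  expect_equal(as.integer(unclass(frames_to_clips(f3, 16))), c(3L, 3L))
  # too few frames
  expect_error(frames_to_clips(frame_labels(rep(1L, 10)), 16), "at least 16")
})

test_that("clip mode agrees with a brute-force mode on random inputs", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(16:120, 1)
    f <- frame_labels(sample(c(0:6), n, replace = TRUE))
    cl <- frames_to_clips(f, 16)
    x <- as.integer(unclass(f))
    for (k in seq_along(cl)) {
      blk <- x[((k - 1) * 16 + 1):(k * 16)]
      tb <- table(blk)
      expect_gte(sum(blk == unclass(cl)[k]), max(tb) )
      # expanding the clip label recovers at least the modal share
      expect_gte(mean(blk == unclass(cl)[k]), max(tb) / 16)
    }
  }
})

test_that("annotation and label files round-trip and reject bad content", {
  tmp <- tempfile(fileext = ".csv")
  ann <- phase_annotation(
    data.frame(phase_id = c(1, 1, 2, 2),
               event = c("start", "end", "start", "end"),
               time_s = c(0.125, 10, 12, 20)),
    video_duration_s = 25.5, fps_native = 24)
  write_annotation(ann, tmp)
  back <- read_annotation(tmp)
  expect_equal(back$phase_id, ann$phase_id)
  expect_equal(back$event, ann$event)
  expect_equal(back$time_s, ann$time_s, tolerance = 1e-3)
  expect_equal(attr(back, "video_duration_s"), 25.5)

  # unknown event kind named with line number
  writeLines(c("phase_id,event,time_s", "1,begin,0", "1,end,5"), tmp)
  expect_error(read_annotation(tmp), "unknown event kind 'begin'.*line 2")

  # labels round-trip and vocabulary check
  cl <- clip_labels(c(1, 1, 6, 2, 0, 5))
  write_labels(cl, tmp)
  expect_equal(as.integer(unclass(read_labels(tmp))), c(1L, 1L, 6L, 2L, 0L, 5L))
  writeLines(c("label", "1", "9"), tmp)
  expect_error(read_labels(tmp), "invalid label code 9.*line 3")

  # feature matrix round-trip
  m <- matrix(rnorm(12), 4, 3)
  write_features(m, tmp)
  expect_equal(read_features(tmp), m, tolerance = 1e-12)
})
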