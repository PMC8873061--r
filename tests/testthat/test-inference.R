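# an oracle predictor that simply copies its target sequence
copy_target <- function(features, target) as.integer(target)

test_that("time-synchronous tiling covers the video exactly", {
  set.seed(1)
  fine <- clip_labels(sample(1:5, 200, TRUE))
  feats <- matrix(0, 200, 2)
  seg <- segment_time_synchronous(copy_target, feats, fine, window_len = 100)
  expect_length(seg$labels, 200)
  expect_identical(as.integer(unclass(seg$labels)), as.integer(unclass(fine)))

  # non-divisible length: right-aligned final window, earlier windows win
  fine250 <- clip_labels(sample(1:5, 250, TRUE))
  feats250 <- matrix(0, 250, 2)
  calls <- new.env(); calls$starts <- integer()
  spy <- function(features, target) {
    calls$starts <- c(calls$starts, nrow(features))
    as.integer(target)
  }
  seg250 <- segment_time_synchronous(spy, feats250, fine250, window_len = 100)
  expect_length(seg250$labels, 250)
  expect_equal(length(calls$starts), 3L)  # windows at 0, 100, and 150 (right-aligned)
  expect_identical(as.integer(unclass(seg250$labels)), as.integer(unclass(fine250)))

  expect_error(segment_time_synchronous(copy_target, matrix(0, 50, 2),
                                        clip_labels(rep(1, 50)),
                                        window_len = 100),
               "fine-level predictions directly")
})

test_that("time-shifted recursion propagates and covers every clip", {
  set.seed(2)
  gt <- c(rep(1L, 60), rep(2L, 70), rep(3L, 60))
  fine <- clip_labels(gt)
  feats <- matrix(0, 190, 2)
  n_windows <- new.env(); n_windows$k <- 0L
  # a model that copies its target with the time shift: output position
  # k (window position k + shift) takes the target label at the same
  # absolute clip, extending the final label past the target span
  copy_shifted <- function(features, target) {
    n_windows$k <- n_windows$k + 1L
    tl <- length(target)
    c(as.integer(target)[11:tl], rep(as.integer(target)[tl], 10L))
  }
  const_fine <- clip_labels(rep(2L, 190))
  seg <- segment_time_shifted(copy_shifted, feats, const_fine,
                              window_len = 100, out_len = 90, shift = 10)
  expect_equal(n_windows$k, 10L)  # starts 0,10,...,90
  expect_length(seg$labels, 190)
  # identity recursion: the fine-level initialisation propagates through
  # the whole video (target copying can only carry information forward)
  expect_identical(as.integer(unclass(seg$labels)), rep(2L, 190))
  # initialisation prefix provenance: only the first `shift` clips have no
  # model prediction
  expect_equal(which(seg$provenance == "fine_init"), 1:10)

  # a perfect oracle (returns groundtruth for its output span) recovers
  # groundtruth everywhere outside the initialisation prefix
  starts <- seq(0, 90, by = 10)
  k <- new.env(); k$i <- 0L
  oracle <- function(features, target) {
    k$i <- k$i + 1L
    s <- starts[k$i]
    gt[(s + 11):(s + 100)]
  }
  noisy_fine <- clip_labels(ifelse(seq_along(gt) %% 7 == 0, 6L, gt))
  seg2 <- segment_time_shifted(oracle, feats, noisy_fine, window_len = 100,
                               out_len = 90, shift = 10)
  expect_identical(unclass(seg2$labels)[11:190], gt[11:190])

  expect_warning(segment_time_shifted(copy_target, feats, fine,
                                      stride = 20, window_len = 100,
                                      out_len = 90, shift = 10),
                 "stride")
  expect_error(segment_time_shifted(copy_target, matrix(0, 50, 2),
                                    clip_labels(gt[1:50]), window_len = 100,
                                    out_len = 90, shift = 10), "window needs")
})

test_that("mode filter matches brute force and honours edge cases", {
  expect_identical(as.integer(unclass(mode_average_filter(clip_labels(c(1, 1, 2, 1, 1)), 3))),
                   rep(1L, 5))
  const <- clip_labels(rep(4L, 20))
  expect_identical(as.integer(unclass(mode_average_filter(const, 7))), rep(4L, 20))
  x <- clip_labels(c(3, 1, 2, 2, 5))
  expect_identical(mode_average_filter(x, 1), x)
  expect_error(mode_average_filter(x, 4), "odd")
  set.seed(3)
  for (rep in 1:10) {
    v <- sample(1:4, 40, replace = TRUE)
    width <- sample(c(3, 5, 9), 1)
    got <- as.integer(unclass(mode_average_filter(clip_labels(v), width)))
    expect_identical(got, as.integer(oracle_mode_filter(v, width)))
  }
})

test_that("segmentation output labels come from the candidate multiset", {
  set.seed(4)
  gt <- sample(1:5, 150, TRUE)
  fine <- clip_labels(gt)
  feats <- matrix(0, 150, 2)
  recorded <- new.env(); recorded$all <- list()
  tracker <- function(features, target) {
    out <- as.integer(target)
    recorded$all[[length(recorded$all) + 1L]] <- out
    out
  }
  seg <- segment_time_shifted(tracker, feats, fine, window_len = 100,
                              out_len = 90, shift = 10)
  # every final label was observed among candidates or the fine initialisation
  expect_true(all(unclass(seg$labels) %in% c(gt, unclass(fine))))
  td <- tidy(seg)
  expect_equal(nrow(td), 150L)
  expect_named(td, c("clip", "label", "provenance"))
})
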