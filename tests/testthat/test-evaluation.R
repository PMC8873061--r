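test_that("events are maximal runs with inclusive 0-based indices", {
  ev <- extract_events(clip_labels(c(1, 1, 2, 1)), 1)
  expect_equal(ev$start, c(0L, 3L))
  expect_equal(ev$stop, c(1L, 3L))
  expect_equal(nrow(extract_events(clip_labels(c(1, 1, 2, 1)), 5)), 0L)
  ev3 <- extract_events(clip_labels(rep(3L, 7)), 3)
  expect_equal(ev3$start, 0L)
  expect_equal(ev3$stop, 6L)
})

test_that("Ward scoring reproduces worked fragmentation and merge cases", {
  # one fragmented groundtruth event plus an insertion
  ws <- ward_score(clip_labels(c(1, 1, 1, 1, 2, 2, 2, 2)),
                   clip_labels(c(1, 1, 3, 1, 2, 2, 2, 2)), classes = 1:3)
  expect_equal(ws$counts$C, 1)
  expect_equal(ws$counts$F, 1)
  expect_equal(ws$counts$Fp, 2)
  expect_equal(ws$counts$Ip, 1)
  expect_equal(ws$counts$D + ws$counts$M + ws$counts$Mp + ws$counts$FM +
                 ws$counts$FMp, 0)
  expect_equal(ws$event_ratio, 0.5)

  # two merged groundtruth events and one deletion
  ws2 <- ward_score(clip_labels(c(1, 1, 2, 2, 1, 1)),
                    clip_labels(c(1, 1, 1, 1, 1, 1)), classes = 1:2)
  expect_equal(ws2$counts$M, 2)
  expect_equal(ws2$counts$Mp, 1)
  expect_equal(ws2$counts$D, 1)
  expect_equal(ws2$counts$C, 0)
  expect_equal(ws2$event_ratio, 3)

  # identity: everything correct
  gt <- clip_labels(c(rep(1, 5), 6, rep(2, 6), 6, rep(3, 4)))
  ws3 <- ward_score(gt, gt)
  expect_equal(ws3$counts$C, 3)
  expect_equal(ws3$event_ratio, 1)
  expect_equal(ws3$n_gt_events, ws3$n_pred_events)

  expect_error(ward_score(clip_labels(1:3), clip_labels(1:2)), "length mismatch")
})

test_that("Ward scoring matches the brute-force oracle with conservation", {
  set.seed(11)
  for (rep in 1:200) {
    n <- sample(5:50, 1)
    k <- sample(2:4, 1)
    gt <- sample(seq_len(k), n, replace = TRUE)
    pred <- sample(seq_len(k), n, replace = TRUE)
    ws <- ward_score(clip_labels(gt), clip_labels(pred), classes = seq_len(k))
    orc <- oracle_ward(gt, pred, seq_len(k))
    expect_identical(lapply(ws$counts, as.integer), orc$counts)
    cnt <- ws$counts
    expect_equal(ws$n_gt_events, cnt$C + cnt$D + cnt$F + cnt$M + cnt$FM)
    expect_equal(ws$n_pred_events, cnt$C + cnt$Ip + cnt$Fp + cnt$Mp + cnt$FMp)
  }
})

test_that("an isolated spurious event adds exactly one insertion", {
  gt <- c(rep(1L, 10), rep(2L, 10))
  pred <- gt
  base <- ward_score(clip_labels(gt), clip_labels(pred))
  pred2 <- pred
  pred2[5] <- 3L  # spurious class-3 event inside the class-1 span
  mod <- ward_score(clip_labels(gt), clip_labels(pred2))
  expect_equal(mod$counts$Ip, base$counts$Ip + 1)
  # class-2 groundtruth side untouched
  expect_equal(mod$per_class$C[mod$per_class$class == 2],
               base$per_class$C[base$per_class$class == 2])
})

test_that("zero predicted events gives the worst-case event ratio", {
  ws <- ward_score(clip_labels(c(1, 1, 2, 2)), clip_labels(c(6, 6, 6, 6)))
  expect_equal(ws$n_pred_events, 0)
  expect_equal(ws$event_ratio, 0)
  expect_equal(ws$counts$D, 2)
})

test_that("frame metrics behave on identity and reported P/R pairs", {
  gt <- clip_labels(c(0, 0, rep(1, 10), 6, rep(2, 10), rep(3, 5), 0))
  fm <- frame_metrics(gt, gt)
  expect_equal(fm$macro_precision, 100)
  expect_equal(fm$macro_recall, 100)
  expect_equal(fm$f1, 1)
  expect_equal(fm$micro_accuracy, 100)

  expect_equal(round(f1_from_pr(74.6, 78.8), 2), 0.77)
  expect_equal(round(f1_from_pr(74.9, 71.2), 2), 0.73)
  expect_equal(round(f1_from_pr(58.5, 68.6), 2), 0.63)

  expect_error(frame_metrics(clip_labels(c(0, 0, 6)), clip_labels(c(1, 1, 1))),
               "no phase positions")
  # transition predictions degrade precision but transition is not a
  # macro-averaged class
  pred <- clip_labels(c(0, 0, rep(1, 9), 6, 6, rep(2, 10), rep(3, 5), 0))
  fm2 <- frame_metrics(gt, pred)
  expect_lt(fm2$micro_accuracy, 100)
  expect_equal(fm2$macro_precision, 100)  # no phase mispredicted as a phase
})

test_that("confusion matrix is row-normalised over groundtruth phases", {
  gt <- clip_labels(c(1, 1, 2, 2))
  pred <- clip_labels(c(1, 2, 2, 2))
  m <- confusion_matrix(gt, pred)
  expect_equal(unname(m[1, ]), c(0.5, 0.5, 0, 0, 0))
  expect_equal(unname(m[2, ]), c(0, 1, 0, 0, 0))
  expect_identical(rownames(m), c("1", "2"))

  set.seed(5)
  g <- clip_labels(sample(1:5, 200, TRUE))
  p <- clip_labels(sample(c(1:6), 200, TRUE))
  mm <- confusion_matrix(g, p)
  expect_equal(unname(rowSums(mm)), rep(1, nrow(mm)), tolerance = 1e-9)
  # identity gives the unit matrix on phase columns
  mi <- confusion_matrix(g, g)
  expect_equal(unname(mi), diag(5))
})
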