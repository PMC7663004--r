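test_that("the four accuracy metrics reproduce hand-computable ratios", {
  c1 <- confusion_counts(tp = 198, fp = 1, fn = 25)
  expect_equal(c1$gt, 223)
  expect_equal(round(producer_accuracy(c1), 4), 0.8879)
  expect_equal(round(user_accuracy(c1), 4), 0.9950)
  expect_equal(recall_metric(c1), producer_accuracy(c1))
  expect_equal(round(average_accuracy(c1), 4), 0.9414)

  c2 <- confusion_counts(tp = 177, fp = 7, fn = 8)
  expect_equal(round(average_accuracy(c2), 4), 0.9594)
  c3 <- confusion_counts(tp = 101, fp = 10, fn = 2)
  expect_equal(round(producer_accuracy(c3), 4), 0.9806)
  c4 <- confusion_counts(tp = 78, fp = 15, fn = 5)
  expect_equal(round(user_accuracy(c4), 4), 0.8387)
  c5 <- confusion_counts(tp = 99, fp = 13, fn = 6)
  expect_equal(round(recall_metric(c5), 4), 0.9429)
  c6 <- confusion_counts(tp = 326, fp = 25, fn = 60)
  expect_equal(round(recall_metric(c6), 4), 0.8446)

  perfect <- confusion_counts(tp = 10, fp = 0, fn = 0)
  expect_equal(average_accuracy(perfect), 1)
  expect_equal(producer_accuracy(confusion_counts(tp = 0, fp = 3, fn = 10)), 0)
})

test_that("degenerate confusion counts raise informative errors", {
  expect_error(producer_accuracy(confusion_counts(0, 5, 0)), "no ground truth")
  expect_error(user_accuracy(confusion_counts(0, 0, 4)), "no detections")
  expect_error(recall_metric(confusion_counts(0, 2, 0)), "tp \\+ fn")
  expect_error(confusion_counts(-1, 0, 0), "nonnegative")
  expect_error(confusion_counts(1, 0, 1, gt = 5), "gt must equal")
})

test_that("metrics_report bundles counts with all four measures", {
  r <- metrics_report(confusion_counts(tp = 336, fp = 9, fn = 33))
  expect_equal(round(r$p_acc, 4), 0.9106)
  expect_equal(round(r$u_acc, 4), 0.9739)
  expect_equal(round(r$acc, 4), 0.9422)
  expect_equal(r$acc, (r$p_acc + r$u_acc) / 2)
  expect_equal(r$recall, r$p_acc)   # gt = tp + fn by construction
  expect_true(all(unlist(r[c("p_acc", "u_acc", "recall", "acc")]) >= 0))
  expect_true(all(unlist(r[c("p_acc", "u_acc", "recall", "acc")]) <= 1))
})

test_that("pooling sums counts before computing metrics", {
  a <- confusion_counts(tp = 10, fp = 2, fn = 3)
  b <- confusion_counts(tp = 30, fp = 1, fn = 7)
  pooled <- pooled_summary(list(a, b))
  expect_equal(pooled$counts$tp, 40)
  expect_equal(pooled$p_acc, 40 / 50)
  # single region: identical to its own report
  single <- pooled_summary(list(a))
  expect_equal(single$p_acc, producer_accuracy(a))
  expect_equal(single$macro_acc, average_accuracy(a))
  # two equal regions: same metrics as either (pooling invariance)
  twin <- pooled_summary(list(a, a))
  expect_equal(twin$p_acc, producer_accuracy(a))
  expect_equal(twin$u_acc, user_accuracy(a))
  expect_error(pooled_summary(list()), "nonempty")
})

test_that("greedy matching produces exact counts on constructed layouts", {
  pts <- data.frame(row = c(10, 20, 30), col = c(10, 40, 70))
  m <- match_detections(pts, pts, radius_px = 5)
  expect_equal(unlist(m), c(tp = 3, fp = 0, fn = 0, gt = 3))
  none <- match_detections(pts[0, ], pts, radius_px = 5)
  expect_equal(unlist(none), c(tp = 0, fp = 0, fn = 3, gt = 3))
  far <- match_detections(data.frame(row = 10, col = 30),
                          data.frame(row = 10, col = 10), radius_px = 10)
  expect_equal(unlist(far), c(tp = 0, fp = 1, fn = 1, gt = 1))
  # one-to-one: two detections cannot share one plant
  dup <- match_detections(data.frame(row = c(10, 11), col = c(10, 10)),
                          data.frame(row = 10, col = 10), radius_px = 5)
  expect_equal(dup$tp, 1)
  expect_equal(dup$fp, 1)
})

test_that("matching bookkeeping identities hold on random instances", {
  set.seed(41)
  for (i in 1:20) {
    nd <- sample(0:8, 1); ng <- sample(0:8, 1)
    det <- data.frame(row = runif(nd, 0, 50), col = runif(nd, 0, 50))
    gt <- data.frame(row = runif(ng, 0, 50), col = runif(ng, 0, 50))
    m <- match_detections(det, gt, radius_px = 12)
    expect_equal(m$tp + m$fp, nd)
    expect_equal(m$tp + m$fn, ng)
    expect_lte(m$tp, min(nd, ng))
  }
})

test_that("greedy matching attains the exhaustive optimal TP on small instances", {
  set.seed(43)
  for (i in 1:25) {
    nd <- sample(1:8, 1); ng <- sample(1:8, 1)
    det <- data.frame(row = runif(nd, 0, 40), col = runif(nd, 0, 40))
    gt <- data.frame(row = runif(ng, 0, 40), col = runif(ng, 0, 40))
    radius <- runif(1, 5, 15)
    expect_equal(match_detections(det, gt, radius)$tp,
                 oracle_max_matching(det, gt, radius))
  }
})

test_that("the shipped field survey counts satisfy the gt = tp + fn identity", {
  fc <- agave_field_counts()
  expect_equal(nrow(fc), 9)
  expect_equal(fc$gt, fc$tp + fc$fn)
})
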