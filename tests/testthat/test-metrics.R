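test_that("greedy matching handles the canonical cases", {
  gts <- boxes_df(c(0, 0), c(.2, .8), c(.2, .8), c(.1, .1), c(.1, .1))
  # perfect predictions: all TP
  perfect <- gts; perfect$conf <- c(.9, .8)
  m <- match_detections(perfect, gts)
  expect_true(all(m$tp))
  expect_identical(c(m$n_fp, m$n_fn), c(0L, 0L))
  # no predictions: everything missed
  m0 <- match_detections(boxes_df(), gts)
  expect_identical(m0$n_fn, 2L)
  # 2 GT, 3 preds: TP(.9), FP(.8), TP(.7)
  preds <- boxes_df(c(0, 0, 0), c(.2, .6, .8), c(.2, .6, .8),
                    rep(.1, 3), rep(.1, 3), c(.9, .8, .7))
  m3 <- match_detections(preds, gts)
  expect_identical(m3$tp, c(TRUE, FALSE, TRUE))
  expect_identical(c(m3$n_tp, m3$n_fp, m3$n_fn), c(2L, 1L, 0L))
  # each ground truth matches at most once
  dup <- boxes_df(c(0, 0), c(.2, .2), c(.2, .2), c(.1, .1), c(.1, .1),
                  c(.9, .8))
  md <- match_detections(dup, gts[1, ])
  expect_identical(sum(md$tp), 1L)
})

test_that("precision and recall follow their definitions with logged 0/0", {
  m <- list(n_tp = 5L, n_fp = 3L, n_fn = 0L)
  expect_equal(unname(precision_recall(m)["precision"]), 0.625)
  m2 <- list(n_tp = 5L, n_fp = 0L, n_fn = 5L)
  expect_equal(unname(precision_recall(m2)["recall"]), 0.5)
  expect_message(pr <- precision_recall(list(n_tp = 0L, n_fp = 0L,
                                             n_fn = 3L)), "no predictions")
  expect_equal(unname(pr["precision"]), 0)
  expect_message(pr2 <- precision_recall(list(n_tp = 0L, n_fp = 2L,
                                              n_fn = 0L)), "no ground truths")
  expect_equal(unname(pr2["recall"]), 1)
})

test_that("average precision integrates the envelope exactly", {
  expect_equal(average_precision(c(TRUE, TRUE), n_gt = 2)$ap, 1)
  expect_equal(average_precision(c(FALSE, FALSE), n_gt = 2)$ap, 0)
  # worked sweep: (R=.5,P=1), (.5,.5), (1,2/3) -> 0.5*1 + 0.5*(2/3)
  ap <- average_precision(c(TRUE, FALSE, TRUE), n_gt = 2)$ap
  expect_equal(ap, 0.5 + 0.5 * 2 / 3, tolerance = 1e-12)
  expect_true(is.na(average_precision(logical(), n_gt = 0)$ap))
})

test_that("AP equals the brute-force threshold sweep on random scenes", {
  for (s in 1:200) {
    n <- withr::with_seed(s, sample(1:30, 1))
    tp <- withr::with_seed(s + 1e4, runif(n) < 0.6)
    n_gt <- sum(tp) + withr::with_seed(s + 2e4, sample(0:5, 1))
    if (n_gt == 0) next
    expect_equal(average_precision(tp, n_gt = n_gt)$ap,
                 ap_bruteforce(tp, n_gt), tolerance = 1e-9)
  }
})

test_that("AP is stable under duplicated confidences with the stable tie-break", {
  preds <- boxes_df(rep(0, 4), c(.2, .4, .6, .8), rep(.5, 4),
                    rep(.1, 4), rep(.1, 4), c(.9, .5, .5, .5))
  gts <- boxes_df(rep(0, 2), c(.2, .4), rep(.5, 2), rep(.1, 2), rep(.1, 2))
  m <- match_detections(preds, gts)
  # order() is stable: equal confidences keep input order
  expect_identical(m$conf, c(.9, .5, .5, .5))
  expect_identical(m$tp, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("mAP averages only classes present in the ground truth", {
  expect_equal(map50(c(0.5, 0.5, 0.5)), 0.5)
  # per-class pattern mirroring a typical four-class report
  expect_equal(map50(c(.745, .846, .810, .818)), .80475, tolerance = 1e-12)
  expect_message(v <- map50(c(0.6, NA, 0.8)), "absent")
  expect_equal(v, 0.7)
})

test_that("the end-to-end evaluator scores a perfect detector at 1", {
  gts <- lapply(1:5, function(i) rand_boxes(3, seed = i))
  preds <- lapply(gts, function(g) { g$conf <- 0.9; g })
  suppressMessages(rep <- evaluate_detections(preds, gts, 4))
  expect_equal(rep$map50, 1)
  expect_equal(rep$precision, 1)
  expect_equal(rep$recall, 1)
  diagm <- rep$confusion[1:4, 1:4]
  expect_equal(sum(diag(diagm)), sum(vapply(gts, nrow, integer(1))))
  expect_equal(sum(rep$confusion) - sum(diag(diagm)), 0)
})

test_that("the confusion matrix routes misses and misclassifications", {
  gts <- boxes_df(0, .5, .5, .2, .2)
  # wrong-class overlapping prediction lands off-diagonal
  wrong <- boxes_df(1, .5, .5, .2, .2, .9)
  cm <- confusion_matrix(wrong, gts, n_classes = 2)
  expect_identical(cm["1", "0"], 1L)
  expect_identical(sum(cm), 1L)
  # no predictions: ground truth mass in the background row
  cm0 <- confusion_matrix(boxes_df(), gts, n_classes = 2)
  expect_identical(cm0["bg", "0"], 1L)
  # below-threshold predictions are dropped
  weak <- boxes_df(0, .5, .5, .2, .2, .1)
  cm1 <- confusion_matrix(weak, gts, n_classes = 2, conf_thresh = 0.25)
  expect_identical(cm1["bg", "0"], 1L)
  expect_identical(sum(cm1), 1L)
})

test_that("per-class counting identities hold on random scenes", {
  for (s in 1:25) {
    gts <- rand_boxes(6, seed = s)
    preds <- rand_boxes(8, seed = s + 500, conf = TRUE)
    for (cls in 0:3) {
      p <- preds[preds$cls == cls, , drop = FALSE]
      g <- gts[gts$cls == cls, , drop = FALSE]
      m <- match_detections(p, g)
      expect_identical(m$n_tp + m$n_fn, nrow(g))
      expect_identical(m$n_tp + m$n_fp, nrow(p))
    }
  }
})
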