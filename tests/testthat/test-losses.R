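test_that("IoU agrees with a rasterized pixel-counting oracle", {
  expect_equal(iou(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(iou(c(1, 1, 1, 1), c(5, 5, 1, 1)), 0)
  # corners (0,0,2,2) vs (1,1,3,3): intersection 1, union 7
  a <- c(1, 1, 2, 2); b <- c(2, 2, 2, 2)
  expect_equal(iou(a, b), 1 / 7, tolerance = 1e-12)
  expect_equal(iou(a, b), iou_raster(c(0, 0, 2, 2), c(1, 1, 3, 3)),
               tolerance = 2e-2)
  expect_equal(iou(a, b), iou(b, a))
  expect_error(iou(c(0, 0, 0, 1), b), "degenerate")
})

test_that("CIoU reduces to the IoU loss for concentric same-aspect boxes", {
  expect_equal(ciou(c(1, 1, 2, 2), c(1, 1, 2, 2)), 0)
  a <- c(3, 3, 1, 2); b <- c(3, 3, 2, 4)
  expect_equal(ciou(a, b), l_iou(a, b), tolerance = 1e-12)
  for (s in 1:20) {
    pr <- withr::with_seed(s, runif(4, c(0, 0, .1, .1), c(4, 4, 2, 2)))
    tg <- withr::with_seed(s + 99, runif(4, c(0, 0, .1, .1), c(4, 4, 2, 2)))
    expect_gte(ciou(pr, tg), l_iou(pr, tg))
  }
})

test_that("the Wise-IoU distance factor matches its worked example", {
  expect_equal(r_wiou(c(2, 2, 1, 1), c(2, 2, 3, 3)), 1)   # coincident centers
  # corner boxes (0,0,1,1) and (2,2,3,3): centers .5/2.5, enclosing 3x3
  expect_equal(r_wiou(c(0.5, 0.5, 1, 1), c(2.5, 2.5, 1, 1)), exp(8 / 18),
               tolerance = 1e-9)
  # monotone in center distance for a fixed enclosing box
  r1 <- r_wiou(c(1.0, 1.0, 1, 1), c(2.5, 2.5, 1, 1))
  r2 <- r_wiou(c(0.8, 0.8, 1, 1), c(2.5, 2.5, 1, 1))
  expect_gt(r2, r1)
})

test_that("WIoUv1 is the distance-scaled IoU loss", {
  expect_equal(wiou_v1(c(1, 1, 2, 2), c(1, 1, 2, 2)), 0)
  expect_equal(wiou_v1(c(0.5, 0.5, 1, 1), c(2.5, 2.5, 1, 1)),
               exp(8 / 18) * 1, tolerance = 1e-9)
  for (s in 1:20) {
    pr <- withr::with_seed(s, runif(4, c(0, 0, .1, .1), c(4, 4, 2, 2)))
    tg <- withr::with_seed(s + 55, runif(4, c(0, 0, .1, .1), c(4, 4, 2, 2)))
    expect_gte(wiou_v1(pr, tg), l_iou(pr, tg))
  }
})

test_that("the outlier degree self-normalizes and tracks the momentum mean", {
  st <- wiou_state(momentum = 0.1)
  expect_equal(outlier_degree(0.4, st), 1)           # lazy init -> beta = 1
  expect_equal(outlier_degree(2 * st$mean, st), 2)   # ratio definition
  st2 <- wiou_state(momentum = 0.2)
  outlier_degree(0.9, st2)
  for (k in 1:60) b <- outlier_degree(0.3, st2)
  expect_equal(st2$mean, 0.3, tolerance = 1e-3)      # fixed point of the update
  expect_equal(b, 1, tolerance = 1e-2)
  # the printed instantaneous form is identically 1
  st3 <- wiou_state()
  expect_equal(outlier_degree(0.7, st3, literal = TRUE), 1)
})

test_that("focusing gain is non-monotonic with the analytic extremum", {
  expect_equal(focusing_gain(0), 0)
  expect_equal(focusing_gain(3, 1.9, 3), 3)          # alpha^0 = 1 at beta = delta
  grid <- seq(0, 10, by = 1e-3)
  r <- focusing_gain(grid, 1.9, 3)
  expect_equal(grid[which.max(r)], 1 / log(1.9), tolerance = 1e-3)
  # rises then falls: extreme outliers get less gain than average anchors
  expect_lt(focusing_gain(5, 1.9, 3), focusing_gain(3, 1.9, 3))
  expect_equal(focusing_gain(5, 1.9, 3), 5 * 1.9^-2, tolerance = 1e-12)
  expect_true(all(diff(r[grid < 1 / log(1.9)]) > 0))
  expect_true(all(diff(r[grid > 1 / log(1.9)]) < 0))
})

test_that("WIoUv3 composes the gain with WIoUv1 and hits its special cases", {
  st <- wiou_state()
  expect_equal(wiou_v3(c(1, 1, 2, 2), c(1, 1, 2, 2), st), 0)
  # manufacture beta = delta: mean set so current/mean = 3
  pr <- c(0.5, 0.5, 1, 1); tg <- c(2.5, 2.5, 1, 1)
  li <- l_iou(pr, tg)
  st2 <- wiou_state()
  st2$mean <- li / 3
  expect_equal(wiou_v3(pr, tg, st2), 3 * wiou_v1(pr, tg), tolerance = 1e-9)
})

test_that("gradients respect detachment of the enclosing box and the gain", {
  pr <- c(1.3, 1.1, 1.4, 0.9); tg <- c(2.0, 1.8, 1.1, 1.5)
  g <- wiou_grad(pr, tg, "wiou1")
  # full finite differences of the unfrozen loss differ in w/h (the
  # enclosing-box diagonal depends on them), but not in x/y direction
  g_full <- num_grad(function(p) wiou_v1(p, tg), pr, eps = 1e-6)
  e <- flexdetect:::enclosing_wh(pr, tg)
  denom <- e["w"]^2 + e["h"]^2
  g_frozen <- num_grad(function(p) {
    unname(exp(((p[1] - tg[1])^2 + (p[2] - tg[2])^2) / denom)) * l_iou(p, tg)
  }, pr, eps = 1e-6)
  expect_equal(as.vector(g), as.vector(g_frozen), tolerance = 1e-4)
  expect_gt(max(abs(g_full - g)), 1e-3)  # detachment visibly changes w/h grads
  # v3: the gain is frozen during differentiation and beta is read once
  st <- wiou_state(); outlier_degree(0.5, st)
  mean_before <- st$mean
  g3 <- wiou_grad(pr, tg, "wiou3", state = st)
  beta <- l_iou(pr, tg) / mean_before
  r <- focusing_gain(beta, st$alpha, st$delta)
  expect_equal(as.vector(g3), as.vector(r * g_frozen), tolerance = 1e-4)
  expect_false(identical(st$mean, mean_before))      # one update per read
})

test_that("dynamically focused regression resists corrupted labels", {
  # scaled-down check of the shared-model simulation (the full 5-seed
  # comparison runs in the acceptance suite)
  a <- box_regression_sim("wiou3", steps = 150L, seed = 3)
  b <- box_regression_sim("ciou", steps = 150L, seed = 3)
  expect_lt(a$median_clean_error, b$median_clean_error)
  expect_equal(length(a$errors), 50L)
  expect_true(any(a$corrupted) && !all(a$corrupted))
})
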