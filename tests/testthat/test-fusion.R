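make_ladder <- function(H, cs, cm, cd, seed = 1) {
  withr::with_seed(seed, list(
    shallow = array(rnorm(4 * H * H * cs), c(2L * H, 2L * H, cs)),
    mid = array(rnorm(H * H * cm), c(H, H, cm)),
    deep = array(rnorm(H * H * cd / 4), c(H %/% 2L, H %/% 2L, cd))))
}

test_that("BiC output matches the same-depth spatial size on valid ladders", {
  for (H in c(8L, 16L, 40L)) {
    p <- bic_init(4, 8, 16, 8, seed = H)
    l <- make_ladder(H, 4, 8, 16, seed = H)
    out <- bic(l$shallow, l$mid, l$deep, p)
    expect_identical(dim(out), c(H, H, 8L))
  }
  p <- bic_init(4, 8, 16, 8)
  l <- make_ladder(8L, 4, 8, 16)
  expect_error(bic(l$mid, l$mid, l$deep, p), "ladder")
  expect_error(bic(l$shallow, l$mid, l$mid, p), "ladder")
})

test_that("all-zero inputs with zero biases give zero BiC output", {
  p <- bic_init(3, 6, 12, 6, seed = 2)
  out <- bic(array(0, c(16, 16, 3)), array(0, c(8, 8, 6)),
             array(0, c(4, 4, 12)), p)
  expect_true(all(out == 0))
})

test_that("zeroing side branches isolates the same-depth path", {
  p <- bic_init(3, 6, 12, 6, seed = 3)
  p0 <- p
  p0$sh_red$w[] <- 0; p0$sh_down$w[] <- 0; p0$deep_up$w[] <- 0
  l <- make_ladder(8L, 3, 6, 12, seed = 4)
  out <- bic(l$shallow, l$mid, l$deep, p0, activation = "identity")
  # oracle: mid 1x1 -> concat with zeros -> final 1x1
  a <- conv2d(l$mid, p$mid_red$w, p$mid_red$b)
  cat3 <- array(0, c(8, 8, 3L * p$hidden))
  cat3[, , seq_len(p$hidden)] <- a
  want <- conv2d(cat3, p$out_red$w, p$out_red$b)
  expect_lt(max(abs(out - want)), 1e-10)
})

test_that("SlimCSPSPPF preserves spatial shape and zero maps to zero", {
  p <- slim_csp_sppf_init(8, 8, seed = 5)
  for (H in c(6L, 16L, 23L)) {
    x <- withr::with_seed(H, array(rnorm(H * H * 8), c(H, H, 8)))
    expect_identical(dim(slim_csp_sppf(x, p)), c(H, H, 8L))
  }
  expect_true(all(slim_csp_sppf(array(0, c(8, 8, 8)), p) == 0))
})

test_that("the pooled path spreads an impulse over the cascaded receptive field", {
  p <- slim_csp_sppf_init(1, 4, hidden = 2L, seed = 6)
  x <- array(0, c(21, 21, 1)); x[11, 11, 1] <- 5
  out <- slim_csp_sppf(x, p, activation = "identity")
  energy <- apply(abs(out), c(1, 2), sum)
  nz <- which(energy > 1e-10, arr.ind = TRUE)
  # 3 cascaded 5x5 pools + two 3x3/1x1 convs: reach at least 13 pixels wide
  expect_gte(diff(range(nz[, 1])) + 1, 13)
  expect_gte(diff(range(nz[, 2])) + 1, 13)
})

test_that("blocks are linear in the input under the identity-activation harness", {
  p <- slim_csp_sppf_init(3, 4, seed = 7)
  x1 <- withr::with_seed(8, array(rnorm(8 * 8 * 3), c(8, 8, 3)))
  # max-pooling is only positively homogeneous, so test scaling by c > 0
  lhs <- slim_csp_sppf(2.5 * x1, p, activation = "identity")
  rhs <- 2.5 * slim_csp_sppf(x1, p, activation = "identity")
  expect_lt(max(abs(lhs - rhs)), 1e-9)
  pb <- bic_init(3, 6, 12, 6, seed = 9)
  l1 <- make_ladder(8L, 3, 6, 12, seed = 10)
  l2 <- make_ladder(8L, 3, 6, 12, seed = 11)
  lhs <- bic(0.5 * l1$shallow + 2 * l2$shallow, 0.5 * l1$mid + 2 * l2$mid,
             0.5 * l1$deep + 2 * l2$deep, pb, activation = "identity")
  rhs <- 0.5 * bic(l1$shallow, l1$mid, l1$deep, pb, "identity") +
    2 * bic(l2$shallow, l2$mid, l2$deep, pb, "identity")
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("parameter counts match their closed forms", {
  cfgs <- list(c(4, 8, 16, 8), c(3, 6, 12, 10), c(8, 8, 8, 4))
  for (cf in cfgs) {
    p <- bic_init(cf[1], cf[2], cf[3], cf[4], seed = 1)
    expect_equal(n_params(p), bic_n_params(cf[1], cf[2], cf[3], cf[4]))
  }
  for (cf in list(c(8, 8), c(16, 8), c(6, 12))) {
    p <- slim_csp_sppf_init(cf[1], cf[2], seed = 1)
    expect_equal(n_params(p), slim_csp_sppf_n_params(cf[1], cf[2]))
  }
})
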