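test_that("bilinear sampling interpolates, pads with zero at the border", {
  m <- matrix(c(0, 1, 2, 3), 2, 2)
  expect_equal(bilinear_sample(m, 2, 1), 1)            # exact node
  expect_equal(bilinear_sample(m, 1.5, 1), 0.5)        # midpoint
  expect_equal(bilinear_sample(m, 1.25, 1.75),
               0 * .75 * .25 + 2 * .75 * .75 + 1 * .25 * .25 + 3 * .25 * .75)
  expect_equal(bilinear_sample(m, -5, -5), 0)          # fully outside
  expect_equal(bilinear_sample(m, 0.5, 1), 0)          # half-in: 0.5 weight on 0
})

test_that("zero offsets reduce deformable conv to standard convolution", {
  for (s in 1:100) {
    dims <- withr::with_seed(s, c(sample(3:6, 2, TRUE), sample(1:3, 2, TRUE)))
    x <- withr::with_seed(s, array(rnorm(prod(dims[c(1, 2, 3)])),
                                   dims[c(1, 2, 3)]))
    w <- withr::with_seed(s + 1, array(rnorm(9 * dims[3] * dims[4]),
                                       c(3, 3, dims[3], dims[4])))
    expect_lt(max(abs(deformable_conv2d(x, w) - conv2d(x, w))), 1e-5)
  }
})

test_that("constant integer offsets equal convolution of the shifted input", {
  for (s in 1:10) {
    x <- withr::with_seed(s, array(rnorm(8 * 9 * 2), c(8, 9, 2)))
    w <- withr::with_seed(s + 50, array(rnorm(9 * 2 * 2), c(3, 3, 2, 2)))
    off <- array(0, c(8, 9, 18))
    off[, , seq(1, 17, 2)] <- 1          # all taps displaced by (dy, dx) = (1, 0)
    got <- deformable_conv2d(x, w, off)
    xs <- array(0, dim(x)); xs[1:7, , ] <- x[2:8, , ]   # input translated by -1
    want <- conv2d(xs, w)
    interior_r <- 2:6; interior_c <- 2:8
    expect_lt(max(abs(got[interior_r, interior_c, ] -
                        want[interior_r, interior_c, ])), 1e-9)
  }
})

test_that("1x1 input with a 3x3 kernel reads only the center tap", {
  x <- array(2, c(1, 1, 1))
  w <- array(1:9, c(3, 3, 1, 1))
  expect_equal(as.vector(deformable_conv2d(x, w)), 2 * 5)
})

test_that("deformable conv is linear in the input for frozen offsets", {
  x1 <- withr::with_seed(1, array(rnorm(5 * 5 * 2), c(5, 5, 2)))
  x2 <- withr::with_seed(2, array(rnorm(5 * 5 * 2), c(5, 5, 2)))
  w <- withr::with_seed(3, array(rnorm(9 * 2 * 2), c(3, 3, 2, 2)))
  off <- withr::with_seed(4, array(runif(5 * 5 * 18, -1, 1), c(5, 5, 18)))
  lhs <- deformable_conv2d(0.3 * x1 + 1.7 * x2, w, off)
  rhs <- 0.3 * deformable_conv2d(x1, w, off) +
    1.7 * deformable_conv2d(x2, w, off)
  expect_lt(max(abs(lhs - rhs)), 1e-6)
})

test_that("analytic gradients match finite differences", {
  x <- withr::with_seed(11, array(rnorm(4 * 4 * 2), c(4, 4, 2)))
  w <- withr::with_seed(12, array(rnorm(9 * 2 * 2), c(3, 3, 2, 2)))
  # keep sampling points away from integer grid lines (kinks of bilinear)
  off <- withr::with_seed(13,
    array(runif(4 * 4 * 18, -0.65, 0.65) + 0.17, c(4, 4, 18)))
  b <- withr::with_seed(14, rnorm(2))
  gy <- withr::with_seed(15, array(rnorm(4 * 4 * 2), c(4, 4, 2)))
  gr <- deformable_conv2d_grad(x, w, off, gy, b)
  f_x <- function(a) sum(deformable_conv2d(array(a, dim(x)), w, off, b) * gy)
  f_w <- function(a) sum(deformable_conv2d(x, array(a, dim(w)), off, b) * gy)
  f_o <- function(a) sum(deformable_conv2d(x, w, array(a, dim(off)), b) * gy)
  expect_lt(max(abs(num_grad(f_x, x) - gr$gx)), 1e-4)
  expect_lt(max(abs(num_grad(f_w, w) - gr$gw)), 1e-4)
  expect_lt(max(abs(num_grad(f_o, off) - gr$goffsets)), 1e-4)
  expect_equal(gr$gbias, apply(gy, 3, sum), tolerance = 1e-9)
})

test_that("DCN block degenerates to a residual conv block at zero offsets", {
  p <- dcn_block_init(2, 3, seed = 5)
  x <- withr::with_seed(6, array(rnorm(6 * 6 * 2), c(6, 6, 2)))
  out <- dcn_block(x, p)
  # offset predictors are zero-initialized: forward must equal the plain
  # residual composition with standard convolutions
  h <- flexdetect:::silu(batchnorm(conv2d(x, p$cbl$w, p$cbl$b), p$cbl$bn))
  d1 <- flexdetect:::silu(batchnorm(conv2d(h, p$dcn1$w, p$dcn1$b),
                                    p$dcn1$bn))
  d2 <- conv2d(d1, p$dcn2$w, p$dcn2$b)
  expect_lt(max(abs(out - flexdetect:::silu(d2 + h))), 1e-9)
  # zero input, zero biases -> zero output
  z <- dcn_block(array(0, c(5, 5, 2)), p)
  expect_true(all(z == 0))
})
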