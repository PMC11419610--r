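test_that("histogram clipping redistributes excess and conserves mass", {
  # worked toy: excess 6 over T=4 spread as L=1.5 per bin
  expect_equal(clip_redistribute(c(10, 0, 0, 0), 4), c(5.5, 1.5, 1.5, 1.5))
  # no clipping when all bins below threshold
  h <- c(1, 2, 3, 2)
  expect_equal(clip_redistribute(h, 5), h)
  # uniform histogram at its own max is untouched
  expect_equal(clip_redistribute(rep(4, 8), 4), rep(4, 8))
  expect_error(clip_redistribute(h, 0), "threshold")
  # mass conservation on random histograms
  for (s in 1:50) {
    counts <- withr::with_seed(s, rpois(256, lambda = runif(1, 1, 40)))
    thr <- withr::with_seed(s + 1000, runif(1, 0.5, 30))
    out <- clip_redistribute(counts, thr)
    expect_lt(abs(sum(out) - sum(counts)), 1e-9)
    expect_true(all(out >= 0))
  }
})

test_that("slope-derived clip threshold matches hand computations", {
  expect_equal(clip_threshold_from_slope(2, 16), 512 / 255)
  expect_equal(clip_threshold_from_slope(4, 8), 256 / 255)
  expect_equal(clip_threshold_from_slope(255 / 16^2, 16), 1)
})

test_that("tile mapping applies round-half-up and is monotone", {
  # 64-pixel window with CDF(i) = 32 at some level -> 255*32/64 = 127.5 -> 128
  h <- rep(0, 256); h[1] <- 32; h[101] <- 32
  lut <- tile_mapping(h)
  expect_identical(lut[1], 128L)
  expect_identical(lut[256], 255L)
  # all pixels at level 0: CDF saturates immediately
  h0 <- c(64, rep(0, 255))
  expect_identical(tile_mapping(h0)[1], 255L)
  # uniform histogram: mapping is identity within one gray level
  lu <- tile_mapping(rep(1, 256))
  expect_true(all(abs(lu - (0:255)) <= 1))
  # monotone for random histograms
  for (s in 1:20) {
    hh <- withr::with_seed(s, rpois(256, 5))
    if (sum(hh) == 0) hh[1] <- 1
    expect_true(all(diff(tile_mapping(hh)) >= 0))
  }
  expect_error(tile_mapping(rep(0, 256)), "empty")
})

test_that("single-tile unclipped CLAHE equals global histogram equalization", {
  for (s in 1:20) {
    img <- rand_image(48, 40, seed = s, lo = 60L, hi = 200L)
    a <- clahe(img, clahe_params(1, 1, Inf))
    b <- global_he(img)
    expect_lte(max(abs(a - b)), 1)
  }
})

test_that("CLAHE raises contrast of low-contrast images and is deterministic", {
  for (s in 1:5) {
    img <- rand_image(64, 64, seed = 200 + s, lo = 100L, hi = 140L)
    out <- clahe(img)
    expect_gt(rms_contrast(out), rms_contrast(img))
    expect_identical(out, clahe(img))
    expect_true(min(out) >= 0 && max(out) <= 255)
  }
  # constant image maps to a constant image
  out <- clahe(flat_image(32, 32, 77L))
  expect_identical(length(unique(as.vector(luma_u8(out)))), 1L)
  expect_error(clahe(flat_image(4, 4), clahe_params(8, 8)), "tile grid")
})

test_that("global HE maps a two-level image to the CDF-implied levels", {
  img <- flat_image(10, 10, 50L)
  img[, 6:10, ] <- 200L
  y <- luma_u8(global_he(img))
  lv <- sort(unique(as.vector(y)))
  expect_equal(lv[1], 127, tolerance = 1)
  expect_equal(lv[2], 255)
})

test_that("boundary channel responds to structure and gates fine texture", {
  expect_true(all(boundary_channel(flat_image(32, 32)) == 0))
  # sharp vertical step: response concentrated at the step, zero far away
  img <- flat_image(32, 32, 30L); img[, 17:32, ] <- 220L
  b <- boundary_channel(img)
  expect_equal(max(b[, 16:17]), 1)
  expect_true(all(b[, c(1:8, 25:32)] == 0))
  # high-frequency checkerboard vanishes after 4x downsampling -> masked out
  ck <- flat_image(32, 32, 0L)
  chk <- as.integer(255 * ((row(matrix(0, 32, 32)) +
                              col(matrix(0, 32, 32))) %% 2))
  for (ch in 1:3) ck[, , ch] <- chk
  expect_lt(max(boundary_channel(ck)), 1e-9)
})

test_that("fused enhancement obeys its limits and sharpens boundaries", {
  img <- rand_image(64, 64, seed = 31, lo = 90L, hi = 150L)
  expect_identical(enhance(img, bem_par = bem_params(gamma = 0)),
                   clahe(img))
  cflat <- flat_image(48, 48, 120L)
  out <- enhance(cflat)
  expect_identical(length(unique(as.vector(luma_u8(out)))), 1L)
  # degraded synthetic scenes: contrast and boundary-band gradient rise
  spec <- scene_spec(size = 96)
  for (s in 1:6) {
    sc <- generate_scene(spec, seed = 400 + s)
    deg <- degrade_underwater(sc$image, spec$degrade, seed = 400 + s)
    en <- enhance(deg)
    expect_gt(rms_contrast(en), rms_contrast(deg))
    expect_gt(boundary_band_energy(en, sc$boxes),
              boundary_band_energy(deg, sc$boxes))
  }
})

test_that("per-tile mappings preserve gray-level rank order", {
  img <- rand_image(64, 64, seed = 77)
  # per-channel mode applies the tile mappings exactly (no luma rescale
  # rounding); in the corner region inside the outer tile centers the blend
  # weights are constant, so a single monotone mapping applies
  out <- clahe(img, clahe_params(2, 2, 4, "per_channel"))
  corner <- function(m) m[1:16, 1:16]
  for (ch in 1:3) {
    o <- order(corner(img[, , ch]))
    expect_true(all(diff(corner(out[, , ch])[o]) >= 0))
  }
})
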