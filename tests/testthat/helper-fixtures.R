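# Fixture builders and independent oracles used across the suite.

# deterministic random ImageU8
rand_image <- function(H, W, seed = 1, lo = 0L, hi = 255L) {
  withr::with_seed(seed,
    array(as.integer(sample(lo:hi, H * W * 3, replace = TRUE)), c(H, W, 3L)))
}

flat_image <- function(H, W, value = 128L) {
  array(as.integer(value), c(H, W, 3L))
}

# O(n^2) brute-force average precision: for every sweep point take the best
# precision at equal-or-higher recall, integrate rectangles explicitly
ap_bruteforce <- function(tp, n_gt) {
  if (n_gt == 0) return(NA_real_)
  if (length(tp) == 0) return(0)
  ctp <- cumsum(tp); cfp <- cumsum(!tp)
  rec <- ctp / n_gt; prec <- ctp / (ctp + cfp)
  ap <- 0
  prev_r <- 0
  for (i in seq_along(rec)) {
    p_env <- max(prec[i:length(prec)])
    ap <- ap + (rec[i] - prev_r) * p_env
    prev_r <- rec[i]
  }
  ap
}

# pixel-counting IoU oracle on a fine raster (corner-form boxes)
iou_raster <- function(a_corners, b_corners, res = 400L) {
  lo <- pmin(a_corners[c(1, 2)], b_corners[c(1, 2)])
  hi <- pmax(a_corners[c(3, 4)], b_corners[c(3, 4)])
  xs <- seq(lo[1], hi[1], length.out = res)
  ys <- seq(lo[2], hi[2], length.out = res)
  inside <- function(co) outer(ys >= co[2] & ys <= co[4],
                               xs >= co[1] & xs <= co[3], "&")
  A <- inside(a_corners); B <- inside(b_corners)
  sum(A & B) / sum(A | B)
}

# random normalized boxes data frame
rand_boxes <- function(n, n_classes = 4, seed = 1, conf = FALSE) {
  withr::with_seed(seed, {
    w <- runif(n, 0.05, 0.3); h <- runif(n, 0.05, 0.3)
    boxes_df(sample(0:(n_classes - 1), n, replace = TRUE),
             runif(n, 0.2, 0.8), runif(n, 0.2, 0.8), w, h,
             if (conf) runif(n) else NA_real_)
  })
}

# finite-difference gradient of f at x (numeric vector/array)
num_grad <- function(f, x, eps = 1e-6) {
  g <- array(0, dim(as.array(x)))
  for (i in seq_along(x)) {
    hi <- x; hi[i] <- hi[i] + eps
    lo <- x; lo[i] <- lo[i] - eps
    g[i] <- (f(hi) - f(lo)) / (2 * eps)
  }
  g
}
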