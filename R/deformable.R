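#' Deformable 2-D convolution
#'
#' A deformable convolution displaces every kernel tap of a regular
#' convolution by a learned, per-output-position fractional offset and reads
#' the input by bilinear interpolation:
#' `y(p0) = sum_n w(p_n) * x(p0 + p_n + delta[p0, n])`.
#' With all offsets zero it reduces exactly to the regular convolution; this
#' file provides the forward pass, an analytic backward pass (inputs,
#' weights, offsets), and the residual DCN block that stacks two
#' offset-predicting deformable layers behind a CBL stem with a skip
#' connection.
#'
#' @name deformable
NULL

#' Regular sampling grid of a k x k kernel
#'
#' Integer tap displacements `(dy, dx)` of the regular convolution grid,
#' centered at 0 for odd `k`, enumerated kernel-row fastest to match the
#' weight-array flattening order.
#'
#' @param k kernel size.
#' @return `N x 2` integer matrix (`N = k^2`), columns `dy`, `dx`.
#' @export
sampling_grid <- function(k) {
  r <- (k - 1) / 2
  dy <- rep(seq_len(k) - 1 - r, times = k)
  dx <- rep(seq_len(k) - 1 - r, each = k)
  cbind(dy = dy, dx = dx)
}

bilin <- function(mat, py, px, deriv = FALSE) {
  H <- nrow(mat); W <- ncol(mat)
  y0 <- floor(py); x0 <- floor(px)
  fy <- py - y0; fx <- px - x0
  gv <- function(yy, xx) {
    ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
    v <- numeric(length(yy))
    if (any(ok)) v[ok] <- mat[cbind(yy[ok], xx[ok])]
    v
  }
  v00 <- gv(y0, x0); v01 <- gv(y0, x0 + 1)
  v10 <- gv(y0 + 1, x0); v11 <- gv(y0 + 1, x0 + 1)
  val <- v00 * (1 - fy) * (1 - fx) + v01 * (1 - fy) * fx +
    v10 * fy * (1 - fx) + v11 * fy * fx
  if (!deriv) return(val)
  list(val = val,
       dpy = (v10 - v00) * (1 - fx) + (v11 - v01) * fx,
       dpx = (v01 - v00) * (1 - fy) + (v11 - v10) * fy,
       y0 = y0, x0 = x0, fy = fy, fx = fx)
}

#' Bilinear sampling of a single-channel map
#'
#' Interpolates the four integer neighbors of each fractional point
#' `(py, px)` (1-based array coordinates); points outside the map read as
#' zero (zero padding), so an integer in-range point returns the exact array
#' value.
#'
#' @param mat numeric matrix.
#' @param py,px fractional row/column coordinates (vectors of equal length).
#' @return numeric vector of sampled values.
#' @export
bilinear_sample <- function(mat, py, px) {
  stopifnot(length(py) == length(px))
  bilin(mat, py, px)
}

#' Deformable convolution forward pass
#'
#' Stride 1; out-of-grid samples read zero, so the output has the input's
#' spatial size (the zero-padding `k %/% 2` convention). With `offsets`
#' identically zero the result equals [conv2d()] with the same weights.
#'
#' @param x `H x W x C_in` array.
#' @param w `k x k x C_in x C_out` weights.
#' @param offsets `H x W x 2N` array of per-tap displacements, interleaved
#'   `(dy_1, dx_1, ..., dy_N, dx_N)` with `N = k^2`; `NULL` means zero.
#' @param bias length-`C_out` vector or `NULL`.
#' @return `H x W x C_out` array.
#' @export
deformable_conv2d <- function(x, w, offsets = NULL, bias = NULL) {
  d <- dim(x); H <- d[1]; W <- d[2]; Cin <- d[3]
  kd <- dim(w); k <- kd[1]
  if (kd[2] != k) stop("kernel must be square")
  if (kd[3] != Cin) stop("input channel mismatch")
  Cout <- kd[4]; N <- k * k
  if (is.null(offsets)) offsets <- array(0, c(H, W, 2L * N))
  od <- dim(offsets)
  if (od[1] != H || od[2] != W || od[3] != 2L * N)
    stop("offset field shape mismatch: expected ", H, " x ", W, " x ", 2 * N)
  grid <- sampling_grid(k)
  base_y <- matrix(seq_len(H), H, W)
  base_x <- matrix(seq_len(W), H, W, byrow = TRUE)
  out <- array(0, c(H, W, Cout))
  wm <- matrix(w, nrow = N * Cin, ncol = Cout)   # rows: (tap, cin), tap fastest
  for (n in seq_len(N)) {
    py <- base_y + grid[n, 1] + offsets[, , 2L * n - 1L]
    px <- base_x + grid[n, 2] + offsets[, , 2L * n]
    for (cin in seq_len(Cin)) {
      ch <- matrix(x[, , cin], H, W)
      s <- matrix(bilin(ch, as.vector(py), as.vector(px)), H, W)
      wrow <- wm[(cin - 1L) * N + n, ]
      for (co in seq_len(Cout)) out[, , co] <- out[, , co] + wrow[co] * s
    }
  }
  if (!is.null(bias)) for (co in seq_len(Cout))
    out[, , co] <- out[, , co] + bias[co]
  out
}

#' Analytic gradients of the deformable convolution
#'
#' Backpropagates an upstream gradient `gy` through
#' [deformable_conv2d()], returning gradients with respect to the input,
#' the weights, the offset field and the bias. The bilinear read is
#' piecewise linear, so gradients are exact away from integer sampling
#' coordinates.
#'
#' @inheritParams deformable_conv2d
#' @param gy `H x W x C_out` upstream gradient.
#' @return list with `gx`, `gw`, `goffsets`, `gbias`.
#' @export
deformable_conv2d_grad <- function(x, w, offsets, gy, bias = NULL) {
  d <- dim(x); H <- d[1]; W <- d[2]; Cin <- d[3]
  k <- dim(w)[1]; Cout <- dim(w)[4]; N <- k * k
  if (is.null(offsets)) offsets <- array(0, c(H, W, 2L * N))
  grid <- sampling_grid(k)
  base_y <- matrix(seq_len(H), H, W)
  base_x <- matrix(seq_len(W), H, W, byrow = TRUE)
  gx <- array(0, c(H, W, Cin))
  gw <- array(0, dim(w))
  goff <- array(0, dim(offsets))
  gyl <- lapply(seq_len(Cout), function(co) matrix(gy[, , co], H, W))
  for (n in seq_len(N)) {
    ki <- (n - 1L) %% k + 1L; kj <- (n - 1L) %/% k + 1L
    py <- as.vector(base_y + grid[n, 1] + offsets[, , 2L * n - 1L])
    px <- as.vector(base_x + grid[n, 2] + offsets[, , 2L * n])
    for (cin in seq_len(Cin)) {
      sb <- bilin(matrix(x[, , cin], H, W), py, px, deriv = TRUE)
      # a = sum_cout w[n, cin, cout] * gy[cout], the per-position weight field
      a <- 0
      for (co in seq_len(Cout)) {
        gw[ki, kj, cin, co] <- gw[ki, kj, cin, co] + sum(sb$val * gyl[[co]])
        a <- a + w[ki, kj, cin, co] * gyl[[co]]
      }
      a <- as.vector(a)
      goff[, , 2L * n - 1L] <- goff[, , 2L * n - 1L] + matrix(a * sb$dpy, H, W)
      goff[, , 2L * n] <- goff[, , 2L * n] + matrix(a * sb$dpx, H, W)
      # scatter the bilinear corner weights back into the input
      gch <- matrix(0, H, W)
      corners <- list(list(sb$y0, sb$x0, (1 - sb$fy) * (1 - sb$fx)),
                      list(sb$y0, sb$x0 + 1, (1 - sb$fy) * sb$fx),
                      list(sb$y0 + 1, sb$x0, sb$fy * (1 - sb$fx)),
                      list(sb$y0 + 1, sb$x0 + 1, sb$fy * sb$fx))
      for (cr in corners) {
        yy <- cr[[1]]; xx <- cr[[2]]
        ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
        if (!any(ok)) next
        idx <- yy[ok] + (xx[ok] - 1) * H
        contrib <- a[ok] * cr[[3]][ok]
        s <- rowsum(contrib, group = idx)
        gch[as.integer(rownames(s))] <- gch[as.integer(rownames(s))] + s[, 1]
      }
      gx[, , cin] <- gx[, , cin] + gch
    }
  }
  gbias <- vapply(gyl, sum, numeric(1))
  list(gx = gx, gw = gw, goffsets = goff, gbias = gbias)
}

#' Residual DCN block parameters
#'
#' CBL stem (3 x 3 conv, channel-wise norm, SiLU) followed by two
#' deformable convolutions whose offsets are predicted by internal standard
#' convolutions on their inputs, with a skip connection from the stem output
#' to the block output. Offset predictors are zero-initialized, so a fresh
#' block behaves as a plain residual convolution block.
#'
#' @param in_ch,out_ch channel counts.
#' @param kernel deformable kernel size (default 3).
#' @param seed RNG seed for weight initialization.
#' @return parameter list for [dcn_block()].
#' @export
dcn_block_init <- function(in_ch, out_ch, kernel = 3L, seed = 0L) {
  N <- kernel^2
  with_seed(seed, list(
    kernel = kernel,
    cbl = list(w = init_w(3L, 3L, in_ch, out_ch), b = rep(0, out_ch),
               bn = bn_identity(out_ch)),
    off1 = list(w = array(0, c(3L, 3L, out_ch, 2L * N)), b = rep(0, 2L * N)),
    dcn1 = list(w = init_w(kernel, kernel, out_ch, out_ch), b = rep(0, out_ch),
                bn = bn_identity(out_ch)),
    off2 = list(w = array(0, c(3L, 3L, out_ch, 2L * N)), b = rep(0, 2L * N)),
    dcn2 = list(w = init_w(kernel, kernel, out_ch, out_ch), b = rep(0, out_ch))
  ))
}

#' Residual deformable-convolution block
#'
#' @param x `H x W x C_in` array.
#' @param params from [dcn_block_init()].
#' @param activation `"silu"` (default) or `"identity"` (linearity harness).
#' @return `H x W x out_ch` array.
#' @export
dcn_block <- function(x, params, activation = "silu") {
  h <- apply_act(batchnorm(conv2d(x, params$cbl$w, params$cbl$b),
                           params$cbl$bn), activation)
  off1 <- conv2d(h, params$off1$w, params$off1$b)
  d1 <- apply_act(batchnorm(
    deformable_conv2d(h, params$dcn1$w, off1, params$dcn1$b),
    params$dcn1$bn), activation)
  off2 <- conv2d(d1, params$off2$w, params$off2$b)
  d2 <- deformable_conv2d(d1, params$dcn2$w, off2, params$dcn2$b)
  if (!identical(dim(d2), dim(h)))
    stop("channel mismatch between skip and main path")
  apply_act(d2 + h, activation)
}
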