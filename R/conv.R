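#' Feature-map tensor operations
#'
#' Feature maps are plain numeric `H x W x C` arrays. Convolution weights
#' are `kh x kw x C_in x C_out` arrays; flattening order follows R's native
#' column-major order (kernel row fastest, then kernel column, then input
#' channel).
#'
#' @name feature_ops
NULL

#' 2-D convolution (stride, zero padding)
#'
#' @param x `H x W x C_in` array.
#' @param w `kh x kw x C_in x C_out` weights.
#' @param bias length-`C_out` vector or `NULL`.
#' @param stride positive integer stride.
#' @param pad zero-padding width (default `floor(kh / 2)`, "same" for odd
#'   kernels at stride 1).
#' @return `H_out x W_out x C_out` array.
#' @export
conv2d <- function(x, w, bias = NULL, stride = 1L,
                   pad = as.integer(dim(w)[1] %/% 2)) {
  d <- dim(x); H <- d[1]; W <- d[2]; Cin <- d[3]
  kd <- dim(w); kh <- kd[1]; kw <- kd[2]
  if (kd[3] != Cin) stop("input channel mismatch: x has ", Cin,
                         ", weights expect ", kd[3])
  Cout <- kd[4]
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  xp <- array(0, c(Hp, Wp, Cin))
  xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  Ho <- (Hp - kh) %/% stride + 1L
  Wo <- (Wp - kw) %/% stride + 1L
  ri <- seq(1L, by = stride, length.out = Ho)
  ci <- seq(1L, by = stride, length.out = Wo)
  cols <- matrix(0, Ho * Wo, kh * kw * Cin)
  k <- 0L
  for (cin in seq_len(Cin)) for (kj in seq_len(kw)) for (ki in seq_len(kh)) {
    k <- k + 1L
    cols[, k] <- xp[ri + (ki - 1L), ci + (kj - 1L), cin]
  }
  wm <- matrix(w, nrow = kh * kw * Cin, ncol = Cout)
  out <- cols %*% wm
  if (!is.null(bias)) out <- sweep(out, 2L, bias, "+")
  array(out, c(Ho, Wo, Cout))
}

#' Transposed 2 x 2 stride-2 convolution (learned 2x upsampling)
#'
#' @param x `H x W x C_in` array.
#' @param w `2 x 2 x C_in x C_out` weights.
#' @param bias length-`C_out` vector or `NULL`.
#' @return `2H x 2W x C_out` array.
#' @export
tconv2x2 <- function(x, w, bias = NULL) {
  d <- dim(x); H <- d[1]; W <- d[2]; Cin <- d[3]
  Cout <- dim(w)[4]
  out <- array(0, c(2L * H, 2L * W, Cout))
  for (co in seq_len(Cout)) {
    acc <- matrix(if (is.null(bias)) 0 else bias[co], 2L * H, 2L * W)
    for (a in 1:2) for (b in 1:2) {
      blk <- matrix(0, H, W)
      for (ci in seq_len(Cin)) blk <- blk + x[, , ci] * w[a, b, ci, co]
      acc[seq(a, by = 2, length.out = H), seq(b, by = 2, length.out = W)] <-
        acc[seq(a, by = 2, length.out = H), seq(b, by = 2, length.out = W)] + blk
    }
    out[, , co] <- acc
  }
  out
}

#' Max pooling (stride 1, same padding)
#'
#' @param x `H x W x C` array.
#' @param k odd pool size (default 5).
#' @return array of the same shape.
#' @export
maxpool_same <- function(x, k = 5L) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  pad <- k %/% 2L
  out <- array(-Inf, d)
  xp <- array(-Inf, c(H + 2L * pad, W + 2L * pad, C))
  xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  for (a in seq_len(k)) for (b in seq_len(k))
    out <- pmax(out, xp[(a - 1L) + seq_len(H), (b - 1L) + seq_len(W), ,
                        drop = FALSE])
  out
}

#' Channel-wise affine normalization (inference-mode batch norm)
#'
#' Applies `gamma * (x - mean) / sqrt(var + eps) + beta` per channel with
#' stored statistics; identity at initialization (`gamma = 1`, `beta = 0`,
#' `mean = 0`, `var = 1`).
#'
#' @param x `H x W x C` array.
#' @param bn list with `gamma`, `beta`, `mean`, `var` vectors of length `C`.
#' @param eps numerical floor.
#' @return normalized array.
#' @export
batchnorm <- function(x, bn, eps = 1e-5) {
  C <- dim(x)[3]
  out <- x
  for (ch in seq_len(C))
    out[, , ch] <- bn$gamma[ch] * (x[, , ch] - bn$mean[ch]) /
      sqrt(bn$var[ch] + eps) + bn$beta[ch]
  out
}

bn_identity <- function(C) list(gamma = rep(1, C), beta = rep(0, C),
                                mean = rep(0, C), var = rep(1, C))

apply_act <- function(x, activation) {
  switch(activation, silu = silu(x), identity = x,
         stop("unknown activation: ", activation))
}

# Kaiming-style init used by all block constructors
init_w <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

#' Total parameter count of a block parameter list
#'
#' Recursively sums the lengths of all double-typed leaves of a nested
#' parameter list (weights, biases and normalization statistics are stored
#' as doubles; integer configuration fields such as kernel or pool sizes
#' are not parameters). SimAM contributes zero because it has no parameter
#' list at all.
#'
#' @param params nested list of numeric arrays/vectors.
#' @return parameter count.
#' @export
n_params <- function(params) {
  if (is.double(params)) return(length(params))
  if (is.list(params)) return(sum(vapply(params, n_params, numeric(1))))
  0
}
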