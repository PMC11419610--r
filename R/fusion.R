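#' Feature-fusion blocks of the bidirectional neck
#'
#' The Bi-directional Concatenation (BiC) block fuses three adjacent
#' pyramid depths: the same-depth map through a 1 x 1 reduction, the
#' shallower (2x larger) map through 1 x 1 reduction plus stride-2 3 x 3
#' downsampling, and the deeper (2x smaller) map through a 2 x 2 transposed
#' convolution; the three are concatenated and reduced again by 1 x 1. The
#' SlimCSPSPPF block splits the deepest map into a pooled path (1 x 1 then
#' 3 x 3 compound convolution, cascaded 5 x 5 max-pool pyramid, 1 x 1
#' reduction) and a 1 x 1 skip path, then concatenates and reduces.
#'
#' @name fusion
NULL

#' BiC block parameters
#'
#' Internal branch widths default to half the output channels.
#'
#' @param ch_shallow,ch_mid,ch_deep input channel counts of the three
#'   pyramid levels.
#' @param out_ch output channel count.
#' @param hidden per-branch reduced width (default `out_ch %/% 2`).
#' @param seed RNG seed for initialization.
#' @return parameter list for [bic()].
#' @export
bic_init <- function(ch_shallow, ch_mid, ch_deep, out_ch,
                     hidden = max(1L, out_ch %/% 2L), seed = 0L) {
  hidden <- as.integer(hidden)
  with_seed(seed, list(
    hidden = hidden,
    mid_red = list(w = init_w(1L, 1L, ch_mid, hidden), b = rep(0, hidden)),
    sh_red = list(w = init_w(1L, 1L, ch_shallow, hidden), b = rep(0, hidden)),
    sh_down = list(w = init_w(3L, 3L, hidden, hidden), b = rep(0, hidden)),
    deep_up = list(w = init_w(2L, 2L, ch_deep, hidden), b = rep(0, hidden)),
    out_red = list(w = init_w(1L, 1L, 3L * hidden, out_ch),
                   b = rep(0, out_ch))
  ))
}

#' Bi-directional concatenation block
#'
#' @param shallow `2H x 2W x C_s` array (shallower level).
#' @param mid `H x W x C_m` array (same depth); sets the output size.
#' @param deep `H/2 x W/2 x C_d` array (deeper level).
#' @param params from [bic_init()].
#' @param activation `"silu"` or `"identity"`.
#' @return `H x W x out_ch` array.
#' @export
bic <- function(shallow, mid, deep, params, activation = "silu") {
  H <- dim(mid)[1]; W <- dim(mid)[2]
  if (!identical(dim(shallow)[1:2], c(2L * H, 2L * W)) &&
      !identical(as.integer(dim(shallow)[1:2]), as.integer(c(2 * H, 2 * W))))
    stop("inconsistent ladder: shallow level must be 2x the mid level")
  if (!identical(as.integer(dim(deep)[1:2]), as.integer(c(H / 2, W / 2))))
    stop("inconsistent ladder: deep level must be half the mid level")
  a <- apply_act(conv2d(mid, params$mid_red$w, params$mid_red$b), activation)
  s <- apply_act(conv2d(shallow, params$sh_red$w, params$sh_red$b), activation)
  s <- apply_act(conv2d(s, params$sh_down$w, params$sh_down$b, stride = 2L,
                        pad = 1L), activation)
  d <- apply_act(tconv2x2(deep, params$deep_up$w, params$deep_up$b),
                 activation)
  cat3 <- array(c(a, s, d), c(H, W, 3L * params$hidden))
  apply_act(conv2d(cat3, params$out_red$w, params$out_red$b), activation)
}

#' SlimCSPSPPF block parameters
#'
#' @param in_ch,out_ch channel counts.
#' @param hidden internal width (default `out_ch %/% 2`).
#' @param pool max-pool size of the cascaded pyramid (default 5).
#' @param seed RNG seed.
#' @return parameter list for [slim_csp_sppf()].
#' @export
slim_csp_sppf_init <- function(in_ch, out_ch,
                               hidden = max(1L, out_ch %/% 2L),
                               pool = 5L, seed = 0L) {
  hidden <- as.integer(hidden)
  with_seed(seed, list(
    hidden = hidden, pool = as.integer(pool),
    a1 = list(w = init_w(1L, 1L, in_ch, hidden), b = rep(0, hidden)),
    a2 = list(w = init_w(3L, 3L, hidden, hidden), b = rep(0, hidden)),
    a3 = list(w = init_w(1L, 1L, 4L * hidden, hidden), b = rep(0, hidden)),
    skip = list(w = init_w(1L, 1L, in_ch, hidden), b = rep(0, hidden)),
    out_red = list(w = init_w(1L, 1L, 2L * hidden, out_ch),
                   b = rep(0, out_ch))
  ))
}

#' SlimCSPSPPF block
#'
#' Pooled path: compound 1 x 1 then 3 x 3 convolution, three cascaded
#' same-size max-pools concatenated with their input (receptive field
#' `3 (pool - 1) + 1`, i.e. 13 for pool 5), 1 x 1 reduction. Skip path:
#' 1 x 1 convolution. Concatenate, reduce; spatial size is preserved.
#'
#' @param x `H x W x C_in` array.
#' @param params from [slim_csp_sppf_init()].
#' @param activation `"silu"` or `"identity"`.
#' @return `H x W x out_ch` array.
#' @export
slim_csp_sppf <- function(x, params, activation = "silu") {
  h <- apply_act(conv2d(x, params$a1$w, params$a1$b), activation)
  h <- apply_act(conv2d(h, params$a2$w, params$a2$b), activation)
  p1 <- maxpool_same(h, params$pool)
  p2 <- maxpool_same(p1, params$pool)
  p3 <- maxpool_same(p2, params$pool)
  cat4 <- array(c(h, p1, p2, p3), c(dim(h)[1], dim(h)[2], 4L * params$hidden))
  a <- apply_act(conv2d(cat4, params$a3$w, params$a3$b), activation)
  s <- apply_act(conv2d(x, params$skip$w, params$skip$b), activation)
  cat2 <- array(c(a, s), c(dim(a)[1], dim(a)[2], 2L * params$hidden))
  apply_act(conv2d(cat2, params$out_red$w, params$out_red$b), activation)
}

#' Closed-form parameter counts of the fusion blocks
#'
#' @param ch_shallow,ch_mid,ch_deep,in_ch,out_ch,hidden,pool as in the
#'   corresponding constructors.
#' @return integer parameter count (weights + biases).
#' @export
bic_n_params <- function(ch_shallow, ch_mid, ch_deep, out_ch,
                         hidden = max(1L, out_ch %/% 2L)) {
  (ch_mid * hidden + hidden) + (ch_shallow * hidden + hidden) +
    (9L * hidden * hidden + hidden) + (4L * ch_deep * hidden + hidden) +
    (3L * hidden * out_ch + out_ch)
}

#' @rdname bic_n_params
#' @export
slim_csp_sppf_n_params <- function(in_ch, out_ch,
                                   hidden = max(1L, out_ch %/% 2L)) {
  (in_ch * hidden + hidden) + (9L * hidden * hidden + hidden) +
    (4L * hidden * hidden + hidden) + (in_ch * hidden + hidden) +
    (2L * hidden * out_ch + out_ch)
}
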