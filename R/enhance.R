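#' Contrast-limited adaptive histogram equalization for underwater images
#'
#' The enhancer partitions the image into tiles (e.g. 8 x 8), clips each
#' tile's histogram at a height derived from a maximal mapping slope
#' `S_max`, redistributes the clipped mass uniformly over all bins, builds a
#' per-tile gray-level mapping from the clipped cumulative distribution, and
#' bilinearly blends the four surrounding tile mappings at every pixel. A
#' boundary-detection channel (an edge map gated by coarse-scale structure)
#' is fused additively to sharpen foreground/background boundaries, which
#' camouflaged soft-bodied organisms otherwise blur into.
#'
#' @name enhancement
NULL

#' CLAHE parameters
#'
#' @param tiles_x,tiles_y tile grid (default 8 x 8).
#' @param s_max maximal slope of the local gray-level mapping; the clip
#'   threshold of a tile with `n` pixels is `s_max * n / 255`. `Inf`
#'   disables clipping.
#' @param channel_mode `"luminance"` (equalize luma, rescale RGB
#'   proportionally, avoiding hue shifts) or `"per_channel"`.
#' @return parameter list.
#' @export
clahe_params <- function(tiles_x = 8L, tiles_y = 8L, s_max = 4.0,
                         channel_mode = c("luminance", "per_channel")) {
  stopifnot(tiles_x >= 1L, tiles_y >= 1L, s_max > 0)
  list(tiles_x = as.integer(tiles_x), tiles_y = as.integer(tiles_y),
       s_max = s_max, channel_mode = match.arg(channel_mode))
}

#' Boundary-enhancement parameters
#'
#' @param fine_scale_radius radius (pixels) of the fine gradient operator
#'   (1 = 3x3 Sobel).
#' @param coarse_downsample integer downsampling factor (>= 2) for the
#'   coarse structural mask.
#' @param tau mask threshold in `[0, 1]`: fine edges are kept only where the
#'   upsampled coarse gradient exceeds `tau`.
#' @param gamma fusion weight of the boundary channel in [enhance()].
#' @return parameter list.
#' @export
bem_params <- function(fine_scale_radius = 1L, coarse_downsample = 4L,
                       tau = 0.2, gamma = 0.3) {
  stopifnot(coarse_downsample >= 2L, tau >= 0, tau <= 1, gamma >= 0)
  list(fine_scale_radius = as.integer(fine_scale_radius),
       coarse_downsample = as.integer(coarse_downsample),
       tau = tau, gamma = gamma)
}

#' Integer luma of an RGB image
#' @param img ImageU8.
#' @return H x W integer matrix in `[0, 255]`.
#' @export
luma_u8 <- function(img) {
  y <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  matrix(as.integer(round_half_up(y)), nrow = dim(img)[1])
}

#' Clip a histogram and redistribute the excess
#'
#' Mass above the threshold `T` is truncated and spread uniformly: with
#' `excess = sum(max(0, counts - T))` and `L = excess / nbins`, bins below
#' `T` become `counts + L` and bins at or above `T` become `T + L`. Total
#' mass is conserved exactly.
#'
#' @param counts non-negative bin counts (any length; 256 for images).
#' @param threshold clip threshold `T > 0`.
#' @return clipped counts, same length.
#' @export
clip_redistribute <- function(counts, threshold) {
  if (threshold <= 0) stop("threshold must be > 0")
  if (!is.finite(threshold)) return(counts)
  excess <- sum(pmax(counts - threshold, 0))
  L <- excess / length(counts)
  ifelse(counts < threshold, counts + L, threshold + L)
}

#' Clip threshold from a maximal mapping slope
#'
#' For a window/tile of side `M` (so `M^2` pixels), a maximal mapping slope
#' `S_max` bounds the histogram at `S_max * M^2 / 255`.
#'
#' @param s_max maximal slope (> 0).
#' @param M window side length (>= 1); may be non-integer for non-square
#'   tiles (pass `sqrt(n_pixels)`).
#' @return histogram height bound `H_max`.
#' @export
clip_threshold_from_slope <- function(s_max, M) {
  stopifnot(s_max > 0, M >= 1)
  s_max * M^2 / 255
}

#' Gray-level mapping from a (clipped) histogram
#'
#' `m(i) = round(255 * CDF(i) / total)` with round-half-up; the mapping is
#' monotone non-decreasing with values in `[0, 255]`.
#'
#' @param counts histogram over gray levels `0..length(counts)-1`
#'   (256 bins for 8-bit images); total must be > 0.
#' @return integer lookup table, index `i+1` maps level `i`.
#' @export
tile_mapping <- function(counts) {
  total <- sum(counts)
  if (total <= 0) stop("empty region: histogram has zero total")
  cdf <- cumsum(counts)
  as.integer(round_half_up(255 * cdf / total))
}

# CLAHE on a single gray-level (integer 0..255) matrix
clahe_gray <- function(y, tiles_x, tiles_y, s_max) {
  H <- nrow(y); W <- ncol(y)
  if (H < tiles_y || W < tiles_x)
    stop("image smaller than the tile grid")
  ey <- round(seq(0, H, length.out = tiles_y + 1))
  ex <- round(seq(0, W, length.out = tiles_x + 1))
  nt <- tiles_x * tiles_y
  luts <- matrix(0L, nrow = 256, ncol = nt)
  cy <- numeric(tiles_y); cx <- numeric(tiles_x)
  for (tx in seq_len(tiles_x)) {
    for (ty in seq_len(tiles_y)) {
      rows <- (ey[ty] + 1):ey[ty + 1]
      cols <- (ex[tx] + 1):ex[tx + 1]
      vals <- y[rows, cols]
      hist <- tabulate(as.vector(vals) + 1L, nbins = 256L)
      n <- length(vals)
      clipped <- if (is.finite(s_max)) {
        clip_redistribute(hist, clip_threshold_from_slope(s_max, sqrt(n)))
      } else hist
      luts[, (tx - 1L) * tiles_y + ty] <- tile_mapping(clipped)
      cy[ty] <- (ey[ty] + 1 + ey[ty + 1]) / 2
      cx[tx] <- (ex[tx] + 1 + ex[tx + 1]) / 2
    }
  }
  # per-pixel bilinear blend of the 4 surrounding tile mappings;
  # rows/cols beyond the outer tile centers use the nearest tile (constant)
  interp_axis <- function(pos, centers) {
    n <- length(centers)
    i0 <- findInterval(pos, centers)
    i0c <- pmin(pmax(i0, 1L), n - if (n > 1L) 1L else 0L)
    if (n == 1L) return(list(i0 = rep(1L, length(pos)),
                             i1 = rep(1L, length(pos)),
                             w0 = rep(1, length(pos))))
    i1 <- i0c + 1L
    w1 <- (pos - centers[i0c]) / (centers[i1] - centers[i0c])
    w1 <- clip01(w1)
    list(i0 = i0c, i1 = i1, w0 = 1 - w1)
  }
  ay <- interp_axis(seq_len(H), cy)
  ax <- interp_axis(seq_len(W), cx)
  vflat <- as.vector(y) + 1L                       # 1-based gray level
  rr <- rep(seq_len(H), times = W)
  cc <- rep(seq_len(W), each = H)
  gather <- function(tyi, txi) {
    tid <- (txi[cc] - 1L) * tiles_y + tyi[rr]
    luts[(tid - 1L) * 256L + vflat]
  }
  out <- ay$w0[rr] * ax$w0[cc] * gather(ay$i0, ax$i0) +
    ay$w0[rr] * (1 - ax$w0[cc]) * gather(ay$i0, ax$i1) +
    (1 - ay$w0[rr]) * ax$w0[cc] * gather(ay$i1, ax$i0) +
    (1 - ay$w0[rr]) * (1 - ax$w0[cc]) * gather(ay$i1, ax$i1)
  matrix(as.integer(round_half_up(out)), nrow = H)
}

# rescale RGB by a new/old luma ratio, preserving hue
rescale_by_luma <- function(img, y_old, y_new) {
  ratio <- (y_new + 0.5) / (y_old + 0.5)
  out <- img
  for (ch in 1:3)
    out[, , ch] <- as.integer(clip_u8(round_half_up(img[, , ch] * ratio)))
  out
}

#' Contrast-limited adaptive histogram equalization
#'
#' @param img ImageU8.
#' @param params [clahe_params()].
#' @return enhanced ImageU8.
#' @export
clahe <- function(img, params = clahe_params()) {
  validate_image(img)
  if (params$channel_mode == "per_channel") {
    out <- img
    for (ch in 1:3)
      out[, , ch] <- clahe_gray(matrix(as.integer(img[, , ch]),
                                       nrow = dim(img)[1]),
                                params$tiles_x, params$tiles_y, params$s_max)
    return(out)
  }
  y <- luma_u8(img)
  y2 <- clahe_gray(y, params$tiles_x, params$tiles_y, params$s_max)
  rescale_by_luma(img, y, y2)
}

#' Global histogram equalization (baseline)
#'
#' Plain luminance histogram equalization of the whole image; equivalent to
#' unclipped CLAHE with a single 1 x 1 tile.
#'
#' @param img ImageU8.
#' @return equalized ImageU8.
#' @export
global_he <- function(img) {
  validate_image(img)
  y <- luma_u8(img)
  lut <- tile_mapping(tabulate(as.vector(y) + 1L, nbins = 256L))
  y2 <- matrix(lut[y + 1L], nrow = nrow(y))
  rescale_by_luma(img, y, y2)
}

sobel_magnitude <- function(g) {
  H <- nrow(g); W <- ncol(g)
  # replicate-pad by 1 then apply 3x3 Sobel
  gp <- rbind(g[1, , drop = FALSE], g, g[H, , drop = FALSE])
  gp <- cbind(gp[, 1, drop = FALSE], gp, gp[, W, drop = FALSE])
  sh <- function(dy, dx) gp[(1 + dy):(H + dy), (1 + dx):(W + dx)]
  gx <- -sh(0, 0) - 2 * sh(1, 0) - sh(2, 0) +
    sh(0, 2) + 2 * sh(1, 2) + sh(2, 2)
  gy <- -sh(0, 0) - 2 * sh(0, 1) - sh(0, 2) +
    sh(2, 0) + 2 * sh(2, 1) + sh(2, 2)
  sqrt(gx^2 + gy^2)
}

block_mean_downsample <- function(g, f) {
  H2 <- nrow(g) %/% f; W2 <- ncol(g) %/% f
  if (H2 < 1 || W2 < 1) stop("image too small for downsample factor")
  g <- g[seq_len(H2 * f), seq_len(W2 * f), drop = FALSE]
  m <- matrix(0, H2, W2)
  for (a in seq_len(f)) for (b in seq_len(f))
    m <- m + g[seq(a, by = f, length.out = H2),
               seq(b, by = f, length.out = W2)]
  m / f^2
}

#' Boundary-detection enhancement channel
#'
#' Computes a full-resolution gradient-magnitude map (low-level detail) and
#' gates it by the thresholded, upsampled gradient magnitude of a
#' downsampled copy (high-level structure): fine texture with no coarse
#' support is suppressed, true object boundaries are kept.
#'
#' @param img ImageU8.
#' @param params [bem_params()].
#' @return H x W edge map with values in `[0, 1]`.
#' @export
boundary_channel <- function(img, params = bem_params()) {
  validate_image(img)
  g <- luma_u8(img) / 255
  fine <- sobel_magnitude(g)
  if (max(fine) > 0) fine <- fine / max(fine)
  f <- params$coarse_downsample
  coarse <- sobel_magnitude(block_mean_downsample(g, f))
  if (max(coarse) > 0) coarse <- coarse / max(coarse)
  up <- coarse[pmin(ceiling(seq_len(nrow(g)) / f), nrow(coarse)),
               pmin(ceiling(seq_len(ncol(g)) / f), ncol(coarse)),
               drop = FALSE]
  b <- fine * (up > params$tau)
  if (max(b) > 0) b <- b / max(b)
  b
}

#' Full underwater enhancement: CLAHE + boundary channel
#'
#' `out = clip(CLAHE(img) + gamma * 255 * B)`, with `B` the boundary channel
#' of the raw input broadcast over RGB; a pure function of its inputs.
#'
#' @param img ImageU8.
#' @param clahe_par [clahe_params()].
#' @param bem_par [bem_params()]; `bem_par$gamma = 0` disables the channel.
#' @return enhanced ImageU8.
#' @export
enhance <- function(img, clahe_par = clahe_params(), bem_par = bem_params()) {
  base <- clahe(img, clahe_par)
  if (bem_par$gamma == 0) return(base)
  b <- boundary_channel(img, bem_par)
  out <- base
  for (ch in 1:3)
    out[, , ch] <- as.integer(clip_u8(round_half_up(
      base[, , ch] + bem_par$gamma * 255 * b)))
  out
}

#' RMS contrast of an image
#'
#' Standard deviation of the luma channel; the quantity the enhancer is
#' meant to raise on low-contrast underwater frames.
#'
#' @param img ImageU8.
#' @return non-negative scalar.
#' @export
rms_contrast <- function(img) stats::sd(as.numeric(luma_u8(img)))

#' Mean gradient energy near box boundaries
#'
#' Mean Sobel gradient magnitude over pixels within `band` pixels of any
#' ground-truth box perimeter; used to quantify how much the enhancer
#' sharpens object boundaries.
#'
#' @param img ImageU8.
#' @param boxes normalized box data frame.
#' @param band half-width of the perimeter band in pixels.
#' @return mean gradient magnitude in the band (0 if no boxes).
#' @export
boundary_band_energy <- function(img, boxes, band = 3L) {
  if (nrow(boxes) == 0L) return(0)
  H <- dim(img)[1]; W <- dim(img)[2]
  mag <- sobel_magnitude(luma_u8(img) / 255)
  in_band <- matrix(FALSE, H, W)
  co <- to_corners(boxes)
  px <- function(v, n) pmin(pmax(round(v * n), 1L), n)
  for (i in seq_len(nrow(co))) {
    x1 <- px(co[i, "x1"], W); x2 <- px(co[i, "x2"], W)
    y1 <- px(co[i, "y1"], H); y2 <- px(co[i, "y2"], H)
    rows <- max(1L, y1 - band):min(H, y2 + band)
    cols <- max(1L, x1 - band):min(W, x2 + band)
    # band = dilated box minus eroded interior
    this <- matrix(FALSE, H, W)
    this[rows, cols] <- TRUE
    if (y1 + band <= y2 - band && x1 + band <= x2 - band)
      this[(y1 + band):(y2 - band), (x1 + band):(x2 - band)] <- FALSE
    in_band <- in_band | this
  }
  if (!any(in_band)) return(0)
  mean(mag[in_band])
}
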