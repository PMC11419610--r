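#' Synthetic underwater detection scenes
#'
#' Generates underwater-like images with matching YOLO labels so the whole
#' pipeline is testable without external data: a textured blue-green
#' background, deformable elliptical "organisms" of four classes
#' (holothurian, starfish, jellyfish, octopus) whose outlines are low-order
#' Fourier perturbations of an ellipse (emulating soft, deformable bodies),
#' an underwater degradation operator (color cast, contrast compression,
#' blur, noise), and an optional label-corruption step emulating
#' low-quality annotations. Generation is a pure function of (spec, seed).
#'
#' @name synthetic
NULL

#' Scene specification
#'
#' @param size image side in pixels (square scenes).
#' @param classes class-name vector (default the four organism classes).
#' @param n_objects inclusive range of objects per image.
#' @param deform_amp relative amplitude of the Fourier outline perturbation.
#' @param degrade degradation parameters: `gains` (RGB channel gains
#'   suppressing red, boosting green/blue), `contrast` (compression factor
#'   toward mid-gray, < 1 lowers contrast), `blur` (Gaussian sigma, pixels),
#'   `noise_sd` (additive noise sd, 8-bit units).
#' @param label_noise `fraction` of boxes corrupted and multiplicative
#'   `jitter` scale.
#' @return spec list.
#' @export
scene_spec <- function(size = 160L,
                       classes = c("holothurian", "starfish",
                                   "jellyfish", "octopus"),
                       n_objects = c(1L, 4L),
                       deform_amp = 0.25,
                       degrade = list(gains = c(0.5, 1.05, 1.15),
                                      contrast = 0.45, blur = 1.2,
                                      noise_sd = 4),
                       label_noise = list(fraction = 0, jitter = 0.3)) {
  stopifnot(size >= 32, length(classes) >= 1, deform_amp >= 0,
            label_noise$fraction >= 0, label_noise$fraction <= 1)
  list(size = as.integer(size), classes = classes,
       n_objects = as.integer(n_objects), deform_amp = deform_amp,
       degrade = degrade, label_noise = label_noise)
}

# smooth multiplicative noise field: coarse Gaussian grid, bilinear upsample
smooth_field <- function(H, W, cell = 8L, sd = 1) {
  h2 <- ceiling(H / cell) + 1L; w2 <- ceiling(W / cell) + 1L
  g <- matrix(stats::rnorm(h2 * w2, sd = sd), h2, w2)
  ry <- (seq_len(H) - 1) / cell + 1
  rx <- (seq_len(W) - 1) / cell + 1
  y0 <- pmin(floor(ry), h2 - 1L); fy <- ry - y0
  x0 <- pmin(floor(rx), w2 - 1L); fx <- rx - x0
  g[y0, x0] * outer(1 - fy, 1 - fx) + g[y0, x0 + 1] * outer(1 - fy, fx) +
    g[y0 + 1, x0] * outer(fy, 1 - fx) + g[y0 + 1, x0 + 1] * outer(fy, fx)
}

gauss_blur_mat <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2)); k <- k / sum(k)
  H <- nrow(m); W <- ncol(m)
  # replicate-pad indices, separable passes
  ri <- pmin(pmax(outer(seq_len(H), seq(-r, r), "+"), 1L), H)
  tmp <- matrix(0, H, W)
  for (j in seq_along(k)) tmp <- tmp + k[j] * m[ri[, j], , drop = FALSE]
  ci <- pmin(pmax(outer(seq_len(W), seq(-r, r), "+"), 1L), W)
  out <- matrix(0, H, W)
  for (j in seq_along(k)) out <- out + k[j] * tmp[, ci[, j], drop = FALSE]
  out
}

# class visual signatures: base RGB and a texture motif
class_palette <- function(cls_idx) {
  switch(((cls_idx - 1L) %% 4L) + 1L,
         c(95, 62, 40),     # holothurian: dark brown, lengthwise stripes
         c(205, 120, 55),   # starfish: orange, 5-fold arm modulation
         c(185, 195, 215),  # jellyfish: pale, radial fade
         c(155, 75, 95))    # octopus: reddish purple, speckle
}

render_blob <- function(canvas, cls_idx, cx, cy, r0, aspect, ang, amp) {
  H <- nrow(canvas[[1]]); W <- ncol(canvas[[1]])
  a_k <- stats::runif(3, -amp, amp) / c(1, 1.5, 2)
  phi <- stats::runif(3, 0, 2 * pi)
  ext <- ceiling(r0 * max(1, aspect) * (1 + sum(abs(a_k))) + 2)
  rows <- max(1, floor(cy - ext)):min(H, ceiling(cy + ext))
  cols <- max(1, floor(cx - ext)):min(W, ceiling(cx + ext))
  dy <- outer(rows - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - cx)
  # rotate, squash into ellipse frame
  ry <- dy * cos(ang) - dx * sin(ang)
  rx <- (dy * sin(ang) + dx * cos(ang)) / aspect
  th <- atan2(ry, rx)
  rad <- r0 * pmax(1 + a_k[1] * cos(2 * th + phi[1]) +
                     a_k[2] * cos(3 * th + phi[2]) +
                     a_k[3] * cos(4 * th + phi[3]), 0.3)
  rho <- sqrt(rx^2 + ry^2)
  alpha <- clip01((rad - rho) / 1.5 + 0.5)
  base <- class_palette(cls_idx)
  tex <- switch(((cls_idx - 1L) %% 4L) + 1L,
                1 + 0.18 * cos(rx * 1.2),            # stripes
                1 + 0.25 * cos(5 * th),              # 5 arms
                1 - 0.35 * clip01(rho / pmax(rad, 1e-6)),  # radial fade
                1 + 0.2 * sin(rx * 2.1) * sin(ry * 2.3))   # speckle
  for (ch in 1:3) {
    sub <- canvas[[ch]][rows, cols]
    canvas[[ch]][rows, cols] <- (1 - alpha) * sub + alpha * base[ch] * tex
  }
  mask <- alpha > 0.5
  list(canvas = canvas, mask = mask, rows = rows, cols = cols)
}

#' Generate one synthetic scene
#'
#' Renders the textured background and the per-class deformable blobs, then
#' computes each label as the tight box of the rendered object mask. The
#' returned image is the *clean* scene; apply [degrade_underwater()] for the
#' underwater look and [perturb_labels()] for label corruption.
#'
#' @param spec a [scene_spec()].
#' @param seed RNG seed; the scene is a pure function of `(spec, seed)`.
#' @return list with `image` (ImageU8) and `boxes` (normalized box data
#'   frame with 0-based class ids).
#' @export
generate_scene <- function(spec = scene_spec(), seed = 1L) {
  with_seed(seed, {
    H <- spec$size; W <- spec$size
    base <- c(46, 88, 104)
    canvas <- lapply(1:3, function(ch)
      base[ch] * (1 + 0.18 * smooth_field(H, W, cell = max(8L, H %/% 10L))) +
        4 * smooth_field(H, W, cell = 4L))
    n_obj <- if (spec$n_objects[1] == spec$n_objects[2]) spec$n_objects[1]
             else sample(spec$n_objects[1]:spec$n_objects[2], 1L)
    rows_out <- list()
    if (n_obj > 0) for (i in seq_len(n_obj)) {
      cls_idx <- sample(seq_along(spec$classes), 1L)
      r0 <- stats::runif(1, 0.07, 0.16) * H
      placed <- FALSE
      for (attempt in 1:20) {
        cx <- stats::runif(1, r0 + 2, W - r0 - 2)
        cy <- stats::runif(1, r0 + 2, H - r0 - 2)
        if (is.finite(cx) && is.finite(cy)) { placed <- TRUE; break }
      }
      if (!placed) stop("could not place object ", i, " in the scene")
      rb <- render_blob(canvas, cls_idx, cx, cy, r0,
                        aspect = stats::runif(1, 0.6, 1.6),
                        ang = stats::runif(1, 0, pi),
                        amp = spec$deform_amp)
      canvas <- rb$canvas
      if (any(rb$mask)) {
        rr <- range(rb$rows[apply(rb$mask, 1, any)])
        cc <- range(rb$cols[apply(rb$mask, 2, any)])
        rows_out[[length(rows_out) + 1L]] <- c(
          cls = cls_idx - 1L,
          cx = (mean(cc) - 0.5) / W, cy = (mean(rr) - 0.5) / H,
          w = (diff(cc) + 1) / W, h = (diff(rr) + 1) / H)
      }
    }
    img <- array(0L, c(H, W, 3L))
    for (ch in 1:3)
      img[, , ch] <- as.integer(clip_u8(round_half_up(canvas[[ch]])))
    boxes <- if (length(rows_out) == 0) boxes_df() else {
      m <- do.call(rbind, rows_out)
      clip_boxes(boxes_df(m[, "cls"], m[, "cx"], m[, "cy"],
                          m[, "w"], m[, "h"]))
    }
    list(image = img, boxes = boxes)
  })
}

#' Underwater degradation operator
#'
#' Channel gains (suppress red, boost green/blue), contrast compression
#' toward mid-gray, Gaussian blur, additive Gaussian noise, clip to
#' `[0, 255]`. With gains 1, contrast 1, blur 0 and noise 0 it is the
#' identity.
#'
#' @param img ImageU8.
#' @param degrade degradation list (see [scene_spec()]).
#' @param seed RNG seed for the noise draw.
#' @return degraded ImageU8.
#' @export
degrade_underwater <- function(img, degrade = scene_spec()$degrade,
                               seed = 1L) {
  validate_image(img)
  with_seed(seed, {
    out <- array(0, dim(img))
    for (ch in 1:3) {
      m <- img[, , ch] * degrade$gains[ch]
      m <- 128 + degrade$contrast * (m - 128)
      m <- gauss_blur_mat(m, degrade$blur)
      if (degrade$noise_sd > 0)
        m <- m + stats::rnorm(length(m), sd = degrade$noise_sd)
      out[, , ch] <- clip_u8(round_half_up(m))
    }
    array(as.integer(out), dim(img))
  })
}

#' Corrupt a seeded fraction of labels
#'
#' Selected boxes get center jitter proportional to their size and
#' multiplicative (log-normal) size jitter, emulating low-quality
#' annotations; the returned data frame carries a logical `corrupted`
#' attribute recording which rows were touched.
#'
#' @param boxes normalized box data frame.
#' @param fraction fraction of boxes corrupted.
#' @param jitter jitter scale.
#' @param seed RNG seed.
#' @return perturbed (and re-clipped) box data frame.
#' @export
perturb_labels <- function(boxes, fraction, jitter, seed = 1L) {
  n <- nrow(boxes)
  if (n == 0L || fraction == 0) {
    attr(boxes, "corrupted") <- logical(n)
    return(boxes)
  }
  with_seed(seed, {
    hit <- stats::runif(n) < fraction
    out <- boxes
    k <- sum(hit)
    if (k > 0) {
      out$cx[hit] <- out$cx[hit] + stats::rnorm(k, sd = jitter) * out$w[hit]
      out$cy[hit] <- out$cy[hit] + stats::rnorm(k, sd = jitter) * out$h[hit]
      out$w[hit] <- out$w[hit] * exp(stats::rnorm(k, sd = jitter))
      out$h[hit] <- out$h[hit] * exp(stats::rnorm(k, sd = jitter))
    }
    # clip in corner form without dropping rows, so flags stay aligned
    co <- to_corners(out)
    co[, c("x1", "y1")] <- pmax(co[, c("x1", "y1")], 0)
    co[, c("x2", "y2")] <- pmin(co[, c("x2", "y2")], 1)
    co[, "x2"] <- pmax(co[, "x2"], co[, "x1"] + 1e-3)
    co[, "y2"] <- pmax(co[, "y2"], co[, "y1"] + 1e-3)
    ce <- to_center(co)
    out[, c("cx", "cy", "w", "h")] <- ce
    attr(out, "corrupted") <- hit
    out
  })
}

#' Write a synthetic dataset tree
#'
#' Generates degraded scenes with labels into
#' `out_dir/images/{train,val}` and `out_dir/labels/{train,val}` plus a
#' `dataset.yaml` manifest, ready for the enhancement, evaluation and
#' demo-training tools.
#'
#' @param out_dir output directory (created).
#' @param n_train,n_val split sizes.
#' @param spec [scene_spec()]; `spec$label_noise` is applied to *training*
#'   labels only (validation labels stay clean).
#' @param seed base RNG seed.
#' @return manifest path, invisibly.
#' @export
generate_dataset <- function(out_dir, n_train = 100L, n_val = 30L,
                             spec = scene_spec(), seed = 7L) {
  for (sub in c("images/train", "images/val", "labels/train", "labels/val"))
    dir.create(file.path(out_dir, sub), recursive = TRUE,
               showWarnings = FALSE)
  splits <- list(train = character(), val = character())
  idx <- 0L
  for (split in c("train", "val")) {
    n <- if (split == "train") n_train else n_val
    for (i in seq_len(n)) {
      idx <- idx + 1L
      sc <- generate_scene(spec, seed = seed + idx)
      img <- degrade_underwater(sc$image, spec$degrade, seed = seed + idx)
      boxes <- sc$boxes
      if (split == "train" && spec$label_noise$fraction > 0)
        boxes <- perturb_labels(boxes, spec$label_noise$fraction,
                                spec$label_noise$jitter, seed = seed + idx)
      name <- sprintf("scene_%04d", idx)
      write_image(img, file.path(out_dir, "images", split,
                                 paste0(name, ".png")))
      write_yolo_labels(boxes, file.path(out_dir, "labels", split,
                                         paste0(name, ".txt")))
      splits[[split]] <- c(splits[[split]], paste0(name, ".png"))
    }
  }
  manifest <- list(images_dir = "images", labels_dir = "labels",
                   names = as.list(spec$classes), splits = splits)
  path <- file.path(out_dir, "dataset.yaml")
  write_manifest(manifest, path)
  invisible(path)
}
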