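#' Image and YOLO-label input/output
#'
#' Images are plain `H x W x 3` integer arrays in `[0, 255]` ("ImageU8");
#' labels are data frames with columns `cls, cx, cy, w, h` (and optionally
#' `conf`) in normalized center form, the YOLO text-label convention.
#' Pixel coordinates use the image convention: origin at the top-left corner,
#' x rightward, y downward; normalized coordinates are continuous in `[0, 1]`.
#'
#' @name io_formats
NULL

#' Validate an ImageU8 array
#' @param img candidate image.
#' @return `img`, invisibly, after validation.
#' @export
validate_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("image must be an H x W x 3 array")
  if (dim(img)[1] < 1L || dim(img)[2] < 1L)
    stop("image must have H >= 1, W >= 1")
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop("image values must lie in [0, 255]")
  invisible(img)
}

#' Read an 8-bit RGB image
#'
#' Reads PNG (via \pkg{png}) or JPEG (via \pkg{EBImage}, if installed).
#' Grayscale files are rejected with a format error naming the channel
#' mismatch; 4-channel (RGBA) images drop the alpha channel with a warning.
#'
#' @param path file path ending in `.png`, `.jpg` or `.jpeg`.
#' @return an `H x W x 3` integer array in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  a <- if (ext == "png") {
    tryCatch(png::readPNG(path), error = function(e)
      stop("undecodable PNG: ", path, " (", conditionMessage(e), ")"))
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("JPEG support requires the EBImage package")
    img <- EBImage::readImage(path)
    d <- dim(img)
    # EBImage stores X x Y (x channels); transpose to H x W
    if (length(d) == 2L) array(t(img), c(d[2], d[1], 1L))
    else aperm(array(img, d), c(2L, 1L, 3L))
  } else stop("unsupported image format: .", ext)
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  nc <- dim(a)[3]
  if (nc == 1L)
    stop("format error: expected a 3-channel RGB image, got 1 channel (grayscale)")
  if (nc == 4L) {
    warning("dropping alpha channel of 4-channel image: ", path)
    a <- a[, , 1:3, drop = FALSE]
  }
  if (dim(a)[3] != 3L)
    stop("format error: expected 3 channels, got ", dim(a)[3])
  img <- array(as.integer(round(a * 255)), dim(a))
  validate_image(img)
  img
}

#' Write an ImageU8 as PNG
#'
#' PNG round trips are bit-exact: `read_image(write_image(img, p))`
#' reproduces `img`.
#'
#' @param img `H x W x 3` array in `[0, 255]`.
#' @param path output path; the parent directory must exist.
#' @export
write_image <- function(img, path) {
  validate_image(img)
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  png::writePNG(img / 255, target = path)
  invisible(path)
}

#' Construct a box table
#'
#' @param cls integer class ids (>= 0).
#' @param cx,cy,w,h normalized center-form coordinates.
#' @param conf optional confidences in `[0, 1]` (`NA` if absent).
#' @return data frame with columns `cls, cx, cy, w, h, conf`.
#' @export
boxes_df <- function(cls = integer(), cx = numeric(), cy = numeric(),
                     w = numeric(), h = numeric(), conf = NA_real_) {
  data.frame(cls = as.integer(cls), cx = as.numeric(cx), cy = as.numeric(cy),
             w = as.numeric(w), h = as.numeric(h),
             conf = rep_len(as.numeric(conf), length(cls)))
}

#' Convert center-form boxes to corner form and back
#'
#' Corner form is `(x1, y1, x2, y2)` with `x1 < x2`, `y1 < y2`, in the same
#' (normalized or pixel) units as the input. The two conversions are exact
#' inverses of each other.
#'
#' @param b matrix or data frame with columns `cx, cy, w, h` (`to_corners`)
#'   or `x1, y1, x2, y2` (`to_center`).
#' @return a 4-column matrix.
#' @export
to_corners <- function(b) {
  b <- as.data.frame(b)
  cbind(x1 = b$cx - b$w / 2, y1 = b$cy - b$h / 2,
        x2 = b$cx + b$w / 2, y2 = b$cy + b$h / 2)
}

#' @rdname to_corners
#' @export
to_center <- function(b) {
  b <- as.data.frame(b)
  cbind(cx = (b$x1 + b$x2) / 2, cy = (b$y1 + b$y2) / 2,
        w = b$x2 - b$x1, h = b$y2 - b$y1)
}

#' Clip normalized boxes to the unit square
#'
#' Boxes partially outside `[0, 1]` (as real annotation tools emit) are
#' clipped in corner form and converted back; boxes that vanish entirely
#' are dropped.
#'
#' @param boxes box data frame (normalized center form).
#' @return clipped box data frame.
#' @export
clip_boxes <- function(boxes) {
  if (nrow(boxes) == 0L) return(boxes)
  co <- to_corners(boxes)
  co[, c("x1", "y1")] <- pmax(co[, c("x1", "y1")], 0)
  co[, c("x2", "y2")] <- pmin(co[, c("x2", "y2")], 1)
  keep <- co[, "x2"] > co[, "x1"] & co[, "y2"] > co[, "y1"]
  ce <- to_center(co[keep, , drop = FALSE])
  out <- boxes[keep, , drop = FALSE]
  out[, c("cx", "cy", "w", "h")] <- ce
  rownames(out) <- NULL
  out
}

#' Read YOLO-format labels
#'
#' Each non-empty line is `class cx cy w h` (plus an optional sixth
#' confidence column for prediction files), whitespace separated, normalized
#' coordinates. Malformed lines, class ids `>= n_classes` and non-positive
#' sizes are rejected with the offending line number; boxes partially outside
#' the unit square are clipped.
#'
#' @param path label file (may be empty).
#' @param n_classes number of classes; ids must be `< n_classes`.
#' @return box data frame (see [boxes_df()]).
#' @export
read_yolo_labels <- function(path, n_classes) {
  if (!file.exists(path)) stop("label file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0L) return(boxes_df())
  rows <- lapply(seq_along(idx), function(k) {
    ln <- idx[k]
    f <- strsplit(lines[ln], "[[:space:]]+")[[1]]
    if (!length(f) %in% c(5L, 6L))
      stop("malformed label line ", ln, " in ", path, ": expected 5 fields")
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v))
      stop("malformed label line ", ln, " in ", path, ": non-numeric field")
    if (v[1] < 0 || v[1] != floor(v[1]) || v[1] >= n_classes)
      stop("class id out of range at line ", ln, " in ", path,
           ": ", f[1], " (n_classes = ", n_classes, ")")
    if (v[4] <= 0 || v[5] <= 0)
      stop("non-positive box size at line ", ln, " in ", path)
    c(v, if (length(v) == 5L) NA_real_)
  })
  m <- do.call(rbind, rows)
  b <- boxes_df(m[, 1], m[, 2], m[, 3], m[, 4], m[, 5], m[, 6])
  clip_boxes(b)
}

#' Write YOLO-format labels
#'
#' Emits 6 decimal places; a `conf` column, if present and non-`NA`, is
#' written as a sixth field. Read-after-write reproduces the boxes to 1e-6.
#'
#' @param boxes box data frame.
#' @param path output path.
#' @export
write_yolo_labels <- function(boxes, path) {
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  if (nrow(boxes) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  has_conf <- "conf" %in% names(boxes) && !all(is.na(boxes$conf))
  lines <- vapply(seq_len(nrow(boxes)), function(i) {
    base <- sprintf("%d %.6f %.6f %.6f %.6f", boxes$cls[i], boxes$cx[i],
                    boxes$cy[i], boxes$w[i], boxes$h[i])
    if (has_conf && !is.na(boxes$conf[i]))
      paste(base, sprintf("%.6f", boxes$conf[i]))
    else base
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a dataset manifest
#'
#' The manifest is a YAML file with keys `images_dir`, `labels_dir`, `names`
#' (class-name list) and optional `splits` (named lists of image file names).
#'
#' @param path YAML manifest path.
#' @return a list with the manifest fields; directories resolved relative to
#'   the manifest location.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest does not exist: ", path)
  m <- yaml::read_yaml(path)
  for (k in c("images_dir", "labels_dir", "names"))
    if (is.null(m[[k]])) stop("manifest missing key: ", k)
  root <- dirname(normalizePath(path))
  for (k in c("images_dir", "labels_dir"))
    if (!grepl("^(/|[A-Za-z]:)", m[[k]])) m[[k]] <- file.path(root, m[[k]])
  m$names <- as.character(unlist(m$names))
  m
}

#' @rdname read_manifest
#' @param manifest list with `images_dir`, `labels_dir`, `names`, `splits`.
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' List image/label pairs of a manifest split
#'
#' Every image must have exactly one label file (possibly empty).
#'
#' @param manifest manifest list from [read_manifest()].
#' @param split split name (default `"train"`); ignored when the manifest
#'   has no `splits` entry.
#' @return data frame with columns `image`, `label`.
#' @export
manifest_pairs <- function(manifest, split = "train") {
  imgs <- if (!is.null(manifest$splits)) {
    file.path(manifest$images_dir, split,
              unlist(manifest$splits[[split]]))
  } else {
    list.files(manifest$images_dir, pattern = "\\.(png|jpe?g)$",
               full.names = TRUE)
  }
  labs <- file.path(
    if (!is.null(manifest$splits)) file.path(manifest$labels_dir, split)
    else manifest$labels_dir,
    paste0(tools::file_path_sans_ext(basename(imgs)), ".txt"))
  missing <- !file.exists(labs)
  if (any(missing))
    stop("missing label file(s): ", paste(labs[missing], collapse = ", "))
  data.frame(image = imgs, label = labs, stringsAsFactors = FALSE)
}
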