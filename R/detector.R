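#' Miniature anchor-free demo detector
#'
#' A desk-scale, single-scale detector that wires the package's blocks
#' together for end-to-end smoke experiments: three stride-2 convolution
#' stages (with an optional residual DCN block after the second), SimAM
#' attention before the head, and a linear per-cell head predicting
#' objectness, class scores and a box. The convolutional trunk is frozen at
#' a seeded random initialization (random convolutional features); only the
#' linear head is trained — objectness/class by logistic regression, the box
#' by the selected IoU-family loss with gradients taken through the decode.
#' It exists to smoke-test block interactions and loss behavior, not to
#' approach full-scale detector accuracy.
#'
#' @name demo_detector
NULL

#' Build a demo detector
#'
#' @param n_classes number of classes.
#' @param size input image side (multiple of 8; cells are `size/8`).
#' @param use_dcn include the residual DCN block (default `TRUE`).
#' @param use_simam apply SimAM before the head (default `TRUE`).
#' @param channels trunk widths, length 3.
#' @param seed RNG seed for trunk initialization.
#' @return model list; the head starts at zero (the "untrained" baseline).
#' @export
demo_detector <- function(n_classes = 4L, size = 64L, use_dcn = TRUE,
                          use_simam = TRUE, channels = c(8L, 16L, 24L),
                          seed = 0L) {
  stopifnot(size %% 8L == 0L)
  trunk <- with_seed(seed, list(
    conv1 = list(w = init_w(3L, 3L, 3L, channels[1]),
                 b = rep(0, channels[1])),
    conv2 = list(w = init_w(3L, 3L, channels[1], channels[2]),
                 b = rep(0, channels[2])),
    conv3 = list(w = init_w(3L, 3L, channels[2], channels[3]),
                 b = rep(0, channels[3]))))
  dcn <- if (use_dcn) dcn_block_init(channels[2], channels[2],
                                     seed = seed + 1L) else NULL
  n_out <- 1L + n_classes + 4L
  list(n_classes = n_classes, size = size, grid = size %/% 8L,
       use_dcn = use_dcn, use_simam = use_simam, channels = channels,
       trunk = trunk, dcn = dcn,
       head = matrix(0, channels[3] + 6L + 1L, n_out))
}

#' Extract per-cell features of the demo detector trunk
#'
#' Trunk activations are concatenated with first- and second-moment color
#' statistics of each cell's image patch (organism palettes differ from the
#' blue-green background, so patch moments carry strong localization and
#' class signal at this scale), then normalized channel-wise over cells —
#' low-contrast underwater scenes otherwise yield feature variance too
#' small for a linear head.
#'
#' @param model from [demo_detector()].
#' @param img ImageU8 of side `model$size`.
#' @return `(grid^2) x (C + 7)` matrix (last column the intercept).
#' @export
demo_features <- function(model, img) {
  x <- (img / 255) - 0.5
  h <- silu(conv2d(x, model$trunk$conv1$w, model$trunk$conv1$b, stride = 2L))
  h <- silu(conv2d(h, model$trunk$conv2$w, model$trunk$conv2$b, stride = 2L))
  if (model$use_dcn) h <- dcn_block(h, model$dcn)
  h <- silu(conv2d(h, model$trunk$conv3$w, model$trunk$conv3$b, stride = 2L))
  if (model$use_simam) h <- simam(h)
  S <- model$grid
  cs <- model$size %/% S
  col_stats <- matrix(0, S * S, 6L)
  for (ci in seq_len(S)) for (cj in seq_len(S)) {
    patch <- x[((ci - 1L) * cs + 1L):(ci * cs),
               ((cj - 1L) * cs + 1L):(cj * cs), , drop = FALSE]
    col_stats[ci + (cj - 1L) * S, ] <-
      c(apply(patch, 3L, mean), apply(patch, 3L, stats::sd))
  }
  f <- cbind(matrix(h, S * S, dim(h)[3]), col_stats)
  mu <- colMeans(f)
  sg <- sqrt(colMeans(sweep(f, 2L, mu)^2) + 1e-8)
  cbind(sweep(sweep(f, 2L, mu), 2L, sg, "/"), 1)
}

decode_cell_box <- function(ci, cj, t, S) {
  c(x = (cj - 1 + sigmoid(t[1])) / S,
    y = (ci - 1 + sigmoid(t[2])) / S,
    w = max(sigmoid(t[3]), 1e-3), h = max(sigmoid(t[4]), 1e-3))
}

# cell targets: obj/cls one-hot per cell plus the owning box, by box center
demo_targets <- function(boxes, S, n_classes) {
  obj <- matrix(0, S, S)
  cls <- array(0, c(S, S, n_classes))
  boxat <- vector("list", S * S)
  for (i in seq_len(nrow(boxes))) {
    ci <- min(S, max(1L, ceiling(boxes$cy[i] * S)))
    cj <- min(S, max(1L, ceiling(boxes$cx[i] * S)))
    obj[ci, cj] <- 1
    cls[ci, cj, boxes$cls[i] + 1L] <- 1
    boxat[[ci + (cj - 1L) * S]] <-
      c(boxes$cx[i], boxes$cy[i], boxes$w[i], boxes$h[i])
  }
  list(obj = obj, cls = cls, boxat = boxat)
}

#' Train the demo detector head
#'
#' Stochastic gradient descent on the linear head: binary cross-entropy for
#' objectness (all cells) and class scores (object cells), plus the selected
#' box loss on object cells with gradients taken by central differences
#' through the box decode (Wise-IoU detachment semantics preserved).
#'
#' @param model from [demo_detector()].
#' @param images list of ImageU8 training scenes.
#' @param labels list of box data frames.
#' @param box_loss `"iou"`, `"ciou"`, `"wiou1"` or `"wiou3"`.
#' @param epochs training epochs (0 = no-op, head unchanged).
#' @param lr learning rate.
#' @param lambda_box box-loss weight.
#' @param pos_weight weight of object cells in the objectness term
#'   (object cells are rare; upweighting keeps their scores usable).
#' @param seed RNG seed (shuffling).
#' @param state_args Wise-IoU v3 hyperparameters.
#' @return model with the trained head and a `history` of mean epoch losses.
#' @export
demo_train_head <- function(model, images, labels, box_loss = "ciou",
                            epochs = 60L, lr = 0.03, lambda_box = 0.5,
                            pos_weight = 8, seed = 0L, state_args = list()) {
  S <- model$grid; nc <- model$n_classes
  feats <- lapply(images, function(im) demo_features(model, im))
  targs <- lapply(labels, function(b) demo_targets(b, S, nc))
  state <- do.call(wiou_state, state_args)
  W <- model$head
  history <- numeric(0)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(seed + ep, sample(seq_along(feats)))
    ep_loss <- 0
    for (ii in ord) {
      X <- feats[[ii]]; tg <- targs[[ii]]
      logits <- X %*% W
      n_cells <- S * S
      G <- matrix(0, n_cells, ncol(W))
      # objectness BCE over all cells
      po <- sigmoid(logits[, 1])
      yo <- as.vector(tg$obj)
      wcell <- ifelse(yo > 0, pos_weight, 1)
      G[, 1] <- wcell * (po - yo) / n_cells
      ep_loss <- ep_loss - mean(wcell * (yo * log(pmax(po, 1e-12)) +
                                  (1 - yo) * log(pmax(1 - po, 1e-12))))
      pos <- which(yo > 0)
      if (length(pos) > 0) {
        for (p in pos) {
          yc <- tg$cls[((p - 1L) %% S) + 1L, ((p - 1L) %/% S) + 1L, ]
          pc <- sigmoid(logits[p, 1L + seq_len(nc)])
          G[p, 1L + seq_len(nc)] <- (pc - yc) / length(pos)
          # box loss through the decode, by central differences
          tb <- tg$boxat[[p]]
          ci <- ((p - 1L) %% S) + 1L; cj <- ((p - 1L) %/% S) + 1L
          tvec <- logits[p, 1L + nc + 1:4]
          pb0 <- decode_cell_box(ci, cj, tvec, S)
          base_fn <- frozen_loss_fn(box_loss, pb0, tb,
                                    if (box_loss == "wiou3") state)
          fb <- function(tv) base_fn(decode_cell_box(ci, cj, tv, S))
          gb <- numeric(4); eps <- 1e-4
          for (q in 1:4) {
            hi <- tvec; hi[q] <- hi[q] + eps
            lo <- tvec; lo[q] <- lo[q] - eps
            gb[q] <- (fb(hi) - fb(lo)) / (2 * eps)
          }
          if (box_loss == "wiou3") {
            pb <- decode_cell_box(ci, cj, tvec, S)
            outlier_degree(l_iou(pb, tb), state, update = TRUE)
          }
          G[p, 1L + nc + 1:4] <- lambda_box * gb / length(pos)
          ep_loss <- ep_loss + lambda_box * fb(tvec) / length(pos)
        }
      }
      W <- W - lr * crossprod(X, G)
    }
    history <- c(history, ep_loss / length(feats))
    if (!all(is.finite(W)))
      stop("training diverged: non-finite head weights at epoch ", ep)
  }
  model$head <- W
  model$history <- history
  model
}

#' Greedy non-maximum suppression
#'
#' @param boxes box data frame with `conf`.
#' @param iou_thresh suppression threshold (default 0.45).
#' @return filtered box data frame.
#' @export
nms <- function(boxes, iou_thresh = 0.45) {
  if (nrow(boxes) <= 1L) return(boxes)
  keep <- logical(nrow(boxes))
  ord <- order(-boxes$conf)
  alive <- rep(TRUE, nrow(boxes))
  for (k in ord) {
    if (!alive[k]) next
    keep[k] <- TRUE
    for (j in ord) {
      if (j == k || !alive[j]) next
      if (boxes$cls[j] == boxes$cls[k] &&
          iou_rows(boxes[k, ], boxes[j, ]) > iou_thresh)
        alive[j] <- FALSE
    }
  }
  out <- boxes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the demo detector on one image
#'
#' @param model (possibly trained) demo detector.
#' @param img ImageU8 of side `model$size`.
#' @param conf_thresh minimum confidence (objectness x best class score).
#' @param nms_iou NMS threshold.
#' @return prediction box data frame with `conf`.
#' @export
demo_predict <- function(model, img, conf_thresh = 0.1, nms_iou = 0.45) {
  S <- model$grid; nc <- model$n_classes
  logits <- demo_features(model, img) %*% model$head
  po <- sigmoid(logits[, 1])
  pc <- sigmoid(logits[, 1L + seq_len(nc), drop = FALSE])
  best_cls <- max.col(pc, ties.method = "first")
  conf <- po * pc[cbind(seq_len(S * S), best_cls)]
  keep <- which(conf >= conf_thresh)
  if (length(keep) == 0) return(boxes_df())
  rows <- lapply(keep, function(p) {
    ci <- ((p - 1L) %% S) + 1L; cj <- ((p - 1L) %/% S) + 1L
    b <- decode_cell_box(ci, cj, logits[p, 1L + nc + 1:4], S)
    c(cls = best_cls[p] - 1L, b, conf = conf[p])
  })
  m <- do.call(rbind, rows)
  out <- boxes_df(m[, 1], m[, 2], m[, 3], m[, 4], m[, 5], m[, 6])
  nms(clip_boxes(out), nms_iou)
}

#' End-to-end demo training experiment
#'
#' Generates degraded synthetic train/val scenes, optionally enhances them,
#' trains the demo head with the selected box loss, and reports mAP50 on
#' the held-out split for both the untrained and the trained model.
#'
#' @param n_train,n_val split sizes.
#' @param size image side (multiple of 8).
#' @param box_loss box-loss name.
#' @param label_noise fraction of corrupted training labels.
#' @param epochs,lr head-training schedule; `epochs = 0` returns baseline
#'   metrics unchanged.
#' @param enhance_images run [enhance()] on every scene first.
#' @param seed global RNG seed for data, init and shuffling.
#' @param spec optional [scene_spec()] override (size is forced).
#' @return list with `map50_untrained`, `map50_trained`, `report`
#'   (trained-model `eval_report`), `history`.
#' @export
demo_run <- function(n_train = 32L, n_val = 16L, size = 64L,
                     box_loss = "ciou", label_noise = 0, epochs = 60L,
                     lr = 0.03, enhance_images = FALSE, seed = 1L,
                     spec = NULL) {
  if (is.null(spec)) spec <- scene_spec(size = size)
  spec$size <- as.integer(size)
  make_split <- function(n, off, noisy) {
    imgs <- vector("list", n); labs <- vector("list", n)
    for (i in seq_len(n)) {
      sc <- generate_scene(spec, seed = seed * 1000L + off + i)
      im <- degrade_underwater(sc$image, spec$degrade,
                               seed = seed * 1000L + off + i)
      if (enhance_images)
        im <- enhance(im, clahe_params(tiles_x = 4L, tiles_y = 4L))
      b <- sc$boxes
      if (noisy && label_noise > 0)
        b <- perturb_labels(b, label_noise, 0.5,
                            seed = seed * 1000L + off + i)
      imgs[[i]] <- im; labs[[i]] <- b
    }
    list(images = imgs, labels = labs)
  }
  tr <- make_split(n_train, 0L, noisy = TRUE)
  va <- make_split(n_val, n_train, noisy = FALSE)
  model <- demo_detector(n_classes = length(spec$classes), size = size,
                         seed = seed)
  eval_model <- function(m) {
    preds <- lapply(va$images, function(im) demo_predict(m, im))
    evaluate_detections(preds, va$labels, length(spec$classes),
                        class_names = spec$classes)
  }
  rep0 <- eval_model(model)
  trained <- if (epochs > 0)
    demo_train_head(model, tr$images, tr$labels, box_loss = box_loss,
                    epochs = epochs, lr = lr, seed = seed)
  else model
  rep1 <- eval_model(trained)
  list(map50_untrained = if (is.nan(rep0$map50)) 0 else rep0$map50,
       map50_trained = if (is.nan(rep1$map50)) 0 else rep1$map50,
       report = rep1, history = trained$history %||% numeric(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
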