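#' Detection evaluation: precision, recall, AP50, mAP50, confusion matrix
#'
#' Predictions are matched to ground truth greedily in descending
#' confidence order at a fixed IoU threshold (0.5 for the headline AP50);
#' average precision integrates the precision envelope over recall exactly
#' (all-point interpolation), and mAP50 averages per-class AP over the
#' classes present in the ground truth.
#'
#' @name metrics
NULL

iou_rows <- function(a, b) {
  # IoU between two box data-frame rows (normalized center form)
  iou(c(a$cx, a$cy, a$w, a$h), c(b$cx, b$cy, b$w, b$h))
}

#' Greedy confidence-ordered matching of detections to ground truth
#'
#' Predictions are sorted by descending confidence (stable; ties keep input
#' order) and each is matched to the unmatched same-class ground truth with
#' the highest IoU `>= iou_thresh` (IoU ties broken by lower ground-truth
#' index). Each ground truth matches at most once.
#'
#' @param preds box data frame with `conf`.
#' @param gts box data frame.
#' @param iou_thresh matching threshold (default 0.5).
#' @return list with `tp` (logical, in confidence order), `conf`, `cls`
#'   (same order), `gt_matched` (logical per ground truth), and counts
#'   `n_tp`, `n_fp`, `n_fn`.
#' @export
match_detections <- function(preds, gts, iou_thresh = 0.5) {
  np <- nrow(preds); ng <- nrow(gts)
  ord <- if (np > 0) order(-preds$conf) else integer()
  tp <- logical(np)
  gt_matched <- logical(ng)
  match_gt <- rep(NA_integer_, np)
  for (k in seq_len(np)) {
    p <- preds[ord[k], ]
    best <- NA_integer_; best_iou <- -1
    for (j in seq_len(ng)) {
      if (gt_matched[j] || gts$cls[j] != p$cls) next
      v <- iou_rows(p, gts[j, ])
      if (v >= iou_thresh && v > best_iou) { best <- j; best_iou <- v }
    }
    if (!is.na(best)) { tp[k] <- TRUE; gt_matched[best] <- TRUE
                        match_gt[k] <- best }
  }
  list(tp = tp, conf = preds$conf[ord], cls = preds$cls[ord],
       match_gt = match_gt, gt_matched = gt_matched,
       n_tp = sum(tp), n_fp = np - sum(tp), n_fn = ng - sum(gt_matched))
}

#' Precision and recall from a match result
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`. With no predictions the
#' precision is defined as 0; with no ground truths the recall is defined
#' as 1 (both logged as messages).
#'
#' @param match result of [match_detections()].
#' @return named vector `c(precision, recall)`.
#' @export
precision_recall <- function(match) {
  np <- match$n_tp + match$n_fp
  ng <- match$n_tp + match$n_fn
  p <- if (np == 0) { message("no predictions: precision defined as 0"); 0 }
       else match$n_tp / np
  r <- if (ng == 0) { message("no ground truths: recall defined as 1"); 1 }
       else match$n_tp / ng
  c(precision = p, recall = r)
}

#' Average precision by exact envelope integration
#'
#' Sweeps the confidence-ordered TP/FP flags, makes the precision envelope
#' monotone non-increasing from the right, and integrates rectangles over
#' recall (all-point interpolation — the exact value of the
#' area-under-P(R) integral for a step curve).
#'
#' @param tp logical TP flags in descending-confidence order.
#' @param conf confidences in the same order (used only for the stable
#'   tie-break already applied; may be `NULL`).
#' @param n_gt number of ground-truth boxes.
#' @return list with `ap`, and the `recall`/`precision` sweep points.
#' @export
average_precision <- function(tp, conf = NULL, n_gt) {
  if (n_gt == 0) return(list(ap = NA_real_, recall = numeric(),
                             precision = numeric()))
  if (length(tp) == 0) return(list(ap = 0, recall = numeric(),
                                   precision = numeric()))
  ctp <- cumsum(tp)
  cfp <- cumsum(!tp)
  rec <- ctp / n_gt
  prec <- ctp / (ctp + cfp)
  env <- rev(cummax(rev(prec)))
  ap <- sum(diff(c(0, rec)) * env)
  list(ap = ap, recall = rec, precision = prec)
}

#' Mean AP over classes present in the ground truth
#'
#' @param per_class_ap numeric vector of per-class AP values; `NA` marks
#'   classes absent from the ground truth, which are excluded (logged).
#' @return mean AP in `[0, 1]` (`NaN` when no class is present).
#' @export
map50 <- function(per_class_ap) {
  if (anyNA(per_class_ap))
    message("excluding ", sum(is.na(per_class_ap)),
            " class(es) absent from ground truth")
  mean(per_class_ap, na.rm = TRUE)
}

#' Detection confusion matrix
#'
#' Rows are predicted classes (+ background), columns are true classes
#' (+ background). Predictions below `conf_thresh` are dropped; matching is
#' greedy by descending confidence with cross-class IoU allowed, so
#' misclassifications land off-diagonal. Unmatched ground truths count in
#' the background row; unmatched predictions in the background column.
#'
#' @param preds,gts box data frames (single pooled image set: pass
#'   per-image pairs and sum, or use [evaluate_detections()]).
#' @param n_classes number of classes.
#' @param iou_thresh matching IoU (default 0.45).
#' @param conf_thresh confidence cut (default 0.25).
#' @return `(n_classes + 1) x (n_classes + 1)` integer matrix.
#' @export
confusion_matrix <- function(preds, gts, n_classes, iou_thresh = 0.45,
                             conf_thresh = 0.25) {
  cm <- matrix(0L, n_classes + 1L, n_classes + 1L,
               dimnames = list(pred = c(seq_len(n_classes) - 1L, "bg"),
                               true = c(seq_len(n_classes) - 1L, "bg")))
  preds <- preds[!is.na(preds$conf) & preds$conf >= conf_thresh, ,
                 drop = FALSE]
  np <- nrow(preds); ng <- nrow(gts)
  ord <- if (np > 0) order(-preds$conf) else integer()
  gt_taken <- logical(ng)
  for (k in seq_len(np)) {
    p <- preds[ord[k], ]
    best <- NA_integer_; best_iou <- -1
    for (j in seq_len(ng)) {
      if (gt_taken[j]) next
      v <- iou_rows(p, gts[j, ])
      if (v >= iou_thresh && v > best_iou) { best <- j; best_iou <- v }
    }
    if (!is.na(best)) {
      gt_taken[best] <- TRUE
      cm[p$cls + 1L, gts$cls[best] + 1L] <- cm[p$cls + 1L,
                                               gts$cls[best] + 1L] + 1L
    } else {
      cm[p$cls + 1L, n_classes + 1L] <- cm[p$cls + 1L, n_classes + 1L] + 1L
    }
  }
  for (j in which(!gt_taken))
    cm[n_classes + 1L, gts$cls[j] + 1L] <- cm[n_classes + 1L,
                                              gts$cls[j] + 1L] + 1L
  cm
}

#' Evaluate detections over an image set
#'
#' Aggregates per-image greedy matches per class, computes AP50 per class,
#' mAP50 over classes present in the ground truth, precision/recall at the
#' maximum-F1 point of the pooled sweep, and the confusion matrix.
#'
#' @param preds_list list (one per image) of prediction box data frames
#'   (with `conf`).
#' @param gts_list list (one per image) of ground-truth box data frames.
#' @param n_classes number of classes.
#' @param iou_thresh AP matching threshold (default 0.5).
#' @param class_names optional character vector of class names.
#' @return an `eval_report` list: `per_class_ap`, `map50`, `precision`,
#'   `recall`, `f1_conf` (confidence at max F1), `curves` (per-class
#'   recall/precision points), `confusion`.
#' @export
evaluate_detections <- function(preds_list, gts_list, n_classes,
                                iou_thresh = 0.5, class_names = NULL) {
  stopifnot(length(preds_list) == length(gts_list))
  per_cls <- vector("list", n_classes)
  for (cls in seq_len(n_classes) - 1L) {
    tp_all <- logical(0); conf_all <- numeric(0); n_gt <- 0L
    for (i in seq_along(preds_list)) {
      p <- preds_list[[i]]; g <- gts_list[[i]]
      p <- p[p$cls == cls, , drop = FALSE]
      g <- g[g$cls == cls, , drop = FALSE]
      n_gt <- n_gt + nrow(g)
      if (nrow(p) > 0) {
        m <- match_detections(p, g, iou_thresh)
        tp_all <- c(tp_all, m$tp); conf_all <- c(conf_all, m$conf)
      }
    }
    ord <- order(-conf_all)
    per_cls[[cls + 1L]] <- list(tp = tp_all[ord], conf = conf_all[ord],
                                n_gt = n_gt)
  }
  aps <- vapply(per_cls, function(z)
    average_precision(z$tp, z$conf, z$n_gt)$ap, numeric(1))
  curves <- lapply(per_cls, function(z)
    average_precision(z$tp, z$conf, z$n_gt)[c("recall", "precision")])
  # pooled sweep for the max-F1 operating point
  tp <- unlist(lapply(per_cls, `[[`, "tp"))
  conf <- unlist(lapply(per_cls, `[[`, "conf"))
  ngt <- sum(vapply(per_cls, `[[`, numeric(1), "n_gt"))
  op <- if (length(tp) > 0 && ngt > 0) {
    ord <- order(-conf)
    ctp <- cumsum(tp[ord]); cfp <- cumsum(!tp[ord])
    prec <- ctp / (ctp + cfp); rec <- ctp / ngt
    f1 <- 2 * prec * rec / pmax(prec + rec, 1e-12)
    k <- which.max(f1)
    list(p = prec[k], r = rec[k], conf = conf[ord][k])
  } else list(p = 0, r = if (ngt == 0) 1 else 0, conf = NA_real_)
  cm <- Reduce(`+`, Map(function(p, g)
    confusion_matrix(p, g, n_classes), preds_list, gts_list),
    matrix(0L, n_classes + 1L, n_classes + 1L))
  if (!is.null(class_names)) names(aps) <- class_names
  structure(list(per_class_ap = aps, map50 = map50(aps),
                 precision = op$p, recall = op$r, f1_conf = op$conf,
                 curves = curves, confusion = cm),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Detection evaluation report\n")
  cat("  mAP50:", formatC(x$map50, digits = 4, format = "f"), "\n")
  cat("  per-class AP50:",
      paste(formatC(x$per_class_ap, digits = 4, format = "f"),
            collapse = ", "), "\n")
  cat("  P/R at max-F1:", formatC(x$precision, digits = 4, format = "f"),
      "/", formatC(x$recall, digits = 4, format = "f"),
      " (conf ", formatC(x$f1_conf, digits = 3, format = "f"), ")\n",
      sep = "")
  invisible(x)
}

#' Plot per-class precision-recall curves
#'
#' @param report an `eval_report`.
#' @param class_names optional class names for the legend.
#' @export
plot_pr_curves <- function(report, class_names = NULL) {
  n <- length(report$curves)
  cols <- grDevices::hcl.colors(max(n, 2L), "Dark 3")
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "Recall", ylab = "Precision",
                 main = "Precision-recall (IoU 0.5)")
  for (i in seq_len(n)) {
    cu <- report$curves[[i]]
    if (length(cu$recall) > 0)
      graphics::lines(c(0, cu$recall), c(1, cu$precision), col = cols[i],
                      lwd = 2, type = "s")
  }
  lab <- if (is.null(class_names)) paste("class", seq_len(n) - 1L)
         else class_names
  graphics::legend("bottomleft", legend = sprintf(
    "%s (AP %.3f)", lab, report$per_class_ap), col = cols[seq_len(n)],
    lwd = 2, bty = "n")
  invisible(report)
}
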