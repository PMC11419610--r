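#' IoU-family bounding-box losses (IoU, CIoU, Wise-IoU v1/v3)
#'
#' Boxes are length-4 numerics `c(x, y, w, h)` in continuous center form
#' (any consistent unit). Wise-IoU v1 scales the IoU loss by an exponential
#' center-distance factor computed against the smallest enclosing box;
#' v3 further multiplies by a dynamic non-monotonic focusing gain
#' `r = beta * alpha^(delta - beta)` driven by the "outlier degree"
#' `beta` — the ratio of a sample's instantaneous IoU loss to a
#' momentum-averaged running mean. Average-quality anchors get the largest
#' gain; extreme outliers (typically mislabeled boxes) are down-weighted,
#' which is what makes the loss robust to low-quality annotations.
#'
#' @name losses
NULL

as_box <- function(b) {
  b <- as.numeric(b)
  if (length(b) != 4L) stop("box must be c(x, y, w, h)")
  if (b[3] <= 0 || b[4] <= 0) stop("degenerate box: w and h must be > 0")
  b
}

#' Intersection over union of two center-form boxes
#'
#' @param a,b boxes `c(x, y, w, h)`, positive sizes.
#' @return IoU in `[0, 1]`; symmetric in its arguments.
#' @export
iou <- function(a, b) {
  a <- as_box(a); b <- as_box(b)
  ix <- pmax(0, pmin(a[1] + a[3] / 2, b[1] + b[3] / 2) -
               pmax(a[1] - a[3] / 2, b[1] - b[3] / 2))
  iy <- pmax(0, pmin(a[2] + a[4] / 2, b[2] + b[4] / 2) -
               pmax(a[2] - a[4] / 2, b[2] - b[4] / 2))
  inter <- ix * iy
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

#' IoU loss `1 - IoU`
#' @inheritParams iou
#' @return loss in `[0, 1]`.
#' @export
l_iou <- function(a, b) 1 - iou(a, b)

enclosing_wh <- function(a, b) {
  c(w = max(a[1] + a[3] / 2, b[1] + b[3] / 2) -
      min(a[1] - a[3] / 2, b[1] - b[3] / 2),
    h = max(a[2] + a[4] / 2, b[2] + b[4] / 2) -
      min(a[2] - a[4] / 2, b[2] - b[4] / 2))
}

#' Complete-IoU loss (baseline)
#'
#' `L_IoU` plus the normalized center distance (squared center offset over
#' squared enclosing-box diagonal) and an aspect-ratio consistency penalty
#' `alpha * v` with `v = 4/pi^2 (atan(w_t/h_t) - atan(w/h))^2`,
#' `alpha = v / (1 - IoU + v)`.
#'
#' @param pred,target boxes `c(x, y, w, h)`.
#' @return non-negative loss; 0 iff the boxes are identical.
#' @export
ciou <- function(pred, target) {
  pred <- as_box(pred); target <- as_box(target)
  i <- iou(pred, target)
  e <- enclosing_wh(pred, target)
  rho2 <- (pred[1] - target[1])^2 + (pred[2] - target[2])^2
  c2 <- e["w"]^2 + e["h"]^2
  v <- 4 / pi^2 * (atan(target[3] / target[4]) - atan(pred[3] / pred[4]))^2
  av <- if (v > 0) v^2 / (1 - i + v) else 0
  unname((1 - i) + rho2 / c2 + av)
}

#' Wise-IoU distance factor
#'
#' `R_WIoU = exp(((x - x_t)^2 + (y - y_t)^2) / (w_c^2 + h_c^2))` with
#' `(w_c, h_c)` the enclosing-box sides; the denominator is treated as a
#' constant in gradient computations (see [wiou_grad()]). Always `>= 1`,
#' with equality iff the centers coincide.
#'
#' @inheritParams ciou
#' @return factor `>= 1`.
#' @export
r_wiou <- function(pred, target) {
  pred <- as_box(pred); target <- as_box(target)
  e <- enclosing_wh(pred, target)
  denom <- e["w"]^2 + e["h"]^2
  if (denom <= 0) stop("zero enclosing box")
  unname(exp(((pred[1] - target[1])^2 + (pred[2] - target[2])^2) / denom))
}

#' Wise-IoU v1 loss
#'
#' `L_WIoUv1 = R_WIoU * L_IoU`; zero iff the boxes are identical, and never
#' below `L_IoU`.
#'
#' @inheritParams ciou
#' @return non-negative loss.
#' @export
wiou_v1 <- function(pred, target) r_wiou(pred, target) * l_iou(pred, target)

#' Running state for Wise-IoU v3
#'
#' Holds the momentum-averaged IoU loss (excluded from gradient flow) and
#' the focusing hyperparameters. The running mean is initialized lazily to
#' the first observed loss, so the first outlier degree is 1.
#'
#' @param alpha focusing base (> 1), default 1.9.
#' @param delta focusing offset (> 0), default 3.
#' @param momentum running-mean momentum in `(0, 1]`, default 0.01.
#' @return an environment with fields `alpha`, `delta`, `momentum`, `mean`.
#' @export
wiou_state <- function(alpha = 1.9, delta = 3, momentum = 0.01) {
  stopifnot(alpha > 1, delta > 0, momentum > 0, momentum <= 1)
  e <- new.env(parent = emptyenv())
  e$alpha <- alpha; e$delta <- delta; e$momentum <- momentum
  e$mean <- NA_real_
  e
}

#' Outlier degree of a sample
#'
#' `beta = L_IoU / mean(L_IoU)`, the instantaneous (detached) IoU loss over
#' the momentum running mean; the running mean is updated after the read:
#' `mean <- (1 - m) mean + m L_IoU`. With `literal = TRUE` the printed
#' instantaneous ratio is used instead (identically 1; kept for reference).
#'
#' @param liou_value instantaneous IoU loss in `[0, 1]`.
#' @param state a [wiou_state()].
#' @param update whether to update the running mean (default `TRUE`).
#' @param literal use the degenerate instantaneous/instantaneous ratio.
#' @return `beta >= 0`.
#' @export
outlier_degree <- function(liou_value, state, update = TRUE,
                           literal = FALSE) {
  if (is.na(state$mean)) state$mean <- liou_value
  beta <- if (literal) 1 else liou_value / max(state$mean, 1e-8)
  if (update)
    state$mean <- (1 - state$momentum) * state$mean +
      state$momentum * liou_value
  beta
}

#' Non-monotonic focusing gain
#'
#' `r = beta * alpha^(delta - beta)`: zero at `beta = 0`, equal to `delta`
#' at `beta = delta`, maximal at `beta = 1/log(alpha)`, and decaying to zero
#' as `beta` grows — extreme outliers receive smaller gain than
#' average-quality anchors.
#'
#' @param beta outlier degree (>= 0).
#' @param alpha focusing base (> 1).
#' @param delta focusing offset (> 0).
#' @return gain `r >= 0`.
#' @export
focusing_gain <- function(beta, alpha = 1.9, delta = 3) {
  stopifnot(all(beta >= 0), alpha > 1, delta > 0)
  beta * alpha^(delta - beta)
}

#' Wise-IoU v3 loss
#'
#' `L_WIoUv3 = r * L_WIoUv1` with the gain `r` computed from the detached
#' outlier degree; gradients flow only through `L_WIoUv1`.
#'
#' @inheritParams ciou
#' @param state a [wiou_state()]; its running mean is read and updated.
#' @param literal_eq16 use the degenerate instantaneous outlier ratio.
#' @return non-negative loss.
#' @export
wiou_v3 <- function(pred, target, state, literal_eq16 = FALSE) {
  li <- l_iou(pred, target)
  beta <- outlier_degree(li, state, literal = literal_eq16)
  focusing_gain(beta, state$alpha, state$delta) * r_wiou(pred, target) * li
}

# loss with detachment semantics frozen: the enclosing-diagonal denominator
# (and, for v3, the focusing gain) are held at their base-point values
frozen_loss_fn <- function(loss, pred0, target, state = NULL) {
  switch(loss,
    iou = function(p) l_iou(p, target),
    ciou = function(p) ciou(p, target),
    wiou1 = {
      e <- enclosing_wh(pred0, target)
      denom <- e["w"]^2 + e["h"]^2
      function(p) unname(exp(((p[1] - target[1])^2 + (p[2] - target[2])^2) /
                               denom)) * l_iou(p, target)
    },
    wiou3 = {
      e <- enclosing_wh(pred0, target)
      denom <- e["w"]^2 + e["h"]^2
      li0 <- l_iou(pred0, target)
      beta <- outlier_degree(li0, state, update = FALSE)
      r <- focusing_gain(beta, state$alpha, state$delta)
      function(p) r * unname(exp(((p[1] - target[1])^2 +
                                    (p[2] - target[2])^2) / denom)) *
        l_iou(p, target)
    },
    stop("unknown loss: ", loss))
}

#' Gradient of a box loss with Wise-IoU detachment semantics
#'
#' Central finite differences of the loss with its detached quantities (the
#' enclosing-box denominator of the distance factor; the v3 focusing gain)
#' frozen at the evaluation point, which reproduces the gradient the
#' training recurrences prescribe. For `wiou3`, reading the gradient also
#' updates `state`'s running mean once.
#'
#' @param pred,target boxes `c(x, y, w, h)`.
#' @param loss one of `"iou"`, `"ciou"`, `"wiou1"`, `"wiou3"`.
#' @param state [wiou_state()] (required for `"wiou3"`).
#' @param eps finite-difference step.
#' @return length-4 gradient with respect to `pred`.
#' @export
wiou_grad <- function(pred, target, loss = "wiou1", state = NULL,
                      eps = 1e-5) {
  pred <- as_box(pred); target <- as_box(target)
  f <- frozen_loss_fn(loss, pred, target, state)
  g <- numeric(4)
  for (i in 1:4) {
    hi <- pred; hi[i] <- hi[i] + eps
    lo <- pred; lo[i] <- lo[i] - eps
    g[i] <- (f(hi) - f(lo)) / (2 * eps)
  }
  if (loss == "wiou3")
    outlier_degree(l_iou(pred, target), state, update = TRUE)
  g
}

#' Shared-model box-regression robustness simulation
#'
#' Random anchors descend on fixed targets through a *shared* linear
#' correction model, a seeded fraction of the targets being corrupted by
#' large jitter (emulating low-quality annotations). Each anchor `i` is the
#' true box displaced by a systematic, feature-dependent error
#' `phi_i W*` plus small noise; a shared weight matrix `W` (zero-init)
#' learns to undo that error by full-batch gradient descent on the selected
#' box loss. Because `W` is shared, misdirected gradients from corrupted
#' targets pollute every prediction — the mechanism a shared-weight
#' detector suffers from, and the one a dynamically focused loss is built
#' to resist. Loss functions differ in overall gradient scale, so the step
#' size is normalized once by the first-step RMS gradient, making the
#' comparison across losses one of equal steps in a common metric. The
#' corrupted set has exactly `round(corrupt_frac * n_anchors)` members (a
#' fixed corruption rate, not a Bernoulli draw). The score is the median
#' IoU error `1 - IoU` of predictions against the *clean* targets,
#' averaged over the last `tail` steps — the equilibrium error level of the
#' descent, including its oscillation, which is where suppressing the
#' large gradients of corrupted samples pays off.
#'
#' @param loss `"ciou"`, `"wiou1"`, `"wiou3"` or `"iou"`.
#' @param n_anchors number of anchor/target pairs.
#' @param n_features dimension of the random anchor features.
#' @param corrupt_frac fraction of targets corrupted.
#' @param jitter corruption magnitude (relative).
#' @param steps gradient steps.
#' @param lr base learning rate (normalized by the first-step RMS
#'   gradient).
#' @param noise_sd anchor noise floor (absolute, normalized units).
#' @param tail number of final steps the error is averaged over.
#' @param seed RNG seed (targets, features, corruption).
#' @param state_args hyperparameters passed to [wiou_state()].
#' @return list with `median_clean_error` (tail-averaged), `errors`
#'   (per-anchor, final step), `corrupted` flags.
#' @export
box_regression_sim <- function(loss = "wiou3", n_anchors = 50L,
                               n_features = 8L, corrupt_frac = 0.1,
                               jitter = 0.8, steps = 400L, lr = 1e-3,
                               noise_sd = 0.003, tail = 50L, seed = 1L,
                               state_args = list()) {
  p <- n_features; n <- n_anchors
  dat <- with_seed(seed, {
    targets <- cbind(x = stats::runif(n, 0.25, 0.75),
                     y = stats::runif(n, 0.25, 0.75),
                     w = stats::runif(n, 0.1, 0.3),
                     h = stats::runif(n, 0.1, 0.3))
    phi <- matrix(stats::rnorm(n * p), n, p)
    w_true <- cbind(matrix(stats::rnorm(p * 2, sd = 0.08 / sqrt(p)), p, 2),
                    matrix(stats::rnorm(p * 2, sd = 0.04 / sqrt(p)), p, 2))
    anchors <- targets + phi %*% w_true +
      matrix(stats::rnorm(n * 4, sd = noise_sd), n, 4)
    anchors[, 3:4] <- pmax(anchors[, 3:4], 0.02)
    corrupted <- logical(n)
    corrupted[sample.int(n, round(corrupt_frac * n))] <- TRUE
    observed <- targets
    k <- sum(corrupted)
    if (k > 0) {
      observed[corrupted, "x"] <- observed[corrupted, "x"] +
        stats::rnorm(k, sd = jitter) * observed[corrupted, "w"]
      observed[corrupted, "y"] <- observed[corrupted, "y"] +
        stats::rnorm(k, sd = jitter) * observed[corrupted, "h"]
      observed[corrupted, "w"] <- pmax(observed[corrupted, "w"] *
        exp(stats::rnorm(k, sd = jitter)), 0.02)
      observed[corrupted, "h"] <- pmax(observed[corrupted, "h"] *
        exp(stats::rnorm(k, sd = jitter)), 0.02)
    }
    list(targets = targets, observed = observed, corrupted = corrupted,
         anchors = anchors, phi = phi)
  })
  predict_i <- function(W, i) {
    pr <- dat$anchors[i, ] - as.vector(dat$phi[i, ] %*% W)
    pr[3:4] <- pmax(pr[3:4], 1e-3)
    pr
  }
  clean_median <- function(W) {
    errs <- vapply(seq_len(n), function(i)
      1 - iou(predict_i(W, i), dat$targets[i, ]), numeric(1))
    stats::median(errs[!dat$corrupted])
  }
  W <- matrix(0, p, 4)
  state <- do.call(wiou_state, state_args)
  lr_eff <- NULL
  trace <- numeric(0)
  for (s in seq_len(steps)) {
    gW <- matrix(0, p, 4)
    for (i in seq_len(n)) {
      g <- wiou_grad(predict_i(W, i), dat$observed[i, ], loss = loss,
                     state = state)
      gW <- gW - outer(dat$phi[i, ], g)
    }
    gW <- gW / n
    if (is.null(lr_eff)) lr_eff <- lr / sqrt(mean(gW^2))
    W <- W - lr_eff * gW
    if (s > steps - tail) trace <- c(trace, clean_median(W))
  }
  errs <- vapply(seq_len(n), function(i)
    1 - iou(predict_i(W, i), dat$targets[i, ]), numeric(1))
  list(median_clean_error = mean(trace),
       errors = errs, corrupted = dat$corrupted)
}
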