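#' SimAM: parameter-free energy-based attention
#'
#' Every feature element `t` of a channel is scored by the energy
#' `E(t) = 4 (sigma^2 + lambda)^2 / ((t - mu)^2 + 2 sigma^2 + 2 lambda)`,
#' where `mu` and `sigma^2` are the channel mean and biased variance over
#' its `M = W x H` elements. Low energy marks elements that stand out from
#' their channel; the attention output is `sigmoid(1/E) * X`, a full 3-D
#' weighting that adds zero learnable parameters.
#'
#' @name attention
NULL

simam_moments <- function(ch, exclude_self) {
  M <- length(ch)
  if (!exclude_self || M == 1L) {
    mu <- mean(ch)
    list(mu = mu, var = mean((ch - mu)^2))
  } else {
    # leave-one-out moments per element
    s <- sum(ch); s2 <- sum(ch^2)
    mu <- (s - ch) / (M - 1)
    list(mu = mu, var = (s2 - ch^2) / (M - 1) - mu^2)
  }
}

#' Per-element SimAM energy
#'
#' @param x `H x W x C` array.
#' @param lambda regularizer (default 1e-4).
#' @param exclude_self if `TRUE`, compute each element's channel moments
#'   excluding the element itself (leave-one-out); default `FALSE` sums over
#'   all `M` elements.
#' @return array of strictly positive energies, same shape as `x`.
#' @export
simam_energy <- function(x, lambda = 1e-4, exclude_self = FALSE) {
  stopifnot(lambda > 0)
  d <- dim(x)
  out <- array(0, d)
  for (ch in seq_len(d[3])) {
    v <- x[, , ch]
    m <- simam_moments(as.vector(v), exclude_self)
    out[, , ch] <- 4 * (m$var + lambda)^2 /
      ((as.vector(v) - m$mu)^2 + 2 * m$var + 2 * lambda)
  }
  out
}

#' SimAM attention operator
#'
#' `X_hat = sigmoid(1 / E) * X` elementwise; shape-preserving and
#' parameter-free.
#'
#' @inheritParams simam_energy
#' @return weighted array, same shape as `x`.
#' @export
simam <- function(x, lambda = 1e-4, exclude_self = FALSE) {
  sigmoid(1 / simam_energy(x, lambda, exclude_self)) * x
}
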