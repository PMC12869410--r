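#' Fourier ring correlation loss
#'
#' Negative mean, over Fourier rings `1 <= r <= max_freq`, of the
#' normalized real cross-correlation between predicted and observed
#' coefficients:
#' `loss = -mean_r Re<P_r, O_r> / (||P_r|| * ||O_r|| + eps)`.
#' The loss is bounded in `[-1, 1]`, equals -1 when the prediction matches
#' the observation up to a positive per-ring scale, and is invariant to
#' per-ring positive rescaling of either argument. Rings where either
#' argument is identically zero contribute 0. The DC ring carries no
#' correlation information and is excluded.
#'
#' @param predicted,observed Complex half-plane matrices of equal shape
#'   (see [fourier_from_image()]).
#' @param max_freq Highest ring (cycles/box) included; defaults to Nyquist.
#' @return A single number in `[-1, 1]`.
#' @export
frc_loss <- function(predicted, observed, max_freq = NULL) {
  D <- ncol(predicted)
  stopifnot(identical(dim(predicted), dim(observed)))
  if (is.null(max_freq)) max_freq <- D / 2
  stopifnot(max_freq <= D / 2)
  m <- ring_mask(D, max_freq)
  frc_loss_masked(predicted[m$idx], observed[m$idx], m$ring)$loss
}

# Masked FRC loss with gradient w.r.t. the predicted coefficients.
# P, O complex vectors over the mask; ring integer ring id per entry.
frc_loss_masked <- function(P, O, ring, eps = 1e-12) {
  rf <- factor(ring)
  n <- rowsum(Re(P * Conj(O)), rf)[, 1]
  p <- rowsum(Re(P)^2 + Im(P)^2, rf)[, 1]
  o <- rowsum(Re(O)^2 + Im(O)^2, rf)[, 1]
  den <- sqrt(p * o) + eps
  cc <- n / den
  R <- length(cc)
  loss <- -mean(cc)
  grad <- function() {
    # dloss/dP as gbar = dL/dRe(P) + i dL/dIm(P), expanded to entries
    live <- p > 0 & o > 0
    g1 <- ifelse(live, 1 / den, 0) / R
    g2 <- ifelse(live, n * o / (sqrt(pmax(p * o, eps)) * den^2), 0) / R
    ir <- as.integer(rf)
    -(O * g1[ir] - P * g2[ir])
  }
  list(loss = loss, cc = cc, grad = grad)
}
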