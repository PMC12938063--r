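#' Combined Dice + binary cross-entropy loss
#'
#' The segmentation loss balances region overlap (soft Dice) against
#' per-pixel classification confidence (BCE):
#' `loss = w_dice * (1 - softDice) + w_bce * meanBCE`, with
#' `softDice = (2 * sum(p*t) + eps) / (sum(p) + sum(t) + eps)`.
#' Probabilities are clipped away from 0 and 1 before the logarithm.
#'
#' @param prob Matrix of per-pixel probabilities in \[0, 1\].
#' @param target Binary matrix of the same shape.
#' @param eps Dice smoothing constant (default 1), which makes the Dice
#'   term 0 when both prediction and target are empty.
#' @param w_dice,w_bce Term weights (default 1 and 1).
#' @param clip Clipping bound for the BCE logarithms.
#' @param gradient If `TRUE`, also return the gradient with respect to the
#'   pre-sigmoid logits (used by the trainer).
#' @return Scalar loss, or a list `(loss, dice, bce, grad_logit)` when
#'   `gradient = TRUE`.
#' @export
dice_bce_loss <- function(prob, target, eps = 1, w_dice = 1, w_bce = 1,
                          clip = 1e-7, gradient = FALSE) {
  if (!all(dim(prob) == dim(target))) stop_aaawall("probability/target shape mismatch")
  p <- pmin(pmax(prob, clip), 1 - clip)
  t <- target
  n <- length(p)
  inter <- sum(p * t); denom <- sum(p) + sum(t) + eps
  soft_dice <- (2 * inter + eps) / denom
  bce <- -mean(t * log(p) + (1 - t) * log(1 - p))
  loss <- w_dice * (1 - soft_dice) + w_bce * bce
  if (!gradient) return(loss)
  # d(softDice)/dp, then chain through the sigmoid: dp/dz = p(1-p);
  # the BCE term collapses to (p - t)/n directly in logit space
  ddice_dp <- (2 * t * denom - (2 * inter + eps)) / denom^2
  grad <- w_dice * (-ddice_dp) * p * (1 - p) + w_bce * (p - t) / n
  list(loss = loss, dice = 1 - soft_dice, bce = bce, grad_logit = grad)
}

#' Hard Dice overlap between a probability map and a mask
#'
#' Thresholds the probabilities and computes `2|A n B| / (|A| + |B|)`;
#' returns 1 when both sets are empty.
#'
#' @param prob Probability matrix.
#' @param target Binary matrix.
#' @param threshold Binarisation threshold (default 0.5).
#' @return Dice coefficient in \[0, 1\].
#' @export
hard_dice <- function(prob, target, threshold = 0.5) {
  a <- prob >= threshold; b <- target > 0.5
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}
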