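#' Segmentation loss functions
#'
#' Reference (framework-agnostic) implementations of the loss families used
#' to train segmentation networks, operating on flat vectors of expected
#' label values `p` and predicted values `phat`, both in \[0, 1\]. Binary
#' masks are the hard special case; probabilistic predictions give the soft
#' ("differentiable") values.
#'
#' `dice_loss()` is
#' \deqn{1 - \frac{2\sum_i p_i \hat p_i + \epsilon}{\sum_i p_i^2 + \sum_i \hat p_i^2 + \epsilon}.}
#'
#' `tversky_loss()` uses soft confusion counts
#' \eqn{TP = \sum p \hat p}, \eqn{FP = \sum (1-p)\hat p},
#' \eqn{FN = \sum p(1-\hat p)} and returns
#' \eqn{1 - (TP+\epsilon)/(TP + \alpha FP + \beta FN + \epsilon)} with
#' \eqn{\alpha + \beta = 1} and \eqn{\beta \ge \alpha}; at
#' \eqn{\alpha = \beta = 0.5} the Tversky index reduces to the Dice
#' similarity coefficient.
#'
#' @param p numeric vector (or, for [generalized_dice_loss()], an N x K
#'   matrix with one column per class) of expected label values in \[0, 1\].
#' @param phat predicted values, same shape as `p`, in \[0, 1\].
#' @param eps smoothing constant added to numerator and denominator
#'   (default `1e-6`).
#' @return A single numeric loss value in \[0, 1\].
#' @examples
#' dice_loss(c(1, 1, 0, 0), c(1, 0, 0, 0))        # ~ 1/3
#' tversky_loss(c(1, 1, 0, 0), c(1, 0, 1, 0), alpha = 0.1, beta = 0.9)
#' @export
dice_loss <- function(p, phat, eps = 1e-6) {
  check_loss_inputs(p, phat)
  1 - (2 * sum(p * phat) + eps) / (sum(p^2) + sum(phat^2) + eps)
}

#' @rdname dice_loss
#' @param weighting `"prediction"` uses per-class weights
#'   \eqn{w_l = 1/\sum_n \hat p_{ln}} (the form printed with the generalized
#'   Dice loss used here); `"squared_gt"` uses the conventional
#'   generalized-Dice weight \eqn{w_l = 1/(\sum_n p_{ln})^2}.
#' @export
generalized_dice_loss <- function(p, phat,
                                  weighting = c("prediction", "squared_gt")) {
  weighting <- match.arg(weighting)
  if (is.null(dim(p))) p <- matrix(p, ncol = 1)
  if (is.null(dim(phat))) phat <- matrix(phat, ncol = 1)
  check_loss_inputs(p, phat)
  K <- ncol(p)
  num <- 0; den <- 0; n_used <- 0L
  for (l in seq_len(K)) {
    wden <- if (weighting == "prediction") sum(phat[, l]) else sum(p[, l])^2
    if (wden == 0) {
      warning(sprintf("class %d has zero weight denominator; it contributes 0", l))
      next
    }
    w <- 1 / wden
    num <- num + w * sum(p[, l] * phat[, l])
    den <- den + w * sum(p[, l] + phat[, l])
    n_used <- n_used + 1L
  }
  if (n_used == 0L || den == 0)
    stop("generalized Dice loss undefined: all classes empty", call. = FALSE)
  1 - 2 * num / den
}

#' @rdname dice_loss
#' @param alpha false-positive weight of the Tversky index.
#' @param beta false-negative weight; `alpha + beta` must equal 1 (within
#'   1e-12) with `beta >= alpha`.
#' @export
tversky_loss <- function(p, phat, alpha, beta = 1 - alpha, eps = 1e-6) {
  check_loss_inputs(p, phat)
  if (abs(alpha + beta - 1) > 1e-12)
    stop("Tversky weights must satisfy alpha + beta = 1", call. = FALSE)
  if (beta < alpha - 1e-12)
    stop("Tversky weights must satisfy beta >= alpha (false negatives weighted at least as much as false positives)",
         call. = FALSE)
  tp <- sum(p * phat)
  fp <- sum((1 - p) * phat)
  fn <- sum(p * (1 - phat))
  1 - (tp + eps) / (tp + alpha * fp + beta * fn + eps)
}

#' Named Tversky weight presets
#'
#' The four `(alpha, beta)` grid points commonly swept when weighting false
#' negatives more than false positives: `TL46 = (0.4, 0.6)`,
#' `TL37 = (0.3, 0.7)`, `TL28 = (0.2, 0.8)`, `TL19 = (0.1, 0.9)`.
#'
#' @return A named list of `c(alpha =, beta =)` pairs.
#' @examples
#' w <- tversky_presets()$TL19
#' tversky_loss(c(1, 0), c(1, 0), alpha = w["alpha"], beta = w["beta"])
#' @export
tversky_presets <- function() {
  list(TL46 = c(alpha = 0.4, beta = 0.6),
       TL37 = c(alpha = 0.3, beta = 0.7),
       TL28 = c(alpha = 0.2, beta = 0.8),
       TL19 = c(alpha = 0.1, beta = 0.9))
}

check_loss_inputs <- function(p, phat) {
  if (length(p) != length(phat))
    stop("expected and predicted inputs must have equal length", call. = FALSE)
  if (length(p) == 0) stop("empty loss inputs", call. = FALSE)
  rng <- range(p, phat)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 1)
    stop("loss inputs must lie in [0, 1]", call. = FALSE)
  invisible(TRUE)
}
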