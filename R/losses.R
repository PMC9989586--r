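# Combined binary cross-entropy + Dice training objective and the
# differentiable loss node used by the training loop.

#' Loss configuration
#'
#' @param alpha,beta Non-negative weights of the BCE and Dice terms
#'   (`alpha * L_BCE + beta * L_Dice`); both default to 0.5.
#' @param epsilon Smoothing constant of the Dice term (default `1e-6`).
#' @param dice_form `"conventional"` uses `1 - (2*sum(yp)+eps)/(sum(y)+sum(p)+eps)`
#'   so a perfect prediction scores 0; `"printed"` omits the factor 2
#'   (`1 - (sum(yp)+eps)/(sum(y+p)+eps)`), which tends to 0.5 for a
#'   perfect prediction on a large mask.
#' @param bce_reduce `"mean"` (default) averages the per-pixel BCE so the
#'   term stays commensurate with the Dice term at any resolution;
#'   `"sum"` keeps the raw per-pixel sum.
#' @return List of class `gu_loss_config`.
#' @export
loss_config <- function(alpha = 0.5, beta = 0.5, epsilon = 1e-6,
                        dice_form = c("conventional", "printed"),
                        bce_reduce = c("mean", "sum")) {
  stopifnot(alpha >= 0, beta >= 0, epsilon > 0)
  structure(list(alpha = alpha, beta = beta, epsilon = epsilon,
                 dice_form = match.arg(dice_form),
                 bce_reduce = match.arg(bce_reduce)),
            class = "gu_loss_config")
}

clip_prob <- function(p) pmin(pmax(p, 1e-7), 1 - 1e-7)

#' Binary cross-entropy loss
#'
#' Mean (or sum) over pixels of `-(y log p + (1-y) log(1-p))`, with `p`
#' clipped to `[1e-7, 1 - 1e-7]` before the logarithms.
#'
#' @param y Binary ground-truth array/vector.
#' @param p Predicted probabilities, same shape as `y`.
#' @param reduce `"mean"` (default) or `"sum"`.
#' @return A single number.
#' @export
bce_loss <- function(y, p, reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  if (length(y) != length(p))
    stop("bce_loss: y and p must have the same shape")
  pc <- clip_prob(p)
  s <- -sum(y * log(pc) + (1 - y) * log(1 - pc))
  if (reduce == "mean") s / length(y) else s
}

#' Dice loss
#'
#' @inheritParams bce_loss
#' @param config A [loss_config()]; `epsilon` and `dice_form` are used.
#' @return A single number.
#' @export
dice_loss <- function(y, p, config = loss_config()) {
  if (length(y) != length(p))
    stop("dice_loss: y and p must have the same shape")
  eps <- config$epsilon
  if (config$dice_form == "conventional") {
    1 - (2 * sum(y * p) + eps) / (sum(y) + sum(p) + eps)
  } else {
    1 - (sum(y * p) + eps) / (sum(y + p) + eps)
  }
}

#' Combined segmentation loss
#'
#' `alpha * L_BCE + beta * L_Dice` with the defaults `alpha = beta = 0.5`,
#' `epsilon = 1e-6`.
#'
#' @inheritParams dice_loss
#' @return A single number.
#' @export
total_loss <- function(y, p, config = loss_config()) {
  config$alpha * bce_loss(y, p, config$bce_reduce) +
    config$beta * dice_loss(y, p, config)
}

# Differentiable loss node: BCE reduced over the whole batch, Dice
# computed per sample and averaged (matching per-image evaluation).
n_seg_loss <- function(p, y, cfg = loss_config()) {
  pv <- p$value
  d <- dim(pv)
  N <- d[4]
  pc <- clip_prob(pv)
  nb <- if (cfg$bce_reduce == "mean") length(pv) else 1
  bce <- -sum(y * log(pc) + (1 - y) * log(1 - pc)) / nb
  dbce <- (-(y / pc) + (1 - y) / (1 - pc)) / nb
  eps <- cfg$epsilon
  dice <- 0
  ddice <- array(0, d)
  for (n in seq_len(N)) {
    ys <- y[, , , n]
    ps <- pv[, , , n]
    if (cfg$dice_form == "conventional") {
      num <- 2 * sum(ys * ps) + eps
      den <- sum(ys) + sum(ps) + eps
      dd <- -(2 * ys * den - num) / den^2
    } else {
      num <- sum(ys * ps) + eps
      den <- sum(ys + ps) + eps
      dd <- -(ys * den - num) / den^2
    }
    dice <- dice + (1 - num / den) / N
    ddice[, , , n] <- dd / N
  }
  val <- cfg$alpha * bce + cfg$beta * dice
  grad_p <- cfg$alpha * dbce + cfg$beta * ddice
  node <- gu_node(val, list(p), function(g) list(g * grad_p))
  node$bce <- bce
  node$dice <- dice
  node
}
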