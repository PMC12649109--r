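# Training objectives: pixel BCE, recall-biased Tversky, their composite,
# the differentiable morphological-gradient edge target, and the weighted
# total. All losses pool pixels over the whole batch and are permutation
# invariant. Probabilities are clamped at 1e-7 before logs.

PROB_CLAMP <- 1e-7

#' Build loss hyperparameters
#'
#' Defaults: Tversky alpha 0.3 (false-positive weight) and beta 0.7
#' (false-negative weight) — the asymmetry that biases training towards
#' recall — epsilon 1e-6, composite mixing 0.3 BCE + 0.7 Tversky, and branch
#' weights 1.0 (segmentation) and 0.4 (edge).
#'
#' @param alpha,beta Tversky FP/FN weights.
#' @param epsilon smoothing constant.
#' @param wBce,wTversky composite mixing weights (sum to 1).
#' @param wHisto,wEdge branch weights of the total objective.
#' @return a \code{LossWeights}.
#' @export
lossWeights <- function(alpha = 0.3, beta = 0.7, epsilon = 1e-6,
                        wBce = 0.3, wTversky = 0.7, wHisto = 1.0,
                        wEdge = 0.4) {
  new("LossWeights", alpha = alpha, beta = beta, epsilon = epsilon,
      wBce = wBce, wTversky = wTversky, wHisto = wHisto, wEdge = wEdge)
}

checkShapes <- function(pred, target) {
  if (!identical(dim(pred), dim(target)) || length(pred) != length(target))
    stop("prediction and target shapes differ")
}

#' Binary cross-entropy over all pixels
#'
#' Mean negative log-likelihood \code{-1/N sum(y log p + (1-y) log(1-p))}
#' with probabilities clamped to [1e-7, 1 - 1e-7].
#'
#' @param pred probability raster (any shape).
#' @param target binary raster of the same shape.
#' @return scalar loss.
#' @export
bceLoss <- function(pred, target) {
  checkShapes(pred, target)
  p <- clamp(pred, PROB_CLAMP, 1 - PROB_CLAMP)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

#' Tversky loss with asymmetric error weighting
#'
#' Soft counts pooled over the batch: TP = sum(p y), FP = sum(p (1-y)),
#' FN = sum((1-p) y); loss = 1 - (TP+eps) / (TP + alpha FP + beta FN + eps).
#' With beta > alpha a missed positive costs more than a false alarm, so the
#' gradient pushes recall up.
#'
#' @param pred probability raster.
#' @param target binary raster.
#' @param w a \code{LossWeights}.
#' @return scalar in [0,1].
#' @export
tverskyLoss <- function(pred, target, w = lossWeights()) {
  checkShapes(pred, target)
  tp <- sum(pred * target)
  fp <- sum(pred * (1 - target))
  fn <- sum((1 - pred) * target)
  1 - (tp + w@epsilon) / (tp + w@alpha * fp + w@beta * fn + w@epsilon)
}

#' Composite recall-prioritised segmentation loss
#'
#' Weighted sum \code{wBce * BCE + wTversky * Tversky} (defaults 0.3/0.7):
#' BCE stabilises the probability field, the Tversky term drives recall.
#'
#' @inheritParams tverskyLoss
#' @return scalar loss.
#' @export
histoLoss <- function(pred, target, w = lossWeights()) {
  w@wBce * bceLoss(pred, target) + w@wTversky * tverskyLoss(pred, target, w)
}

#' Morphological-gradient edge target
#'
#' \code{Dilate(X) - Erode(X)} with both operators approximated by 3x3
#' stride-1 max pooling (dilate = maxpool(X), erode = 1 - maxpool(1-X)), the
#' differentiable formulation. Out-of-frame pixels count as background for
#' dilation and as foreground for erosion, so a mask touching the border
#' produces no spurious border edge; an all-ones mask therefore has no edge.
#'
#' @param mask binary H x W matrix (or B x H x W array).
#' @return binary edge raster of the same shape.
#' @export
edgeTarget <- function(mask) {
  if (!isBinary(mask)) stop("edge target requires a binary mask")
  one <- function(m) {
    dil <- maxpool3x3(m, pad = 0)
    ero <- 1 - maxpool3x3(1 - m, pad = 0)
    dil - ero
  }
  if (is.matrix(mask)) return(one(mask))
  out <- mask
  for (b in seq_len(dim(mask)[1])) out[b, , ] <- one(mask[b, , ])
  out
}

#' Edge-branch BCE loss
#'
#' The same batch-pooled binary cross-entropy estimator as
#' \code{\link{bceLoss}}, applied to edge probability maps against the
#' morphological-gradient target.
#'
#' @param edgePred edge probability raster.
#' @param edgeTgt binary edge raster.
#' @return scalar loss.
#' @export
edgeLoss <- function(edgePred, edgeTgt) bceLoss(edgePred, edgeTgt)

#' Total training objective with component breakdown
#'
#' \code{wHisto * (composite segmentation loss) + wEdge * (edge BCE)}; the
#' edge target is derived internally from the mask. When \code{edgePred} is
#' NULL (edge head disabled) the edge term is dropped.
#'
#' @param pred segmentation probability raster.
#' @param edgePred edge probability raster or NULL.
#' @param target binary mask raster.
#' @param w a \code{LossWeights}.
#' @return list(total, histo, bce, tversky, edge).
#' @export
totalLoss <- function(pred, edgePred, target, w = lossWeights()) {
  b <- bceLoss(pred, target)
  t <- tverskyLoss(pred, target, w)
  h <- w@wBce * b + w@wTversky * t
  e <- if (is.null(edgePred)) 0 else edgeLoss(edgePred, edgeTarget(target))
  list(total = w@wHisto * h + w@wEdge * e, histo = h, bce = b, tversky = t,
       edge = e)
}

# ---- gradients w.r.t. logits (internal, used by the trainer) ----

# d(BCE)/d(logit) for mean-over-N estimator: (p - y) / N
bceGradLogit <- function(pred, target) (pred - target) / length(pred)

# d(Tversky)/d(logit): chain d/dp through the quotient, then p(1-p)
tverskyGradLogit <- function(pred, target, w) {
  tp <- sum(pred * target)
  fp <- sum(pred * (1 - target))
  fn <- sum((1 - pred) * target)
  num <- tp + w@epsilon
  den <- tp + w@alpha * fp + w@beta * fn + w@epsilon
  # dL/dp_i = -( y_i * den - num * (y_i + alpha (1-y_i) - beta y_i) ) / den^2
  dLdp <- -(target * den - num * (target + w@alpha * (1 - target) -
                                    w@beta * target)) / den^2
  dLdp * pred * (1 - pred)
}

segGradLogit <- function(pred, target, w) {
  w@wHisto * (w@wBce * bceGradLogit(pred, target) +
                w@wTversky * tverskyGradLogit(pred, target, w))
}

edgeGradLogit <- function(edgePred, edgeTgt, w) {
  w@wEdge * bceGradLogit(edgePred, edgeTgt)
}
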