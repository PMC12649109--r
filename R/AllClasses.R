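#' @import methods
NULL

#' Configuration for the synthetic paired-stain generator
#'
#' Holds every tunable of the synthetic histology generator: patch geometry,
#' lesion count/size ranges, the DAB (brown chromogen) hue band and the
#' haematoxylin background hue, stain jitter, per-organ style parameters and
#' the base RNG seed. With a fixed seed the generator is bit-reproducible.
#'
#' @slot imageSize integer, side length in pixels of square single-stain patches.
#' @slot nLesions integer length-2, inclusive range of lesion blobs per patch.
#' @slot lesionRadius numeric length-2, lesion radius range in pixels.
#' @slot dabHue numeric length-2, DAB hue band in degrees on the HSV wheel.
#' @slot backgroundHue numeric, haematoxylin/blue background hue in degrees.
#' @slot stainJitter numeric, fractional amplitude of stain intensity jitter.
#' @slot organStyles data.frame with one row per organ (columns \code{organ},
#'   \code{baseIntensity}, \code{textureAmp}, \code{textureScale},
#'   \code{lesionContrast}).
#' @slot roiSize integer length-2 (rows, cols) of generated ROI pairs.
#' @slot seed integer base seed.
#' @exportClass SynthConfig
setClass("SynthConfig", representation(
  imageSize = "integer", nLesions = "integer", lesionRadius = "numeric",
  dabHue = "numeric", backgroundHue = "numeric", stainJitter = "numeric",
  organStyles = "data.frame", roiSize = "integer", seed = "integer"
), validity = function(object) {
  msg <- character()
  if (object@imageSize <= 0L) msg <- c(msg, "imageSize must be > 0")
  if (any(object@dabHue < 0 | object@dabHue >= 360))
    msg <- c(msg, "dabHue must lie in [0, 360)")
  if (object@backgroundHue < 0 || object@backgroundHue >= 360)
    msg <- c(msg, "backgroundHue must lie in [0, 360)")
  if (length(object@nLesions) != 2L || any(object@nLesions < 0L))
    msg <- c(msg, "nLesions must be a non-negative length-2 range")
  if (!all(c("organ", "baseIntensity", "textureAmp", "textureScale",
             "lesionContrast") %in% names(object@organStyles)))
    msg <- c(msg, "organStyles is missing required columns")
  if (length(msg)) msg else TRUE
})

#' A synthetic paired-stain sample
#'
#' One synthetic histology patch: pseudo-H&E rendering, pseudo-IHC rendering
#' (DAB chromogen confined to lesion pixels), binary ground-truth mask, organ
#' label and integer id.
#'
#' @slot he numeric H x W x 3 RGB array in [0,1].
#' @slot ihc numeric H x W x 3 RGB array in [0,1].
#' @slot mask numeric H x W matrix with values in {0,1}.
#' @slot organ character organ name.
#' @slot id integer sample id.
#' @exportClass SynthSample
setClass("SynthSample", representation(
  he = "array", ihc = "array", mask = "matrix", organ = "character",
  id = "integer"
), validity = function(object) {
  msg <- character()
  if (!isBinary(object@mask)) msg <- c(msg, "mask must be binary")
  d <- dim(object@mask)
  if (!identical(dim(object@he)[1:2], d) || !identical(dim(object@ihc)[1:2], d))
    msg <- c(msg, "he/ihc/mask must share H x W")
  if (length(msg)) msg else TRUE
})

#' A synthetic misaligned region-of-interest stain pair
#'
#' A pseudo-H&E ROI with its ground-truth lesion mask, plus a pseudo-IHC ROI
#' displaced by the inverse of a known rigid transform. Applying
#' \code{trueTransform} with \code{\link{alignPair}} superimposes the IHC DAB
#' signal back onto the mask.
#'
#' @slot he numeric RGB array (H&E ROI).
#' @slot ihc numeric RGB array (misaligned IHC ROI).
#' @slot mask numeric binary matrix aligned to \code{he}.
#' @slot trueTransform named numeric (deg, dx, dy).
#' @exportClass SynthROIPair
setClass("SynthROIPair", representation(
  he = "array", ihc = "array", mask = "matrix", trueTransform = "numeric"
), validity = function(object) {
  if (!all(c("deg", "dx", "dy") %in% names(object@trueTransform)))
    return("trueTransform must be named (deg, dx, dy)")
  if (!isBinary(object@mask)) return("mask must be binary")
  TRUE
})

#' Configuration of the DAB mask generators
#'
#' Thresholds and morphology settings shared by the HSV-gate and
#' stain-deconvolution (HED) mask generators: the DAB hue band, the excluded
#' haematoxylin blue band, saturation/value gates, Gaussian smoothing sigma,
#' minimum connected-component area and opening/closing radii.
#'
#' @slot hueBand numeric length-2, kept DAB hue band (degrees).
#' @slot blueBand numeric length-2, excluded background hue band (degrees).
#' @slot satMin numeric, minimum HSV saturation.
#' @slot valMax numeric, maximum HSV value.
#' @slot gaussianSigma numeric, blur sigma in pixels before Otsu.
#' @slot minArea numeric, components smaller than this (pixels) are dropped.
#' @slot openRadius,closeRadius numeric, structuring-element radii in pixels.
#' @slot fillHoles logical, fill enclosed holes in the HED mask.
#' @exportClass MaskGenConfig
setClass("MaskGenConfig", representation(
  hueBand = "numeric", blueBand = "numeric", satMin = "numeric",
  valMax = "numeric", gaussianSigma = "numeric", minArea = "numeric",
  openRadius = "numeric", closeRadius = "numeric", fillHoles = "logical"
), validity = function(object) {
  msg <- character()
  if (any(c(object@hueBand, object@blueBand) < 0) ||
      any(c(object@hueBand, object@blueBand) >= 360))
    msg <- c(msg, "hue bands must lie in [0, 360)")
  if (object@minArea < 0) msg <- c(msg, "minArea must be >= 0")
  if (object@openRadius < 0 || object@closeRadius < 0)
    msg <- c(msg, "morphology radii must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A candidate DAB mask
#'
#' Binary mask produced by one of the two weak-label generators, tagged with
#' the method that produced it.
#'
#' @slot mask numeric binary matrix.
#' @slot method character, "HSV" or "HED".
#' @exportClass CandidateMask
setClass("CandidateMask", representation(
  mask = "matrix", method = "character"
), validity = function(object) {
  if (!object@method %in% c("HSV", "HED")) return("method must be HSV or HED")
  if (!isBinary(object@mask)) return("mask must be binary")
  TRUE
})

#' A dataset record: image, mask and metadata
#'
#' One sample of the training corpus: raster image (RGB or greyscale), binary
#' mask, the \code{human_\{organ\}_\{id\}} filename convention, organ label,
#' source id, split assignment and augmentation tag.
#'
#' @slot filename character.
#' @slot image numeric array (H x W or H x W x 3) in [0,1].
#' @slot mask numeric binary H x W matrix.
#' @slot organ character.
#' @slot id integer source-image id.
#' @slot split character, "train", "test" or "" (unassigned).
#' @slot aug character augmentation tag ("orig", "hflip", "vflip", "colour").
#' @exportClass SampleRecord
setClass("SampleRecord", representation(
  filename = "character", image = "array", mask = "matrix",
  organ = "character", id = "integer", split = "character", aug = "character"
), validity = function(object) {
  d <- dim(object@mask)
  if (!identical(dim(object@image)[1:2], d))
    return("image and mask must share H x W")
  if (!isBinary(object@mask)) return("mask must be binary")
  TRUE
})

#' Loss hyperparameters
#'
#' All weights of the composite training objective: the Tversky asymmetry
#' (alpha penalises false positives, beta false negatives; beta > alpha biases
#' optimisation towards recall), the smoothing epsilon, the BCE/Tversky mixing
#' weights of the composite histology loss, and the branch weights of the
#' total objective.
#'
#' @slot alpha,beta numeric Tversky FP/FN weights (defaults 0.3 / 0.7).
#' @slot epsilon numeric smoothing constant.
#' @slot wBce,wTversky numeric mixing weights (must sum to 1; defaults 0.3 / 0.7).
#' @slot wHisto,wEdge numeric branch weights of the total loss (1.0 / 0.4).
#' @exportClass LossWeights
setClass("LossWeights", representation(
  alpha = "numeric", beta = "numeric", epsilon = "numeric",
  wBce = "numeric", wTversky = "numeric", wHisto = "numeric", wEdge = "numeric"
), validity = function(object) {
  msg <- character()
  vals <- c(object@alpha, object@beta, object@epsilon, object@wBce,
            object@wTversky, object@wHisto, object@wEdge)
  if (any(vals < 0)) msg <- c(msg, "all loss weights must be >= 0")
  if (abs(object@wBce + object@wTversky - 1) > 1e-9)
    msg <- c(msg, "wBce + wTversky must equal 1")
  if (length(msg)) msg else TRUE
})

#' Network architecture configuration
#'
#' Defines the encoder-decoder: input channels, the seven stage widths (four
#' encoder stages, the fourth acting as bottleneck, and three decoder stages),
#' organ-embedding dimension, squeeze-and-excitation reduction ratio, the
#' fixed dilation rates of the edge head, the module ablation flags and the
#' expected input size (any size divisible by 8 is accepted at forward time).
#'
#' @slot inChannels integer (1 = greyscale input).
#' @slot stageChannels integer length-7 stage widths.
#' @slot embedDim integer organ-embedding dimension.
#' @slot seReduction integer SE bottleneck reduction ratio.
#' @slot dilations integer length-3, fixed (1,2,3).
#' @slot useSE,useFiLM,useEdge logical module toggles.
#' @slot inputSize integer nominal input side length.
#' @exportClass NetworkConfig
setClass("NetworkConfig", representation(
  inChannels = "integer", stageChannels = "integer", embedDim = "integer",
  seReduction = "integer", dilations = "integer",
  useSE = "logical", useFiLM = "logical", useEdge = "logical",
  inputSize = "integer"
), validity = function(object) {
  msg <- character()
  if (length(object@stageChannels) != 7L)
    msg <- c(msg, "stageChannels must have length 7")
  if (!identical(object@dilations, c(1L, 2L, 3L)))
    msg <- c(msg, "dilations are fixed at (1,2,3)")
  if (object@embedDim <= 0L) msg <- c(msg, "embedDim must be > 0")
  if (object@inputSize %% 8L != 0L)
    msg <- c(msg, "inputSize must be divisible by 8")
  if (length(msg)) msg else TRUE
})

#' The segmentation model
#'
#' Container for a built network: its architecture configuration, the ordered
#' organ vocabulary (persisted so label encoding stays stable across
#' checkpoints), and the named list of parameter arrays.
#'
#' @slot config a \code{NetworkConfig}.
#' @slot organs character, ordered organ vocabulary (label y is its index).
#' @slot params named list of numeric parameter arrays.
#' @exportClass SegNetwork
setClass("SegNetwork", representation(
  config = "NetworkConfig", organs = "character", params = "list"
), validity = function(object) {
  if (anyDuplicated(object@organs)) return("organ vocabulary must be unique")
  TRUE
})

#' One forward pass result
#'
#' Lesion probability rasters and (if the edge head is enabled) edge
#' probability rasters for a batch, both sigmoid outputs at input resolution.
#'
#' @slot prob numeric array B x H x W in (0,1).
#' @slot edgeProb numeric array B x H x W in (0,1), or empty when disabled.
#' @exportClass SegmentationOutput
setClass("SegmentationOutput", representation(
  prob = "array", edgeProb = "array"
))

#' Main-training configuration
#'
#' @slot lr numeric Adam learning rate (default 5e-4).
#' @slot batchSize integer (default 8).
#' @slot maxEpochs integer (default 50).
#' @slot inputSize integer training resolution (default 224).
#' @slot selectionMetric character, metric used to keep the best checkpoint
#'   (default "recall").
#' @slot threshold numeric evaluation threshold (default 0.5).
#' @slot seed integer.
#' @exportClass TrainConfig
setClass("TrainConfig", representation(
  lr = "numeric", batchSize = "integer", maxEpochs = "integer",
  inputSize = "integer", selectionMetric = "character", threshold = "numeric",
  seed = "integer"
))

#' Human-in-the-loop fine-tuning configuration
#'
#' @slot hitlRatio numeric fraction of each organ class selected (default 0.30).
#' @slot minPerClass integer selection floor per organ (default 2).
#' @slot lr numeric fine-tuning peak learning rate (default 2e-4).
#' @slot weightDecay numeric decoupled weight decay (default 1e-2).
#' @slot batchSize integer (default 8).
#' @slot epochs integer (default 8).
#' @slot emaDecay numeric exponential-moving-average decay (default 0.999).
#' @slot seed integer.
#' @exportClass HITLConfig
setClass("HITLConfig", representation(
  hitlRatio = "numeric", minPerClass = "integer", lr = "numeric",
  weightDecay = "numeric", batchSize = "integer", epochs = "integer",
  emaDecay = "numeric", seed = "integer"
))

#' Pixel confusion counts at a fixed threshold
#'
#' @slot tp,fp,fn,tn numeric non-negative pixel counts.
#' @exportClass ConfusionCounts
setClass("ConfusionCounts", representation(
  tp = "numeric", fp = "numeric", fn = "numeric", tn = "numeric"
), validity = function(object) {
  if (any(c(object@tp, object@fp, object@fn, object@tn) < 0))
    return("counts must be non-negative")
  TRUE
})

setMethod("show", "SynthSample", function(object) {
  d <- dim(object@mask)
  cat(sprintf("SynthSample '%s' id %d: %d x %d, lesion fraction %.3f\n",
              object@organ, object@id, d[1], d[2], mean(object@mask)))
})

setMethod("show", "SynthROIPair", function(object) {
  d <- dim(object@mask)
  t <- object@trueTransform
  cat(sprintf("SynthROIPair %d x %d, true transform (%.1f deg, %+.0f, %+.0f)\n",
              d[1], d[2], t["deg"], t["dx"], t["dy"]))
})

setMethod("show", "SegNetwork", function(object) {
  cfg <- object@config
  cat(sprintf(
    "SegNetwork: stages (%s), embed %d, SE=%s FiLM=%s Edge=%s, %d organs, %s parameters\n",
    paste(cfg@stageChannels, collapse = ","), cfg@embedDim,
    cfg@useSE, cfg@useFiLM, cfg@useEdge, length(object@organs),
    format(countParameters(object)$total, big.mark = ",")
  ))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%g FP=%g FN=%g TN=%g\n",
              object@tp, object@fp, object@fn, object@tn))
})
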