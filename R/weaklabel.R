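# IHC-to-H&E weak-label generation: rigid alignment of stain pairs,
# sliding-window patch extraction, HSV-gate and stain-deconvolution DAB mask
# generation, morphological clean-up and union fusion.

#' Build a mask-generator configuration
#'
#' Defaults are the package's own calibration (kept DAB hue band 15-45
#' degrees, excluded blue band 180-260, saturation gate 0.15, blur sigma 2 px,
#' minimum component area 64 px, opening/closing radii 2 px); all are exposed
#' because published pipelines of this kind rarely report their exact
#' thresholds.
#'
#' @param hueBand kept DAB hue band (degrees).
#' @param blueBand excluded haematoxylin band (degrees).
#' @param satMin minimum HSV saturation of kept pixels.
#' @param valMax maximum HSV value of kept pixels.
#' @param gaussianSigma Gaussian blur sigma (px) before Otsu thresholding.
#' @param minArea connected components smaller than this many pixels are dropped.
#' @param openRadius,closeRadius structuring-element radii (px).
#' @param fillHoles fill enclosed holes in the deconvolution mask.
#' @return a \code{MaskGenConfig}.
#' @export
maskGenConfig <- function(hueBand = c(15, 45), blueBand = c(180, 260),
                          satMin = 0.15, valMax = 0.98, gaussianSigma = 2,
                          minArea = 64, openRadius = 2, closeRadius = 2,
                          fillHoles = TRUE) {
  new("MaskGenConfig", hueBand = as.numeric(hueBand),
      blueBand = as.numeric(blueBand), satMin = satMin, valMax = valMax,
      gaussianSigma = gaussianSigma, minArea = minArea,
      openRadius = openRadius, closeRadius = closeRadius,
      fillHoles = fillHoles)
}

#' Rigidly align an IHC ROI onto its H&E partner
#'
#' Applies a rotation about the image centre followed by a translation,
#' resampling bilinearly (use \code{filter = "nearest"} for masks).
#' Out-of-frame pixels are filled with white, the slide background.
#'
#' @param ihcRoi raster (H x W or H x W x 3).
#' @param params numeric (deg, dx, dy), finite.
#' @param filter "bilinear" (intensities) or "nearest" (masks).
#' @return raster of the same shape as the input.
#' @export
alignPair <- function(ihcRoi, params, filter = "bilinear") {
  if (length(ihcRoi) == 0) stop("empty raster")
  params <- as.numeric(params)
  if (length(params) != 3 || !all(is.finite(params)))
    stop("alignment parameters must be three finite numbers (deg, dx, dy)")
  warpRigid(ihcRoi, params[1], params[2], params[3], inverse = FALSE,
            filter = filter, bg = 1)
}

#' Extract paired sliding-window patches
#'
#' Windows are half-open \code{[r, r+patch)} on a stride lattice starting at
#' the top-left corner; windows that would overrun the frame are dropped, so
#' the count is \code{(floor((H-patch)/stride)+1) * (floor((W-patch)/stride)+1)}.
#'
#' @param he,ihc rasters of identical H x W.
#' @param patch window side length (default 512).
#' @param stride lattice step (default 256).
#' @return list of patch pairs, each \code{list(he, ihc, origin = c(row, col))}
#'   with 1-based origins; empty list with a warning if a dimension is
#'   smaller than \code{patch}.
#' @export
extractPatches <- function(he, ihc, patch = 512L, stride = 256L) {
  dh <- rasterDim(he); di <- rasterDim(ihc)
  if (!identical(dh, di)) stop("he and ihc rasters must share H x W")
  h <- dh[1]; w <- dh[2]
  if (h < patch || w < patch) {
    warning("raster smaller than patch size; no patches extracted")
    return(list())
  }
  rows <- seq(0L, h - patch, by = stride)
  cols <- seq(0L, w - patch, by = stride)
  out <- vector("list", length(rows) * length(cols))
  k <- 0L
  crop <- function(x, r, c) {
    if (isRGB(x)) x[r + seq_len(patch), c + seq_len(patch), , drop = FALSE]
    else x[r + seq_len(patch), c + seq_len(patch), drop = FALSE]
  }
  for (r in rows) for (c in cols) {
    k <- k + 1L
    out[[k]] <- list(he = crop(he, r, c), ihc = crop(ihc, r, c),
                     origin = c(row = r + 1L, col = c + 1L))
  }
  out
}

# connected-component area filter (8-connectivity)
removeSmall <- function(mask, minArea) {
  if (minArea <= 0 || sum(mask) == 0) return(mask)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= minArea)
  (matrix(lab %in% keep, nrow(mask), ncol(mask))) * 1
}

morphCleanup <- function(mask, openRadius, closeRadius) {
  m <- EBImage::Image(mask)
  if (openRadius > 0)
    m <- EBImage::opening(m, EBImage::makeBrush(2 * openRadius + 1, "disc"))
  if (closeRadius > 0)
    m <- EBImage::closing(m, EBImage::makeBrush(2 * closeRadius + 1, "disc"))
  matrix(as.numeric(EBImage::imageData(m) > 0.5), nrow(mask), ncol(mask))
}

#' HSV-gate DAB candidate mask
#'
#' Keeps pixels whose hue lies in the DAB band and outside the blue
#' counterstain band, with saturation at least \code{satMin} and value at most
#' \code{valMax}; then applies morphological opening/closing and removes
#' components smaller than \code{minArea}.
#'
#' @param ihcPatch RGB raster.
#' @param cfg a \code{MaskGenConfig}.
#' @return a \code{CandidateMask} (method "HSV").
#' @export
hsvMask <- function(ihcPatch, cfg = maskGenConfig()) {
  if (!isRGB(ihcPatch)) stop("hsvMask needs an RGB raster (hue is undefined on greyscale)")
  hsv <- rgbToHsvRaster(ihcPatch)
  keep <- hueInBand(hsv$h, cfg@hueBand) & !hueInBand(hsv$h, cfg@blueBand) &
    hsv$s >= cfg@satMin & hsv$v <= cfg@valMax
  m <- keep * 1
  m <- morphCleanup(m, cfg@openRadius, cfg@closeRadius)
  m <- removeSmall(m, cfg@minArea)
  new("CandidateMask", mask = m, method = "HSV")
}

# Ruifrok-Johnston haematoxylin/eosin/DAB stain vectors (rows, unit norm).
hedStainMatrix <- function() {
  m <- rbind(
    h = c(0.650, 0.704, 0.286),
    e = c(0.072, 0.990, 0.105),
    d = c(0.268, 0.570, 0.776)
  )
  m / sqrt(rowSums(m^2))
}

#' DAB channel by colour deconvolution
#'
#' Converts RGB to optical density and unmixes with the standard
#' haematoxylin/eosin/DAB stain basis, returning the DAB concentration raster.
#'
#' @param rgb RGB raster in [0,1].
#' @return numeric H x W matrix of DAB optical-density concentrations.
#' @export
hedDabChannel <- function(rgb) {
  if (!isRGB(rgb)) stop("RGB raster required")
  d <- dim(rgb)
  od <- -log10(pmax(matrix(rgb, ncol = 3L), 1e-6))
  conc <- od %*% solve(t(hedStainMatrix()))
  matrix(conc[, 3], d[1], d[2])
}

#' Stain-deconvolution (HED) DAB candidate mask
#'
#' DAB channel from colour deconvolution, Gaussian smoothing, Otsu threshold
#' on the min-max rescaled channel, opening/closing and hole filling. A patch
#' with a (near-)constant DAB channel has no Otsu threshold and yields an
#' empty mask with a warning.
#'
#' @param ihcPatch RGB raster with non-constant DAB channel.
#' @param cfg a \code{MaskGenConfig}.
#' @return a \code{CandidateMask} (method "HED").
#' @export
hedMask <- function(ihcPatch, cfg = maskGenConfig()) {
  dab <- hedDabChannel(ihcPatch)
  if (cfg@gaussianSigma > 0)
    dab <- as.matrix(EBImage::imageData(
      EBImage::gblur(EBImage::Image(dab), sigma = cfg@gaussianSigma)))
  rng <- range(dab)
  if (diff(rng) < 1e-4) {
    warning("constant DAB channel; Otsu threshold undefined, returning empty mask")
    return(new("CandidateMask", mask = matrix(0, nrow(dab), ncol(dab)),
               method = "HED"))
  }
  z <- (dab - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(z), range = c(0, 1))
  m <- (z > thr) * 1
  # bimodality gate (shift-invariant): a signal-free patch where Otsu merely
  # splits noise shows almost no foreground/background contrast in OD units
  if (sum(m) > 0 && sum(m) < length(m) &&
      (mean(dab[m == 1]) - mean(dab[m == 0])) < 0.08)
    m[] <- 0
  m <- morphCleanup(m, cfg@openRadius, cfg@closeRadius)
  if (cfg@fillHoles)
    m <- matrix(as.numeric(EBImage::imageData(
      EBImage::fillHull(EBImage::Image(m))) > 0.5), nrow(m), ncol(m))
  m <- removeSmall(m, cfg@minArea)
  new("CandidateMask", mask = m, method = "HED")
}

#' Fuse two candidate masks by logical OR
#'
#' Union fusion is deliberately recall-biased: the fused weak label covers
#' every pixel either generator flags.
#'
#' @param a,b \code{CandidateMask} objects (or binary matrices) of equal shape.
#' @return binary matrix.
#' @export
fuseMasks <- function(a, b) {
  ma <- if (is(a, "CandidateMask")) a@mask else a
  mb <- if (is(b, "CandidateMask")) b@mask else b
  if (!identical(dim(ma), dim(mb))) stop("candidate masks must share shape")
  pmax(ma, mb)
}

#' End-to-end weak-label pipeline on one ROI pair
#'
#' Align the IHC ROI, extract paired patches, generate both candidate masks
#' per patch and fuse them.
#'
#' @param he,ihc ROI rasters.
#' @param params alignment parameters (deg, dx, dy).
#' @param cfg a \code{MaskGenConfig}.
#' @param patch,stride window geometry.
#' @return list of \code{list(he, ihc, origin, mask)}.
#' @export
weakLabelPipeline <- function(he, ihc, params, cfg = maskGenConfig(),
                              patch = 512L, stride = 256L) {
  aligned <- alignPair(ihc, params)
  pairs <- extractPatches(he, aligned, patch = patch, stride = stride)
  lapply(pairs, function(p) {
    a <- hsvMask(p$ihc, cfg)
    b <- suppressWarnings(hedMask(p$ihc, cfg))
    p$mask <- fuseMasks(a, b)
    p
  })
}
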