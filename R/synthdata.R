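# Synthetic paired-stain histology generator.
#
# Lesions are unions of randomly perturbed ellipses (boundary modulated by
# low-order harmonics), giving irregular blob contours with exact ground
# truth. The pseudo-H&E rendering places a subtle lesion contrast on a
# haematoxylin/eosin-toned textured background; the pseudo-IHC rendering puts
# the DAB brown chromogen only on lesion pixels over a pale blue counterstain,
# so weak-label recovery is testable against construction.

#' Default per-organ style table
#'
#' Texture and intensity parameters that vary across organs, emulating the
#' morphology/staining differences between tissue types.
#'
#' @return data.frame with columns organ, baseIntensity, textureAmp,
#'   textureScale, lesionContrast.
#' @export
defaultOrganStyles <- function() {
  data.frame(
    organ = c("kidney", "liver", "spleen", "lung", "muscle", "rectum"),
    baseIntensity = c(0.78, 0.72, 0.70, 0.82, 0.75, 0.74),
    textureAmp = c(0.06, 0.08, 0.10, 0.05, 0.07, 0.09),
    textureScale = c(10, 14, 8, 18, 12, 9),
    lesionContrast = c(0.16, 0.14, 0.18, 0.15, 0.13, 0.17),
    stringsAsFactors = FALSE
  )
}

#' Build a synthetic-data configuration
#'
#' @param imageSize patch side length in pixels.
#' @param nLesions inclusive range of lesion count per patch.
#' @param lesionRadius lesion radius range in pixels.
#' @param dabHue DAB hue band in degrees (brown chromogen).
#' @param backgroundHue haematoxylin background hue in degrees (blue).
#' @param stainJitter fractional stain intensity jitter.
#' @param organStyles per-organ style table (see \code{\link{defaultOrganStyles}}).
#' @param roiSize (rows, cols) of generated ROI pairs.
#' @param seed base RNG seed; fixed seed implies bit-identical output.
#' @return a \code{SynthConfig}.
#' @export
synthConfig <- function(imageSize = 512L, nLesions = c(2L, 5L),
                        lesionRadius = NULL,
                        dabHue = c(20, 40), backgroundHue = 220,
                        stainJitter = 0.05,
                        organStyles = defaultOrganStyles(),
                        roiSize = c(1500L, 2100L), seed = 1L) {
  if (is.null(lesionRadius))
    lesionRadius <- c(imageSize / 16, imageSize / 6)
  new("SynthConfig", imageSize = as.integer(imageSize),
      nLesions = as.integer(nLesions), lesionRadius = as.numeric(lesionRadius),
      dabHue = as.numeric(dabHue), backgroundHue = as.numeric(backgroundHue),
      stainJitter = as.numeric(stainJitter), organStyles = organStyles,
      roiSize = as.integer(roiSize), seed = as.integer(seed))
}

organStyleRow <- function(config, organ) {
  i <- match(organ, config@organStyles$organ)
  if (is.na(i))
    stop(sprintf("unknown organ '%s'; configured organs: %s", organ,
                 paste(config@organStyles$organ, collapse = ", ")))
  config@organStyles[i, ]
}

# One perturbed-ellipse blob rasterised into an existing mask matrix.
drawBlob <- function(mask, cy, cx, r0) {
  h <- nrow(mask); w <- ncol(mask)
  ecc <- runif(1, 0.6, 1)                   # axis ratio
  rot <- runif(1, 0, pi)
  amp <- runif(3, 0.05, 0.22)               # harmonic amplitudes
  ph <- runif(3, 0, 2 * pi)
  rmax <- r0 * (1 + sum(amp)) / min(ecc, 1) + 2
  y0 <- max(1, floor(cy - rmax)); y1 <- min(h, ceiling(cy + rmax))
  x0 <- max(1, floor(cx - rmax)); x1 <- min(w, ceiling(cx + rmax))
  if (y0 > y1 || x0 > x1) return(mask)
  yy <- rep(y0:y1, times = x1 - x0 + 1) - cy
  xx <- rep(x0:x1, each = y1 - y0 + 1) - cx
  u <- cos(rot) * xx + sin(rot) * yy
  v <- (-sin(rot) * xx + cos(rot) * yy) / ecc
  th <- atan2(v, u)
  rb <- r0 * (1 + amp[1] * sin(2 * th + ph[1]) + amp[2] * sin(3 * th + ph[2]) +
                amp[3] * sin(5 * th + ph[3]))
  inside <- sqrt(u^2 + v^2) <= rb
  sub <- matrix(inside * 1, y1 - y0 + 1, x1 - x0 + 1)
  mask[y0:y1, x0:x1] <- pmax(mask[y0:y1, x0:x1], sub)
  mask
}

# Draw a lesion mask with coverage in [1%, 50%] (when any lesion is drawn).
drawLesionMask <- function(h, w, nRange, rRange) {
  n <- if (nRange[1] == nRange[2]) nRange[1] else
    sample(seq(nRange[1], nRange[2]), 1)
  if (n == 0L) return(matrix(0, h, w))
  for (attempt in 1:25) {
    mask <- matrix(0, h, w)
    for (i in seq_len(n)) {
      r0 <- runif(1, rRange[1], rRange[2])
      cy <- runif(1, 1 + r0 * 0.5, h - r0 * 0.5)
      cx <- runif(1, 1 + r0 * 0.5, w - r0 * 0.5)
      mask <- drawBlob(mask, cy, cx, r0)
    }
    cov <- mean(mask)
    if (cov >= 0.01 && cov <= 0.5) return(mask)
  }
  stop("could not draw a lesion mask with coverage in [1%, 50%]; ",
       "check lesionRadius against imageSize")
}

renderHE <- function(mask, style, jitter) {
  h <- nrow(mask); w <- ncol(mask)
  tex <- smoothNoise(h, w, scale = style$textureScale, amplitude = style$textureAmp)
  fine <- matrix(rnorm(h * w, 0, 0.02), h, w)
  base <- style$baseIntensity * (1 + runif(1, -jitter, jitter))
  mod <- 0.85 + clamp(smoothNoise(h, w, scale = 6, amplitude = 0.15), -0.15, 0.15)
  val <- clamp(base + tex + fine - style$lesionContrast * mask * mod, 0.05, 1)
  # haematoxylin-toned background with eosin blotches
  eos <- clamp(smoothNoise(h, w, scale = 16, amplitude = 0.5) + 0.2, 0, 1)
  hue <- 280 - 40 * eos                      # purple-blue -> pink
  sat <- clamp(0.25 + 0.15 * eos + 0.10 * mask, 0, 1)
  rgb <- hsv2rgbNum(as.vector(hue), as.vector(sat), as.vector(val))
  array(c(rgb$r, rgb$g, rgb$b), dim = c(h, w, 3))
}

renderIHC <- function(mask, config, style) {
  h <- nrow(mask); w <- ncol(mask)
  jit <- config@stainJitter
  band <- config@dabHue
  # lesion: DAB brown strictly inside the configured hue band
  pad <- 0.1 * (band[2] - band[1])
  hueL <- matrix(runif(h * w, band[1] + pad, band[2] - pad), h, w)
  satL <- clamp(0.75 + smoothNoise(h, w, 12, 0.08) +
                  matrix(rnorm(h * w, 0, jit / 2), h, w), 0.5, 0.98)
  valL <- clamp(0.45 + smoothNoise(h, w, 12, 0.06) +
                  matrix(rnorm(h * w, 0, jit / 2), h, w), 0.25, 0.7)
  # background: pale haematoxylin counterstain
  hueB <- matrix(config@backgroundHue + rnorm(h * w, 0, 4), h, w) %% 360
  satB <- clamp(0.12 + smoothNoise(h, w, 20, 0.04), 0.03, 0.35)
  valB <- clamp(0.93 + smoothNoise(h, w, 20, 0.03) +
                  matrix(rnorm(h * w, 0, 0.01), h, w), 0.8, 1)
  hue <- ifelse(mask > 0, hueL, hueB)
  sat <- ifelse(mask > 0, satL, satB)
  val <- ifelse(mask > 0, valL, valB)
  rgb <- hsv2rgbNum(as.vector(hue), as.vector(sat), as.vector(val))
  array(c(rgb$r, rgb$g, rgb$b), dim = c(h, w, 3))
}

#' Generate one synthetic paired-stain sample
#'
#' Deterministic for a fixed (config seed, organ, id): the RNG stream is keyed
#' by the triple, so dataset generation is order-independent. Lesion pixels in
#' the IHC rendering always carry a hue inside the configured DAB band and
#' DAB pixels appear only where the mask is 1.
#'
#' @param config a \code{SynthConfig}.
#' @param organ organ name; must be a key of \code{config@organStyles}.
#' @param id integer sample id.
#' @return a \code{\link{SynthSample-class}}.
#' @export
generateSample <- function(config, organ, id) {
  style <- organStyleRow(config, organ)
  s <- deriveSeed(config@seed, match(organ, config@organStyles$organ), id)
  withSeed(s, {
    n <- config@imageSize
    mask <- drawLesionMask(n, n, config@nLesions, config@lesionRadius)
    he <- renderHE(mask, style, config@stainJitter)
    ihc <- renderIHC(mask, config, style)
    new("SynthSample", he = he, ihc = ihc, mask = mask,
        organ = organ, id = as.integer(id))
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes 8-bit PNG image/mask pairs named \code{human_\{organ\}_\{id\}} (the
#' naming convention parsed by \code{\link{parseFilename}}) and returns a
#' manifest data.frame, also written as \code{manifest.csv}.
#'
#' @param config a \code{SynthConfig}.
#' @param organs character vector of organ names.
#' @param perOrgan samples per organ (>= 1).
#' @param outDir output directory (created if missing).
#' @return manifest data.frame (filename, organ, id, imagePath, maskPath).
#' @export
generateDataset <- function(config, organs, perOrgan, outDir) {
  if (perOrgan < 1) stop("perOrgan must be >= 1")
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  imgDir <- file.path(outDir, "images"); mskDir <- file.path(outDir, "masks")
  dir.create(imgDir, showWarnings = FALSE); dir.create(mskDir, showWarnings = FALSE)
  rows <- list()
  for (organ in organs) for (id in seq_len(perOrgan) - 1L) {
    smp <- generateSample(config, organ, id)
    fn <- sprintf("human_%s_%d", organ, id)
    ip <- file.path(imgDir, paste0(fn, ".png"))
    mp <- file.path(mskDir, paste0(fn, ".png"))
    png::writePNG(smp@he, ip)
    writeMaskPNG(smp@mask, mp)
    rows[[length(rows) + 1L]] <- data.frame(
      filename = fn, organ = organ, id = id, imagePath = ip, maskPath = mp,
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Generate a misaligned ROI stain pair with known rigid transform
#'
#' Builds an aligned scene (H&E ROI, mask, aligned IHC) at
#' \code{config@roiSize}, then displaces the IHC by the inverse of
#' \code{transform}, so that \code{\link{alignPair}} with the recorded
#' transform superimposes the DAB signal back onto the mask.
#'
#' @param config a \code{SynthConfig}.
#' @param transform numeric (deg, dx, dy); |deg| <= 15, |dx|,|dy| <= 200.
#' @param organ organ style used for the H&E rendering.
#' @param id integer id keying the RNG stream.
#' @return a \code{\link{SynthROIPair-class}}.
#' @export
generateRoiPair <- function(config, transform = c(deg = 0, dx = 0, dy = 0),
                            organ = config@organStyles$organ[1], id = 0L) {
  transform <- stats::setNames(as.numeric(transform), c("deg", "dx", "dy"))
  if (abs(transform["deg"]) > 15 || any(abs(transform[c("dx", "dy")]) > 200))
    stop("transform outside the plausible manual-alignment range")
  style <- organStyleRow(config, organ)
  s <- deriveSeed(config@seed, 7919L, match(organ, config@organStyles$organ), id)
  withSeed(s, {
    h <- config@roiSize[1]; w <- config@roiSize[2]
    rr <- config@lesionRadius
    mask <- drawLesionMask(h, w, pmax(config@nLesions, c(1L, 1L)),
                           c(min(rr[2], h / 10), min(rr[2] * 2, h / 5)))
    he <- renderHE(mask, style, config@stainJitter)
    ihcAligned <- renderIHC(mask, config, style)
    ihc <- warpRigid(ihcAligned, transform["deg"], transform["dx"],
                     transform["dy"], inverse = TRUE, bg = 1)
    # reject transforms that push the lesion signal fully out of frame
    maskBack <- warpRigid(mask, transform["deg"], transform["dx"],
                          transform["dy"], inverse = TRUE,
                          filter = "nearest", bg = 0)
    if (sum(maskBack) == 0 && sum(mask) > 0)
      stop("transform moves the lesion fully out of frame")
    new("SynthROIPair", he = he, ihc = ihc, mask = mask,
        trueTransform = transform)
  })
}

#' @describeIn accessors H&E raster of a sample or ROI pair.
#' @export
heImage <- function(x) x@he

#' @describeIn accessors IHC raster of a sample or ROI pair.
#' @export
ihcImage <- function(x) x@ihc

#' @describeIn accessors Binary ground-truth mask.
#' @export
maskImage <- function(x) x@mask

#' Accessors for synthetic samples and records
#'
#' Small read accessors so slots are not accessed directly.
#' @param x a \code{SynthSample}, \code{SynthROIPair} or \code{SampleRecord}.
#' @name accessors
#' @return the corresponding slot value.
#' @export
organLabel <- function(x) x@organ
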