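# Dataset preparation: 4x augmentation, greyscale conversion,
# human_{organ}_{id} filename handling, seeded stratified 8:2 split and
# resize-on-load.

#' Default organ vocabulary
#'
#' The multi-organ vocabulary used for filename parsing; organ tokens may
#' contain underscores (e.g. \code{salivary_gland}), resolved by longest
#' match.
#' @return character vector of organ tokens.
#' @export
organVocabulary <- function() {
  c("bladder", "brain", "cardia", "cerebellum", "epiglottis", "jejunum",
    "kidney", "liver", "lung", "melanoma", "melanomaLN", "muscle",
    "oesophagus", "pancreas", "peritoneum", "placenta", "pylorus", "rectum",
    "salivary_gland", "spleen", "testis", "tongue", "tonsil",
    "umbilical_cord")
}

#' Build a sample record
#'
#' @param image raster (H x W or H x W x 3) in [0,1].
#' @param mask binary H x W matrix.
#' @param organ organ name.
#' @param id integer source id.
#' @param split "train", "test" or "" when unassigned.
#' @param aug augmentation tag.
#' @param filename optional; defaults to \code{human_\{organ\}_\{id\}}.
#' @return a \code{SampleRecord}.
#' @export
sampleRecord <- function(image, mask, organ, id, split = "", aug = "orig",
                         filename = sprintf("human_%s_%d", organ, id)) {
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
  new("SampleRecord", filename = filename, image = image, mask = mask,
      organ = organ, id = as.integer(id), split = split, aug = aug)
}

hflip <- function(x) {
  if (isRGB(x)) x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
  else x[, rev(seq_len(ncol(x))), drop = FALSE]
}

vflip <- function(x) {
  if (isRGB(x)) x[rev(seq_len(dim(x)[1])), , , drop = FALSE]
  else x[rev(seq_len(nrow(x))), , drop = FALSE]
}

# brightness/contrast/saturation jitter, each U(-amount, amount), seeded
colourPerturb <- function(img, seed, amount = 0.1) {
  withSeed(seed, {
    b <- runif(1, -amount, amount)
    cfac <- 1 + runif(1, -amount, amount)
    sfac <- 1 + runif(1, -amount, amount)
    out <- img
    if (isRGB(out)) {
      mu <- (out[, , 1] + out[, , 2] + out[, , 3]) / 3
      for (k in 1:3)
        out[, , k] <- mu + (out[, , k] - mu) * sfac
    }
    out <- (out - 0.5) * cfac + 0.5 + b
    clamp(out, 0, 1)
  })
}

#' Augment one record fourfold
#'
#' Returns the original, a horizontal flip, a vertical flip and a
#' colour-perturbed copy (mild brightness/contrast/saturation jitter).
#' Flips are applied identically to the mask; the colour perturbation leaves
#' the mask untouched, so the positive-pixel count is identical across all
#' four outputs. Deterministic given \code{seed}.
#'
#' @param rec a \code{SampleRecord}.
#' @param seed integer RNG seed for the colour jitter.
#' @return list of exactly 4 \code{SampleRecord}s.
#' @export
augmentSample <- function(rec, seed = 0L) {
  mk <- function(image, mask, aug) {
    r <- rec
    if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
    r@image <- image; r@mask <- mask; r@aug <- aug
    r
  }
  s <- deriveSeed(seed, rec@id, match(rec@organ, c(organVocabulary(), rec@organ)))
  list(
    rec,
    mk(hflip(rec@image), hflip(rec@mask), "hflip"),
    mk(vflip(rec@image), vflip(rec@mask), "vflip"),
    mk(colourPerturb(rec@image, s), rec@mask, "colour")
  )
}

#' Convert an RGB raster to greyscale
#'
#' Luma-weighted combination (0.299 R + 0.587 G + 0.114 B), suppressing stain
#' colour so the model trains on structure rather than staining variance.
#'
#' @param image RGB raster in [0,1] (greyscale input is returned as is).
#' @return H x W matrix in [0,1].
#' @export
toGreyscale <- function(image) {
  if (!isRGB(image)) {
    if (length(dim(image)) == 3L) return(image[, , 1])
    return(image)
  }
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Parse a \code{human_\{organ\}_\{id\}} filename
#'
#' The organ token may itself contain underscores; it is resolved by longest
#' match against the vocabulary, and the remainder must be an integer id.
#'
#' @param name filename (extension optional).
#' @param vocabulary organ vocabulary (default \code{\link{organVocabulary}}).
#' @return list(organ, id).
#' @export
parseFilename <- function(name, vocabulary = organVocabulary()) {
  base <- sub("\\.[A-Za-z]+$", "", basename(name))
  fail <- function() stop(sprintf(
    "cannot parse '%s'; expected human_{organ}_{id} with organ in: %s",
    name, paste(vocabulary, collapse = ", ")))
  if (!startsWith(base, "human_")) fail()
  rest <- substring(base, 7L)
  hits <- vocabulary[vapply(vocabulary, function(v)
    startsWith(rest, paste0(v, "_")), logical(1))]
  if (!length(hits)) fail()
  organ <- hits[which.max(nchar(hits))]
  idStr <- substring(rest, nchar(organ) + 2L)
  if (!grepl("^[0-9]+$", idStr)) fail()
  list(organ = organ, id = as.integer(idStr))
}

#' Seeded stratified train/test split
#'
#' Splits at source-image level (before augmentation) so augmented copies of
#' one source never straddle the split, shuffling within each organ with the
#' configured seed and assigning \code{ceiling(fraction * n)} sources to
#' train. An organ with a single source goes entirely to train with a
#' warning.
#'
#' @param records list of \code{SampleRecord}s.
#' @param trainFraction train fraction (default 0.8).
#' @param seed split seed.
#' @return the records with the \code{split} slot filled.
#' @export
stratifiedSplit <- function(records, trainFraction = 0.8, seed = 42L) {
  stopifnot(trainFraction > 0, trainFraction < 1)
  organs <- vapply(records, function(r) r@organ, character(1))
  ids <- vapply(records, function(r) r@id, integer(1))
  key <- paste(organs, ids)
  assign <- character(length(records))
  for (org in unique(organs)) {
    srcIds <- sort(unique(ids[organs == org]))
    n <- length(srcIds)
    if (n == 1L) {
      warning(sprintf("organ '%s' has a single source image; assigned to train", org))
      trainIds <- srcIds
    } else {
      perm <- withSeed(deriveSeed(seed, match(org, sort(unique(organs)))),
                       sample(srcIds))
      # round towards train but keep at least one test source per organ
      k <- min(ceiling(trainFraction * n), n - 1L)
      trainIds <- perm[seq_len(k)]
    }
    sel <- organs == org
    assign[sel] <- ifelse(ids[sel] %in% trainIds, "train", "test")
  }
  for (i in seq_along(records)) records[[i]]@split <- assign[i]
  records
}

#' Load one record at training resolution
#'
#' Converts the image to greyscale, resizes it bilinearly and the mask by
#' nearest neighbour (so it stays strictly binary), both to
#' \code{size x size}.
#'
#' @param rec a \code{SampleRecord}.
#' @param size target side length (default 224).
#' @return list(image, mask), each a \code{size x size} matrix.
#' @export
loadPair <- function(rec, size = 224L) {
  img <- toGreyscale(rec@image)
  msk <- rec@mask
  if (!identical(dim(img), c(size, size)))
    img <- as.matrix(EBImage::imageData(EBImage::resize(
      EBImage::Image(img), w = size, h = size, filter = "bilinear")))
  if (!identical(dim(msk), c(size, size)))
    msk <- as.matrix(EBImage::imageData(EBImage::resize(
      EBImage::Image(msk), w = size, h = size, filter = "none")))
  list(image = clamp(img, 0, 1), mask = (msk > 0.5) * 1)
}
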