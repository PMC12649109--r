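# Shared fixtures: tiny network configurations and synthetic records so every
# test builds its inputs in code.

tinyNetConfig <- function(embedDim = 3L, ...) {
  networkConfig(stageChannels = c(4L, 6L, 8L, 10L, 8L, 6L, 4L),
                embedDim = embedDim, seReduction = 2L, inputSize = 16L, ...)
}

tinyModel <- function(organs = c("kidney", "liver"), seed = 3L, ...) {
  segNetwork(tinyNetConfig(...), organs = organs, seed = seed)
}

smallNetConfig <- function(...) {
  networkConfig(stageChannels = c(8L, 16L, 32L, 64L, 32L, 16L, 8L),
                embedDim = 8L, seReduction = 4L, inputSize = 32L, ...)
}

# synthetic training records at a given patch size
makeRecords <- function(organs, perOrgan, imageSize = 32L, seed = 5L) {
  sc <- synthConfig(imageSize = imageSize, seed = seed)
  recs <- list()
  for (org in organs) for (id in seq_len(perOrgan) - 1L) {
    s <- generateSample(sc, org, id)
    recs[[length(recs) + 1L]] <- sampleRecord(s@he, s@mask, s@organ, s@id)
  }
  recs
}

randomMask <- function(h, w, p = 0.3) (matrix(runif(h * w), h, w) < p) * 1

diceOf <- function(a, b) {
  if (sum(a) + sum(b) == 0) return(1)
  2 * sum(a * b) / (sum(a) + sum(b))
}

# independent set-morphology oracle for the 3x3 morphological gradient:
# dilation = max over the in-frame 3x3 neighbourhood, erosion = min over the
# in-frame neighbourhood (out-of-frame counting as foreground)
bruteEdgeTarget <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0, h, w)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    ys <- max(1, y - 1):min(h, y + 1)
    xs <- max(1, x - 1):min(w, x + 1)
    nb <- mask[ys, xs]
    out[y, x] <- max(nb) - min(nb)
  }
  out
}

meanPoolRecall <- function(model, records, size) {
  tens <- histoseg:::prepareTensors(records, size)
  probs <- histoseg:::predictRecords(model, tens)
  mean(mapply(function(p, m) segMetrics(confusionCounts(p, m))$recall,
              probs, tens$masks))
}
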