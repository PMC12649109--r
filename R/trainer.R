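# Training loop and the offline human-in-the-loop stage: entropy-based
# uncertainty scoring, organ-stratified subset selection and targeted
# fine-tuning with only the last two decoder stages, their FiLM maps and the
# output layer unfrozen.

#' Build a main-training configuration
#'
#' Defaults: Adam at learning rate 5e-4, batch size 8, 50 epochs, 224 x 224
#' inputs, evaluation threshold 0.5, best checkpoint kept by validation
#' recall.
#'
#' @param lr,batchSize,maxEpochs,inputSize,threshold,seed see slots.
#' @param selectionMetric metric maximised when keeping the best epoch.
#' @return a \code{TrainConfig}.
#' @export
trainConfig <- function(lr = 5e-4, batchSize = 8L, maxEpochs = 50L,
                        inputSize = 224L, selectionMetric = "recall",
                        threshold = 0.5, seed = 1L) {
  new("TrainConfig", lr = lr, batchSize = as.integer(batchSize),
      maxEpochs = as.integer(maxEpochs), inputSize = as.integer(inputSize),
      selectionMetric = selectionMetric, threshold = threshold,
      seed = as.integer(seed))
}

#' Build a human-in-the-loop configuration
#'
#' Defaults: 30% of each organ class selected with a floor of 2, Adam with
#' decoupled weight decay (lr 2e-4, decay 1e-2), batch size 8, eight epochs,
#' one-cycle schedule and EMA decay 0.999.
#'
#' @param hitlRatio,minPerClass,lr,weightDecay,batchSize,epochs,emaDecay,seed
#'   see slots.
#' @return a \code{HITLConfig}.
#' @export
hitlConfig <- function(hitlRatio = 0.30, minPerClass = 2L, lr = 2e-4,
                       weightDecay = 1e-2, batchSize = 8L, epochs = 8L,
                       emaDecay = 0.999, seed = 1L) {
  new("HITLConfig", hitlRatio = hitlRatio, minPerClass = as.integer(minPerClass),
      lr = lr, weightDecay = weightDecay, batchSize = as.integer(batchSize),
      epochs = as.integer(epochs), emaDecay = emaDecay, seed = as.integer(seed))
}

# ---- Adam / AdamW ----

adamInit <- function(params) {
  list(m = lapply(params, function(v) v * 0),
       v = lapply(params, function(v) v * 0), t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, weightDecay = 0, unfrozen = NULL) {
  state$t <- state$t + 1L
  upd <- if (is.null(unfrozen)) names(params) else unfrozen
  for (nm in upd) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps) -
      lr * weightDecay * params[[nm]]
  }
  list(params = params, state = state)
}

# one-cycle learning rate: cosine warmup over the first 30% of steps from
# maxLr/25, cosine anneal to maxLr/25/1e4
oneCycleLr <- function(step, totalSteps, maxLr, pctStart = 0.3,
                       divFactor = 25, finalDivFactor = 1e4) {
  warm <- max(1, round(pctStart * totalSteps))
  lo <- maxLr / divFactor
  fin <- lo / finalDivFactor
  if (step <= warm) {
    frac <- (step - 1) / max(1, warm - 1)
    lo + (maxLr - lo) * (1 - cos(pi * frac)) / 2
  } else {
    frac <- (step - warm) / max(1, totalSteps - warm)
    fin + (maxLr - fin) * (1 + cos(pi * frac)) / 2
  }
}

# preload records at training resolution
prepareTensors <- function(records, inputSize) {
  pairs <- lapply(records, loadPair, size = inputSize)
  list(images = lapply(pairs, `[[`, "image"),
       masks = lapply(pairs, `[[`, "mask"),
       organs = vapply(records, function(r) r@organ, character(1)))
}

batchForwardBackward <- function(params, cfg, images, masks, ylab, w) {
  x <- stackBatch(images)
  res <- networkForward(params, cfg, x, ylab, train = TRUE)
  tgt <- stackBatch(masks)$x
  pred <- res$prob
  comps <- list(bce = bceLoss(pred, tgt), tversky = tverskyLoss(pred, tgt, w))
  comps$histo <- w@wBce * comps$bce + w@wTversky * comps$tversky
  dSeg <- segGradLogit(pred, tgt, w)
  dEdge <- NULL
  if (cfg@useEdge) {
    etgt <- stackBatch(lapply(masks, edgeTarget))$x
    comps$edge <- bceLoss(res$edgeProb, etgt)
    dEdge <- edgeGradLogit(res$edgeProb, etgt, w)
  } else comps$edge <- 0
  comps$total <- w@wHisto * comps$histo + w@wEdge * comps$edge
  grads <- networkBackward(params, cfg, res$cache, dSeg, dEdge, x$B)
  list(loss = comps, grads = grads)
}

# predict probabilities for a list of records; returns list of H x W matrices
predictRecords <- function(model, tensors, batchSize = 8L) {
  n <- length(tensors$images)
  out <- vector("list", n)
  ylab <- organToLabel(model, tensors$organs)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + batchSize - 1L)
    x <- stackBatch(tensors$images[i:j])
    res <- networkForward(model@params, model@config, x, ylab[i:j])
    probs <- unstackBatch(fm(res$prob, x$B, x$H, x$W))
    out[i:j] <- probs
    i <- j + 1L
  }
  out
}

evalRecall <- function(model, tensors, threshold = 0.5) {
  probs <- predictRecords(model, tensors)
  rows <- mapply(function(p, m) {
    segMetrics(confusionCounts(p, m, threshold))
  }, probs, tensors$masks, SIMPLIFY = FALSE)
  df <- do.call(rbind, lapply(rows, as.data.frame))
  colMeans(df)
}

#' Train the segmentation network
#'
#' Optimises the total objective with Adam, evaluates every epoch on the
#' validation records at the configured threshold, and keeps the parameters
#' of the epoch with the highest validation recall (the recall-first model
#' selection rule). Fully deterministic for a fixed seed.
#'
#' @param model a \code{SegNetwork}.
#' @param trainRecords,valRecords non-empty lists of \code{SampleRecord}s.
#' @param cfg a \code{TrainConfig}.
#' @param w a \code{LossWeights}.
#' @return list(model = best checkpoint, history = per-epoch data.frame of
#'   loss components and validation metrics).
#' @export
trainModel <- function(model, trainRecords, valRecords, cfg = trainConfig(),
                       w = lossWeights()) {
  if (!length(trainRecords) || !length(valRecords))
    stop("training and validation splits must be non-empty")
  tr <- prepareTensors(trainRecords, cfg@inputSize)
  va <- prepareTensors(valRecords, cfg@inputSize)
  ylab <- organToLabel(model, tr$organs)
  params <- model@params
  state <- adamInit(params)
  n <- length(tr$images)
  hist <- list()
  best <- list(metric = -Inf, params = params, epoch = 0L)
  withSeed(deriveSeed(cfg@seed, 1L), {
    for (epoch in seq_len(cfg@maxEpochs)) {
      ord <- sample(n)
      sums <- c(total = 0, histo = 0, bce = 0, tversky = 0, edge = 0)
      nb <- 0L
      i <- 1L
      while (i <= n) {
        j <- min(n, i + cfg@batchSize - 1L)
        idx <- ord[i:j]
        fb <- batchForwardBackward(params, model@config, tr$images[idx],
                                   tr$masks[idx], ylab[idx], w)
        st <- adamStep(params, fb$grads, state, cfg@lr)
        params <- st$params; state <- st$state
        sums <- sums + unlist(fb$loss[names(sums)])
        nb <- nb + 1L
        i <- j + 1L
      }
      model@params <- params
      m <- evalRecall(model, va, cfg@threshold)
      hist[[epoch]] <- data.frame(epoch = epoch, t(sums / nb),
                                  valRecall = m["recall"],
                                  valPrecision = m["precision"],
                                  valDice = m["dice"], valIou = m["iou"])
      sel <- m[[cfg@selectionMetric]]
      if (sel > best$metric) best <- list(metric = sel, params = params,
                                          epoch = epoch)
    }
  })
  model@params <- best$params
  history <- do.call(rbind, hist)
  rownames(history) <- NULL
  list(model = model, history = history, bestEpoch = best$epoch)
}

#' Mean per-pixel binary entropy of a probability map
#'
#' \code{mean(-p log p - (1-p) log(1-p))} in nats, clamped; bounded by
#' [0, ln 2] with the maximum at a uniform 0.5 map.
#'
#' @param prob probability raster.
#' @return scalar entropy.
#' @export
sampleEntropy <- function(prob) {
  p <- clamp(prob, 0, 1)
  t1 <- ifelse(p > 0, -p * log(p), 0)
  t2 <- ifelse(p < 1, -(1 - p) * log(1 - p), 0)
  min(mean(t1 + t2), log(2))
}

#' Organ-stratified uncertainty selection
#'
#' Per organ, selects the top-k samples by entropy where
#' \code{k = min(n, max(minPerClass, round(hitlRatio * n)))} (round half up);
#' ties are broken by ascending sample id, so the selection is deterministic
#' and independent of input order.
#'
#' @param ids sample identifiers.
#' @param entropies matching uncertainty scores.
#' @param organs matching organ labels.
#' @param cfg a \code{HITLConfig}.
#' @return vector of selected ids (in per-organ rank order).
#' @export
selectHitlSubset <- function(ids, entropies, organs, cfg = hitlConfig()) {
  stopifnot(length(ids) == length(entropies), length(ids) == length(organs))
  selected <- list()
  for (org in sort(unique(organs))) {
    sel <- which(organs == org)
    if (!length(sel)) { warning("empty organ class skipped: ", org); next }
    n <- length(sel)
    k <- min(n, max(cfg@minPerClass, floor(cfg@hitlRatio * n + 0.5)))
    ord <- sel[order(-entropies[sel], ids[sel])]
    selected[[org]] <- ids[ord[seq_len(k)]]
  }
  unlist(selected, use.names = FALSE)
}

#' Names of the parameters unfrozen during HITL fine-tuning
#'
#' The last two decoder stages (their upsamplers, double-conv blocks, SE
#' blocks and FiLM maps) and the 1x1 output layer; everything else —
#' encoder, bottleneck, first decoder stage, organ embedding table and edge
#' head — stays frozen.
#'
#' @param model a \code{SegNetwork}.
#' @return character vector of parameter names.
#' @export
hitlUnfrozenParams <- function(model) {
  nm <- names(model@params)
  nm[grepl("^(stage6|stage7|up6|up7|out)\\.", nm)]
}

#' Targeted fine-tuning on the uncertainty subset
#'
#' Adam with decoupled weight decay on the unfrozen parameter set only, under
#' a one-cycle learning-rate schedule peaking at \code{cfg@lr}, with an
#' exponential moving average of the unfrozen weights applied to the returned
#' model. Frozen parameter tensors are bit-identical before and after.
#'
#' @param model a trained \code{SegNetwork}.
#' @param subsetRecords non-empty list of \code{SampleRecord}s.
#' @param cfg a \code{HITLConfig}.
#' @param w a \code{LossWeights}.
#' @param inputSize training resolution.
#' @return list(model, history = per-epoch mean fine-tuning loss).
#' @export
finetuneHitl <- function(model, subsetRecords, cfg = hitlConfig(),
                         w = lossWeights(), inputSize = model@config@inputSize) {
  if (!length(subsetRecords)) stop("HITL subset must be non-empty")
  tensors <- prepareTensors(subsetRecords, inputSize)
  ylab <- organToLabel(model, tensors$organs)
  unfrozen <- hitlUnfrozenParams(model)
  params <- model@params
  ema <- params[unfrozen]
  state <- adamInit(params)
  n <- length(tensors$images)
  stepsPerEpoch <- ceiling(n / cfg@batchSize)
  totalSteps <- cfg@epochs * stepsPerEpoch
  step <- 0L
  histLoss <- numeric(cfg@epochs)
  withSeed(deriveSeed(cfg@seed, 2L), {
    for (epoch in seq_len(cfg@epochs)) {
      ord <- sample(n)
      lsum <- 0; nb <- 0L
      i <- 1L
      while (i <= n) {
        j <- min(n, i + cfg@batchSize - 1L)
        idx <- ord[i:j]
        fb <- batchForwardBackward(params, model@config, tensors$images[idx],
                                   tensors$masks[idx], ylab[idx], w)
        step <- step + 1L
        lr <- oneCycleLr(step, totalSteps, cfg@lr)
        st <- adamStep(params, fb$grads, state, lr,
                       weightDecay = cfg@weightDecay, unfrozen = unfrozen)
        params <- st$params; state <- st$state
        for (nm in unfrozen)
          ema[[nm]] <- cfg@emaDecay * ema[[nm]] + (1 - cfg@emaDecay) * params[[nm]]
        lsum <- lsum + fb$loss$total; nb <- nb + 1L
        i <- j + 1L
      }
      histLoss[epoch] <- lsum / nb
    }
  })
  params[unfrozen] <- ema
  model@params <- params
  list(model = model, history = data.frame(epoch = seq_len(cfg@epochs),
                                           loss = histLoss))
}

#' One full human-in-the-loop round
#'
#' Predicts on the pool, scores uncertainty by mean binary entropy, selects
#' the organ-stratified high-entropy subset, fine-tunes the decoder on it and
#' reports per-organ recall before and after.
#'
#' @param model a trained \code{SegNetwork}.
#' @param poolRecords list of \code{SampleRecord}s (the sampling pool).
#' @param cfg a \code{HITLConfig}.
#' @param w a \code{LossWeights}.
#' @param inputSize evaluation/fine-tuning resolution.
#' @param threshold evaluation threshold.
#' @return list(model, report = per-organ recall before/after data.frame,
#'   selected = selected indices into poolRecords, history).
#' @export
hitlRound <- function(model, poolRecords, cfg = hitlConfig(),
                      w = lossWeights(), inputSize = model@config@inputSize,
                      threshold = 0.5) {
  tensors <- prepareTensors(poolRecords, inputSize)
  probsBefore <- predictRecords(model, tensors)
  ent <- vapply(probsBefore, sampleEntropy, numeric(1))
  ids <- seq_along(poolRecords)
  selected <- selectHitlSubset(ids, ent, tensors$organs, cfg)
  ft <- finetuneHitl(model, poolRecords[selected], cfg, w, inputSize)
  probsAfter <- predictRecords(ft$model, tensors)
  recallOf <- function(probs) {
    r <- mapply(function(p, m) segMetrics(confusionCounts(p, m, threshold))$recall,
                probs, tensors$masks)
    tapply(r, tensors$organs, mean)
  }
  rb <- recallOf(probsBefore); ra <- recallOf(probsAfter)
  report <- data.frame(organ = names(rb), recallBefore = as.numeric(rb),
                       recallAfter = as.numeric(ra[names(rb)]),
                       stringsAsFactors = FALSE)
  list(model = ft$model, report = report, selected = selected,
       history = ft$history, entropies = ent)
}
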