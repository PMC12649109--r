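test_that("entropy scoring has the right closed forms and bounds", {
  expect_equal(sampleEntropy(matrix(0.5, 4, 4)), log(2), tolerance = 1e-12)
  expect_equal(sampleEntropy(randomMask(6, 6)), 0)
  half <- matrix(c(rep(0.5, 8), rep(1, 8)), 4, 4)
  expect_equal(sampleEntropy(half), log(2) / 2, tolerance = 1e-12)
  set.seed(1)
  for (i in 1:20) {
    e <- sampleEntropy(matrix(runif(16), 4, 4))
    expect_gte(e, 0); expect_lte(e, log(2))
  }
})

test_that("stratified selection takes the top-k per organ deterministically", {
  cfg <- hitlConfig()
  # class of 10 at ratio 0.30: the 3 largest entropies
  ids <- 1:10
  ent <- c(0.1, 0.5, 0.3, 0.69, 0.2, 0.65, 0.05, 0.6, 0.4, 0.35)
  sel <- selectHitlSubset(ids, ent, rep("kidney", 10), cfg)
  expect_setequal(sel, c(4, 6, 8))
  # class of 4: the floor of 2 wins over round(1.2)
  sel4 <- selectHitlSubset(1:4, c(0.1, 0.4, 0.3, 0.2), rep("liver", 4), cfg)
  expect_setequal(sel4, c(2, 3))
  # class of 1: capped at class size
  expect_equal(selectHitlSubset(9L, 0.5, "spleen", cfg), 9L)
  # input order does not matter
  perm <- c(7, 2, 9, 1, 5, 10, 3, 8, 6, 4)
  sel2 <- selectHitlSubset(ids[perm], ent[perm], rep("kidney", 10), cfg)
  expect_setequal(sel2, sel)
  # ties break towards the smaller id
  selT <- selectHitlSubset(1:5, c(0.3, 0.3, 0.3, 0.3, 0.3), rep("k", 5),
                           hitlConfig(minPerClass = 1L, hitlRatio = 0.2))
  expect_equal(selT, 1L)
})

test_that("training is seeded-deterministic and inert at lr zero", {
  recs <- makeRecords("kidney", 6, imageSize = 16L)
  m <- tinyModel(organs = "kidney")
  tc <- trainConfig(maxEpochs = 2L, inputSize = 16L, batchSize = 4L, seed = 3L)
  r1 <- trainModel(m, recs, recs, tc)
  r2 <- trainModel(m, recs, recs, tc)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$model@params, r2$model@params)
  tc0 <- trainConfig(lr = 0, maxEpochs = 1L, inputSize = 16L, seed = 3L)
  r0 <- trainModel(m, recs, recs, tc0)
  expect_identical(r0$model@params, m@params)
  expect_error(trainModel(m, list(), recs, tc), "non-empty")
})

test_that("fine-tuning updates exactly the configured unfrozen set", {
  recs <- makeRecords(c("kidney", "liver"), 3, imageSize = 16L)
  m <- tinyModel()
  unfrozen <- hitlUnfrozenParams(m)
  expect_true(all(grepl("^(stage6|stage7|up6|up7|out)\\.", unfrozen)))
  expect_true("out.W" %in% unfrozen)
  expect_false("embed" %in% unfrozen)
  expect_false(any(grepl("^edge\\.", unfrozen)))
  hc <- hitlConfig(epochs = 2L, seed = 1L)
  ft <- finetuneHitl(m, recs, hc, inputSize = 16L)
  for (nm in setdiff(names(m@params), unfrozen))
    expect_identical(ft$model@params[[nm]], m@params[[nm]])
  # every unfrozen weight matrix moves (a bottleneck bias behind a dead ReLU
  # unit may legitimately see zero gradient, so biases are not required to)
  for (nm in grep("\\.W$", unfrozen, value = TRUE))
    expect_false(identical(ft$model@params[[nm]], m@params[[nm]]))
  expect_error(finetuneHitl(m, list(), hc), "non-empty")
})

test_that("EMA shadows track, freeze or follow the live weights", {
  recs <- makeRecords("kidney", 4, imageSize = 16L)
  m <- tinyModel(organs = "kidney")
  unfrozen <- hitlUnfrozenParams(m)
  # decay 0: returned weights equal the live fine-tuned weights (they moved)
  ft0 <- finetuneHitl(m, recs, hitlConfig(epochs = 1L, emaDecay = 0, seed = 1L),
                      inputSize = 16L)
  expect_false(identical(ft0$model@params[["out.W"]], m@params[["out.W"]]))
  # decay ~ 1: the shadow barely moves from the initial weights
  ft1 <- finetuneHitl(m, recs,
                      hitlConfig(epochs = 1L, emaDecay = 1 - 1e-9, seed = 1L),
                      inputSize = 16L)
  expect_equal(ft1$model@params[["out.W"]], m@params[["out.W"]],
               tolerance = 1e-6)
})

test_that("a HITL round reports per-organ recall and honours ratio one", {
  recs <- makeRecords(c("kidney", "liver"), 4, imageSize = 16L)
  m <- tinyModel()
  hr <- hitlRound(m, recs, hitlConfig(epochs = 1L, seed = 2L),
                  inputSize = 16L)
  expect_setequal(hr$report$organ, c("kidney", "liver"))
  expect_true(all(c("recallBefore", "recallAfter") %in% names(hr$report)))
  expect_true(all(hr$entropies >= 0 & hr$entropies <= log(2)))
  hrAll <- hitlRound(m, recs, hitlConfig(hitlRatio = 1, epochs = 1L, seed = 2L),
                     inputSize = 16L)
  expect_setequal(hrAll$selected, seq_along(recs))
})

test_that("uncertainty sampling concentrates on a corrupted organ class", {
  # train briefly on two organs, then corrupt one organ's images with noise:
  # its entropies should dominate the selection
  recs <- makeRecords(c("kidney", "liver"), 6, imageSize = 16L)
  m <- tinyModel()
  tr <- trainModel(m, recs, recs,
                   trainConfig(maxEpochs = 10L, inputSize = 16L, seed = 1L))
  tens <- histoseg:::prepareTensors(recs, 16L)
  organs <- tens$organs
  # wash out the contrast of one organ's images: its predictions should sit
  # nearer 0.5 and dominate the uncertainty ranking
  for (i in which(organs == "liver"))
    tens$images[[i]] <- 0.25 * tens$images[[i]] + 0.75 * 0.5
  probs <- histoseg:::predictRecords(tr$model, tens)
  ent <- vapply(probs, sampleEntropy, numeric(1))
  expect_gt(mean(ent[organs == "liver"]), mean(ent[organs == "kidney"]))
})
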