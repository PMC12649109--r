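test_that("confusion counts tabulate pixels exactly", {
  set.seed(1)
  m <- randomMask(6, 6)
  cc <- confusionCounts(m, m)
  expect_equal(cc@fp, 0); expect_equal(cc@fn, 0)
  inv <- confusionCounts(1 - m, m)
  expect_equal(inv@tp, 0); expect_equal(inv@tn, 0)
  # 4x4 toy: 4 positives, prediction hits 2 of them and adds 6 spurious
  mask <- matrix(0, 4, 4); mask[1, 1:4] <- 1
  pred <- matrix(0, 4, 4); pred[1, 1:2] <- 1; pred[2:3, 1:3] <- 1
  cc2 <- confusionCounts(pred, mask)
  expect_equal(c(cc2@tp, cc2@fp, cc2@fn, cc2@tn), c(2, 6, 2, 6))
  expect_equal(cc2@tp + cc2@fp + cc2@fn + cc2@tn, 16)
  expect_error(confusionCounts(matrix(0.5, 2, 2), matrix(0, 3, 3)), "shapes")
})

test_that("metrics follow the confusion-matrix definitions", {
  cc <- new("ConfusionCounts", tp = 2, fp = 6, fn = 2, tn = 6)
  m <- segMetrics(cc)
  expect_equal(m$recall, 0.5)
  expect_equal(m$precision, 0.25)
  expect_equal(m$dice, 1 / 3)
  expect_equal(m$iou, 0.2)
  perfect <- segMetrics(new("ConfusionCounts", tp = 5, fp = 0, fn = 0, tn = 3))
  expect_true(all(unlist(perfect) == 1))
  # dice = 2 iou / (1 + iou) identity on random counts
  set.seed(2)
  for (i in 1:20) {
    cts <- new("ConfusionCounts", tp = sample(1:50, 1), fp = sample(0:50, 1),
               fn = sample(0:50, 1), tn = sample(0:50, 1))
    mm <- segMetrics(cts)
    expect_equal(mm$dice, 2 * mm$iou / (1 + mm$iou), tolerance = 1e-12)
  }
  # empty ground truth: 1 when prediction is also empty, else 0
  both <- segMetrics(new("ConfusionCounts", tp = 0, fp = 0, fn = 0, tn = 9))
  expect_equal(both$recall, 1); expect_equal(both$dice, 1)
  spur <- segMetrics(new("ConfusionCounts", tp = 0, fp = 3, fn = 0, tn = 6))
  expect_equal(spur$recall, 0)
})

test_that("metrics are invariant under image/mask transposition", {
  set.seed(3)
  p <- matrix(runif(30), 5, 6); y <- randomMask(5, 6)
  a <- segMetrics(confusionCounts(p, y))
  b <- segMetrics(confusionCounts(t(p), t(y)))
  expect_equal(a, b)
})

test_that("false-negative reduction reproduces its closed form", {
  expect_equal(fnReduction(0.9, 0.9), 0)
  expect_equal(round(100 * fnReduction(0.8917, 0.8701), 1), 18.6)
  expect_equal(round(100 * fnReduction(0.8917, 0.9562), 1), -165.1)
  expect_error(fnReduction(0.9, 1), "undefined")
  expect_error(fnReduction(0, 0.9), "positive")
})

test_that("improvement percentages match the printed before/after pairs", {
  expect_equal(improvementPct(0.4, 0.4), 0)
  expect_equal(round(improvementPct(0.8917, 0.9053), 2), 1.53)
  expect_equal(round(improvementPct(0.6869, 0.7759), 2), 12.96)
  expect_error(improvementPct(0, 0.5), "> 0")
})

test_that("per-organ report equals a flat regroup of per-image metrics", {
  set.seed(4)
  n <- 9
  probs <- lapply(1:n, function(i) matrix(runif(64), 8, 8))
  masks <- lapply(1:n, function(i) randomMask(8, 8))
  organs <- rep(c("a", "b", "c"), each = 3)
  rep1 <- perOrganReport(probs, masks, organs)
  flat <- vapply(1:n, function(i)
    segMetrics(confusionCounts(probs[[i]], masks[[i]]))$recall, numeric(1))
  for (org in c("a", "b", "c"))
    expect_equal(rep1$recall[rep1$organ == org], mean(flat[organs == org]))
  expect_equal(rep1$recall[rep1$organ == "all"], mean(flat))
  # single organ: aggregate equals that organ's row
  rep2 <- perOrganReport(probs[1:3], masks[1:3], rep("a", 3))
  expect_equal(rep2$recall[1], rep2$recall[2])
  # exact per-image values on a constructed two-organ case
  p1 <- matrix(1, 2, 2); m1 <- matrix(1, 2, 2)         # recall 1
  p2 <- matrix(c(1, 0, 0, 0), 2, 2); m2 <- matrix(c(1, 1, 0, 0), 2, 2) # 0.5
  rep3 <- perOrganReport(list(p1, p2), list(m1, m2), c("x", "y"))
  expect_equal(rep3$recall[rep3$organ == "x"], 1)
  expect_equal(rep3$recall[rep3$organ == "y"], 0.5)
})

test_that("paired tests agree with the reference implementations", {
  before <- c(0.70, 0.75, 0.80, 0.85, 0.90, 0.72, 0.78, 0.83, 0.88, 0.92)
  same <- pairedTests(before, before)
  expect_equal(same$meanDiff, 0)
  expect_true(is.na(same$tP))
  shifted <- pairedTests(before, before + 0.05)
  expect_equal(shifted$meanDiff, 0.05, tolerance = 1e-12)
  set.seed(5)
  after <- before + rnorm(10, 0.03, 0.02)
  got <- pairedTests(before, after)
  # independent recomputation of the paired t statistic
  d <- after - before
  tstat <- mean(d) / (sd(d) / sqrt(length(d)))
  pRef <- 2 * stats::pt(-abs(tstat), df = length(d) - 1)
  expect_equal(got$tP, pRef, tolerance = 1e-12)
  expect_equal(got$wilcoxonP,
               stats::wilcox.test(after, before, paired = TRUE,
                                  exact = FALSE)$p.value)
  expect_length(got$ci, 2L)
  expect_true(got$ci[1] < got$meanDiff && got$meanDiff < got$ci[2])
})

test_that("heatmap overlay blends warm colours onto the greyscale base", {
  set.seed(6)
  img <- matrix(runif(64), 8, 8)
  out <- file.path(tempdir(), "heat.png")
  # zero probability: output equals the greyscale base
  r0 <- heatmapOverlay(img, matrix(0, 8, 8), out)
  expect_true(file.exists(out))
  for (k in 1:3) expect_equal(r0[, , k], img, tolerance = 1e-12)
  p <- matrix(seq(0, 1, length.out = 64), 8, 8)
  r1 <- heatmapOverlay(img, p, out)
  expect_equal(dim(r1), c(8L, 8L, 3L))
  # higher probability maps to warmer colour: red minus blue increases
  warmth <- r1[, , 1] - r1[, , 3]
  expect_gt(warmth[which.max(p)], warmth[which.min(p)])
  expect_equal(dim(png::readPNG(out)), c(8L, 8L, 3L))
})
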