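mkRec <- function(seed = 1, h = 16, w = 16) {
  set.seed(seed)
  img <- array(runif(h * w * 3), dim = c(h, w, 3))
  sampleRecord(img, randomMask(h, w), "kidney", 0L)
}

test_that("augmentation yields exactly four geometry-consistent copies", {
  rec <- mkRec()
  out <- augmentSample(rec, seed = 9L)
  expect_length(out, 4L)
  expect_equal(vapply(out, function(r) r@aug, character(1)),
               c("orig", "hflip", "vflip", "colour"))
  # flips move image and mask together; colour jitter leaves the mask alone
  counts <- vapply(out, function(r) sum(r@mask), numeric(1))
  expect_true(all(counts == counts[1]))
  expect_identical(out[[2]]@mask[, ncol(rec@mask):1], rec@mask)
  # involution
  again <- augmentSample(out[[2]], seed = 9L)
  expect_identical(again[[2]]@image, out[[1]]@image)
  # determinism of the jitter
  out2 <- augmentSample(rec, seed = 9L)
  expect_identical(out[[4]]@image, out2[[4]]@image)
  out3 <- augmentSample(rec, seed = 10L)
  expect_false(identical(out[[4]]@image, out3[[4]]@image))
})

test_that("greyscale conversion uses luma weights", {
  white <- array(1, dim = c(2, 2, 3))
  black <- array(0, dim = c(2, 2, 3))
  red <- array(0, dim = c(2, 2, 3)); red[, , 1] <- 1
  expect_equal(unique(as.vector(toGreyscale(white))), 1)
  expect_equal(unique(as.vector(toGreyscale(black))), 0)
  expect_equal(unique(as.vector(toGreyscale(red))), 0.299)
})

test_that("filename parsing resolves multi-word organs by longest match", {
  expect_equal(parseFilename("human_kidney_3"), list(organ = "kidney", id = 3L))
  expect_equal(parseFilename("human_salivary_gland_7"),
               list(organ = "salivary_gland", id = 7L))
  expect_equal(parseFilename("human_lung_12.png"),
               list(organ = "lung", id = 12L))
  expect_error(parseFilename("kidney_3"), "human_")
  expect_error(parseFilename("human_gallbladder_1"), "kidney")
  # encode -> parse is the identity over the whole vocabulary
  for (org in organVocabulary()) {
    p <- parseFilename(sprintf("human_%s_%d", org, 5L))
    expect_equal(p$organ, org)
    expect_equal(p$id, 5L)
  }
})

test_that("stratified split is a seeded source-level partition", {
  recs <- list()
  for (org in c("kidney", "liver")) for (id in 0:4) {
    r <- mkRec(id + 1)
    r@organ <- org; r@id <- as.integer(id)
    recs[[length(recs) + 1L]] <- r
  }
  out <- stratifiedSplit(recs, 0.8, seed = 42L)
  split <- vapply(out, function(r) r@split, character(1))
  expect_equal(sum(split == "train"), 8L)
  expect_equal(sum(split == "test"), 2L)
  out2 <- stratifiedSplit(recs, 0.8, seed = 42L)
  expect_identical(split, vapply(out2, function(r) r@split, character(1)))
  # augmented copies of one source never straddle the split
  aug <- unlist(lapply(recs, augmentSample, seed = 1L), recursive = FALSE)
  outAug <- stratifiedSplit(aug, 0.8, seed = 42L)
  key <- vapply(outAug, function(r) paste(r@organ, r@id), character(1))
  per <- tapply(vapply(outAug, function(r) r@split, character(1)), key,
                function(s) length(unique(s)))
  expect_true(all(per == 1L))
  # per-organ train fraction within one source of 0.8
  fr <- tapply(split == "train",
               vapply(out, function(r) r@organ, character(1)), mean)
  expect_true(all(abs(fr - 0.8) <= 1 / 5))
  # single-source organ goes to train with a warning
  lone <- mkRec(); lone@organ <- "tonsil"
  expect_warning(out3 <- stratifiedSplit(c(recs, list(lone)), 0.8, 42L),
                 "single source")
  expect_equal(out3[[11]]@split, "train")
})

test_that("loading resizes bilinearly for images and nearest for masks", {
  rec <- mkRec(h = 32, w = 32)
  lp <- loadPair(rec, size = 16L)
  expect_equal(dim(lp$image), c(16L, 16L))
  expect_true(all(lp$mask %in% c(0, 1)))
  # already at size: unchanged
  rec2 <- mkRec(h = 16, w = 16)
  lp2 <- loadPair(rec2, size = 16L)
  expect_equal(lp2$mask, rec2@mask)
  expect_equal(lp2$image, toGreyscale(rec2@image), tolerance = 1e-12)
  # checkerboard downsampling keeps the positive fraction near one half
  cb <- outer(0:511, 0:511, function(y, x) ((y %/% 2 + x %/% 2) %% 2)) * 1
  rec3 <- sampleRecord(array(rep(cb, 3), dim = c(512, 512, 3)), cb,
                       "kidney", 0L)
  lp3 <- loadPair(rec3, size = 224L)
  expect_true(abs(mean(lp3$mask) - 0.5) < 0.02)
})
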