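test_that("rigid alignment: identity, inverse and validation", {
  set.seed(1)
  img <- matrix(runif(40 * 50), 40, 50)
  expect_equal(alignPair(img, c(0, 0, 0)), img)
  # pure translation there and back recovers the interior exactly
  back <- alignPair(alignPair(img, c(0, 10, 0)), c(0, -10, 0))
  expect_equal(back[5:35, 15:35], img[5:35, 15:35], tolerance = 1e-10)
  expect_error(alignPair(img, c(NA, 0, 0)), "finite")
  expect_error(alignPair(matrix(numeric(0), 0, 0), c(0, 0, 0)), "empty")
})

test_that("alignment restores a synthetic misaligned pair", {
  sc <- synthConfig(imageSize = 64L, roiSize = c(224L, 288L), seed = 13L)
  pair <- generateRoiPair(sc, c(deg = -4, dx = 18, dy = 9))
  al <- alignPair(pair@ihc, pair@trueTransform)
  m <- hsvMask(al, maskGenConfig(minArea = 16))
  expect_gte(sum(m@mask * pair@mask) / sum(pair@mask), 0.85)
  expect_gte(diceOf(m@mask, pair@mask), 0.85)
})

test_that("patch extraction follows the stride lattice", {
  mk <- function(h, w) matrix(0, h, w)
  expect_length(extractPatches(mk(512, 512), mk(512, 512)), 1L)
  p <- extractPatches(mk(512, 512), mk(512, 512))
  expect_equal(p[[1]]$origin, c(row = 1L, col = 1L))
  expect_length(extractPatches(mk(768, 512), mk(768, 512)), 2L)
  expect_length(extractPatches(mk(1500, 2100), mk(1500, 2100)), 28L)
  expect_warning(out <- extractPatches(mk(100, 100), mk(100, 100)),
                 "smaller than patch")
  expect_length(out, 0L)
  expect_error(extractPatches(mk(512, 512), mk(512, 256)), "share")
})

test_that("patch counts match brute-force enumeration of valid origins", {
  set.seed(42)
  for (i in 1:50) {
    patch <- sample(4:12, 1)
    stride <- sample(2:8, 1)
    h <- sample(patch:40, 1); w <- sample(patch:40, 1)
    got <- length(extractPatches(matrix(0, h, w), matrix(0, h, w),
                                 patch = patch, stride = stride))
    brute <- 0L
    for (r in seq(0L, h, by = stride)) for (cc in seq(0L, w, by = stride))
      if (r + patch <= h && cc + patch <= w) brute <- brute + 1L
    expect_identical(got, brute)
  }
})

dabPatch <- function(h, w, rows, cols) {
  # white background with a DAB-brown block (hue ~30 deg)
  img <- array(1, dim = c(h, w, 3))
  img[rows, cols, 1] <- 0.55
  img[rows, cols, 2] <- 0.35
  img[rows, cols, 3] <- 0.15
  img
}

test_that("HSV gate keeps DAB and rejects the blue counterstain", {
  blue <- array(0, dim = c(32, 32, 3)); blue[, , 3] <- 1
  expect_equal(sum(hsvMask(blue)@mask), 0)
  sq <- dabPatch(100, 100, 21:80, 21:80)
  m <- hsvMask(sq)@mask
  expect_gte(sum(m), 3400)  # 3600 minus corner erosion from opening
  expect_lte(sum(m), 3600)
  expect_equal(sum(m[21:80, 21:80]), sum(m))  # nothing outside the square
  # small speck below the area threshold disappears
  speck <- dabPatch(64, 64, 30:31, 30:34)
  expect_equal(sum(hsvMask(speck, maskGenConfig(minArea = 50,
                                                openRadius = 0))@mask), 0)
  expect_error(hsvMask(matrix(0.5, 8, 8)), "RGB")
})

test_that("HED deconvolution mask recovers a DAB blob", {
  blank <- array(1, dim = c(32, 32, 3))
  expect_warning(m0 <- hedMask(blank), "constant")
  expect_equal(sum(m0@mask), 0)
  sq <- dabPatch(128, 128, 31:98, 31:98)
  m <- hedMask(sq)@mask
  truth <- matrix(0, 128, 128); truth[31:98, 31:98] <- 1
  expect_gte(diceOf(m, truth), 0.90)
})

test_that("HED mask is invariant to a small uniform brightness offset", {
  sc <- synthConfig(imageSize = 96L, seed = 3L)
  s <- generateSample(sc, "liver", 1)
  base <- hedMask(s@ihc)@mask
  for (off in c(-0.05, 0.05)) {
    shifted <- clamp <- pmin(pmax(s@ihc * (1 + off), 1e-4), 1)
    m <- hedMask(shifted)@mask
    expect_gte(mean(m == base), 0.99)
  }
})

test_that("OR fusion is exact, monotone and validated", {
  z <- matrix(0, 10, 10)
  a <- z; a[1:5, 1:2] <- 1          # 10 px
  b <- z; b[8:10, 6:10] <- 1        # 15 px, disjoint
  ca <- new("CandidateMask", mask = a, method = "HSV")
  cb <- new("CandidateMask", mask = b, method = "HED")
  expect_equal(sum(fuseMasks(ca, cb)), 25)
  expect_equal(fuseMasks(z, z), z)
  expect_equal(fuseMasks(ca, z), a)
  fused <- fuseMasks(ca, cb)
  expect_true(all(fused >= a) && all(fused >= b))
  expect_error(fuseMasks(a, matrix(0, 5, 5)), "shape")
})
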