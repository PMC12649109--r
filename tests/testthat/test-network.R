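test_that("organ embedding is a differentiable row lookup", {
  m <- tinyModel()
  z1 <- embedOrgan(m, 1L)
  z2 <- embedOrgan(m, 1L)
  expect_identical(z1, z2)
  expect_equal(dim(z1), c(1L, 3L))
  expect_error(embedOrgan(m, 5L), "out of range")
  m@params$embed[] <- 0
  expect_equal(as.vector(embedOrgan(m, 2L)), c(0, 0, 0))
  # gradient of a loss touches only the looked-up row
  m <- tinyModel()
  for (nm in grep("film", names(m@params), value = TRUE))
    m@params[[nm]][] <- rnorm(length(m@params[[nm]]), 0, 0.3)
  set.seed(2)
  img <- list(matrix(runif(256), 16, 16))
  msk <- list(randomMask(16, 16))
  fb <- histoseg:::batchForwardBackward(m@params, m@config, img, msk, 2L,
                                        lossWeights())
  expect_true(all(fb$grads$embed[1, ] == 0))
  expect_true(any(fb$grads$embed[2, ] != 0))
})

test_that("FiLM is a channel-wise affine with scale confined to (1,2)", {
  m <- tinyModel()
  set.seed(4)
  F <- array(rnorm(2 * 4 * 6 * 6), dim = c(2, 4, 6, 6))
  z <- embedOrgan(m, c(1L, 2L))
  # zero linear maps: sigma(0) = 0.5, so output is exactly 1.5 F
  out <- filmModulate(m, F, z, stage = 1L)
  expect_equal(out, 1.5 * F, tolerance = 1e-12)
  # random parameters against an explicit per-channel scalar loop
  m@params$stage1.film.Wg[] <- rnorm(length(m@params$stage1.film.Wg))
  m@params$stage1.film.bg[] <- rnorm(4)
  m@params$stage1.film.Wb[] <- rnorm(length(m@params$stage1.film.Wb))
  m@params$stage1.film.bb[] <- rnorm(4)
  out <- filmModulate(m, F, z, stage = 1L)
  for (b in 1:2) {
    gam <- 1 / (1 + exp(-(z[b, ] %*% m@params$stage1.film.Wg +
                            m@params$stage1.film.bg)))
    bet <- z[b, ] %*% m@params$stage1.film.Wb + m@params$stage1.film.bb
    expect_true(all(1 + gam > 1 & 1 + gam < 2))
    for (cc in 1:4)
      expect_equal(out[b, cc, , ], (1 + gam[cc]) * F[b, cc, , ] + bet[cc],
                   tolerance = 1e-12)
  }
  expect_equal(dim(out), dim(F))
  expect_error(filmModulate(m, array(0, c(1, 5, 4, 4)), z[1, , drop = FALSE], 1L),
               "channel mismatch")
})

test_that("SE recalibration gates each channel with a weight in (0,1)", {
  m <- tinyModel()
  set.seed(5)
  F <- array(abs(rnorm(2 * 4 * 6 * 6)), dim = c(2, 4, 6, 6))
  res <- seRecalibrate(m, F, stage = 1L)
  expect_true(all(res$weights > 0 & res$weights < 1))
  expect_true(all(abs(res$F) <= abs(F)))
  expect_equal(dim(res$F), dim(F))
  expect_equal(seRecalibrate(m, F * 0, 1L)$F, F * 0)
  # hand-rolled two-matrix computation on a 2-channel 2x2 input
  W1 <- matrix(c(0.5, -0.3, 0.2, 0.7), 2, 2)
  W2 <- matrix(c(-0.2, 0.4, 0.1, 0.3), 2, 2)
  b1 <- c(0.05, -0.1); b2 <- c(0.2, -0.3)
  Fs <- array(c(1, 2, 3, 4, 5, 6, 7, 8), dim = c(1, 2, 2, 2))
  f <- histoseg:::fmFromArray(Fs)
  got <- histoseg:::seForward(f, W1, b1, W2, b2)
  g <- c(mean(Fs[1, 1, , ]), mean(Fs[1, 2, , ]))
  h <- pmax(g %*% W1 + b1, 0)
  wexp <- 1 / (1 + exp(-(h %*% W2 + b2)))
  expect_equal(as.vector(got$weights), as.vector(wexp), tolerance = 1e-12)
  arr <- histoseg:::arrayFromFm(got)
  expect_equal(arr[1, 1, , ], Fs[1, 1, , ] * wexp[1], tolerance = 1e-12)
  expect_equal(arr[1, 2, , ], Fs[1, 2, , ] * wexp[2], tolerance = 1e-12)
})

test_that("edge head preserves shape and zero init gives 0.5 maps", {
  m <- tinyModel()
  set.seed(6)
  F <- array(rnorm(2 * 4 * 8 * 8), dim = c(2, 4, 8, 8))
  e <- edgeHead(m, F)
  expect_equal(dim(e), c(2L, 8L, 8L))
  for (nm in grep("^edge\\.", names(m@params), value = TRUE))
    m@params[[nm]][] <- 0
  e0 <- edgeHead(m, F)
  expect_true(all(e0 == 0.5))
})

test_that("forward pass honours contracts and organ conditioning", {
  m <- tinyModel()
  set.seed(7)
  imgs <- list(matrix(runif(256), 16, 16), matrix(runif(256), 16, 16))
  out <- forwardPass(m, imgs, c("kidney", "liver"))
  expect_equal(dim(out@prob), c(2L, 16L, 16L))
  expect_equal(dim(out@edgeProb), c(2L, 16L, 16L))
  expect_true(all(out@prob > 0 & out@prob < 1))
  expect_true(all(is.finite(out@prob)))
  expect_error(forwardPass(m, matrix(0.5, 15, 15), "kidney"), "divisible")
  # with zero FiLM parameters the output is organ-independent
  same <- forwardPass(m, imgs[[1]], "kidney")@prob
  other <- forwardPass(m, imgs[[1]], "liver")@prob
  expect_equal(same, other, tolerance = 1e-12)
  # with non-zero FiLM maps, different organs give different outputs
  for (nm in grep("film\\.W", names(m@params), value = TRUE))
    m@params[[nm]][] <- rnorm(length(m@params[[nm]]), 0, 0.5)
  d1 <- forwardPass(m, imgs[[1]], "kidney")@prob
  d2 <- forwardPass(m, imgs[[1]], "liver")@prob
  expect_gt(max(abs(d1 - d2)), 1e-6)
})

test_that("ablation flags generate all eight architecture variants", {
  set.seed(8)
  img <- matrix(runif(256), 16, 16)
  for (se in c(FALSE, TRUE)) for (fl in c(FALSE, TRUE)) for (ed in c(FALSE, TRUE)) {
    m <- tinyModel(useSE = se, useFiLM = fl, useEdge = ed)
    nm <- names(m@params)
    expect_equal(any(grepl("\\.se\\.", nm)), se)
    expect_equal(any(grepl("\\.film\\.", nm)), fl)
    expect_equal(any(grepl("^edge\\.", nm)), ed)
    out <- forwardPass(m, img, "kidney")
    expect_equal(dim(out@prob), c(1L, 16L, 16L))
    if (ed) expect_equal(dim(out@edgeProb), c(1L, 16L, 16L))
  }
})

test_that("parameter counting is exact per module", {
  cfg <- tinyNetConfig(embedDim = 32L)
  m <- segNetwork(cfg, organs = paste0("o", 1:5), seed = 1)
  cp <- countParameters(m)
  expect_equal(unname(cp$perModule["embed"]), 5 * 32)
  m2 <- segNetwork(tinyNetConfig(embedDim = 64L), organs = paste0("o", 1:5),
                   seed = 1)
  expect_equal(unname(countParameters(m2)$perModule["embed"]), 2 * 5 * 32)
  expect_equal(cp$total, sum(vapply(m@params, length, numeric(1))))
})
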