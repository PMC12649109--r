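# The organ-conditioned segmentation network: a symmetric encoder-decoder
# backbone (four encoder stages, the fourth acting as bottleneck, and three
# decoder stages with skip concatenation), per-stage squeeze-and-excitation
# recalibration and FiLM organ conditioning, and a dilated-convolution edge
# head on the last decoder features. Stage order: convs -> SE -> FiLM.

#' Build a network configuration
#'
#' Defaults give the full-size architecture: greyscale input, stage widths
#' (64,128,256,512,256,128,64), 32-dimensional organ embedding, SE reduction
#' 16, edge-head dilation rates (1,2,3) and nominal input size 224. The three
#' module flags span the 8 ablation variants (plain backbone through the full
#' model).
#'
#' @param inChannels input channels (1 = greyscale).
#' @param stageChannels the seven stage widths.
#' @param embedDim organ-embedding dimension.
#' @param seReduction SE bottleneck ratio.
#' @param useSE,useFiLM,useEdge module toggles.
#' @param inputSize nominal input side (any multiple of 8 accepted at forward).
#' @return a \code{NetworkConfig}.
#' @export
networkConfig <- function(inChannels = 1L,
                          stageChannels = c(64L, 128L, 256L, 512L, 256L, 128L, 64L),
                          embedDim = 32L, seReduction = 16L,
                          useSE = TRUE, useFiLM = TRUE, useEdge = TRUE,
                          inputSize = 224L) {
  new("NetworkConfig", inChannels = as.integer(inChannels),
      stageChannels = as.integer(stageChannels), embedDim = as.integer(embedDim),
      seReduction = as.integer(seReduction), dilations = c(1L, 2L, 3L),
      useSE = useSE, useFiLM = useFiLM, useEdge = useEdge,
      inputSize = as.integer(inputSize))
}

stageInChannels <- function(cfg) {
  C <- cfg@stageChannels
  c(cfg@inChannels, C[1], C[2], C[3], 2L * C[5], 2L * C[6], 2L * C[7])
}

edgeWidths <- function() list(stem = 32L, branch = 32L, fuse = 32L)

#' Build a segmentation network
#'
#' Initialises all parameters (He-normal convolutions, zero FiLM linear maps
#' so conditioning starts as the identity-plus-half scale, normal organ
#' embeddings) under the given seed.
#'
#' @param config a \code{NetworkConfig}.
#' @param organs ordered organ vocabulary; labels are indices into it.
#' @param seed integer init seed.
#' @return a \code{SegNetwork}.
#' @export
segNetwork <- function(config = networkConfig(), organs, seed = 1L) {
  C <- config@stageChannels
  Cin <- stageInChannels(config)
  d <- config@embedDim
  K <- length(organs)
  withSeed(seed, {
    p <- list()
    p$embed <- matrix(rnorm(K * d, 0, 0.5), K, d)
    for (s in 1:7) {
      pre <- sprintf("stage%d", s)
      p[[paste0(pre, ".c1.W")]] <- heInitMat(9L * Cin[s], C[s])
      p[[paste0(pre, ".c1.b")]] <- numeric(C[s])
      p[[paste0(pre, ".c2.W")]] <- heInitMat(9L * C[s], C[s])
      p[[paste0(pre, ".c2.b")]] <- numeric(C[s])
      if (config@useSE) {
        Cr <- max(1L, C[s] %/% config@seReduction)
        p[[paste0(pre, ".se.W1")]] <- heInitMat(C[s], Cr)
        p[[paste0(pre, ".se.b1")]] <- numeric(Cr)
        p[[paste0(pre, ".se.W2")]] <- heInitMat(Cr, C[s])
        p[[paste0(pre, ".se.b2")]] <- numeric(C[s])
      }
      if (config@useFiLM) {
        p[[paste0(pre, ".film.Wg")]] <- matrix(0, d, C[s])
        p[[paste0(pre, ".film.bg")]] <- numeric(C[s])
        p[[paste0(pre, ".film.Wb")]] <- matrix(0, d, C[s])
        p[[paste0(pre, ".film.bb")]] <- numeric(C[s])
      }
    }
    for (s in 5:7) {
      srcC <- if (s == 5L) C[4] else C[s - 1L]
      W <- array(rnorm(srcC * C[s] * 4L, 0, sqrt(2 / srcC)), c(srcC, C[s], 4L))
      p[[sprintf("up%d.W", s)]] <- W
      p[[sprintf("up%d.b", s)]] <- numeric(C[s])
    }
    p$out.W <- heInitMat(C[7], 1L)
    p$out.b <- numeric(1L)
    if (config@useEdge) {
      ew <- edgeWidths()
      p$edge.stem1.W <- heInitMat(9L * C[7], ew$stem); p$edge.stem1.b <- numeric(ew$stem)
      p$edge.stem2.W <- heInitMat(9L * ew$stem, ew$stem); p$edge.stem2.b <- numeric(ew$stem)
      for (k in 1:3) {
        p[[sprintf("edge.br%d.W", k)]] <- heInitMat(9L * ew$stem, ew$branch)
        p[[sprintf("edge.br%d.b", k)]] <- numeric(ew$branch)
      }
      p$edge.f1.W <- heInitMat(3L * ew$branch, ew$fuse); p$edge.f1.b <- numeric(ew$fuse)
      p$edge.f2.W <- heInitMat(ew$fuse, 1L); p$edge.f2.b <- numeric(1L)
    }
    new("SegNetwork", config = config, organs = organs, params = p)
  })
}

# 4-D feature array (B, C, H, W) <-> internal fm
fmFromArray <- function(arr) {
  d <- dim(arr)
  B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  X <- matrix(0, B * H * W, C)
  for (cc in seq_len(C)) {
    m <- array(arr[, cc, , ], dim = c(B, H, W))
    X[, cc] <- as.vector(aperm(m, c(3, 2, 1)))
  }
  fm(X, B, H, W)
}

arrayFromFm <- function(f) {
  C <- ncol(f$x)
  arr <- array(0, dim = c(f$B, C, f$H, f$W))
  for (cc in seq_len(C)) {
    m <- array(f$x[, cc], dim = c(f$W, f$H, f$B))
    arr[, cc, , ] <- aperm(m, c(3, 2, 1))
  }
  arr
}

#' Look up organ embeddings
#'
#' Row \code{y} of the learnable embedding table for each label.
#'
#' @param model a \code{SegNetwork}.
#' @param y integer labels in 1..K.
#' @return length(y) x d matrix.
#' @export
embedOrgan <- function(model, y) {
  K <- nrow(model@params$embed)
  if (any(y < 1L | y > K)) stop("organ label out of range 1..", K)
  model@params$embed[y, , drop = FALSE]
}

#' FiLM-modulate a feature map
#'
#' Channel-wise affine conditioning \code{(1 + sigmoid(Wg z + bg)) * F +
#' (Wb z + bb)} using the linear maps of the given stage; the scale is
#' confined to (1,2) and spatial dimensions are untouched.
#'
#' @param model a \code{SegNetwork} (with FiLM enabled).
#' @param F numeric array B x C x H x W; C must match the stage width.
#' @param z embedding matrix B x d (see \code{\link{embedOrgan}}).
#' @param stage stage index 1..7.
#' @return modulated array of identical shape.
#' @export
filmModulate <- function(model, F, z, stage) {
  cfg <- model@config
  if (!cfg@useFiLM) stop("FiLM is disabled in this configuration")
  Cs <- cfg@stageChannels[stage]
  if (dim(F)[2] != Cs)
    stop(sprintf("channel mismatch: stage %d expects %d channels, got %d",
                 stage, Cs, dim(F)[2]))
  pre <- sprintf("stage%d.film.", stage)
  f <- fmFromArray(F)
  out <- filmForward(f, z, model@params[[paste0(pre, "Wg")]],
                     model@params[[paste0(pre, "bg")]],
                     model@params[[paste0(pre, "Wb")]],
                     model@params[[paste0(pre, "bb")]])
  arrayFromFm(out)
}

#' Squeeze-and-excitation recalibration
#'
#' Global average pooling, bottleneck MLP and sigmoid gating produce one
#' weight in (0,1) per channel; the feature map is scaled channel-wise.
#'
#' @param model a \code{SegNetwork} (with SE enabled).
#' @param F numeric array B x C x H x W matching the stage width.
#' @param stage stage index 1..7.
#' @return list(F = recalibrated array, weights = B x C gate matrix).
#' @export
seRecalibrate <- function(model, F, stage) {
  cfg <- model@config
  if (!cfg@useSE) stop("SE is disabled in this configuration")
  pre <- sprintf("stage%d.se.", stage)
  f <- fmFromArray(F)
  out <- seForward(f, model@params[[paste0(pre, "W1")]],
                   model@params[[paste0(pre, "b1")]],
                   model@params[[paste0(pre, "W2")]],
                   model@params[[paste0(pre, "b2")]])
  list(F = arrayFromFm(out), weights = out$weights)
}

# one encoder/decoder stage: double conv + ReLU, then SE, then FiLM
stageForward <- function(p, cfg, f, s, z, train) {
  pre <- sprintf("stage%d", s)
  cc <- list()
  f <- convForward(f, p[[paste0(pre, ".c1.W")]], p[[paste0(pre, ".c1.b")]],
                   train = train); cc$c1 <- f$cache
  f <- reluForward(f, train); cc$r1 <- f$cache
  f <- convForward(f, p[[paste0(pre, ".c2.W")]], p[[paste0(pre, ".c2.b")]],
                   train = train); cc$c2 <- f$cache
  f <- reluForward(f, train); cc$r2 <- f$cache
  if (cfg@useSE) {
    f <- seForward(f, p[[paste0(pre, ".se.W1")]], p[[paste0(pre, ".se.b1")]],
                   p[[paste0(pre, ".se.W2")]], p[[paste0(pre, ".se.b2")]],
                   train); cc$se <- f$cache
  }
  if (cfg@useFiLM) {
    f <- filmForward(f, z, p[[paste0(pre, ".film.Wg")]],
                     p[[paste0(pre, ".film.bg")]],
                     p[[paste0(pre, ".film.Wb")]],
                     p[[paste0(pre, ".film.bb")]], train); cc$film <- f$cache
  }
  list(f = f, cache = cc)
}

stageBackward <- function(p, cfg, cache, s, dOut, B, H, W, grads) {
  pre <- sprintf("stage%d", s)
  dz <- NULL
  if (cfg@useFiLM) {
    fb <- filmBackward(cache$film, p[[paste0(pre, ".film.Wg")]],
                       p[[paste0(pre, ".film.Wb")]], dOut)
    grads[[paste0(pre, ".film.Wg")]] <- grads[[paste0(pre, ".film.Wg")]] + fb$dWg
    grads[[paste0(pre, ".film.bg")]] <- grads[[paste0(pre, ".film.bg")]] + fb$dbg
    grads[[paste0(pre, ".film.Wb")]] <- grads[[paste0(pre, ".film.Wb")]] + fb$dWb
    grads[[paste0(pre, ".film.bb")]] <- grads[[paste0(pre, ".film.bb")]] + fb$dbb
    dOut <- fb$dX; dz <- fb$dz
  }
  if (cfg@useSE) {
    sb <- seBackward(cache$se, p[[paste0(pre, ".se.W1")]],
                     p[[paste0(pre, ".se.W2")]], dOut)
    grads[[paste0(pre, ".se.W1")]] <- grads[[paste0(pre, ".se.W1")]] + sb$dW1
    grads[[paste0(pre, ".se.b1")]] <- grads[[paste0(pre, ".se.b1")]] + sb$db1
    grads[[paste0(pre, ".se.W2")]] <- grads[[paste0(pre, ".se.W2")]] + sb$dW2
    grads[[paste0(pre, ".se.b2")]] <- grads[[paste0(pre, ".se.b2")]] + sb$db2
    dOut <- sb$dX
  }
  dOut <- reluBackward(cache$r2, dOut)
  cb <- convBackward(cache$c2, p[[paste0(pre, ".c2.W")]], dOut, B, H, W)
  grads[[paste0(pre, ".c2.W")]] <- grads[[paste0(pre, ".c2.W")]] + cb$dW
  grads[[paste0(pre, ".c2.b")]] <- grads[[paste0(pre, ".c2.b")]] + cb$db
  dOut <- reluBackward(cache$r1, cb$dX)
  cb <- convBackward(cache$c1, p[[paste0(pre, ".c1.W")]], dOut, B, H, W)
  grads[[paste0(pre, ".c1.W")]] <- grads[[paste0(pre, ".c1.W")]] + cb$dW
  grads[[paste0(pre, ".c1.b")]] <- grads[[paste0(pre, ".c1.b")]] + cb$db
  list(dX = cb$dX, dz = dz, grads = grads)
}

edgeForward <- function(p, f7, train) {
  cc <- list()
  f <- convForward(f7, p$edge.stem1.W, p$edge.stem1.b, train = train); cc$c1 <- f$cache
  f <- reluForward(f, train); cc$r1 <- f$cache
  f <- convForward(f, p$edge.stem2.W, p$edge.stem2.b, train = train); cc$c2 <- f$cache
  f <- reluForward(f, train); cc$r2 <- f$cache
  brs <- vector("list", 3L)
  for (k in 1:3) {
    bk <- convForward(f, p[[sprintf("edge.br%d.W", k)]],
                      p[[sprintf("edge.br%d.b", k)]], dil = k, train = train)
    cc[[sprintf("b%dconv", k)]] <- bk$cache
    bk <- reluForward(bk, train); cc[[sprintf("b%drelu", k)]] <- bk$cache
    brs[[k]] <- bk
  }
  cat <- fm(cbind(brs[[1]]$x, brs[[2]]$x, brs[[3]]$x), f$B, f$H, f$W)
  g <- conv1x1Forward(cat, p$edge.f1.W, p$edge.f1.b, train); cc$f1 <- g$cache
  g <- reluForward(g, train); cc$fr <- g$cache
  g <- conv1x1Forward(g, p$edge.f2.W, p$edge.f2.b, train); cc$f2 <- g$cache
  list(logit = g, cache = cc)
}

edgeBackward <- function(p, cache, dLogit, B, H, W, grads) {
  cb <- conv1x1Backward(cache$f2, p$edge.f2.W, dLogit)
  grads$edge.f2.W <- grads$edge.f2.W + cb$dW
  grads$edge.f2.b <- grads$edge.f2.b + cb$db
  d <- reluBackward(cache$fr, cb$dX)
  cb <- conv1x1Backward(cache$f1, p$edge.f1.W, d)
  grads$edge.f1.W <- grads$edge.f1.W + cb$dW
  grads$edge.f1.b <- grads$edge.f1.b + cb$db
  w <- ncol(cb$dX) / 3L
  dstem <- 0
  for (k in 1:3) {
    dk <- cb$dX[, (k - 1L) * w + seq_len(w), drop = FALSE]
    dk <- reluBackward(cache[[sprintf("b%drelu", k)]], dk)
    bk <- convBackward(cache[[sprintf("b%dconv", k)]],
                       p[[sprintf("edge.br%d.W", k)]], dk, B, H, W)
    grads[[sprintf("edge.br%d.W", k)]] <- grads[[sprintf("edge.br%d.W", k)]] + bk$dW
    grads[[sprintf("edge.br%d.b", k)]] <- grads[[sprintf("edge.br%d.b", k)]] + bk$db
    dstem <- dstem + bk$dX
  }
  d <- reluBackward(cache$r2, dstem)
  cb <- convBackward(cache$c2, p$edge.stem2.W, d, B, H, W)
  grads$edge.stem2.W <- grads$edge.stem2.W + cb$dW
  grads$edge.stem2.b <- grads$edge.stem2.b + cb$db
  d <- reluBackward(cache$r1, cb$dX)
  cb <- convBackward(cache$c1, p$edge.stem1.W, d, B, H, W)
  grads$edge.stem1.W <- grads$edge.stem1.W + cb$dW
  grads$edge.stem1.b <- grads$edge.stem1.b + cb$db
  list(dX = cb$dX, grads = grads)
}

# full forward pass; returns probabilities, logits and (train) caches
networkForward <- function(p, cfg, x, ylab, train = FALSE) {
  B <- x$B
  z <- p$embed[ylab, , drop = FALSE]
  cc <- list(dims = list())
  s1 <- stageForward(p, cfg, x, 1L, z, train); cc$s1 <- s1$cache
  pl1 <- poolForward(s1$f, train); cc$p1 <- pl1$cache
  s2 <- stageForward(p, cfg, pl1, 2L, z, train); cc$s2 <- s2$cache
  pl2 <- poolForward(s2$f, train); cc$p2 <- pl2$cache
  s3 <- stageForward(p, cfg, pl2, 3L, z, train); cc$s3 <- s3$cache
  pl3 <- poolForward(s3$f, train); cc$p3 <- pl3$cache
  s4 <- stageForward(p, cfg, pl3, 4L, z, train); cc$s4 <- s4$cache

  u5 <- tconvForward(s4$f, p$up5.W, p$up5.b, train); cc$u5 <- u5$cache
  cat5 <- fm(cbind(u5$x, s3$f$x), B, u5$H, u5$W)
  s5 <- stageForward(p, cfg, cat5, 5L, z, train); cc$s5 <- s5$cache
  u6 <- tconvForward(s5$f, p$up6.W, p$up6.b, train); cc$u6 <- u6$cache
  cat6 <- fm(cbind(u6$x, s2$f$x), B, u6$H, u6$W)
  s6 <- stageForward(p, cfg, cat6, 6L, z, train); cc$s6 <- s6$cache
  u7 <- tconvForward(s6$f, p$up7.W, p$up7.b, train); cc$u7 <- u7$cache
  cat7 <- fm(cbind(u7$x, s1$f$x), B, u7$H, u7$W)
  s7 <- stageForward(p, cfg, cat7, 7L, z, train); cc$s7 <- s7$cache

  segLogit <- conv1x1Forward(s7$f, p$out.W, p$out.b, train); cc$out <- segLogit$cache
  res <- list(
    segLogit = segLogit, prob = sigmoid(segLogit$x),
    B = B, H = segLogit$H, W = segLogit$W
  )
  if (cfg@useEdge) {
    eh <- edgeForward(p, s7$f, train); cc$edge <- eh$cache
    res$edgeLogit <- eh$logit
    res$edgeProb <- sigmoid(eh$logit$x)
  }
  if (train) {
    cc$dimList <- list(
      s1 = c(s1$f$H, s1$f$W), s2 = c(s2$f$H, s2$f$W), s3 = c(s3$f$H, s3$f$W),
      s4 = c(s4$f$H, s4$f$W), s5 = c(s5$f$H, s5$f$W), s6 = c(s6$f$H, s6$f$W),
      s7 = c(s7$f$H, s7$f$W)
    )
    cc$C <- cfg@stageChannels
    cc$ylab <- ylab
    res$cache <- cc
  }
  res
}

# full backward pass from gradients w.r.t. the two output logits
networkBackward <- function(p, cfg, cache, dSegLogit, dEdgeLogit, B) {
  grads <- lapply(p, function(v) v * 0)
  dims <- cache$dimList
  C <- cache$C
  dzTotal <- 0
  addz <- function(dz) if (!is.null(dz)) dzTotal <<- dzTotal + dz

  cb <- conv1x1Backward(cache$out, p$out.W, dSegLogit)
  grads$out.W <- grads$out.W + cb$dW
  grads$out.b <- grads$out.b + cb$db
  d7 <- cb$dX
  if (cfg@useEdge && !is.null(dEdgeLogit)) {
    eb <- edgeBackward(p, cache$edge, dEdgeLogit, B, dims$s7[1], dims$s7[2], grads)
    grads <- eb$grads
    d7 <- d7 + eb$dX
  }
  sb <- stageBackward(p, cfg, cache$s7, 7L, d7, B, dims$s7[1], dims$s7[2], grads)
  grads <- sb$grads; addz(sb$dz)
  dcat7 <- sb$dX
  du7 <- dcat7[, seq_len(C[7]), drop = FALSE]
  dskip1 <- dcat7[, C[7] + seq_len(C[7]), drop = FALSE]
  tb <- tconvBackward(cache$u7, p$up7.W, du7)
  grads$up7.W <- grads$up7.W + tb$dW; grads$up7.b <- grads$up7.b + tb$db
  d6 <- tb$dX

  sb <- stageBackward(p, cfg, cache$s6, 6L, d6, B, dims$s6[1], dims$s6[2], grads)
  grads <- sb$grads; addz(sb$dz)
  dcat6 <- sb$dX
  du6 <- dcat6[, seq_len(C[6]), drop = FALSE]
  dskip2 <- dcat6[, C[6] + seq_len(C[6]), drop = FALSE]
  tb <- tconvBackward(cache$u6, p$up6.W, du6)
  grads$up6.W <- grads$up6.W + tb$dW; grads$up6.b <- grads$up6.b + tb$db
  d5 <- tb$dX

  sb <- stageBackward(p, cfg, cache$s5, 5L, d5, B, dims$s5[1], dims$s5[2], grads)
  grads <- sb$grads; addz(sb$dz)
  dcat5 <- sb$dX
  du5 <- dcat5[, seq_len(C[5]), drop = FALSE]
  dskip3 <- dcat5[, C[5] + seq_len(C[5]), drop = FALSE]
  tb <- tconvBackward(cache$u5, p$up5.W, du5)
  grads$up5.W <- grads$up5.W + tb$dW; grads$up5.b <- grads$up5.b + tb$db
  d4 <- tb$dX

  sb <- stageBackward(p, cfg, cache$s4, 4L, d4, B, dims$s4[1], dims$s4[2], grads)
  grads <- sb$grads; addz(sb$dz)
  d <- poolBackward(cache$p3, sb$dX, B)
  sb <- stageBackward(p, cfg, cache$s3, 3L, d + dskip3, B, dims$s3[1], dims$s3[2], grads)
  grads <- sb$grads; addz(sb$dz)
  d <- poolBackward(cache$p2, sb$dX, B)
  sb <- stageBackward(p, cfg, cache$s2, 2L, d + dskip2, B, dims$s2[1], dims$s2[2], grads)
  grads <- sb$grads; addz(sb$dz)
  d <- poolBackward(cache$p1, sb$dX, B)
  sb <- stageBackward(p, cfg, cache$s1, 1L, d + dskip1, B, dims$s1[1], dims$s1[2], grads)
  grads <- sb$grads; addz(sb$dz)

  if (cfg@useFiLM && !identical(dzTotal, 0)) {
    dEmb <- matrix(0, nrow(p$embed), ncol(p$embed))
    ylab <- cache$ylab
    for (i in seq_along(ylab))
      dEmb[ylab[i], ] <- dEmb[ylab[i], ] + dzTotal[i, ]
    grads$embed <- grads$embed + dEmb
  }
  grads
}

#' Run a forward pass
#'
#' @param model a \code{SegNetwork}.
#' @param images list of H x W matrices (or a single matrix); H and W must be
#'   divisible by 8.
#' @param organs integer labels (1..K) or organ names from the vocabulary.
#' @return a \code{SegmentationOutput} with B x H x W probability arrays.
#' @export
forwardPass <- function(model, images, organs) {
  if (is.matrix(images)) images <- list(images)
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  if (H %% 8L != 0L || W %% 8L != 0L)
    stop("input size must be divisible by 8")
  ylab <- organToLabel(model, organs)
  x <- stackBatch(images)
  res <- networkForward(model@params, model@config, x, ylab, train = FALSE)
  B <- length(images)
  toArr <- function(v) {
    a <- array(0, dim = c(B, H, W))
    HW <- H * W
    for (b in seq_len(B)) a[b, , ] <- vec2mat(v[(b - 1) * HW + seq_len(HW)], H, W)
    a
  }
  prob <- toArr(res$prob)
  edge <- if (model@config@useEdge) toArr(res$edgeProb) else array(0.5, c(0, 0, 0))
  new("SegmentationOutput", prob = prob, edgeProb = edge)
}

#' Map organ names to integer labels
#'
#' @param model a \code{SegNetwork}.
#' @param organs character names or integer labels.
#' @return integer labels in 1..K.
#' @export
organToLabel <- function(model, organs) {
  if (is.numeric(organs)) {
    y <- as.integer(organs)
  } else {
    y <- match(organs, model@organs)
    if (anyNA(y)) stop("unknown organ(s): ",
                       paste(organs[is.na(y)], collapse = ", "))
  }
  if (any(y < 1L | y > length(model@organs)))
    stop("organ label out of range 1..", length(model@organs))
  y
}

#' Edge head on decoder features
#'
#' Two purifying 3x3 convolutions, three parallel dilated 3x3 convolutions
#' (rates 1,2,3, same padding), concatenation and two 1x1 convolutions down
#' to one sigmoid channel. Spatial size is preserved end to end.
#'
#' @param model a \code{SegNetwork} with the edge head enabled.
#' @param F numeric array B x C7 x H x W of last-decoder-stage features.
#' @return numeric array B x H x W of edge probabilities.
#' @export
edgeHead <- function(model, F) {
  if (!model@config@useEdge) stop("edge head is disabled in this configuration")
  f <- fmFromArray(F)
  eh <- edgeForward(model@params, f, train = FALSE)
  out <- arrayFromFm(fm(sigmoid(eh$logit$x), f$B, f$H, f$W))
  array(out[, 1L, , ], dim = c(f$B, f$H, f$W))
}

#' Count learnable parameters
#'
#' @param model a \code{SegNetwork}.
#' @return list(total, perModule): total scalar count and a named vector
#'   grouped by submodule prefix.
#' @export
countParameters <- function(model) {
  lens <- vapply(model@params, length, numeric(1))
  prefix <- sub("\\..*$", "", names(lens))
  per <- tapply(lens, prefix, sum)
  list(total = sum(lens), perModule = per)
}
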