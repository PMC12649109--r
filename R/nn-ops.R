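# Minimal dense-prediction neural-network kernels on BLAS matrix ops.
#
# A feature map is an internal list fm(x, B, H, W): x is a (B*H*W) x C
# matrix; rows are ordered batch-major, pixels row-major (p = (y-1)*W + x).
# Convolutions use im2col: shifted copies of x are bound column-wise and
# multiplied against a (k*Cin) x Cout weight matrix; the backward pass is the
# exact transpose of that gather.

fm <- function(x, B, H, W) list(x = x, B = B, H = H, W = W)

# H x W matrix <-> pixel-order vector
mat2vec <- function(m) as.vector(t(m))
vec2mat <- function(v, H, W) t(matrix(v, W, H))

# batch of H x W matrices (list) -> fm with C columns = 1
stackBatch <- function(mats) {
  H <- nrow(mats[[1]]); W <- ncol(mats[[1]])
  fm(matrix(unlist(lapply(mats, mat2vec)), ncol = 1L), length(mats), H, W)
}

# fm with 1 column -> list of H x W matrices
unstackBatch <- function(f) {
  HW <- f$H * f$W
  lapply(seq_len(f$B), function(b)
    vec2mat(f$x[(b - 1) * HW + seq_len(HW), 1], f$H, f$W))
}

# pixel shift map: for each destination pixel, source index or 0 (out of frame)
shiftIdx <- function(H, W, dy, dx) {
  y <- rep(seq_len(H), each = W); x <- rep(seq_len(W), times = H)
  sy <- y + dy; sx <- x + dx
  ok <- sy >= 1 & sy <= H & sx >= 1 & sx <= W
  idx <- integer(H * W)
  idx[ok] <- (sy[ok] - 1L) * W + sx[ok]
  idx
}

expandIdx <- function(idx, B, HW) {
  base <- rep(idx, B)
  off <- rep((seq_len(B) - 1L) * HW, each = length(idx))
  base + off * (base > 0L)
}

convOffsets <- function(d) {
  o <- c(-d, 0L, d)
  cbind(dy = rep(o, each = 3), dx = rep(o, times = 3))
}

# memoised shift-index sets keyed by geometry
.idxCache <- new.env(parent = emptyenv())

# per-offset gather index (clamped) plus the positions that must be zeroed
convIdxs <- function(H, W, B, dil) {
  key <- paste(H, W, B, dil, sep = "x")
  got <- .idxCache[[key]]
  if (!is.null(got)) return(got)
  offs <- convOffsets(dil)
  idxs <- lapply(1:9, function(k) {
    idx <- expandIdx(shiftIdx(H, W, offs[k, 1], offs[k, 2]), B, H * W)
    list(i = pmax(idx, 1L), zero = which(idx == 0L))
  })
  .idxCache[[key]] <- idxs
  idxs
}

gatherRows <- function(M, ix) {
  out <- M[ix$i, , drop = FALSE]
  if (length(ix$zero)) out[ix$zero, ] <- 0
  out
}

# 3x3 convolution (dilation d, same padding). W: (9*Cin) x Cout.
convForward <- function(f, W, b, dil = 1L, train = FALSE) {
  Cin <- ncol(f$x)
  P <- matrix(0, nrow(f$x), 9L * Cin)
  idxs <- convIdxs(f$H, f$W, f$B, dil)
  for (k in 1:9) {
    P[, (k - 1L) * Cin + seq_len(Cin)] <- gatherRows(f$x, idxs[[k]])
  }
  out <- P %*% W
  out <- sweep(out, 2L, b, "+")
  res <- fm(out, f$B, f$H, f$W)
  if (train) res$cache <- list(P = P, idxs = idxs, Cin = Cin)
  res
}

convBackward <- function(cache, W, dOut, B, H, W_img) {
  Cin <- cache$Cin
  dW <- crossprod(cache$P, dOut)
  db <- colSums(dOut)
  dP <- dOut %*% t(W)
  dX <- matrix(0, B * H * W_img, Cin)
  # scattering a shifted block equals gathering with the mirrored shift;
  # offsets are enumerated symmetrically, so block k mirrors to 10-k
  for (k in 1:9) {
    ix <- cache$idxs[[10L - k]]
    blk <- dP[, (k - 1L) * Cin + seq_len(Cin), drop = FALSE][ix$i, , drop = FALSE]
    if (length(ix$zero)) blk[ix$zero, ] <- 0
    dX <- dX + blk
  }
  list(dX = dX, dW = dW, db = db)
}

reluForward <- function(f, train = FALSE) {
  out <- fm(pmax(f$x, 0), f$B, f$H, f$W)
  if (train) out$cache <- f$x > 0
  out
}

reluBackward <- function(cache, dOut) dOut * cache

poolIdxs <- function(H, W, B) {
  key <- paste("p", H, W, B, sep = "x")
  got <- .idxCache[[key]]
  if (!is.null(got)) return(got)
  Ho <- H %/% 2L; Wo <- W %/% 2L
  yo <- rep(seq_len(Ho), each = Wo); xo <- rep(seq_len(Wo), times = Ho)
  mk <- function(dy, dx) (2L * yo - 2L + dy - 1L) * W + (2L * xo - 2L + dx)
  idx <- lapply(list(c(1, 1), c(1, 2), c(2, 1), c(2, 2)),
                function(o) expandIdx(mk(o[1], o[2]), B, H * W))
  .idxCache[[key]] <- idx
  idx
}

# 2x2 max pooling, stride 2
poolForward <- function(f, train = FALSE) {
  H <- f$H; W <- f$W; Ho <- H %/% 2L; Wo <- W %/% 2L
  idx <- poolIdxs(H, W, f$B)
  best <- f$x[idx[[1]], , drop = FALSE]
  arg <- matrix(1L, nrow(best), ncol(best))
  for (k in 2:4) {
    cand <- f$x[idx[[k]], , drop = FALSE]
    sel <- cand > best
    best[sel] <- cand[sel]
    arg[sel] <- k
  }
  out <- fm(best, f$B, Ho, Wo)
  if (train) out$cache <- list(idx = idx, arg = arg, H = H, W = W)
  out
}

poolBackward <- function(cache, dOut, B) {
  dX <- matrix(0, B * cache$H * cache$W, ncol(dOut))
  for (k in 1:4) {
    contrib <- dOut * (cache$arg == k)
    rows <- cache$idx[[k]]
    dX[rows, ] <- dX[rows, , drop = FALSE] + contrib
  }
  dX
}

# 2x2 stride-2 transposed convolution. W: array (Cin, Cout, 4).
tconvForward <- function(f, W, b, train = FALSE) {
  H <- f$H; Wd <- f$W; Ho <- 2L * H; Wo <- 2L * Wd
  Cout <- dim(W)[2]
  key <- paste("t", H, Wd, f$B, sep = "x")
  tidx <- .idxCache[[key]]
  if (is.null(tidx)) {
    y <- rep(seq_len(H), each = Wd); x <- rep(seq_len(Wd), times = H)
    tidx <- vector("list", 4L)
    k <- 0L
    for (a in 1:2) for (bb in 1:2) {
      k <- k + 1L
      t0 <- (2L * (y - 1L) + a - 1L) * Wo + (2L * (x - 1L) + bb)
      tidx[[k]] <- rep(t0, f$B) + rep((seq_len(f$B) - 1L) * Ho * Wo, each = H * Wd)
    }
    .idxCache[[key]] <- tidx
  }
  out <- matrix(0, f$B * Ho * Wo, Cout)
  for (k in 1:4) out[tidx[[k]], ] <- f$x %*% W[, , k]
  out <- sweep(out, 2L, b, "+")
  res <- fm(out, f$B, Ho, Wo)
  if (train) res$cache <- list(tidx = tidx, X = f$x)
  res
}

tconvBackward <- function(cache, W, dOut) {
  Cin <- dim(W)[1]
  dX <- matrix(0, nrow(cache$X), Cin)
  dW <- array(0, dim = dim(W))
  for (k in 1:4) {
    dYk <- dOut[cache$tidx[[k]], , drop = FALSE]
    dX <- dX + dYk %*% t(W[, , k])
    dW[, , k] <- crossprod(cache$X, dYk)
  }
  list(dX = dX, dW = dW, db = colSums(dOut))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# squeeze-and-excitation: GAP -> FC(C -> C/r) -> ReLU -> FC(-> C) -> sigmoid,
# output = weight (x) features
seForward <- function(f, W1, b1, W2, b2, train = FALSE) {
  HW <- f$H * f$W
  grp <- rep(seq_len(f$B), each = HW)
  g <- rowsum(f$x, grp) / HW                    # B x C
  h <- sweep(g %*% W1, 2L, b1, "+")
  hr <- pmax(h, 0)
  wlog <- sweep(hr %*% W2, 2L, b2, "+")
  wgt <- sigmoid(wlog)                          # B x C in (0,1)
  wfull <- wgt[grp, , drop = FALSE]
  out <- fm(f$x * wfull, f$B, f$H, f$W)
  if (train) out$cache <- list(x = f$x, g = g, h = h, hr = hr, wgt = wgt,
                               grp = grp, HW = HW)
  res <- out
  res$weights <- wgt
  res
}

seBackward <- function(cache, W1, W2, dOut) {
  grp <- cache$grp
  wfull <- cache$wgt[grp, , drop = FALSE]
  dX <- dOut * wfull
  dwgt <- rowsum(dOut * cache$x, grp)           # B x C
  dwlog <- dwgt * cache$wgt * (1 - cache$wgt)
  dW2 <- crossprod(cache$hr, dwlog)
  db2 <- colSums(dwlog)
  dhr <- dwlog %*% t(W2)
  dh <- dhr * (cache$h > 0)
  dW1 <- crossprod(cache$g, dh)
  db1 <- colSums(dh)
  dg <- dh %*% t(W1)
  dX <- dX + dg[grp, , drop = FALSE] / cache$HW
  list(dX = dX, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

# FiLM conditional modulation: out = (1 + sigmoid(Wg z + bg)) (x) F + (Wb z + bb)
filmForward <- function(f, z, Wg, bg, Wb, bb, train = FALSE) {
  HW <- f$H * f$W
  grp <- rep(seq_len(f$B), each = HW)
  gam <- sigmoid(sweep(z %*% Wg, 2L, bg, "+"))  # B x C in (0,1)
  bet <- sweep(z %*% Wb, 2L, bb, "+")
  out <- fm(f$x * (1 + gam)[grp, , drop = FALSE] + bet[grp, , drop = FALSE],
            f$B, f$H, f$W)
  if (train) out$cache <- list(x = f$x, z = z, gam = gam, grp = grp)
  out$gamma <- gam
  out
}

filmBackward <- function(cache, Wg, Wb, dOut) {
  grp <- cache$grp
  gam <- cache$gam
  dX <- dOut * (1 + gam)[grp, , drop = FALSE]
  dgam <- rowsum(dOut * cache$x, grp)
  dglog <- dgam * gam * (1 - gam)
  dbet <- rowsum(dOut, grp)
  dWg <- crossprod(cache$z, dglog)
  dbg <- colSums(dglog)
  dWb <- crossprod(cache$z, dbet)
  dbb <- colSums(dbet)
  dz <- dglog %*% t(Wg) + dbet %*% t(Wb)
  list(dX = dX, dWg = dWg, dbg = dbg, dWb = dWb, dbb = dbb, dz = dz)
}

# 1x1 convolution = plain matrix multiply over channels
conv1x1Forward <- function(f, W, b, train = FALSE) {
  out <- fm(sweep(f$x %*% W, 2L, b, "+"), f$B, f$H, f$W)
  if (train) out$cache <- f$x
  out
}

conv1x1Backward <- function(cache, W, dOut) {
  list(dX = dOut %*% t(W), dW = crossprod(cache, dOut), db = colSums(dOut))
}

heInitMat <- function(nin, nout) {
  matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}
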