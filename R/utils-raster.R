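# Internal raster and RNG utilities. Rasters are base arrays: H x W numeric
# matrices in [0,1] for masks/greyscale, H x W x 3 arrays for RGB.

#' @importFrom stats runif rnorm
NULL

# Evaluate expr under a temporary RNG seed, restoring global RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic sub-seed from a base seed and integer keys (kept < 2^31).
deriveSeed <- function(seed, ...) {
  keys <- c(...)
  h <- as.numeric(seed) %% 2147483647
  for (k in keys) {
    h <- (h * 48271 + (as.numeric(k) %% 2147483647) + 1) %% 2147483647
  }
  as.integer(h)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

isBinary <- function(x, tol = 1e-8) {
  all(abs(x) < tol | abs(x - 1) < tol)
}

rasterDim <- function(x) dim(x)[1:2]

isRGB <- function(x) length(dim(x)) == 3L && dim(x)[3] == 3L

# Vectorised HSV -> RGB. h in degrees [0,360), s,v in [0,1]; returns list(r,g,b).
hsv2rgbNum <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- g <- b <- numeric(length(h))
  idx <- i == 0; r[idx] <- v[idx]; g[idx] <- t[idx]; b[idx] <- p[idx]
  idx <- i == 1; r[idx] <- q[idx]; g[idx] <- v[idx]; b[idx] <- p[idx]
  idx <- i == 2; r[idx] <- p[idx]; g[idx] <- v[idx]; b[idx] <- t[idx]
  idx <- i == 3; r[idx] <- p[idx]; g[idx] <- q[idx]; b[idx] <- v[idx]
  idx <- i == 4; r[idx] <- t[idx]; g[idx] <- p[idx]; b[idx] <- v[idx]
  idx <- i >= 5; r[idx] <- v[idx]; g[idx] <- p[idx]; b[idx] <- q[idx]
  list(r = r, g = g, b = b)
}

# Hue (degrees), saturation, value of an RGB raster, as H x W matrices.
rgbToHsvRaster <- function(img) {
  stopifnot(isRGB(img))
  d <- dim(img)
  m <- grDevices::rgb2hsv(
    r = as.vector(img[, , 1]), g = as.vector(img[, , 2]),
    b = as.vector(img[, , 3]), maxColorValue = 1
  )
  list(
    h = matrix(m[1, ] * 360, d[1], d[2]),
    s = matrix(m[2, ], d[1], d[2]),
    v = matrix(m[3, ], d[1], d[2])
  )
}

hueInBand <- function(h, band) {
  lo <- band[1] %% 360; hi <- band[2] %% 360
  if (lo <= hi) h >= lo & h <= hi else h >= lo | h <= hi
}

# Smooth low-frequency noise field (coarse Gaussian grid, bilinear upsampled).
smoothNoise <- function(h, w, scale = 8, amplitude = 1) {
  gh <- max(2L, ceiling(h / scale)); gw <- max(2L, ceiling(w / scale))
  g <- matrix(rnorm(gh * gw), gh, gw)
  ys <- seq(1, gh, length.out = h); xs <- seq(1, gw, length.out = w)
  y0 <- pmin(floor(ys), gh - 1L); x0 <- pmin(floor(xs), gw - 1L)
  fy <- ys - y0; fx <- xs - x0
  a <- g[cbind(rep(y0, w), rep(x0, each = h))]
  b <- g[cbind(rep(y0, w), rep(x0 + 1, each = h))]
  cc <- g[cbind(rep(y0 + 1, w), rep(x0, each = h))]
  d <- g[cbind(rep(y0 + 1, w), rep(x0 + 1, each = h))]
  fy <- rep(fy, w); fx <- rep(fx, each = h)
  out <- a * (1 - fy) * (1 - fx) + cc * fy * (1 - fx) +
    b * (1 - fy) * fx + d * fy * fx
  matrix(out * amplitude, h, w)
}

# Rigid warp: rotation (degrees, about image centre) followed by translation
# (dx right, dy down), resampled by inverse mapping. inverse=TRUE applies the
# inverse transform instead. filter "bilinear" or "nearest"; bg fills
# out-of-frame samples.
warpRigid <- function(img, deg, dx, dy, inverse = FALSE,
                      filter = c("bilinear", "nearest"), bg = 1) {
  filter <- match.arg(filter)
  if (!all(is.finite(c(deg, dx, dy)))) stop("transform parameters must be finite")
  d <- dim(img)
  h <- d[1]; w <- d[2]
  nc <- if (length(d) == 3L) d[3] else 1L
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  th <- deg * pi / 180
  # forward map: p' = R (p - c) + c + t. For each destination pixel solve the
  # source position; for inverse=TRUE the roles swap.
  Y <- rep(seq_len(h), times = w); X <- rep(seq_len(w), each = h)
  if (!inverse) {
    # source = R^{-1} (dest - c - t) + c
    u <- X - cx - dx; v <- Y - cy - dy
    sx <- cos(th) * u + sin(th) * v + cx
    sy <- -sin(th) * u + cos(th) * v + cy
  } else {
    # destination of the inverse transform: source = R (dest - c) + c + t
    u <- X - cx; v <- Y - cy
    sx <- cos(th) * u - sin(th) * v + cx + dx
    sy <- sin(th) * u + cos(th) * v + cy + dy
  }
  sampleChannel <- function(ch) {
    if (filter == "nearest") {
      xr <- round(sx); yr <- round(sy)
      ok <- xr >= 1 & xr <= w & yr >= 1 & yr <= h
      out <- rep(bg, h * w)
      out[ok] <- ch[cbind(yr[ok], xr[ok])]
    } else {
      x0 <- floor(sx); y0 <- floor(sy)
      fx <- sx - x0; fy <- sy - y0
      out <- rep(as.numeric(bg), h * w)
      ok <- x0 >= 1 & x0 + 1 <= w & y0 >= 1 & y0 + 1 <= h
      if (any(ok)) {
        i00 <- cbind(y0[ok], x0[ok]); i01 <- cbind(y0[ok], x0[ok] + 1)
        i10 <- cbind(y0[ok] + 1, x0[ok]); i11 <- cbind(y0[ok] + 1, x0[ok] + 1)
        out[ok] <- ch[i00] * (1 - fy[ok]) * (1 - fx[ok]) +
          ch[i01] * (1 - fy[ok]) * fx[ok] +
          ch[i10] * fy[ok] * (1 - fx[ok]) +
          ch[i11] * fy[ok] * fx[ok]
      }
      # border pixels with partial support fall back to nearest valid sample
      edge <- !ok & sx >= 0.5 & sx <= w + 0.49 & sy >= 0.5 & sy <= h + 0.49
      if (any(edge)) {
        xr <- clamp(round(sx[edge]), 1, w); yr <- clamp(round(sy[edge]), 1, h)
        out[edge] <- ch[cbind(yr, xr)]
      }
    }
    matrix(out, h, w)
  }
  if (nc == 1L) {
    sampleChannel(if (length(d) == 3L) img[, , 1] else img)
  } else {
    out <- array(0, dim = d)
    for (k in seq_len(nc)) out[, , k] <- sampleChannel(img[, , k])
    out
  }
}

# 3x3 binary morphology by shifted pmax. pad gives the out-of-frame value.
maxpool3x3 <- function(m, pad = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(pad, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    ys <- seq_len(h) + dy; xs <- seq_len(w) + dx
    okY <- ys >= 1 & ys <= h; okX <- xs >= 1 & xs <= w
    shifted <- matrix(pad, h, w)
    shifted[okY, okX] <- m[ys[okY], xs[okX]]
    out <- pmax(out, shifted)
  }
  out
}

writeMaskPNG <- function(mask, path) {
  png::writePNG(clamp(mask, 0, 1), path)
}

readMaskPNG <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  (m > 0.5) * 1
}
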