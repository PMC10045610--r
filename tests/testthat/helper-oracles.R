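# Brute-force oracle twins of the sampling / convolution / pooling
# operators, written as literal loop transcriptions of their defining
# sums, plus a central finite-difference helper for gradient checks.

oracle_g <- function(a, b) max(0, 1 - abs(a - b))

# x(p) = sum over ALL integer positions q of G(q, p) x(q)
oracle_bilinear <- function(x, p) {
  C <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  out <- numeric(C)
  for (r in 0:(H - 1)) for (cc in 0:(W - 1)) {
    w <- oracle_g(r, p[1]) * oracle_g(cc, p[2])
    if (w > 0) out <- out + w * x[, r + 1, cc + 1]
  }
  out
}

# stride-1 zero-padded same convolution, direct summation
oracle_conv2d <- function(x, k, b = numeric(dim(k)[1])) {
  C <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  O <- dim(k)[1]; KH <- dim(k)[3]; KW <- dim(k)[4]
  ph <- (KH - 1) / 2; pw <- (KW - 1) / 2
  y <- array(0, c(O, H, W))
  for (o in 1:O) for (h in 1:H) for (w in 1:W) {
    acc <- b[o]
    for (kh in 1:KH) for (kw in 1:KW) {
      hi <- h + kh - 1 - ph; wi <- w + kw - 1 - pw
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
        acc <- acc + sum(k[o, , kh, kw] * x[, hi, wi])
    }
    y[o, h, w] <- acc
  }
  y
}

# deformable convolution via the bilinear oracle
oracle_dconv <- function(x, k, b, taps, off) {
  C <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  O <- dim(k)[1]; K <- nrow(taps)
  kflat <- matrix(k, nrow = O)  # columns (c, tap) with c fastest
  y <- array(0, c(O, H, W))
  for (h in 1:H) for (w in 1:W) {
    for (n in 1:K) {
      p <- c(h - 1 + taps[n, 1] + off[2 * n - 1, h, w],
             w - 1 + taps[n, 2] + off[2 * n, h, w])
      v <- oracle_bilinear(x, p)
      for (o in 1:O) {
        y[o, h, w] <- y[o, h, w] + sum(kflat[o, (n - 1) * C + 1:C] * v)
      }
    }
    y[, h, w] <- y[, h, w] + b
  }
  y
}

# RoI average pooling by direct enumeration of integer positions per bin
oracle_roi_pool <- function(x, roi, bins_h, bins_w, bin_off = NULL) {
  C <- dim(x)[1]
  bh <- (roi[4] - roi[2]) / bins_h; bw <- (roi[3] - roi[1]) / bins_w
  pooled <- array(0, c(C, bins_h, bins_w))
  for (i in 1:bins_h) for (j in 1:bins_w) {
    r0 <- roi[2] + (i - 1) * bh; r1 <- roi[2] + i * bh
    c0 <- roi[1] + (j - 1) * bw; c1 <- roi[1] + j * bw
    rows <- if (ceiling(r1) - 1 >= ceiling(r0)) ceiling(r0):(ceiling(r1) - 1) else integer(0)
    cols <- if (ceiling(c1) - 1 >= ceiling(c0)) ceiling(c0):(ceiling(c1) - 1) else integer(0)
    off <- if (is.null(bin_off)) c(0, 0) else bin_off[, i, j]
    if (length(rows) == 0 || length(cols) == 0) {
      pooled[, i, j] <- oracle_bilinear(x, c((r0 + r1) / 2 + off[1],
                                             (c0 + c1) / 2 + off[2]))
    } else {
      acc <- numeric(C)
      for (r in rows) for (cc in cols)
        acc <- acc + oracle_bilinear(x, c(r + off[1], cc + off[2]))
      pooled[, i, j] <- acc / (length(rows) * length(cols))
    }
  }
  pooled
}

# central finite differences of a scalar function over an array
num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim = if (is.null(dim(x))) length(x) else dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

rand_map <- function(C, H, W) array(rnorm(C * H * W), c(C, H, W))
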