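#' Regular sampling grids and convolution weights
#'
#' A sampling grid is the ordered set of integer `(row, col)` tap
#' displacements of a convolution; the default 3x3 grid is
#' `{(-1,-1), (-1,0), ..., (0,1), (1,1)}`.  Taps are ordered row-fastest so
#' they align with the flattening of a kernel array `[out, in, kh, kw]`.
#'
#' @param kh,kw odd kernel extents.
#' @return `sampling_grid()`: an integer matrix `[K, 2]` of
#'   `(d_row, d_col)` displacements.
#' @export
sampling_grid <- function(kh = 3L, kw = kh) {
  stopifnot(kh >= 1L, kw >= 1L, kh %% 2L == 1L, kw %% 2L == 1L)
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  cbind(d_row = rep(seq_len(kh) - 1L - ph, times = kw),
        d_col = rep(seq_len(kw) - 1L - pw, each = kh))
}

#' @param kernel numeric array `[out_channels, in_channels, kh, kw]`.
#' @param bias numeric vector `[out_channels]`; defaults to zeros.
#' @return `conv_weights()`: a `conv_weights` object.
#' @rdname sampling_grid
#' @export
conv_weights <- function(kernel, bias = NULL) {
  stopifnot(is.array(kernel), length(dim(kernel)) == 4L)
  if (is.null(bias)) bias <- numeric(dim(kernel)[1])
  stopifnot(length(bias) == dim(kernel)[1])
  structure(list(kernel = kernel, bias = as.numeric(bias)),
            class = "conv_weights")
}

grid_for_kernel <- function(kernel) sampling_grid(dim(kernel)[3], dim(kernel)[4])

#' Bilinear interpolation kernel
#'
#' The separable hat kernel `G(q, p) = g(q_row, p_row) * g(q_col, p_col)`
#' with `g(a, b) = max(0, 1 - |a - b|)`.  It is nonzero only for the (at
#' most four) integer positions within unit distance of `p`, and its values
#' over those positions sum to one for interior `p`.
#'
#' @param q integer 2-vector `(row, col)`.
#' @param p real 2-vector `(row, col)`.
#' @return a weight in `[0, 1]`.
#' @examples
#' bilinear_kernel(c(0, 0), c(0.25, 0.5)) # 0.75 * 0.5
#' @export
bilinear_kernel <- function(q, p) {
  g <- function(a, b) max(0, 1 - abs(a - b))
  g(q[1], p[1]) * g(q[2], p[2])
}

#' Bilinear sampling of a feature map
#'
#' Evaluates `x(p) = sum_q G(q, p) x(q)` per channel, where `q` ranges over
#' integer positions.  Positions outside the map contribute zero.
#'
#' @param map a [feature_map] (or array / matrix coercible to one).
#' @param p real 2-vector `(row, col)`, 0-based.
#' @return numeric vector of length `channels`.
#' @examples
#' bilinear_sample(matrix(c(1, 3, 2, 4), 2, 2), c(0.5, 0.5)) # 2.5
#' @export
bilinear_sample <- function(map, p) {
  if (any(!is.finite(p))) stop("sampling position must be finite")
  map <- if (inherits(map, "feature_map")) map else feature_map(map)
  x <- map$values
  y <- cpp_bl_gather_fwd(x, dim(x), p[1], p[2])
  as.numeric(y)
}

#' Standard (regular-grid) convolution
#'
#' Stride-1 zero-padded "same" convolution
#' `y(p0) = b + sum_n w(p_n) x(p0 + p_n)`, with the weight indexed by the tap
#' `p_n` of the regular grid.  Output spatial size equals input size.
#'
#' @param map a [feature_map] (or array / matrix).
#' @param weights a [conv_weights].
#' @param grid optional sampling grid; must match the kernel extents.
#' @return a `feature_map` with `out_channels` channels and the input stride.
#' @export
standard_conv <- function(map, weights, grid = NULL) {
  map <- if (inherits(map, "feature_map")) map else feature_map(map)
  x <- map$values
  k <- weights$kernel
  if (dim(x)[1] != dim(k)[2])
    stop(sprintf("channel mismatch: map has %d, kernel expects %d",
                 dim(x)[1], dim(k)[2]))
  if (!is.null(grid) && nrow(grid) != dim(k)[3] * dim(k)[4])
    stop("grid tap count must equal kernel size")
  y <- cpp_conv2d_fwd(x, dim(x), k, dim(k), weights$bias)
  feature_map(y, stride = map$stride)
}

#' Offset prediction for deformable convolution
#'
#' The per-position 2D tap offsets of a deformable convolution are predicted
#' from the input feature map itself by a plain convolution with `2K` output
#' channels (`K` taps; channels `2n-1, 2n` hold tap `n`'s
#' `(d_row, d_col)`).  With zero weights the offsets are zero and the paired
#' deformable convolution reduces to a standard convolution, which is also
#' the training initialization.
#'
#' @param map a [feature_map].
#' @param offset_weights a [conv_weights] with `2K` output channels.
#' @param grid the sampling grid of the paired convolution (default 3x3).
#' @return an offset field: array `[2K, H, W]`.
#' @export
predict_offsets <- function(map, offset_weights, grid = sampling_grid(3L)) {
  K <- nrow(grid)
  if (dim(offset_weights$kernel)[1] != 2L * K)
    stop(sprintf("offset predictor must have 2K = %d output channels", 2L * K))
  standard_conv(map, offset_weights)$values
}

# Fractional sample positions for every (tap, output cell) pair.
# Returns vectors ordered tap-fastest, then output cell (row-fastest).
dconv_positions <- function(H, W, taps, off) {
  K <- nrow(taps)
  h0 <- rep(0:(H - 1L), times = W)
  w0 <- rep(0:(W - 1L), each = H)
  offm <- matrix(off, nrow = 2L * K)
  pr <- outer(taps[, 1], h0, "+") + offm[seq(1L, 2L * K, 2L), , drop = FALSE]
  pc <- outer(taps[, 2], w0, "+") + offm[seq(2L, 2L * K, 2L), , drop = FALSE]
  list(pr = as.numeric(pr), pc = as.numeric(pc))
}

dconv_forward_core <- function(x, kernel, bias, taps, off) {
  C <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  O <- dim(kernel)[1]; K <- nrow(taps)
  pos <- dconv_positions(H, W, taps, off)
  S <- cpp_bl_gather_fwd(x, dim(x), pos$pr, pos$pc)   # [C, K*H*W]
  dim(S) <- c(C * K, H * W)
  y <- matrix(kernel, nrow = O) %*% S + bias
  array(y, dim = c(O, H, W))
}

#' Deformable convolution
#'
#' Each tap of the regular grid samples at `p0 + p_n + dp_n`, where the
#' fractional displacement `dp_n` comes from an offset field (typically
#' produced by [predict_offsets]); fractional positions are resolved by the
#' bilinear kernel.  With a zero offset field the result equals
#' [standard_conv].
#'
#' @inheritParams standard_conv
#' @param offsets offset field array `[2K, H, W]` matching the output size.
#' @return a `feature_map`.
#' @export
deformable_conv <- function(map, weights, grid = NULL, offsets) {
  map <- if (inherits(map, "feature_map")) map else feature_map(map)
  x <- map$values
  k <- weights$kernel
  if (dim(x)[1] != dim(k)[2]) stop("channel mismatch between map and kernel")
  if (is.null(grid)) grid <- grid_for_kernel(k)
  K <- nrow(grid)
  if (!identical(dim(offsets), c(2L * K, dim(x)[2], dim(x)[3])))
    stop("offset field must have shape [2K, H, W]")
  feature_map(dconv_forward_core(x, k, weights$bias, grid, offsets),
              stride = map$stride)
}

# Integer sample positions of one RoI split into bins_h x bins_w equal
# sub-rectangles.  The RoI is half-open in continuous (col, row) = (x, y)
# coordinates; a bin with no integer position falls back to one bilinear
# sample at its center.
roi_samples <- function(roi, bins_h, bins_w) {
  x0 <- roi[1]; y0 <- roi[2]; x1 <- roi[3]; y1 <- roi[4]
  if (!(x0 < x1 && y0 < y1)) stop("degenerate RoI: need x_min < x_max and y_min < y_max")
  bh <- (y1 - y0) / bins_h; bw <- (x1 - x0) / bins_w
  pr <- c(); pc <- c(); bin <- c()
  counts <- integer(bins_h * bins_w)
  for (j in seq_len(bins_w)) {
    c0 <- x0 + (j - 1) * bw; c1 <- x0 + j * bw
    cols <- if (ceiling(c1) - 1 >= ceiling(c0)) seq.int(ceiling(c0), ceiling(c1) - 1) else integer(0)
    for (i in seq_len(bins_h)) {
      r0 <- y0 + (i - 1) * bh; r1 <- y0 + i * bh
      rows <- if (ceiling(r1) - 1 >= ceiling(r0)) seq.int(ceiling(r0), ceiling(r1) - 1) else integer(0)
      b <- i + bins_h * (j - 1)
      if (length(rows) == 0L || length(cols) == 0L) {
        pr <- c(pr, (r0 + r1) / 2); pc <- c(pc, (c0 + c1) / 2)
        bin <- c(bin, b); counts[b] <- 1L
      } else {
        n <- length(rows) * length(cols)
        pr <- c(pr, rep(rows, times = length(cols)))
        pc <- c(pc, rep(cols, each = length(rows)))
        bin <- c(bin, rep(b, n)); counts[b] <- n
      }
    }
  }
  list(pr = pr, pc = pc, bin = bin, counts = counts)
}

roi_pool_core <- function(x, roi, bins_h, bins_w, bin_off = NULL) {
  s <- roi_samples(roi, bins_h, bins_w)
  pr <- s$pr; pc <- s$pc
  if (!is.null(bin_off)) {
    pr <- pr + bin_off[1L + 2L * (s$bin - 1L)]
    pc <- pc + bin_off[2L + 2L * (s$bin - 1L)]
  }
  G <- cpp_bl_gather_fwd(x, dim(x), pr, pc)            # [C, n_samples]
  sums <- rowsum(t(G), s$bin)                          # [bins present, C]
  pooled <- matrix(0, nrow = bins_h * bins_w, ncol = dim(x)[1])
  pooled[as.integer(rownames(sums)), ] <- sums / s$counts[as.integer(rownames(sums))]
  list(pooled = array(t(pooled), dim = c(dim(x)[1], bins_h, bins_w)),
       counts = matrix(s$counts, bins_h, bins_w), samples = s,
       pr = pr, pc = pc)
}

#' RoI average pooling
#'
#' Splits a region of interest into `bins_h x bins_w` equal sub-rectangles
#' and averages the feature values at the integer positions inside each bin:
#' `y(i,j) = sum_{p in bin(i,j)} x(p0 + p) / n_ij`.  A bin containing no
#' integer position contributes one bilinear sample at its center.
#'
#' @param map a [feature_map] (or array / matrix).
#' @param roi numeric 4-vector `(x_min, y_min, x_max, y_max)` in feature-map
#'   cell coordinates (x = col, y = row), half-open.
#' @param bins_h,bins_w number of bins (rows, cols), both >= 1.
#' @return a `bin_grid`: list with `pooled` (`[channels, bins_h, bins_w]`)
#'   and `counts` (`[bins_h, bins_w]`, the `n_ij`).
#' @examples
#' roi_average_pool(matrix(c(1, 3, 2, 4), 2, 2), c(0, 0, 2, 2), 1, 1)
#' @export
roi_average_pool <- function(map, roi, bins_h, bins_w) {
  stopifnot(bins_h >= 1L, bins_w >= 1L)
  map <- if (inherits(map, "feature_map")) map else feature_map(map)
  r <- roi_pool_core(map$values, roi, bins_h, bins_w)
  structure(list(pooled = r$pooled, counts = r$counts), class = "bin_grid")
}

#' Deformable RoI average pooling
#'
#' As [roi_average_pool], but every sample position of bin `(i,j)` is first
#' shifted by that bin's learned displacement `dp_ij`; the shifted
#' (generally fractional) positions are resolved by the bilinear kernel.
#' Zero offsets reproduce plain RoI average pooling exactly.
#'
#' @inheritParams roi_average_pool
#' @param bin_offsets array `[2, bins_h, bins_w]` of per-bin
#'   `(d_row, d_col)` displacements.
#' @return a `bin_grid`.
#' @export
deformable_roi_pool <- function(map, roi, bins_h, bins_w, bin_offsets) {
  stopifnot(bins_h >= 1L, bins_w >= 1L)
  if (!identical(dim(bin_offsets), c(2L, as.integer(bins_h), as.integer(bins_w))))
    stop("bin offsets must have shape [2, bins_h, bins_w]")
  map <- if (inherits(map, "feature_map")) map else feature_map(map)
  r <- roi_pool_core(map$values, roi, bins_h, bins_w, bin_off = bin_offsets)
  structure(list(pooled = r$pooled, counts = r$counts), class = "bin_grid")
}
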