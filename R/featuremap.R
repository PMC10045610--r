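#' Feature maps and feature pyramids
#'
#' A feature map is a real-valued array indexed `[channel, row, col]` together
#' with its stride (pixels of the input image per feature cell).  A feature
#' pyramid is an ordered set of four maps at levels 2..5 with strides
#' 4/8/16/32, consecutive levels differing by exactly 2x in each spatial
#' dimension and all sharing one channel width.
#'
#' All spatial coordinates used by the sampling operators are 0-based
#' `(row, col)` pairs in continuous space; boxes are half-open.
#'
#' @param values numeric array `[channels, height, width]`, or a matrix
#'   `[height, width]` which is promoted to one channel.
#' @param stride positive integer, pixels per feature cell.
#' @return `feature_map()` returns a `feature_map` object.
#' @examples
#' fm <- feature_map(matrix(1:4, 2, 2), stride = 4)
#' dim(fm$values)
#' @export
feature_map <- function(values, stride = 1L) {
  if (is.matrix(values)) {
    values <- array(values, dim = c(1L, nrow(values), ncol(values)))
  }
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (any(!is.finite(values))) stop("feature map values must be finite")
  d <- dim(values)
  if (d[2] < 1L || d[3] < 1L) stop("feature map must be at least 1x1")
  structure(list(values = values, stride = as.integer(stride)),
            class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<feature_map %d x %d x %d (C x H x W), stride %d>\n",
              d[1], d[2], d[3], x$stride))
  invisible(x)
}

as_values <- function(x) if (inherits(x, "feature_map")) x$values else x

#' @param levels named list of four arrays or `feature_map`s for levels
#'   `"2".."5"`; level i has stride `2^i`.
#' @return `feature_pyramid()` returns a `feature_pyramid` object, a list of
#'   four `feature_map`s named `"2".."5"`.
#' @rdname feature_map
#' @export
feature_pyramid <- function(levels) {
  stopifnot(length(levels) == 4L)
  names(levels) <- as.character(2:5)
  out <- lapply(2:5, function(i) {
    v <- as_values(levels[[as.character(i)]])
    if (is.matrix(v)) v <- array(v, dim = c(1L, nrow(v), ncol(v)))
    feature_map(v, stride = 2L^i)
  })
  names(out) <- as.character(2:5)
  ch <- vapply(out, function(m) dim(m$values)[1], 1L)
  if (length(unique(ch)) != 1L) stop("pyramid levels must share channel count")
  for (i in 1:3) {
    da <- dim(out[[i]]$values); db <- dim(out[[i + 1]]$values)
    if (da[2] != 2L * db[2] || da[3] != 2L * db[3])
      stop("consecutive pyramid levels must differ by exactly 2x spatially")
  }
  structure(out, class = "feature_pyramid")
}

#' @export
print.feature_pyramid <- function(x, ...) {
  cat("<feature_pyramid>\n")
  for (nm in names(x)) {
    d <- dim(x[[nm]]$values)
    cat(sprintf("  P%s: %d x %d x %d, stride %d\n", nm, d[1], d[2], d[3],
                x[[nm]]$stride))
  }
  invisible(x)
}

#' Build a constant or random test pyramid
#'
#' Convenience constructors used throughout the examples and tests: a pyramid
#' whose base level (P2) is `base_hw` x `base_hw` with `channels` channels.
#'
#' @param channels channel width shared by all levels.
#' @param base_hw spatial size of level 2 (must be divisible by 8).
#' @param fill either a single number or `"rnorm"` for standard-normal noise.
#' @return a `feature_pyramid`.
#' @export
make_pyramid <- function(channels = 1L, base_hw = 8L, fill = 0) {
  stopifnot(base_hw %% 8L == 0L)
  lv <- lapply(0:3, function(k) {
    hw <- base_hw / 2L^k
    n <- channels * hw * hw
    v <- if (identical(fill, "rnorm")) rnorm(n) else rep(fill, n)
    array(v, dim = c(channels, hw, hw))
  })
  names(lv) <- as.character(2:5)
  feature_pyramid(lv)
}

pyramid_values <- function(pyr) lapply(pyr, function(m) m$values)

zero_like_pyramid <- function(pyr) {
  feature_pyramid(lapply(pyr, function(m) array(0, dim(m$values))))
}
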