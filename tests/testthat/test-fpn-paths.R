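# The six pyramid information paths: boundary rules, telescoping constants
# under identity kernels, and equivalence with a naive sequential
# evaluation of the defining equations built from the (separately
# oracle-tested) numeric operators.

up_nn <- function(x) x[, rep(seq_len(dim(x)[2]), each = 2),
                       rep(seq_len(dim(x)[3]), each = 2), drop = FALSE]
down_max <- function(x) {
  H <- dim(x)[2]; W <- dim(x)[3]
  y <- array(-Inf, c(dim(x)[1], H / 2, W / 2))
  for (dh in 1:2) for (dw in 1:2)
    y <- pmax(y, x[, seq(dh, H, 2), seq(dw, W, 2), drop = FALSE])
  y
}

# apply one stored conv (regular or deformable with predicted offsets)
oracle_path_conv <- function(params, prefix, x, deformable) {
  w <- conv_weights(path_param_get(params, paste0(prefix, ".w")),
                    path_param_get(params, paste0(prefix, ".b")))
  fm <- feature_map(x)
  if (deformable) {
    ow <- conv_weights(path_param_get(params, paste0(prefix, ".ow")),
                       path_param_get(params, paste0(prefix, ".ob")))
    deformable_conv(fm, w, offsets = predict_offsets(fm, ow))$values
  } else {
    standard_conv(fm, w)$values
  }
}

# set every kernel to the center-tap identity (fuse-split kernels sum their
# two concatenated channel blocks); offset predictors stay zero
make_identity_params <- function(kind, channels) {
  p <- make_path_params(kind, channels, seed = 1)
  for (nm in path_param_names(p)) {
    if (!endsWith(nm, ".w")) next
    k <- path_param_get(p, nm) * 0
    O <- dim(k)[1]; I <- dim(k)[2]
    for (o in seq_len(O)) {
      k[o, o, 2, 2] <- 1
      if (I == 2 * O) k[o, O + o, 2, 2] <- 1
    }
    path_param_set(p, nm, k)
  }
  p
}

rand_pyramid <- function(channels = 1, base = 8) make_pyramid(channels, base, "rnorm")

randomize_offsets <- function(p, sd = 0.1) {
  for (nm in path_param_names(p)) {
    if (endsWith(nm, ".ow") || endsWith(nm, ".ob")) {
      v <- path_param_get(p, nm)
      path_param_set(p, nm, rnorm(length(v), sd = sd))
    }
  }
  p
}

test_that("upsample and downsample obey their contracts", {
  v <- feature_map(array(3.5, c(1, 1, 1)), stride = 32)
  u <- upsample(v)
  expect_equal(u$values, array(3.5, c(1, 2, 2)))
  expect_equal(dim(upsample(feature_map(rand_map(3, 4, 5)))$values), c(3L, 8L, 10L))
  m <- feature_map(matrix(c(1, 3, 2, 4), 2, 2))
  expect_equal(downsample(m)$values, array(4, c(1, 1, 1)))
  x <- feature_map(rand_map(2, 4, 6))
  expect_equal(downsample(upsample(x))$values, x$values)
  expect_error(downsample(feature_map(rand_map(1, 3, 4))), "even")
})

test_that("top-down path telescopes and matches its sequential oracle", {
  p <- make_identity_params("TOP_DOWN", 1)
  ones <- make_pyramid(1, 8, 1)
  out <- top_down_path(ones, p)
  # interior cells accumulate one extra pyramid level per step down
  expect_equal(out[["5"]]$values[1, 1, 1], 1)
  expect_equal(out[["4"]]$values[1, 2, 2], 2)
  expect_equal(out[["3"]]$values[1, 2, 2], 3)
  expect_equal(out[["2"]]$values[1, 4, 4], 4)
  z <- top_down_path(make_pyramid(1, 8, 0), make_path_params("TOP_DOWN", 1, seed = 2))
  expect_true(all(vapply(z, function(m) all(m$values == 0), TRUE)))
  set.seed(21)
  pr <- make_path_params("TOP_DOWN", 1, seed = 3)
  randomize_offsets(pr)
  pyr <- rand_pyramid()
  got <- top_down_path(pyr, pr)
  F <- list()
  F[["5"]] <- oracle_path_conv(pr, "l5", pyr[["5"]]$values, TRUE)
  for (i in 4:2) {
    F[[as.character(i)]] <- oracle_path_conv(
      pr, paste0("l", i), up_nn(F[[as.character(i + 1)]]) + pyr[[as.character(i)]]$values,
      deformable = i >= 3)
  }
  for (i in 2:5)
    expect_equal(got[[as.character(i)]]$values, F[[as.character(i)]],
                 tolerance = 1e-10)
})

test_that("bottom-up path mirrors the top-down recursion", {
  p <- make_identity_params("BOTTOM_UP", 1)
  ones <- make_pyramid(1, 8, 1)
  out <- bottom_up_path(ones, p)
  expect_equal(out[["2"]]$values[1, 4, 4], 1)
  expect_equal(out[["3"]]$values[1, 2, 2], 2)
  expect_equal(out[["4"]]$values[1, 2, 2], 3)
  expect_equal(out[["5"]]$values[1, 1, 1], 4)
  set.seed(22)
  pr <- randomize_offsets(make_path_params("BOTTOM_UP", 1, seed = 4))
  pyr <- rand_pyramid()
  got <- bottom_up_path(pyr, pr)
  F <- list()
  F[["2"]] <- oracle_path_conv(pr, "l2", pyr[["2"]]$values, FALSE)
  for (i in 3:5) {
    F[[as.character(i)]] <- oracle_path_conv(
      pr, paste0("l", i), down_max(F[[as.character(i - 1)]]) + pyr[[as.character(i)]]$values,
      deformable = TRUE)
  }
  for (i in 2:5)
    expect_equal(got[[as.character(i)]]$values, F[[as.character(i)]],
                 tolerance = 1e-10)
})

test_that("scale-balanced path counts neighbour terms at the boundaries", {
  p <- make_identity_params("SCALE_BALANCED", 1)
  ones <- make_pyramid(1, 16, 1)
  out <- scale_balanced_path(ones, p)
  expect_equal(out[["3"]]$values[1, 2, 2], 3)
  expect_equal(out[["4"]]$values[1, 2, 2], 3)
  expect_equal(out[["2"]]$values[1, 4, 4], 2)
  expect_equal(out[["5"]]$values[1, 1, 1], 2)
  set.seed(23)
  pr <- randomize_offsets(make_path_params("SCALE_BALANCED", 1, seed = 5))
  pyr <- rand_pyramid()
  got <- scale_balanced_path(pyr, pr)
  for (i in 2:5) {
    acc <- oracle_path_conv(pr, "w0", pyr[[as.character(i)]]$values, i >= 3)
    if (i < 5)
      acc <- acc + up_nn(oracle_path_conv(pr, "w1", pyr[[as.character(i + 1)]]$values, TRUE))
    if (i > 2)
      acc <- acc + down_max(oracle_path_conv(pr, "wm1", pyr[[as.character(i - 1)]]$values,
                                             (i - 1) >= 3))
    expect_equal(got[[as.character(i)]]$values, acc, tolerance = 1e-10)
  }
})

test_that("fuse-split path follows the two-step fuse then split", {
  p <- make_identity_params("FUSE_SPLIT", 1)
  ones <- make_pyramid(1, 8, 1)
  out <- fuse_split_path(ones, p)
  # alpha maps are 2 everywhere, the summing fusion kernels give beta = 4
  expect_equal(out[["3"]]$values[1, 2, 2], 4)
  expect_equal(out[["4"]]$values[1, 2, 2], 4)
  expect_equal(out[["2"]]$values[1, 4, 4], 4)
  expect_equal(out[["5"]]$values[1, 1, 1], 4)
  set.seed(24)
  pr <- randomize_offsets(make_path_params("FUSE_SPLIT", 2, seed = 6))
  pyr <- rand_pyramid(2)
  got <- fuse_split_path(pyr, pr)
  a_s <- pyr[["4"]]$values + up_nn(pyr[["5"]]$values)
  a_l <- down_max(pyr[["2"]]$values) + pyr[["3"]]$values
  cat_ch <- function(a, b) {
    y <- array(0, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
    y[seq_len(dim(a)[1]), , ] <- a
    y[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
    y
  }
  b_s <- oracle_path_conv(pr, "ws", cat_ch(a_s, down_max(a_l)), TRUE)
  b_l <- oracle_path_conv(pr, "wl", cat_ch(up_nn(a_s), a_l), TRUE)
  expect_equal(got[["2"]]$values, up_nn(b_l), tolerance = 1e-10)
  expect_equal(got[["3"]]$values, b_l, tolerance = 1e-10)
  expect_equal(got[["4"]]$values, b_s, tolerance = 1e-10)
  expect_equal(got[["5"]]$values, down_max(b_s), tolerance = 1e-10)
})

test_that("null and skip paths are the additive identity and the identity", {
  pyr <- rand_pyramid(2)
  z <- null_path(pyr)
  expect_true(all(vapply(z, function(m) all(m$values == 0), TRUE)))
  expect_equal(lapply(skip_path(pyr), `[[`, "values"), lapply(pyr, `[[`, "values"))
  s2 <- skip_path(skip_path(pyr))
  expect_equal(lapply(s2, `[[`, "values"), lapply(pyr, `[[`, "values"))
  expect_equal(path_param_count("NULL", 112), 0)
  expect_equal(path_param_count("SKIP", 112), 0)
})

test_that("every path preserves pyramid shapes and the dispatcher routes", {
  pyr <- rand_pyramid(2, 16)
  shapes <- lapply(pyr, function(m) dim(m$values))
  for (kind in PATH_KINDS) {
    prm <- if (kind %in% PARAM_PATH_KINDS) make_path_params(kind, 2, seed = 7) else NULL
    out <- apply_path(kind, pyr, prm)
    expect_equal(lapply(out, function(m) dim(m$values)), shapes)
  }
  expect_error(apply_path("SKIP", pyr, make_path_params("TOP_DOWN", 2)), "no params")
  expect_error(apply_path("TOP_DOWN", pyr), "requires params")
  p <- make_path_params("TOP_DOWN", 2, seed = 8)
  expect_equal(apply_path("TOP_DOWN", pyr, p)[["3"]]$values,
               top_down_path(pyr, p)[["3"]]$values)
})

test_that("stored parameter counts match the closed form", {
  for (kind in PARAM_PATH_KINDS) {
    for (C in c(1L, 3L)) {
      p <- make_path_params(kind, C, seed = 9)
      stored <- sum(vapply(path_param_names(p),
                           function(n) length(path_param_get(p, n)), 1))
      expect_equal(stored, path_param_count(kind, C))
    }
  }
})
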