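# The sampling and pooling operators against their printed formulas and
# brute-force oracle twins.

test_that("bilinear kernel: support, identity and direct evaluation", {
  expect_equal(bilinear_kernel(c(2, 2), c(2.0, 2.0)), 1.0)
  expect_equal(bilinear_kernel(c(0, 0), c(0.0, 1.0)), 0.0)
  expect_equal(bilinear_kernel(c(0, 0), c(0.25, 0.5)), 0.375)
  # zero outside the unit Chebyshev ball; partition of unity inside
  set.seed(1)
  for (rep in 1:20) {
    p <- runif(2, 0.5, 2.5)
    for (q1 in -1:4) for (q2 in -1:4) {
      if (max(abs(c(q1, q2) - p)) >= 1)
        expect_identical(bilinear_kernel(c(q1, q2), p), 0)
    }
    tot <- sum(outer(-1:4, -1:4, Vectorize(function(a, b)
      bilinear_kernel(c(a, b), p))))
    expect_equal(tot, 1)
  }
})

test_that("bilinear sampling matches the full-sum oracle", {
  m <- matrix(c(1, 3, 2, 4), 2, 2)  # [[1,2],[3,4]] by row
  expect_equal(bilinear_sample(m, c(0.5, 0.5)), 2.5)
  expect_equal(bilinear_sample(m, c(1, 1)), 4.0)
  expect_equal(bilinear_sample(m, c(0, 0.5)), 1.5)
  expect_error(bilinear_sample(m, c(NA, 0)), "finite")
  set.seed(2)
  x <- rand_map(3, 5, 4)
  for (rep in 1:25) {
    p <- c(runif(1, -0.8, 4.8), runif(1, -0.8, 3.8))
    expect_equal(bilinear_sample(feature_map(x), p), oracle_bilinear(x, p),
                 tolerance = 1e-12)
  }
})

test_that("standard convolution: identities and oracle equivalence", {
  set.seed(3)
  cmap <- feature_map(array(2.5, c(1, 5, 5)))
  ones <- conv_weights(array(1, c(1, 1, 3, 3)))
  y <- standard_conv(cmap, ones)
  expect_equal(y$values[1, 3, 3], 9 * 2.5)
  ident <- array(0, c(1, 1, 3, 3)); ident[1, 1, 2, 2] <- 1
  x <- rand_map(1, 5, 5)
  expect_equal(standard_conv(feature_map(x), conv_weights(ident))$values, x)
  k <- array(rnorm(9), c(1, 1, 3, 3))
  b <- rnorm(1)
  expect_equal(standard_conv(feature_map(x), conv_weights(k, b))$values,
               oracle_conv2d(x, k, b), tolerance = 1e-12)
  # multi-channel case
  x2 <- rand_map(3, 6, 4); k2 <- array(rnorm(2 * 3 * 9), c(2, 3, 3, 3))
  expect_equal(standard_conv(feature_map(x2), conv_weights(k2))$values,
               oracle_conv2d(x2, k2), tolerance = 1e-12)
  expect_error(standard_conv(feature_map(x2), conv_weights(k)), "channel")
})

test_that("deformable convolution reduces to standard conv at zero offset", {
  set.seed(4)
  for (rep in 1:10) {
    x <- rand_map(2, 6, 5)
    k <- array(rnorm(3 * 2 * 9), c(3, 2, 3, 3))
    b <- rnorm(3)
    off <- array(0, c(18, 6, 5))
    expect_equal(deformable_conv(feature_map(x), conv_weights(k, b), offsets = off)$values,
                 standard_conv(feature_map(x), conv_weights(k, b))$values,
                 tolerance = 1e-12)
  }
})

test_that("deformable convolution matches the bilinear-sum oracle", {
  set.seed(5)
  # center-tap kernel with constant (0.5, 0.5) offset samples at p0 + 0.5
  m <- matrix(c(1, 3, 2, 4), 2, 2)
  ident <- array(0, c(1, 1, 3, 3)); ident[1, 1, 2, 2] <- 1
  off <- array(0, c(18, 2, 2)); off[9, , ] <- 0.5; off[10, , ] <- 0.5
  y <- deformable_conv(feature_map(m), conv_weights(ident), offsets = off)
  expect_equal(y$values[1, 1, 1], 2.5)
  # integer offset (1, 0) on the center tap shifts the image up one row
  off2 <- array(0, c(18, 2, 2)); off2[9, , ] <- 1
  y2 <- deformable_conv(feature_map(m), conv_weights(ident), offsets = off2)
  expect_equal(y2$values[1, , ], rbind(c(3, 4), c(0, 0)))
  # random maps against the full oracle
  taps <- sampling_grid(3)
  for (rep in 1:6) {
    x <- rand_map(3, 8, 8)
    k <- array(rnorm(2 * 3 * 9), c(2, 3, 3, 3))
    b <- rnorm(2)
    offr <- array(rnorm(18 * 8 * 8, sd = 0.7), c(18, 8, 8))
    expect_equal(deformable_conv(feature_map(x), conv_weights(k, b), offsets = offr)$values,
                 oracle_dconv(x, k, b, taps, offr), tolerance = 1e-10)
  }
  expect_error(deformable_conv(feature_map(rand_map(1, 4, 4)),
                               conv_weights(array(rnorm(9), c(1, 1, 3, 3))),
                               offsets = array(0, c(18, 3, 3))), "shape")
})

test_that("offset prediction is a plain conv with the right contracts", {
  set.seed(6)
  x <- feature_map(rand_map(2, 4, 4))
  ow <- conv_weights(array(0, c(18, 2, 3, 3)))
  off <- predict_offsets(x, ow)
  expect_equal(dim(off), c(18L, 4L, 4L))
  expect_true(all(off == 0))
  # paired deformable conv equals standard conv under zero predictor
  k <- conv_weights(array(rnorm(2 * 2 * 9), c(2, 2, 3, 3)))
  expect_equal(deformable_conv(x, k, offsets = off)$values,
               standard_conv(x, k)$values)
  # linearity: doubling the predictor weights doubles the offsets
  ow2 <- conv_weights(array(rnorm(18 * 2 * 9), c(18, 2, 3, 3)))
  ow2x <- conv_weights(2 * ow2$kernel)
  expect_equal(predict_offsets(x, ow2x), 2 * predict_offsets(x, ow2))
  expect_error(predict_offsets(x, conv_weights(array(0, c(17, 2, 3, 3)))),
               "2K")
})

test_that("RoI average pooling enumerates bins like the oracle", {
  m <- matrix(c(1, 3, 2, 4), 2, 2)
  cmap <- feature_map(array(7, c(1, 6, 6)))
  bg <- roi_average_pool(cmap, c(0.3, 0.7, 5.1, 5.9), 3, 2)
  expect_true(all(abs(bg$pooled - 7) < 1e-12))
  expect_equal(roi_average_pool(m, c(0, 0, 2, 2), 1, 1)$pooled[1, 1, 1], 2.5)
  r2 <- roi_average_pool(m, c(0, 0, 2, 2), 1, 2)
  expect_equal(as.numeric(r2$pooled), c(2, 3))
  expect_equal(as.numeric(r2$counts), c(2L, 2L))
  expect_error(roi_average_pool(m, c(1, 1, 1, 2), 1, 1), "degenerate")
  set.seed(7)
  for (rep in 1:10) {
    x <- rand_map(2, 8, 8)
    roi <- c(sort(runif(2, 0, 7.5))[1], sort(runif(2, 0, 7.5))[1],
             0, 0)
    roi <- c(runif(1, 0, 4), runif(1, 0, 4), 0, 0)
    roi[3] <- roi[1] + runif(1, 0.5, 3.5)
    roi[4] <- roi[2] + runif(1, 0.5, 3.5)
    bh <- sample(1:3, 1); bw <- sample(1:3, 1)
    expect_equal(roi_average_pool(feature_map(x), roi, bh, bw)$pooled,
                 oracle_roi_pool(x, roi, bh, bw), tolerance = 1e-12)
  }
})

test_that("deformable RoI pooling shifts bins and matches the oracle", {
  m <- matrix(c(1, 3, 2, 4), 2, 2)
  # zero offsets reproduce plain pooling
  set.seed(8)
  x <- rand_map(2, 8, 8)
  roi <- c(1.2, 0.7, 6.4, 7.1)
  z <- array(0, c(2, 2, 3))
  expect_equal(deformable_roi_pool(feature_map(x), roi, 2, 3, z)$pooled,
               roi_average_pool(feature_map(x), roi, 2, 3)$pooled)
  # linear-ramp map: shifting one bin by (1, 0) adds exactly 1
  ramp <- array(rep(0:7, times = 8), c(1, 8, 8))
  off <- array(0, c(2, 2, 2)); off[1, 2, 1] <- 1
  plain <- roi_average_pool(feature_map(ramp), c(0, 0, 8, 6), 2, 2)
  shifted <- deformable_roi_pool(feature_map(ramp), c(0, 0, 8, 6), 2, 2, off)
  d <- shifted$pooled - plain$pooled
  expect_equal(d[1, 2, 1], 1)
  expect_equal(sum(abs(d)) - 1, 0)
  # fractional offset on the 2x2 worked example
  off5 <- array(0, c(2, 1, 1)); off5[1, 1, 1] <- 0.5
  got <- deformable_roi_pool(m, c(0, 0, 2, 2), 1, 1, off5)$pooled[1, 1, 1]
  expect_equal(got, mean(c(2, 3, 1.5, 2)))  # hand-evaluated bilinear sums
  # random offsets against the oracle
  for (rep in 1:8) {
    bo <- array(rnorm(2 * 2 * 2, sd = 0.8), c(2, 2, 2))
    expect_equal(deformable_roi_pool(feature_map(x), roi, 2, 2, bo)$pooled,
                 oracle_roi_pool(x, roi, 2, 2, bo), tolerance = 1e-12)
  }
  expect_error(deformable_roi_pool(m, c(0, 0, 2, 2), 2, 2,
                                   array(0, c(2, 1, 1))), "shape")
})
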