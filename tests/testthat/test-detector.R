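# Detector assembly: forward smoke, the zero-offset plain-conv twin, the
# loss decomposition identity, training determinism and a short overfit
# trend on one fixed batch.

tiny_set <- function(n, image_size = 64, seed0 = 100) {
  spec <- scene_spec(image_size = image_size, n_vertebrae = 3,
                     lesion_axes = c(3, 7), lesion_count = c(1, 2),
                     distractor_count = c(1, 3))
  lapply(seq_len(n), function(i) {
    g <- generate_image(spec, seed = seed0 + i)
    list(image = g$image, boxes = coco_to_xyxy(g$boxes))
  })
}

fixed_code <- c("P>X1" = "TOP_DOWN", "P>O" = "SKIP", "X1>O" = "SKIP")

test_that("tiny detector forward pass returns finite, well-formed detections", {
  det <- build_detector(tiny_detector_config(), code = fixed_code, seed = 1)
  item <- tiny_set(1)[[1]]
  d <- infer(det, item$image, score_threshold = 0)
  expect_true(is.data.frame(d))
  expect_true(all(is.finite(unlist(d[, 1:5]))))
  expect_true(all(d$x_min < d$x_max & d$y_min < d$y_max))
  expect_true(all(d$x_min >= 0 & d$x_max <= 64 & d$y_min >= 0 & d$y_max <= 64))
  expect_true(all(diff(d$score) <= 0))
  # an impossible threshold yields no detections
  expect_equal(nrow(infer(det, item$image, score_threshold = 1.01)), 0L)
  # head flattens channels x 7 x 7 into the fc layer
  expect_equal(dim(deformnas:::ps_get(det$ps, "head.fc1.w")),
               c(det$cfg$fc_dim, det$cfg$fpn_channels * 7L * 7L))
})

test_that("zero-initialized offsets make the deformable net equal its plain twin", {
  cfg_d <- tiny_detector_config()
  cfg_p <- tiny_detector_config(deformable_stages = integer(0))
  det_d <- build_detector(cfg_d, code = fixed_code, seed = 3)
  det_p <- build_detector(cfg_p, code = fixed_code, seed = 4)
  # share every weight the plain twin knows about (the deformable net's
  # extra offset predictors are zero at initialization)
  for (n in deformnas:::ps_names(det_p$ps)) {
    deformnas:::ps_add(det_p$ps, n, deformnas:::ps_get(det_d$ps, n))
  }
  item <- tiny_set(1, seed0 = 200)[[1]]
  d1 <- infer(det_d, item$image, score_threshold = 0)
  d2 <- infer(det_p, item$image, score_threshold = 0)
  expect_equal(d1, d2, tolerance = 1e-10)
  # and the offset predictors really are zero at initialization
  ow <- grep("\\.ow$|\\.ob$|^head\\.off\\.", deformnas:::ps_names(det_d$ps),
             value = TRUE)
  expect_true(length(ow) > 0)
  expect_true(all(vapply(ow, function(n)
    all(deformnas:::ps_get(det_d$ps, n) == 0), TRUE)))
})

test_that("compute_loss follows the printed decomposition", {
  perfect <- list(class_probs = rbind(c(0, 1), c(1, 0)),
                  box_deltas = rbind(c(0.1, 0.2, 0, 0), c(0, 0, 0, 0)))
  tgt <- list(labels = c(2L, 1L), box_deltas = perfect$box_deltas,
              positive = c(TRUE, FALSE))
  bd <- compute_loss(perfect, tgt, mu = 0.11, weights = NULL)
  expect_equal(bd$total, 0)
  # mu = 0 drops the regularizer
  noisy <- list(class_probs = rbind(c(0.3, 0.7), c(0.8, 0.2)),
                box_deltas = rbind(c(0.4, 0.1, 0, 0), c(0, 0, 0, 0)))
  b0 <- compute_loss(noisy, tgt, mu = 0, weights = list(rnorm(10)))
  expect_equal(b0$total, b0$l_cls + b0$l_loc)
  # mu = 0.11 with a unit-weight vector of length 4
  b1 <- compute_loss(perfect, tgt, mu = 0.11, weights = c(1, 1, 1, 1))
  expect_equal(b1$total, 0.11)
  # no predictions / targets: only the regularizer remains
  b2 <- compute_loss(list(), list(), mu = 0.11, weights = c(2, 2))
  expect_equal(b2$total, 0.11 * 2)
})

test_that("every logged training step satisfies the loss identity", {
  set.seed(51)
  det <- build_detector(tiny_detector_config(), code = fixed_code, seed = 5)
  det <- train(det, tiny_set(2), steps = 5, batch_size = 2, lr = 0.005,
               augment_data = FALSE, seed = 6)
  cc <- det$loss_curve
  expect_equal(nrow(cc), 5L)
  expect_equal(cc$total, cc$l_cls + cc$l_loc + 0.11 * cc$l1_reg)
  expect_true(all(is.finite(cc$total)))
  expect_true(all(cc$l_cls >= 0 & cc$l_loc >= 0 & cc$l1_reg >= 0))
})

test_that("training is reproducible and augmentation keeps the loop valid", {
  ts <- tiny_set(2)
  d1 <- train(build_detector(tiny_detector_config(), fixed_code, seed = 7),
              ts, steps = 4, batch_size = 2, lr = 0.005,
              augment_data = FALSE, seed = 9)
  d2 <- train(build_detector(tiny_detector_config(), fixed_code, seed = 7),
              ts, steps = 4, batch_size = 2, lr = 0.005,
              augment_data = FALSE, seed = 9)
  expect_identical(d1$loss_curve, d2$loss_curve)
  # augmented training pads crops to a pyramid-compatible size and runs
  d3 <- train(build_detector(tiny_detector_config(), fixed_code, seed = 7),
              ts, steps = 3, batch_size = 1, lr = 0.005,
              augment_data = TRUE, seed = 10)
  expect_true(all(is.finite(d3$loss_curve$total)))
  expect_error(train(build_detector(tiny_detector_config(), fixed_code),
                     list()), "empty")
})

test_that("a fixed tiny batch is overfit: loss halves within 80 steps", {
  ts <- tiny_set(2, seed0 = 300)
  det <- build_detector(tiny_detector_config(), fixed_code, seed = 11)
  det <- train(det, ts, steps = 80, batch_size = 2, lr = 0.005,
               augment_data = FALSE, seed = 12)
  first <- mean(det$loss_curve$total[1:3])
  last <- mean(tail(det$loss_curve$total, 3))
  expect_lt(last, 0.5 * first)
})

test_that("images without lesions train against pure background", {
  spec0 <- scene_spec(image_size = 64, n_vertebrae = 3, lesion_axes = c(3, 7),
                      lesion_count = c(0, 0))
  g <- generate_image(spec0, seed = 77)
  det <- build_detector(tiny_detector_config(), fixed_code, seed = 13)
  det <- train(det, list(list(image = g$image, boxes = coco_to_xyxy(g$boxes))),
               steps = 2, batch_size = 1, augment_data = FALSE, seed = 14)
  expect_true(all(is.finite(det$loss_curve$total)))
  expect_equal(det$loss_curve$l_loc, c(0, 0))
})

test_that("NMS keeps one of a set of identical boxes", {
  b <- rbind(c(0, 0, 4, 4), c(0, 0, 4, 4), c(0, 0, 4, 4), c(10, 10, 14, 14))
  keep <- nms(b, c(0.9, 0.8, 0.7, 0.6), 0.5)
  expect_equal(keep, c(1L, 4L))
})

test_that("checkpoints round-trip the full parameter state", {
  det <- build_detector(tiny_detector_config(), fixed_code, seed = 15)
  item <- tiny_set(1, seed0 = 400)[[1]]
  d1 <- infer(det, item$image, score_threshold = 0)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(det, path)
  det2 <- load_checkpoint(path)
  expect_equal(infer(det2, item$image, score_threshold = 0), d1)
})

test_that("the full-scale backbone assembles and runs forward", {
  cfg <- detector_config(backbone = "resnet50", fpn_channels = 16L,
                         head_channels = 16L, fc_dim = 32L, N = 1L)
  det <- build_detector(cfg, code = fixed_code, seed = 16)
  # bottleneck stage widths follow the standard 256/512/1024/2048 layout
  expect_equal(dim(deformnas:::ps_get(det$ps, "bb.s2.b1.c3.w"))[1], 256L)
  expect_equal(dim(deformnas:::ps_get(det$ps, "bb.s5.b3.c3.w"))[1], 2048L)
  item <- tiny_set(1, seed0 = 500)[[1]]
  d <- infer(det, item$image, score_threshold = 0)
  expect_true(is.data.frame(d) && all(is.finite(unlist(d[, 1:5]))))
})
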