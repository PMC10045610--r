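# Seeded generator of MRI-like grayscale scenes.  Fluid-sensitive lumbar
# MRI slices show a grey background, a column of medium-intensity vertebral
# bodies, bright distractor tissue (organs, fat) outside the spine, and --
# when present -- bright, variably shaped oedema lesions inside vertebrae.
# The generator emulates exactly that appearance; it makes no attempt at
# physical MRI simulation.

#' Scene specification for the synthetic generator
#'
#' @param image_size square image side in pixels.
#' @param n_vertebrae number of vertebral bodies in the central column.
#' @param background_intensity grey background level in `[0, 1]`.
#' @param vertebra_intensity mean vertebral body level.
#' @param distractor_count integer range `(min, max)` of bright distractor
#'   streaks/ellipses outside the spine.
#' @param distractor_intensity intensity range of distractors.
#' @param lesion_count integer range `(min, max)` of lesions per image.
#' @param lesion_axes ellipse semi-axis range in pixels (lesions are
#'   rotated ellipses fully inside a vertebra).
#' @param lesion_margin how far the lesion intensity sits above the
#'   vertebral background.
#' @param noise_sd standard deviation of the additive Gaussian pixel noise.
#' @return a `scene_spec`.
#' @export
scene_spec <- function(image_size = 256L, n_vertebrae = 5L,
                       background_intensity = 0.18,
                       vertebra_intensity = 0.45,
                       distractor_count = c(2L, 6L),
                       distractor_intensity = c(0.55, 0.85),
                       lesion_count = c(0L, 3L),
                       lesion_axes = c(4, 30),
                       lesion_margin = 0.3,
                       noise_sd = 0.02) {
  stopifnot(image_size >= 32L, n_vertebrae >= 1L,
            lesion_axes[1] > 0, lesion_axes[2] >= lesion_axes[1],
            lesion_margin > 0, noise_sd >= 0)
  structure(as.list(environment()), class = "scene_spec")
}

# Vertebra layout: centers, half-widths and half-heights of the column.
vertebra_layout <- function(spec) {
  H <- spec$image_size
  n <- spec$n_vertebrae
  slot <- H / (n + 1)
  data.frame(
    cx = H * 0.5,
    cy = slot * (seq_len(n) + 0.5) - slot / 2,
    hw = H * 0.14,
    hh = slot * 0.38
  )
}

rounded_rect_mask <- function(xg, yg, cx, cy, hw, hh, r) {
  dx <- pmax(abs(xg - cx) - (hw - r), 0)
  dy <- pmax(abs(yg - cy) - (hh - r), 0)
  sqrt(dx^2 + dy^2) <= r
}

ellipse_mask <- function(xg, yg, cx, cy, a, b, theta) {
  xr <- (xg - cx) * cos(theta) + (yg - cy) * sin(theta)
  yr <- -(xg - cx) * sin(theta) + (yg - cy) * cos(theta)
  (xr / a)^2 + (yr / b)^2 <= 1
}

#' Generate one synthetic MRI-like image
#'
#' Deterministic under `seed`: renders the vertebral column, distractor
#' tissue and 0..k bright elliptical lesions, adds Gaussian noise, and
#' returns the image with one tight axis-aligned box per lesion in COCO
#' `(x, y, w, h)` pixel convention.  Lesions are constructed brighter than
#' their surroundings, and the box/background intensity contrast is
#' asserted before returning.
#'
#' @param spec a [scene_spec].
#' @param seed integer seed.
#' @return list with `image` (matrix `[H, W]`, values in `[0, 1]`, row =
#'   y) and `boxes` (data frame `x, y, w, h`; zero rows when no lesion).
#' @export
generate_image <- function(spec = scene_spec(), seed = 1L) {
  set.seed(seed)
  H <- spec$image_size
  vt <- vertebra_layout(spec)
  if (2 * spec$lesion_axes[1] > min(vt$hw, vt$hh) * 2)
    stop("infeasible scene: smallest lesion does not fit inside a vertebra")
  # pixel-center grids: xg = col - 0.5, yg = row - 0.5
  xg <- matrix(rep(seq_len(H) - 0.5, each = H), H, H)
  yg <- matrix(rep(seq_len(H) - 0.5, times = H), H, H)
  img <- matrix(spec$background_intensity, H, H)
  for (i in seq_len(nrow(vt))) {
    m <- rounded_rect_mask(xg, yg, vt$cx[i], vt$cy[i], vt$hw[i], vt$hh[i],
                           r = 0.25 * min(vt$hw[i], vt$hh[i]))
    img[m] <- spec$vertebra_intensity + rnorm(1, sd = 0.02)
  }
  nd <- sample(spec$distractor_count[1]:spec$distractor_count[2], 1L)
  for (k in seq_len(nd)) {
    side <- sample(c(-1, 1), 1L)
    cx <- H * 0.5 + side * runif(1, 0.25 * H, 0.42 * H)
    cy <- runif(1, 0.1 * H, 0.9 * H)
    a <- runif(1, 0.02 * H, 0.1 * H)
    b <- runif(1, 0.2, 0.6) * a
    th <- runif(1, 0, pi)
    inten <- runif(1, spec$distractor_intensity[1], spec$distractor_intensity[2])
    m <- ellipse_mask(xg, yg, cx, cy, a, b, th)
    img[m] <- inten
  }
  n_lesion <- sample(spec$lesion_count[1]:spec$lesion_count[2], 1L)
  boxes <- data.frame(x = numeric(0), y = numeric(0), w = numeric(0), h = numeric(0))
  for (k in seq_len(n_lesion)) {
    # distinct oedema foci must stay distinct regions: reject placements
    # whose box overlaps an already placed lesion (bounded retries, then
    # the lesion is skipped)
    for (try in 1:20) {
      v <- vt[sample.int(nrow(vt), 1L), ]
      amax <- min(spec$lesion_axes[2], 0.45 * min(v$hw, v$hh) * 2) / 2
      amax <- max(amax, spec$lesion_axes[1])
      a <- runif(1, spec$lesion_axes[1], amax)
      b <- runif(1, spec$lesion_axes[1], amax)
      th <- runif(1, 0, pi)
      hx <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
      hy <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
      cx <- runif(1, v$cx - v$hw + hx, v$cx + v$hw - hx)
      cy <- runif(1, v$cy - v$hh + hy, v$cy + v$hh - hy)
      cand <- c(cx - hx, cy - hy, cx + hx, cy + hy)
      overlaps <- FALSE
      for (i in seq_len(nrow(boxes))) {
        prev <- c(boxes$x[i], boxes$y[i], boxes$x[i] + boxes$w[i],
                  boxes$y[i] + boxes$h[i])
        iw <- min(cand[3], prev[3]) - max(cand[1], prev[1])
        ih <- min(cand[4], prev[4]) - max(cand[2], prev[2])
        if (iw > 0 && ih > 0) { overlaps <- TRUE; break }
      }
      if (!overlaps) break
    }
    if (overlaps) next
    m <- ellipse_mask(xg, yg, cx, cy, a, b, th)
    img[m] <- spec$vertebra_intensity + spec$lesion_margin + rnorm(1, sd = 0.02)
    boxes <- rbind(boxes, data.frame(x = cx - hx, y = cy - hy,
                                     w = 2 * hx, h = 2 * hy))
  }
  if (spec$noise_sd > 0) img <- img + matrix(rnorm(H * H, sd = spec$noise_sd), H, H)
  img <- pmin(pmax(img, 0), 1)
  bg_mean <- mean(img)
  for (i in seq_len(nrow(boxes))) {
    rows <- max(1, floor(boxes$y[i] + 1)):min(H, ceiling(boxes$y[i] + boxes$h[i]))
    cols <- max(1, floor(boxes$x[i] + 1)):min(H, ceiling(boxes$x[i] + boxes$w[i]))
    stopifnot(mean(img[rows, cols]) > bg_mean)
  }
  list(image = img, boxes = boxes)
}

#' Dataset configuration
#'
#' Defaults mirror the study conditions: 416 training and 105 test images.
#'
#' @param n_train,n_test split sizes (>= 0; the splits are disjoint by
#'   construction because per-image seeds are derived from consecutive
#'   indices).
#' @param seed master seed.
#' @param spec a [scene_spec].
#' @return a `dataset_config`.
#' @export
dataset_config <- function(n_train = 416L, n_test = 105L, seed = 1L,
                           spec = scene_spec()) {
  stopifnot(n_train >= 0L, n_test >= 0L)
  structure(list(n_train = as.integer(n_train), n_test = as.integer(n_test),
                 seed = as.integer(seed), spec = spec),
            class = "dataset_config")
}

image_seed <- function(master, index) {
  as.integer((as.numeric(master) * 7919 + index * 104729) %% 2147483647)
}

config_hash <- function(cfg) {
  s <- utf8ToInt(paste(deparse(cfg), collapse = ""))
  sprintf("%08x", sum(s * (seq_along(s) %% 97 + 1)) %% 4294967296)
}

#' Generate a dataset directory with COCO annotations
#'
#' Writes 8-bit grayscale PNGs and one COCO detection JSON per split
#' (`train.json`, `test.json`), plus a `manifest.json` with the full
#' configuration and its hash so the dataset is reproducible from
#' `(config, seed)` alone.
#'
#' @param cfg a [dataset_config].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly; side effect: files on disk.
#' @export
generate_dataset <- function(cfg = dataset_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_split <- function(name, n, index_offset) {
    dir.create(file.path(out_dir, name), showWarnings = FALSE)
    imgs <- data.frame(); anns <- data.frame(); ann_id <- 0L
    for (i in seq_len(n)) {
      idx <- index_offset + i
      g <- generate_image(cfg$spec, seed = image_seed(cfg$seed, idx))
      fn <- sprintf("img_%05d.png", idx)
      png::writePNG(g$image, file.path(out_dir, name, fn))
      imgs <- rbind(imgs, data.frame(id = idx, file_name = fn,
                                     width = cfg$spec$image_size,
                                     height = cfg$spec$image_size))
      if (nrow(g$boxes) > 0L) {
        anns <- rbind(anns, data.frame(id = ann_id + seq_len(nrow(g$boxes)),
                                       image_id = idx, g$boxes))
        ann_id <- ann_id + nrow(g$boxes)
      }
    }
    if (n > 0L)
      write_coco(imgs, anns, file.path(out_dir, paste0(name, ".json")))
  }
  write_split("train", cfg$n_train, 0L)
  write_split("test", cfg$n_test, cfg$n_train)
  jsonlite::write_json(list(config = unclass(rapply(cfg, unclass, how = "replace")),
                            hash = config_hash(cfg)),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' Load a generated split into memory
#'
#' @param dir dataset directory written by [generate_dataset].
#' @param split `"train"` or `"test"`.
#' @return list of `list(image, boxes)` items with corner-format boxes.
#' @export
load_split <- function(dir, split = "train") {
  coco <- read_coco(file.path(dir, paste0(split, ".json")))
  ann_by_img <- split(coco$annotations,
                      vapply(coco$annotations, `[[`, 1, "image_id"))
  lapply(coco$images, function(m) {
    img <- png::readPNG(file.path(dir, split, m$file_name))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    anns <- ann_by_img[[as.character(m$id)]]
    boxes <- if (is.null(anns)) {
      data.frame(x = numeric(0), y = numeric(0), w = numeric(0), h = numeric(0))
    } else {
      do.call(rbind, lapply(anns, function(a) {
        bb <- as.numeric(a$bbox)
        data.frame(x = bb[1], y = bb[2], w = bb[3], h = bb[4])
      }))
    }
    list(image = img, boxes = coco_to_xyxy(boxes), id = m$id)
  })
}

#' Random flip / random crop augmentation
#'
#' Mirrors the image horizontally with probability `flip_p` (box
#' `x_min' = W - x_max`), then crops a window whose linear scale is drawn
#' uniformly from `crop_range`; boxes are translated, clipped to the
#' window, and dropped when less than `min_visible` of their original area
#' remains.
#'
#' @param image matrix `[H, W]`.
#' @param boxes data frame with corner columns `x_min, y_min, x_max, y_max`.
#' @param seed optional seed.
#' @param flip_p flip probability.
#' @param crop_range linear crop scale range, inside `(0, 1]`.
#' @param min_visible minimum visible-area fraction for a box to survive.
#' @return list `(image, boxes)`.
#' @export
augment <- function(image, boxes, seed = NULL, flip_p = 0.5,
                    crop_range = c(0.6, 1.0), min_visible = 0.25) {
  if (crop_range[1] <= 0 || crop_range[2] > 1 || crop_range[1] > crop_range[2])
    stop("crop_range must lie inside (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  H <- nrow(image); W <- ncol(image)
  if (runif(1) < flip_p) {
    image <- image[, rev(seq_len(W)), drop = FALSE]
    if (nrow(boxes) > 0L) {
      new_xmin <- W - boxes$x_max
      boxes$x_max <- W - boxes$x_min
      boxes$x_min <- new_xmin
    }
  }
  s <- runif(1, crop_range[1], crop_range[2])
  ch <- max(1L, round(s * H)); cw <- max(1L, round(s * W))
  y0 <- if (H > ch) sample.int(H - ch + 1L, 1L) - 1L else 0L
  x0 <- if (W > cw) sample.int(W - cw + 1L, 1L) - 1L else 0L
  image <- image[y0 + seq_len(ch), x0 + seq_len(cw), drop = FALSE]
  if (nrow(boxes) > 0L) {
    area0 <- (boxes$x_max - boxes$x_min) * (boxes$y_max - boxes$y_min)
    boxes$x_min <- pmin(pmax(boxes$x_min - x0, 0), cw)
    boxes$x_max <- pmin(pmax(boxes$x_max - x0, 0), cw)
    boxes$y_min <- pmin(pmax(boxes$y_min - y0, 0), ch)
    boxes$y_max <- pmin(pmax(boxes$y_max - y0, 0), ch)
    vis <- (boxes$x_max - boxes$x_min) * (boxes$y_max - boxes$y_min) / area0
    boxes <- boxes[vis >= min_visible & boxes$x_max > boxes$x_min &
                     boxes$y_max > boxes$y_min, , drop = FALSE]
  }
  list(image = image, boxes = boxes)
}
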