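# Assembly of the two-stage detector: backbone with deformable convolutions
# in stages 3-5, NAS-searched aggregation neck, residual superposition of
# the neck output onto the (laterally projected) backbone pyramid,
# region-proposal network, deformable RoI pooling, fully connected head,
# and the composite loss  L = sum(L_cls + L_loc) + mu * L1.

#' Detector configuration
#'
#' @param backbone `"tiny"` (4 small conv stages; every end-to-end test
#'   runs this on one CPU) or `"resnet50"` (the full-scale architecture
#'   shape, randomly initialized).
#' @param backbone_channels channel width of the tiny backbone.
#' @param deformable_stages backbone stages using deformable convolutions.
#' @param fpn_channels neck / pyramid channel width.
#' @param head_channels RPN hidden width.
#' @param fc_dim width of the fully connected head layer.
#' @param roi_bins RoI pooling grid `(rows, cols)`.
#' @param N supernet intermediate node count.
#' @param mu L1 regularization weight in the total loss.
#' @param l1_scope `"neck"` (regularize the aggregation-neck weights) or
#'   `"all"`.
#' @param lr,momentum,batch_size,epochs SGD training parameters.
#' @param anchor_base anchor side at scale 1 is `anchor_base * stride`.
#' @param anchor_scales,anchor_ratios per-cell anchor shapes
#'   (`length(scales) * length(ratios)` anchors per cell).
#' @param num_classes foreground classes (background is implicit).
#' @return a `detector_config`.
#' @export
detector_config <- function(backbone = c("resnet50", "tiny"),
                            backbone_channels = 16L,
                            deformable_stages = c(3L, 4L, 5L),
                            fpn_channels = 112L, head_channels = 112L,
                            fc_dim = 1024L, roi_bins = c(7L, 7L), N = 5L,
                            mu = 0.11, l1_scope = c("neck", "all"),
                            lr = 0.001, momentum = 0.9, batch_size = 4L,
                            epochs = 30L, anchor_base = 4,
                            anchor_scales = c(0.5, 1, 2),
                            anchor_ratios = c(0.5, 1, 2),
                            num_classes = 1L) {
  backbone <- match.arg(backbone)
  stopifnot(fpn_channels >= 1L, fc_dim >= 1L, all(roi_bins >= 1L), N >= 1L,
            mu >= 0, lr > 0, batch_size >= 1L, epochs >= 1L)
  structure(list(backbone = backbone,
                 backbone_channels = as.integer(backbone_channels),
                 deformable_stages = as.integer(deformable_stages),
                 fpn_channels = as.integer(fpn_channels),
                 head_channels = as.integer(head_channels),
                 fc_dim = as.integer(fc_dim),
                 roi_bins = as.integer(roi_bins), N = as.integer(N),
                 mu = mu, l1_scope = match.arg(l1_scope), lr = lr,
                 momentum = momentum, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), anchor_base = anchor_base,
                 anchor_scales = anchor_scales, anchor_ratios = anchor_ratios,
                 num_classes = as.integer(num_classes)),
            class = "detector_config")
}

#' @rdname detector_config
#' @param ... overrides passed to [detector_config].
#' @export
tiny_detector_config <- function(...) {
  defaults <- list(backbone = "tiny", backbone_channels = 16L,
                   fpn_channels = 16L, head_channels = 16L, fc_dim = 64L,
                   N = 1L, lr = 0.005)
  args <- utils::modifyList(defaults, list(...))
  do.call(detector_config, args)
}

# ---- parameter initialization --------------------------------------------

init_backbone_params <- function(ps, cfg) {
  if (cfg$backbone == "tiny") {
    c0 <- cfg$backbone_channels
    init_conv_params(ps, "bb.stem", c0, 1L, deformable = FALSE)
    for (s in 2:5)
      init_conv_params(ps, paste0("bb.s", s), c0, c0,
                       deformable = s %in% cfg$deformable_stages)
    stage_out <- rep(c0, 4L)
  } else {
    ps_add(ps, "bb.stem.w", he_kernel(64L, 1L, 7L, 7L))
    ps_add(ps, "bb.stem.b", numeric(64L))
    blocks <- c(3L, 4L, 6L, 3L)
    mids <- c(64L, 128L, 256L, 512L)
    in_ch <- 64L
    for (s in 2:5) {
      mid <- mids[s - 1L]; out <- 4L * mid
      for (bkn in seq_len(blocks[s - 1L])) {
        pfx <- sprintf("bb.s%d.b%d", s, bkn)
        ps_add(ps, paste0(pfx, ".c1.w"), he_kernel(mid, in_ch, 1L, 1L))
        ps_add(ps, paste0(pfx, ".c1.b"), numeric(mid))
        init_conv_params(ps, paste0(pfx, ".c2"), mid, mid,
                         deformable = s %in% cfg$deformable_stages)
        ps_add(ps, paste0(pfx, ".c3.w"), he_kernel(out, mid, 1L, 1L))
        ps_add(ps, paste0(pfx, ".c3.b"), numeric(out))
        if (bkn == 1L) {
          ps_add(ps, paste0(pfx, ".sc.w"), he_kernel(out, in_ch, 1L, 1L))
          ps_add(ps, paste0(pfx, ".sc.b"), numeric(out))
        }
        in_ch <- out
      }
    }
    stage_out <- 4L * mids
  }
  for (i in 2:5) {
    ps_add(ps, sprintf("lat.%d.w", i),
           he_kernel(cfg$fpn_channels, stage_out[i - 1L], 1L, 1L))
    ps_add(ps, sprintf("lat.%d.b", i), numeric(cfg$fpn_channels))
  }
  invisible(ps)
}

init_rpn_head_params <- function(ps, cfg) {
  A <- length(cfg$anchor_scales) * length(cfg$anchor_ratios)
  init_conv_params(ps, "rpn.conv", cfg$head_channels, cfg$fpn_channels, FALSE)
  ps_add(ps, "rpn.cls.w", he_kernel(A, cfg$head_channels, 1L, 1L) * 0.1)
  ps_add(ps, "rpn.cls.b", numeric(A))
  ps_add(ps, "rpn.box.w", he_kernel(4L * A, cfg$head_channels, 1L, 1L) * 0.1)
  ps_add(ps, "rpn.box.b", numeric(4L * A))
  d_pool <- cfg$fpn_channels * cfg$roi_bins[1] * cfg$roi_bins[2]
  n_off <- 2L * cfg$roi_bins[1] * cfg$roi_bins[2]
  ps_add(ps, "head.off.w", matrix(0, n_off, d_pool))   # zero init: plain pooling
  ps_add(ps, "head.off.b", numeric(n_off))
  ps_add(ps, "head.fc1.w",
         matrix(rnorm(cfg$fc_dim * d_pool, sd = sqrt(2 / d_pool)), cfg$fc_dim, d_pool))
  ps_add(ps, "head.fc1.b", numeric(cfg$fc_dim))
  ncls <- cfg$num_classes + 1L
  ps_add(ps, "head.cls.w",
         matrix(rnorm(ncls * cfg$fc_dim, sd = 0.01), ncls, cfg$fc_dim))
  ps_add(ps, "head.cls.b", numeric(ncls))
  ps_add(ps, "head.box.w",
         matrix(rnorm(4L * cfg$fc_dim, sd = 0.001), 4L, cfg$fc_dim))
  ps_add(ps, "head.box.b", numeric(4L))
  invisible(ps)
}

#' Build a detector
#'
#' Forward path: backbone stages C2..C5 -> 1x1 lateral projection to the
#' pyramid width -> aggregation neck (a fixed subnet code, or one sampled
#' per training step in supernet mode) -> element-wise superposition of the
#' neck output onto the projected backbone pyramid -> RPN proposals ->
#' deformable RoI pooling (per-bin offsets predicted from the plain pooled
#' features, zero-initialized) -> fully connected head -> class scores and
#' box deltas.
#'
#' @param cfg a [detector_config].
#' @param code a valid subnet code, or `"supernet"` for single-path
#'   one-shot training mode.
#' @param seed seed for weight initialization.
#' @return a `detector`.
#' @export
build_detector <- function(cfg = detector_config(), code = "supernet",
                           seed = 1L) {
  set.seed(seed)
  ps <- param_store()
  init_backbone_params(ps, cfg)
  init_rpn_head_params(ps, cfg)
  neck <- build_supernet(N = cfg$N, channels = cfg$fpn_channels, ps = ps,
                         prefix = "neck")
  if (!identical(code, "supernet")) {
    if (!identical(sort(names(code)), sort(neck$edge_labels)) ||
        !all(code %in% PATH_KINDS) || !is_valid_code(code))
      stop("invalid subnet code for this detector")
  }
  structure(list(cfg = cfg, ps = ps, neck = neck,
                 code = if (identical(code, "supernet")) NULL else code,
                 strides = c(4L, 8L, 16L, 32L)),
            class = "detector")
}

#' @export
print.detector <- function(x, ...) {
  cat(sprintf("<detector backbone=%s, fpn_channels=%d, N=%d, %s mode, %s parameters>\n",
              x$cfg$backbone, x$cfg$fpn_channels, x$cfg$N,
              if (is.null(x$code)) "supernet" else "fixed-code",
              format(ps_n_params(x$ps), big.mark = ",")))
  invisible(x)
}

# ---- backbone forward -----------------------------------------------------

conv_block_ad <- function(cx, tape, x, prefix, deformable) {
  ad_relu(tape, path_conv_ad(cx, tape, x, prefix, deformable))
}

resnet_bottleneck_ad <- function(cx, tape, x, prefix, stride2, deformable) {
  h <- ad_relu(tape, ad_conv2d(tape, x, ad_param(cx, paste0(prefix, ".c1.w")),
                               ad_param(cx, paste0(prefix, ".c1.b"))))
  h <- path_conv_ad(cx, tape, h, paste0(prefix, ".c2"), deformable)
  if (stride2) h <- ad_subsample2(tape, h)
  h <- ad_relu(tape, h)
  h <- ad_conv2d(tape, h, ad_param(cx, paste0(prefix, ".c3.w")),
                 ad_param(cx, paste0(prefix, ".c3.b")))
  sc <- x
  if (!is.null(cx$ps$val[[paste0(prefix, ".sc.w")]])) {
    sc <- ad_conv2d(tape, x, ad_param(cx, paste0(prefix, ".sc.w")),
                    ad_param(cx, paste0(prefix, ".sc.b")))
    if (stride2) sc <- ad_subsample2(tape, sc)
  }
  ad_relu(tape, ad_add(tape, h, sc))
}

backbone_ad <- function(cx, tape, img_node, cfg) {
  if (cfg$backbone == "tiny") {
    x <- ad_maxpool2(tape, conv_block_ad(cx, tape, img_node, "bb.stem", FALSE))
    feats <- list()
    for (s in 2:5) {
      x <- ad_maxpool2(tape, conv_block_ad(cx, tape, x, paste0("bb.s", s),
                                           s %in% cfg$deformable_stages))
      feats[[as.character(s)]] <- x
    }
    feats
  } else {
    x <- ad_subsample2(tape, ad_relu(tape, ad_conv2d(
      tape, img_node, ad_param(cx, "bb.stem.w"), ad_param(cx, "bb.stem.b"))))
    x <- ad_maxpool2(tape, x)
    blocks <- c(3L, 4L, 6L, 3L)
    feats <- list()
    for (s in 2:5) {
      for (bkn in seq_len(blocks[s - 1L])) {
        x <- resnet_bottleneck_ad(cx, tape, x, sprintf("bb.s%d.b%d", s, bkn),
                                  stride2 = (s > 2L && bkn == 1L),
                                  deformable = s %in% cfg$deformable_stages)
      }
      feats[[as.character(s)]] <- x
    }
    feats
  }
}

# Backbone + lateral projection + neck + superposition; returns the fused
# pyramid as a named list of nodes ("2".."5").
detector_trunk_ad <- function(det, cx, tape, image, code) {
  img <- array(image, dim = c(1L, nrow(image), ncol(image)))
  feats <- backbone_ad(cx, tape, ad_const(tape, img), det$cfg)
  pyr <- lapply(as.character(2:5), function(i) {
    ad_conv2d(tape, feats[[i]], ad_param(cx, sprintf("lat.%s.w", i)),
              ad_param(cx, sprintf("lat.%s.b", i)))
  })
  names(pyr) <- as.character(2:5)
  neck_out <- forward_subnet_ad(cx, tape, det$neck, code, pyr)
  fused <- lapply(as.character(2:5), function(i)
    ad_add(tape, neck_out[[i]], pyr[[i]]))
  names(fused) <- as.character(2:5)
  fused
}

rpn_ad <- function(det, cx, tape, fused) {
  lapply(fused, function(f) {
    h <- ad_relu(tape, ad_conv2d(tape, f, ad_param(cx, "rpn.conv.w"),
                                 ad_param(cx, "rpn.conv.b")))
    list(cls = ad_conv2d(tape, h, ad_param(cx, "rpn.cls.w"),
                         ad_param(cx, "rpn.cls.b")),
         box = ad_conv2d(tape, h, ad_param(cx, "rpn.box.w"),
                         ad_param(cx, "rpn.box.b")))
  })
}

# ---- anchors, deltas, proposals ------------------------------------------

anchor_shapes <- function(cfg, stride) {
  shp <- expand.grid(scale = cfg$anchor_scales, ratio = cfg$anchor_ratios)
  size <- cfg$anchor_base * stride * shp$scale
  cbind(w = size * sqrt(shp$ratio), h = size / sqrt(shp$ratio))
}

# All anchors of one level as [n, 4] xyxy, ordered anchor-fastest, then
# row, then col -- matching the flattening of the [A, H, W] RPN outputs.
level_anchors <- function(cfg, stride, Hl, Wl) {
  shp <- anchor_shapes(cfg, stride)
  A <- nrow(shp)
  hr <- rep(seq_len(Hl) - 0.5, times = Wl)
  wc <- rep(seq_len(Wl) - 0.5, each = Hl)
  cx <- rep(wc * stride, each = A)
  cy <- rep(hr * stride, each = A)
  w <- rep(shp[, "w"], times = Hl * Wl)
  h <- rep(shp[, "h"], times = Hl * Wl)
  cbind(x_min = cx - w / 2, y_min = cy - h / 2,
        x_max = cx + w / 2, y_max = cy + h / 2)
}

box_iou_matrix <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(matrix(0, nrow(a), nrow(b)))
  out <- matrix(0, nrow(a), nrow(b))
  area_a <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  area_b <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  for (j in seq_len(nrow(b))) {
    iw <- pmin(a[, 3], b[j, 3]) - pmax(a[, 1], b[j, 1])
    ih <- pmin(a[, 4], b[j, 4]) - pmax(a[, 2], b[j, 2])
    inter <- pmax(iw, 0) * pmax(ih, 0)
    out[, j] <- inter / (area_a + area_b[j] - inter)
  }
  out
}

encode_deltas <- function(boxes, anchors) {
  aw <- anchors[, 3] - anchors[, 1]; ah <- anchors[, 4] - anchors[, 2]
  ax <- (anchors[, 1] + anchors[, 3]) / 2; ay <- (anchors[, 2] + anchors[, 4]) / 2
  gw <- boxes[, 3] - boxes[, 1]; gh <- boxes[, 4] - boxes[, 2]
  gx <- (boxes[, 1] + boxes[, 3]) / 2; gy <- (boxes[, 2] + boxes[, 4]) / 2
  cbind((gx - ax) / aw, (gy - ay) / ah, log(gw / aw), log(gh / ah))
}

decode_deltas <- function(deltas, anchors) {
  aw <- anchors[, 3] - anchors[, 1]; ah <- anchors[, 4] - anchors[, 2]
  ax <- (anchors[, 1] + anchors[, 3]) / 2; ay <- (anchors[, 2] + anchors[, 4]) / 2
  cx <- ax + deltas[, 1] * aw; cy <- ay + deltas[, 2] * ah
  w <- aw * exp(pmin(deltas[, 3], 4)); h <- ah * exp(pmin(deltas[, 4], 4))
  cbind(x_min = cx - w / 2, y_min = cy - h / 2,
        x_max = cx + w / 2, y_max = cy + h / 2)
}

clip_boxes <- function(boxes, H, W) {
  boxes[, c(1, 3)] <- pmin(pmax(boxes[, c(1, 3)], 0), W)
  boxes[, c(2, 4)] <- pmin(pmax(boxes[, c(2, 4)], 0), H)
  boxes
}

#' Greedy non-maximum suppression
#' @param boxes matrix `[n, 4]` xyxy.
#' @param scores numeric vector.
#' @param iou_threshold suppression threshold.
#' @return indices of the kept boxes, in descending score order.
#' @export
nms <- function(boxes, scores, iou_threshold = 0.5) {
  ord <- order(scores, decreasing = TRUE)
  keep <- integer(0)
  while (length(ord) > 0L) {
    i <- ord[1]
    keep <- c(keep, i)
    ord <- ord[-1]
    if (length(ord) == 0L) break
    ious <- box_iou_matrix(boxes[ord, , drop = FALSE],
                           boxes[i, , drop = FALSE])[, 1]
    ord <- ord[ious <= iou_threshold]
  }
  keep
}

# Decode RPN outputs into proposals (plain values; no gradient flows
# through proposal coordinates, the Faster-RCNN convention).
rpn_proposals <- function(det, rpn_out, H, W, pre_nms = 300L, post_nms = 32L,
                          nms_iou = 0.7) {
  all_boxes <- NULL; all_scores <- NULL
  for (li in seq_along(rpn_out)) {
    cls <- ad_val(rpn_out[[li]]$cls)
    box <- ad_val(rpn_out[[li]]$box)
    A <- dim(cls)[1]
    anchors <- level_anchors(det$cfg, det$strides[li], dim(cls)[2], dim(cls)[3])
    # box channels are ordered (4, A) per cell; flatten to [n, 4] anchor-fastest
    deltas <- t(matrix(box, nrow = 4L))
    all_boxes <- rbind(all_boxes, decode_deltas(deltas, anchors))
    all_scores <- c(all_scores, as.numeric(cls))
  }
  keep <- order(all_scores, decreasing = TRUE)[seq_len(min(pre_nms, length(all_scores)))]
  boxes <- clip_boxes(all_boxes[keep, , drop = FALSE], H, W)
  scores <- all_scores[keep]
  ok <- (boxes[, 3] - boxes[, 1]) >= 1 & (boxes[, 4] - boxes[, 2]) >= 1
  boxes <- boxes[ok, , drop = FALSE]; scores <- scores[ok]
  if (nrow(boxes) == 0L) return(list(boxes = boxes, scores = scores))
  k <- nms(boxes, scores, nms_iou)
  k <- k[seq_len(min(post_nms, length(k)))]
  list(boxes = boxes[k, , drop = FALSE], scores = scores[k])
}

roi_level <- function(det, boxes) {
  s <- sqrt(pmax((boxes[, 3] - boxes[, 1]) * (boxes[, 4] - boxes[, 2]), 1))
  pmin(pmax(2L + floor(log2(s / (det$cfg$anchor_base * 4))), 2L), 5L)
}

# Deformable RoI pooling + fully connected head for a set of boxes (image
# pixels).  Returns nodes: cls logits [ncls, n], box deltas [4, n].
head_ad <- function(det, cx, tape, fused, boxes) {
  cfg <- det$cfg
  bh <- cfg$roi_bins[1]; bw <- cfg$roi_bins[2]
  lv <- roi_level(det, boxes)
  pooled_parts <- list(); order_idx <- integer(0)
  for (l in sort(unique(lv))) {
    sel <- which(lv == l)
    stride <- det$strides[l - 1L]
    rois <- boxes[sel, , drop = FALSE] / stride
    # guarantee a nonempty RoI in cell coordinates
    rois[, 3] <- pmax(rois[, 3], rois[, 1] + 0.1)
    rois[, 4] <- pmax(rois[, 4], rois[, 2] + 0.1)
    plain <- ad_droi_pool(tape, fused[[as.character(l)]], rois, bh, bw)
    flat <- ad_reshape(tape, plain, c(cfg$fpn_channels * bh * bw, length(sel)))
    off <- ad_fc(tape, flat, ad_param(cx, "head.off.w"), ad_param(cx, "head.off.b"))
    off <- ad_reshape(tape, off, c(2L, bh, bw, length(sel)))
    pooled_parts[[length(pooled_parts) + 1L]] <-
      ad_reshape(tape,
                 ad_droi_pool(tape, fused[[as.character(l)]], rois, bh, bw, off),
                 c(cfg$fpn_channels * bh * bw, length(sel)))
    order_idx <- c(order_idx, sel)
  }
  feat <- if (length(pooled_parts) == 1L) pooled_parts[[1]] else {
    # concatenate along the RoI axis via vector concat + reshape
    d <- cfg$fpn_channels * bh * bw
    ad_reshape(tape, ad_cat(tape, pooled_parts), c(d, length(order_idx)))
  }
  h <- ad_relu(tape, ad_fc(tape, feat, ad_param(cx, "head.fc1.w"),
                           ad_param(cx, "head.fc1.b")))
  cls <- ad_fc(tape, h, ad_param(cx, "head.cls.w"), ad_param(cx, "head.cls.b"))
  box <- ad_fc(tape, h, ad_param(cx, "head.box.w"), ad_param(cx, "head.box.b"))
  list(cls = cls, box = box, order = order_idx)
}

# ---- loss -----------------------------------------------------------------

#' Composite detection loss
#'
#' `total = l_cls + l_loc + mu * l1_reg`: cross-entropy over class
#' probabilities, smooth-L1 over the box deltas of positive matches
#' (normalized by `4 * n_pos`), and the mean absolute value of the
#' regularized weights.
#'
#' @param predictions list with `class_probs` (`[n, n_classes]` rows
#'   summing to 1) and `box_deltas` (`[n, 4]`).
#' @param targets list with `labels` (1-based class ids), `box_deltas`
#'   and logical `positive`.
#' @param mu L1 weight (default 0.11).
#' @param weights optional list/vector of regularized parameters.
#' @return a `loss_breakdown`: `l_cls`, `l_loc`, `l1_reg`, `mu`, `total`.
#' @export
compute_loss <- function(predictions, targets, mu = 0.11, weights = NULL) {
  n <- if (is.null(predictions$class_probs)) 0L else nrow(predictions$class_probs)
  l_cls <- 0; l_loc <- 0
  if (n > 0L) {
    p <- predictions$class_probs[cbind(seq_len(n), targets$labels)]
    l_cls <- mean(-log(pmax(p, 1e-12)))
    pos <- which(targets$positive)
    if (length(pos) > 0L) {
      d <- predictions$box_deltas[pos, , drop = FALSE] -
        targets$box_deltas[pos, , drop = FALSE]
      a <- abs(d)
      l_loc <- sum(ifelse(a < 1, 0.5 * d^2, a - 0.5)) / (4 * length(pos))
    }
  }
  l1 <- if (is.null(weights)) 0 else mean(abs(unlist(weights)))
  loss_breakdown(l_cls, l_loc, l1, mu)
}

loss_breakdown <- function(l_cls, l_loc, l1_reg, mu) {
  structure(list(l_cls = l_cls, l_loc = l_loc, l1_reg = l1_reg, mu = mu,
                 total = l_cls + l_loc + mu * l1_reg),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("loss: total=%.4f (cls=%.4f, loc=%.4f, mu*l1=%.4f)\n",
              x$total, x$l_cls, x$l_loc, x$mu * x$l1_reg))
  invisible(x)
}

sample_balanced <- function(pos_idx, neg_idx, n_pos_max, n_total) {
  pos <- if (length(pos_idx) > n_pos_max)
    sample(pos_idx, n_pos_max) else pos_idx
  n_neg <- min(length(neg_idx), n_total - length(pos))
  neg <- if (length(neg_idx) > n_neg) sample(neg_idx, n_neg) else neg_idx
  list(pos = pos, neg = neg)
}

# One full forward + loss on a single image; returns the scalar total-loss
# node plus the numeric breakdown.  gt_boxes: [n, 4] xyxy matrix.
detector_loss_ad <- function(det, cx, tape, image, gt_boxes, code) {
  cfg <- det$cfg
  H <- nrow(image); W <- ncol(image)
  fused <- detector_trunk_ad(det, cx, tape, image, code)
  rpn_out <- rpn_ad(det, cx, tape, fused)

  # --- RPN targets over all levels
  cls_nodes <- list(); box_nodes <- list()
  cls_labels <- numeric(0); box_targets <- NULL
  for (li in seq_along(rpn_out)) {
    cls <- rpn_out[[li]]$cls
    dcls <- dim(ad_val(cls))
    A <- dcls[1]
    anchors <- level_anchors(det$cfg, det$strides[li], dcls[2], dcls[3])
    inside <- anchors[, 1] >= -8 & anchors[, 2] >= -8 &
      anchors[, 3] <= W + 8 & anchors[, 4] <= H + 8
    M <- box_iou_matrix(anchors, gt_boxes)
    max_iou <- if (ncol(M) > 0L) apply(M, 1, max) else numeric(nrow(anchors))
    label <- rep(NA, nrow(anchors))            # NA = ignored
    label[max_iou < 0.3] <- 0
    label[max_iou >= 0.7] <- 1
    if (ncol(M) > 0L) {
      for (g in seq_len(ncol(M))) {
        cand <- which(M[, g] == max(M[, g]) & M[, g] > 0)
        label[cand] <- 1
      }
    }
    label[!inside] <- NA
    smp <- sample_balanced(which(label == 1), which(label == 0), 16L, 48L)
    sel <- c(smp$pos, smp$neg)
    if (length(sel) > 0L) {
      cls_nodes[[length(cls_nodes) + 1L]] <- ad_select(tape, cls, sel)
      cls_labels <- c(cls_labels, label[sel])
    }
    if (length(smp$pos) > 0L && ncol(M) > 0L) {
      gt_match <- apply(M[smp$pos, , drop = FALSE], 1, which.max)
      tgt <- encode_deltas(gt_boxes[gt_match, , drop = FALSE],
                           anchors[smp$pos, , drop = FALSE])
      # box output channels are (4, A) per cell: anchor a occupies 4(a-1)+1..4a
      cell <- (smp$pos - 1L) %/% A
      a_i <- (smp$pos - 1L) %% A
      idx4 <- as.vector(vapply(seq_along(smp$pos), function(k)
        4L * A * cell[k] + 4L * a_i[k] + 1:4, integer(4)))
      box_nodes[[length(box_nodes) + 1L]] <- ad_select(tape, rpn_out[[li]]$box, idx4)
      box_targets <- rbind(box_targets, tgt)
    }
  }
  rpn_cls <- ad_sigmoid_ce(tape, ad_cat(tape, cls_nodes), cls_labels)
  rpn_loc <- if (length(box_nodes) > 0L) {
    tgt <- as.numeric(t(box_targets))
    ad_smooth_l1(tape, ad_cat(tape, box_nodes), tgt, norm = length(tgt))
  } else ad_const(tape, 0)

  # --- proposals + head targets
  props <- rpn_proposals(det, rpn_out, H, W)
  boxes <- rbind(props$boxes, gt_boxes)       # append ground truth at train time
  M <- box_iou_matrix(boxes, gt_boxes)
  max_iou <- if (ncol(M) > 0L) apply(M, 1, max) else numeric(nrow(boxes))
  fg <- which(max_iou >= 0.5)
  bg <- which(max_iou < 0.5)
  smp <- sample_balanced(fg, bg, 16L, 48L)
  sel <- c(smp$pos, smp$neg)
  head_cls <- ad_const(tape, 0); head_loc <- ad_const(tape, 0)
  if (length(sel) > 0L) {
    hb <- boxes[sel, , drop = FALSE]
    out <- head_ad(det, cx, tape, fused, hb)
    # head_ad groups RoIs by pyramid level; permute the labels identically
    labels <- c(rep(2L, length(smp$pos)), rep(1L, length(smp$neg)))[out$order]
    head_cls <- ad_softmax_ce(tape, out$cls, labels)
    fg_pos <- which(labels == 2L)
    if (length(fg_pos) > 0L) {
      orig <- sel[out$order][fg_pos]
      gt_match <- apply(M[orig, , drop = FALSE], 1, which.max)
      tgt <- encode_deltas(gt_boxes[gt_match, , drop = FALSE],
                           boxes[orig, , drop = FALSE])
      idx4 <- as.vector(vapply(fg_pos, function(k)
        (k - 1L) * 4L + 1:4, integer(4)))
      head_loc <- ad_smooth_l1(tape, ad_select(tape, out$box, idx4),
                               as.numeric(t(tgt)), norm = 4L * length(fg_pos))
    }
  }

  # --- L1 regularization over the active neck (or all) weights
  pfx <- if (cfg$l1_scope == "neck") "neck" else ""
  reg_names <- ls(cx$nodes)
  reg_names <- reg_names[startsWith(reg_names, pfx)]
  l1 <- if (length(reg_names) > 0L)
    ad_l1_penalty(tape, lapply(reg_names, function(n) cx$nodes[[n]]))
  else ad_const(tape, 0)

  l_cls <- ad_add(tape, rpn_cls, head_cls)
  l_loc <- ad_add(tape, rpn_loc, head_loc)
  total <- ad_add(tape, l_cls, l_loc, ad_scale(tape, l1, cfg$mu))
  list(total = total,
       breakdown = loss_breakdown(ad_val(l_cls), ad_val(l_loc),
                                  ad_val(l1), cfg$mu))
}

#' One supernet training step
#'
#' Samples one subnet uniformly (single-path one-shot), runs the full
#' detector forward/backward through that subnet's parameters only, and
#' updates the shared weights by SGD.  Parameters of edges outside the
#' sampled code are untouched.
#'
#' @param det a detector built with `code = "supernet"`.
#' @param batch list of `list(image, boxes)` items (`boxes` xyxy matrix or
#'   data frame).
#' @param lr,momentum SGD parameters (default from the config).
#' @return the numeric `loss_breakdown` of the step, with the sampled code
#'   attached as attribute `"code"`.
#' @export
train_supernet_step <- function(det, batch, lr = det$cfg$lr,
                                momentum = det$cfg$momentum) {
  if (length(batch) == 0L) stop("empty batch")
  code <- sample_subnet(det$neck)
  bd <- sgd_step(det, batch, code, lr, momentum)
  attr(bd, "code") <- code
  bd
}

to_xyxy_matrix <- function(boxes) {
  if (is.matrix(boxes)) {
    stopifnot(ncol(boxes) == 4L)
    return(boxes)
  }
  boxes_matrix(as.data.frame(boxes))
}

sgd_step <- function(det, batch, code, lr, momentum) {
  grads <- list()
  tot <- list(l_cls = 0, l_loc = 0, l1_reg = 0)
  for (item in batch) {
    tape <- ad_tape()
    cx <- ad_ctx(det$ps, tape)
    gtb <- to_xyxy_matrix(item$boxes)
    r <- detector_loss_ad(det, cx, tape, item$image, gtb, code)
    ad_backward(tape, r$total)
    g <- ctx_grads(cx)
    for (n in names(g)) {
      grads[[n]] <- if (is.null(grads[[n]])) g[[n]] / length(batch)
        else grads[[n]] + g[[n]] / length(batch)
    }
    for (f in names(tot)) tot[[f]] <- tot[[f]] + r$breakdown[[f]] / length(batch)
  }
  ps_sgd_step(det$ps, grads, lr, momentum)
  loss_breakdown(tot$l_cls, tot$l_loc, tot$l1_reg, det$cfg$mu)
}

#' Train a detector by stochastic gradient descent
#'
#' Mini-batch SGD with momentum; optional flip/crop augmentation drawn per
#' image per step.  In supernet mode (`code = NULL` in the detector) a new
#' subnet is sampled uniformly at every step.  Fully reproducible under
#' `seed` (single-threaded).
#'
#' @param det a detector.
#' @param train_set list of `list(image, boxes)` items (corner-format
#'   boxes).
#' @param steps number of SGD steps; the default runs
#'   `epochs * ceiling(n / batch_size)` as configured.
#' @param lr,batch_size,momentum SGD parameters (default from config).
#' @param augment_data apply random flip / crop augmentation.
#' @param seed reproducibility seed.
#' @param verbose print progress every 50 steps.
#' @return the detector, with `$loss_curve` (one row per step: `step,
#'   l_cls, l_loc, l1_reg, total`) attached.
#' @export
train <- function(det, train_set, steps = NULL, lr = det$cfg$lr,
                  batch_size = det$cfg$batch_size,
                  momentum = det$cfg$momentum, augment_data = TRUE,
                  seed = 1L, verbose = FALSE) {
  if (length(train_set) == 0L) stop("empty training set")
  set.seed(seed)
  if (is.null(steps))
    steps <- det$cfg$epochs * ceiling(length(train_set) / batch_size)
  curve <- data.frame()
  for (step in seq_len(steps)) {
    idx <- sample.int(length(train_set), min(batch_size, length(train_set)))
    batch <- lapply(train_set[idx], function(item) {
      boxes <- as.data.frame(item$boxes)
      if (augment_data) {
        a <- augment(item$image, boxes)
        img <- pad_to_multiple(a$image, 32L)
        list(image = img, boxes = a$boxes)
      } else {
        list(image = item$image, boxes = boxes)
      }
    })
    code <- if (is.null(det$code)) sample_subnet(det$neck) else det$code
    bd <- sgd_step(det, batch, code, lr, momentum)
    curve <- rbind(curve, data.frame(step = step, l_cls = bd$l_cls,
                                     l_loc = bd$l_loc, l1_reg = bd$l1_reg,
                                     total = bd$total))
    if (verbose && step %% 50L == 0L)
      message(sprintf("step %d: total=%.4f", step, bd$total))
  }
  det$loss_curve <- curve
  det
}

pad_to_multiple <- function(image, m) {
  H <- nrow(image); W <- ncol(image)
  H2 <- as.integer(ceiling(H / m) * m); W2 <- as.integer(ceiling(W / m) * m)
  if (H2 == H && W2 == W) return(image)
  out <- matrix(stats::median(image), H2, W2)
  out[seq_len(H), seq_len(W)] <- image
  out
}

#' Run inference on one image
#'
#' Forward pass, RPN proposals, head classification and box refinement;
#' boxes are clipped to the image, thresholded on the foreground score,
#' and reduced by non-maximum suppression.
#'
#' @param det a trained detector.
#' @param image matrix `[H, W]` with values in `[0, 1]` (sides divisible
#'   by 32).
#' @param score_threshold minimum foreground score.
#' @param nms_iou suppression threshold (default 0.5).
#' @param code subnet code override (defaults to the detector's fixed
#'   code; required in supernet mode).
#' @return data frame `x_min, y_min, x_max, y_max, score, label`, sorted
#'   by descending score.
#' @export
infer <- function(det, image, score_threshold = 0.05, nms_iou = 0.5,
                  code = NULL) {
  if (is.null(code)) code <- det$code
  if (is.null(code)) stop("supernet-mode detector requires an explicit code")
  H <- nrow(image); W <- ncol(image)
  tape <- ad_tape()
  cx <- ad_ctx(det$ps, tape)
  fused <- detector_trunk_ad(det, cx, tape, image, code)
  rpn_out <- rpn_ad(det, cx, tape, fused)
  props <- rpn_proposals(det, rpn_out, H, W)
  empty <- data.frame(x_min = numeric(0), y_min = numeric(0),
                      x_max = numeric(0), y_max = numeric(0),
                      score = numeric(0), label = integer(0))
  if (nrow(props$boxes) == 0L) return(empty)
  out <- head_ad(det, cx, tape, fused, props$boxes)
  logits <- ad_val(out$cls)
  z <- exp(sweep(logits, 2, apply(logits, 2, max)))
  probs <- sweep(z, 2, colSums(z), "/")
  fg <- probs[2, ]
  deltas <- t(ad_val(out$box))
  boxes <- decode_deltas(deltas, props$boxes[out$order, , drop = FALSE])
  boxes <- clip_boxes(boxes, H, W)
  ok <- fg >= score_threshold & (boxes[, 3] - boxes[, 1]) > 0 &
    (boxes[, 4] - boxes[, 2]) > 0
  if (!any(ok)) return(empty)
  boxes <- boxes[ok, , drop = FALSE]; fg <- fg[ok]
  k <- nms(boxes, fg, nms_iou)
  data.frame(x_min = boxes[k, 1], y_min = boxes[k, 2],
             x_max = boxes[k, 3], y_max = boxes[k, 4],
             score = fg[k], label = 1L)
}

# ---- checkpoints ----------------------------------------------------------

#' Save / load a detector checkpoint
#'
#' Single-file checkpoint with a versioned header: configuration, subnet
#' code and every parameter array.
#'
#' @param det a detector.
#' @param path file path.
#' @export
save_checkpoint <- function(det, path) {
  params <- setNames(lapply(ps_names(det$ps), ps_get, ps = det$ps),
                     ps_names(det$ps))
  saveRDS(list(format = "deformnas-checkpoint", version = 1L,
               cfg = det$cfg, code = det$code, params = params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "deformnas-checkpoint"))
    stop("not a detector checkpoint")
  det <- build_detector(ck$cfg, code = if (is.null(ck$code)) "supernet" else ck$code)
  for (n in names(ck$params)) ps_add(det$ps, n, ck$params[[n]])
  det
}
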