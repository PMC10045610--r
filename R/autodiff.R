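# Minimal tape-based reverse-mode differentiation engine.
#
# Nodes are environments holding a value, a lazily allocated gradient, and a
# backward closure; they are appended to a tape (an environment with a
# growing list) in creation order, so reverse iteration is a valid reverse
# topological order.  Parameters live in a parameter store (name -> array)
# and are wrapped once per forward pass, so gradients from repeated use
# accumulate on a single node.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ad_node <- function(tape, val, parents = list(), bwd = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$bwd <- bwd
  if (!is.null(tape)) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes))
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    tape$nodes[[tape$n]] <- nd
  }
  nd
}

is_ad_node <- function(x) is.environment(x) && !is.null(x$val)

ad_const <- function(tape, val) ad_node(tape, val)

ad_val <- function(x) if (is_ad_node(x)) x$val else x

ad_accum <- function(nd, g) {
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(nd)
}

# Run backward from a scalar node (seed gradient 1).
ad_backward <- function(tape, loss) {
  stopifnot(length(ad_val(loss)) == 1L)
  loss$grad <- 1
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$bwd)) nd$bwd(nd)
  }
  invisible(NULL)
}

# ---- parameter store ------------------------------------------------------

param_store <- function() {
  ps <- new.env(parent = emptyenv())
  ps$val <- new.env(parent = emptyenv())
  ps$mom <- new.env(parent = emptyenv())
  ps
}

ps_add <- function(ps, name, value) {
  assign(name, value, envir = ps$val)
  invisible(ps)
}

ps_get <- function(ps, name) get(name, envir = ps$val)

ps_names <- function(ps) ls(ps$val, sorted = TRUE)

ps_n_params <- function(ps, prefix = "") {
  nms <- ps_names(ps)
  if (nzchar(prefix)) nms <- nms[startsWith(nms, prefix)]
  sum(vapply(nms, function(n) length(ps_get(ps, n)), 1))
}

# Forward-pass context: one node per parameter name.
ad_ctx <- function(ps, tape) {
  cx <- new.env(parent = emptyenv())
  cx$ps <- ps
  cx$tape <- tape
  cx$nodes <- new.env(parent = emptyenv())
  cx
}

ad_param <- function(cx, name) {
  if (!is.null(cx$nodes[[name]])) return(cx$nodes[[name]])
  nd <- ad_node(cx$tape, ps_get(cx$ps, name))
  nd$param_name <- name
  cx$nodes[[name]] <- nd
  nd
}

# Collect gradients accumulated in a context, as name -> array.
ctx_grads <- function(cx) {
  nms <- ls(cx$nodes)
  out <- list()
  for (n in nms) {
    g <- cx$nodes[[n]]$grad
    if (!is.null(g)) out[[n]] <- g
  }
  out
}

# SGD with momentum applied only to parameters that received gradients.
ps_sgd_step <- function(ps, grads, lr, momentum = 0.9) {
  for (n in names(grads)) {
    v <- ps$mom[[n]]
    if (is.null(v)) v <- 0
    v <- momentum * v - lr * grads[[n]]
    ps$mom[[n]] <- v
    assign(n, ps_get(ps, n) + v, envir = ps$val)
  }
  invisible(ps)
}

# ---- primitive operations -------------------------------------------------

ad_conv2d <- function(tape, x, w, b) {
  xv <- ad_val(x); wv <- ad_val(w); bv <- ad_val(b)
  yv <- cpp_conv2d_fwd(xv, dim(xv), wv, dim(wv), bv)
  ad_node(tape, yv, parents = list(x, w, b), bwd = function(nd) {
    r <- cpp_conv2d_bwd(xv, dim(xv), wv, dim(wv), nd$grad)
    ad_accum(nd$parents[[1]], r$gx)
    ad_accum(nd$parents[[2]], r$gw)
    ad_accum(nd$parents[[3]], r$gb)
  })
}

# Deformable 3x3 (or any odd) convolution; `off` is a node [2K, H, W].
ad_deform_conv <- function(tape, x, w, b, off, taps) {
  xv <- ad_val(x); wv <- ad_val(w); bv <- ad_val(b); offv <- ad_val(off)
  C <- dim(xv)[1]; H <- dim(xv)[2]; W <- dim(xv)[3]
  O <- dim(wv)[1]; K <- nrow(taps)
  pos <- dconv_positions(H, W, taps, offv)
  S <- cpp_bl_gather_fwd(xv, dim(xv), pos$pr, pos$pc)
  dim(S) <- c(C * K, H * W)
  Wm <- matrix(wv, nrow = O)
  yv <- array(Wm %*% S + bv, dim = c(O, H, W))
  ad_node(tape, yv, parents = list(x, w, b, off), bwd = function(nd) {
    gy <- matrix(nd$grad, nrow = O)
    gS <- crossprod(Wm, gy)               # [C*K, H*W]
    gW <- tcrossprod(gy, S)               # [O, C*K]
    dim(gS) <- c(C, K * H * W)
    r <- cpp_bl_gather_bwd(xv, dim(xv), pos$pr, pos$pc, gS)
    goff <- array(0, dim = c(2L * K, H * W))
    goff[seq(1L, 2L * K, 2L), ] <- matrix(r$gpr, nrow = K)
    goff[seq(2L, 2L * K, 2L), ] <- matrix(r$gpc, nrow = K)
    ad_accum(nd$parents[[1]], r$gx)
    ad_accum(nd$parents[[2]], array(gW, dim = dim(wv)))
    ad_accum(nd$parents[[3]], rowSums(gy))
    ad_accum(nd$parents[[4]], array(goff, dim = dim(offv)))
  })
}

ad_relu <- function(tape, x) {
  xv <- ad_val(x)
  ad_node(tape, pmax(xv, 0), parents = list(x), bwd = function(nd) {
    ad_accum(nd$parents[[1]], nd$grad * (xv > 0))
  })
}

ad_add <- function(tape, ...) {
  xs <- list(...)
  yv <- Reduce(`+`, lapply(xs, ad_val))
  ad_node(tape, yv, parents = xs, bwd = function(nd) {
    for (p in nd$parents) ad_accum(p, nd$grad)
  })
}

ad_scale <- function(tape, x, a) {
  xv <- ad_val(x)
  ad_node(tape, a * xv, parents = list(x), bwd = function(nd) {
    ad_accum(nd$parents[[1]], a * nd$grad)
  })
}

ad_maxpool2 <- function(tape, x) {
  xv <- ad_val(x)
  r <- cpp_maxpool2_fwd(xv, dim(xv))
  ad_node(tape, r$y, parents = list(x), bwd = function(nd) {
    ad_accum(nd$parents[[1]], cpp_maxpool2_bwd(r$amax, nd$grad, dim(xv)))
  })
}

# Nearest-neighbour 2x upsampling.
ad_upnn2 <- function(tape, x) {
  xv <- ad_val(x)
  H <- dim(xv)[2]; W <- dim(xv)[3]
  yv <- xv[, rep(seq_len(H), each = 2L), rep(seq_len(W), each = 2L), drop = FALSE]
  ad_node(tape, yv, parents = list(x), bwd = function(nd) {
    g <- nd$grad
    gh <- g[, seq(1L, 2L * H, 2L), , drop = FALSE] + g[, seq(2L, 2L * H, 2L), , drop = FALSE]
    gx <- gh[, , seq(1L, 2L * W, 2L), drop = FALSE] + gh[, , seq(2L, 2L * W, 2L), drop = FALSE]
    ad_accum(nd$parents[[1]], gx)
  })
}

# Keep every second row/col (stride-2 subsampling, used for strided convs).
ad_subsample2 <- function(tape, x) {
  xv <- ad_val(x)
  H <- dim(xv)[2]; W <- dim(xv)[3]
  ri <- seq(1L, H, 2L); ci <- seq(1L, W, 2L)
  yv <- xv[, ri, ci, drop = FALSE]
  ad_node(tape, yv, parents = list(x), bwd = function(nd) {
    gx <- array(0, dim = dim(xv))
    gx[, ri, ci] <- nd$grad
    ad_accum(nd$parents[[1]], gx)
  })
}

ad_concat_ch <- function(tape, a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  Ca <- dim(av)[1]; Cb <- dim(bv)[1]
  yv <- array(0, dim = c(Ca + Cb, dim(av)[2], dim(av)[3]))
  yv[seq_len(Ca), , ] <- av
  yv[Ca + seq_len(Cb), , ] <- bv
  ad_node(tape, yv, parents = list(a, b), bwd = function(nd) {
    ad_accum(nd$parents[[1]], nd$grad[seq_len(Ca), , , drop = FALSE])
    ad_accum(nd$parents[[2]], nd$grad[Ca + seq_len(Cb), , , drop = FALSE])
  })
}

ad_reshape <- function(tape, x, new_dim) {
  xv <- ad_val(x)
  yv <- xv
  dim(yv) <- new_dim
  ad_node(tape, yv, parents = list(x), bwd = function(nd) {
    g <- nd$grad
    dim(g) <- dim(xv)
    ad_accum(nd$parents[[1]], g)
  })
}

# Select elements by (1-based) linear index.
ad_select <- function(tape, x, idx) {
  xv <- ad_val(x)
  ad_node(tape, as.numeric(xv[idx]), parents = list(x), bwd = function(nd) {
    gx <- array(0, dim = if (is.null(dim(xv))) length(xv) else dim(xv))
    for (k in seq_along(idx)) gx[idx[k]] <- gx[idx[k]] + nd$grad[k]
    ad_accum(nd$parents[[1]], gx)
  })
}

# Fully connected layer on a [d_in, n] matrix: y = W x + b.
ad_fc <- function(tape, x, w, b) {
  xv <- ad_val(x); wv <- ad_val(w); bv <- ad_val(b)
  xdim <- dim(xv)
  if (is.null(xdim)) {
    xdim <- length(xv)
    xv <- matrix(xv, ncol = 1L)
  }
  yv <- wv %*% xv + bv
  ad_node(tape, yv, parents = list(x, w, b), bwd = function(nd) {
    g <- nd$grad
    if (is.null(dim(g))) g <- matrix(g, ncol = ncol(xv))
    gx <- crossprod(wv, g)
    dim(gx) <- xdim
    ad_accum(nd$parents[[1]], gx)
    ad_accum(nd$parents[[2]], tcrossprod(g, xv))
    ad_accum(nd$parents[[3]], rowSums(g))
  })
}

# Mean binary cross-entropy on logits with labels in {0, 1}.
ad_sigmoid_ce <- function(tape, logits, labels) {
  lv <- ad_val(logits)
  n <- length(lv)
  p <- 1 / (1 + exp(-lv))
  # log(1 + exp(-|z|)) formulation for numerical stability
  loss <- mean(pmax(lv, 0) - lv * labels + log1p(exp(-abs(lv))))
  ad_node(tape, loss, parents = list(logits), bwd = function(nd) {
    ad_accum(nd$parents[[1]], nd$grad * (p - labels) / n)
  })
}

# Mean softmax cross-entropy; logits is [n_classes, n], labels in 1..n_classes.
ad_softmax_ce <- function(tape, logits, labels) {
  lv <- ad_val(logits)
  n <- ncol(lv)
  m <- apply(lv, 2, max)
  z <- exp(sweep(lv, 2, m))
  p <- sweep(z, 2, colSums(z), "/")
  picked <- p[cbind(labels, seq_len(n))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  ad_node(tape, loss, parents = list(logits), bwd = function(nd) {
    g <- p
    g[cbind(labels, seq_len(n))] <- g[cbind(labels, seq_len(n))] - 1
    ad_accum(nd$parents[[1]], nd$grad * g / n)
  })
}

# Smooth L1 (Huber, delta = 1): sum over elements / norm.
ad_smooth_l1 <- function(tape, pred, target, norm = length(ad_val(pred))) {
  pv <- ad_val(pred)
  d <- pv - target
  a <- abs(d)
  loss <- sum(ifelse(a < 1, 0.5 * d^2, a - 0.5)) / norm
  ad_node(tape, loss, parents = list(pred), bwd = function(nd) {
    g <- ifelse(a < 1, d, sign(d)) / norm
    ad_accum(nd$parents[[1]], nd$grad * g)
  })
}

# Deformable RoI pooling over a batch of RoIs on one map.
# rois: matrix [n, 4] (x_min, y_min, x_max, y_max) in cell coordinates.
# off: NULL or node with value [2, bins_h, bins_w, n].
# Returns node [C, bins_h, bins_w, n].
ad_droi_pool <- function(tape, x, rois, bins_h, bins_w, off = NULL) {
  xv <- ad_val(x)
  offv <- if (is.null(off)) NULL else ad_val(off)
  C <- dim(xv)[1]
  n <- nrow(rois)
  nb <- bins_h * bins_w
  pooled <- array(0, dim = c(C, bins_h, bins_w, n))
  meta <- vector("list", n)
  for (r in seq_len(n)) {
    bo <- if (is.null(offv)) NULL else array(offv[, , , r], dim = c(2L, bins_h, bins_w))
    rr <- roi_pool_core(xv, rois[r, ], bins_h, bins_w, bin_off = bo)
    pooled[, , , r] <- rr$pooled
    meta[[r]] <- rr
  }
  parents <- if (is.null(off)) list(x) else list(x, off)
  ad_node(tape, pooled, parents = parents, bwd = function(nd) {
    gx <- array(0, dim = dim(xv))
    goff <- if (is.null(offv)) NULL else array(0, dim = dim(offv))
    for (r in seq_len(n)) {
      rr <- meta[[r]]
      gp <- matrix(nd$grad[, , , r], nrow = C)          # [C, nb]
      cnt <- as.numeric(rr$samples$counts)
      gsamp <- gp[, rr$samples$bin, drop = FALSE] /
        rep(cnt[rr$samples$bin], each = C)
      bl <- cpp_bl_gather_bwd(xv, dim(xv), rr$pr, rr$pc, gsamp)
      gx <- gx + bl$gx
      if (!is.null(goff)) {
        gr <- rowsum(bl$gpr, rr$samples$bin)
        gc <- rowsum(bl$gpc, rr$samples$bin)
        bidx <- as.integer(rownames(gr))
        go <- array(0, dim = c(2L, nb))
        go[1, bidx] <- gr
        go[2, bidx] <- gc
        goff[, , , r] <- array(go, dim = c(2L, bins_h, bins_w))
      }
    }
    ad_accum(nd$parents[[1]], gx)
    if (!is.null(goff)) ad_accum(nd$parents[[2]], goff)
  })
}

# Concatenate vector-valued nodes.
ad_cat <- function(tape, nodes) {
  lens <- vapply(nodes, function(nd) length(ad_val(nd)), 1L)
  yv <- unlist(lapply(nodes, function(nd) as.numeric(ad_val(nd))))
  ends <- cumsum(lens)
  starts <- c(1L, head(ends, -1L) + 1L)
  ad_node(tape, yv, parents = nodes, bwd = function(nd) {
    for (k in seq_along(nd$parents))
      ad_accum(nd$parents[[k]], nd$grad[starts[k]:ends[k]])
  })
}

# Mean absolute value of a set of parameter nodes (L1 regularizer).
ad_l1_penalty <- function(tape, nodes) {
  ntot <- sum(vapply(nodes, function(nd) length(ad_val(nd)), 1))
  loss <- sum(vapply(nodes, function(nd) sum(abs(ad_val(nd))), 1)) / ntot
  ad_node(tape, loss, parents = nodes, bwd = function(nd) {
    for (p in nd$parents) ad_accum(p, nd$grad * sign(ad_val(p)) / ntot)
  })
}
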