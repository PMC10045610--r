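#' The six information paths of the aggregation neck
#'
#' A path maps a 4-level feature pyramid to a 4-level feature pyramid of the
#' same shape.  Four paths carry parameters (top-down, bottom-up,
#' scale-balanced, two-step fuse-split) and two are parameter-free (null,
#' which contributes the additive identity, and skip, the identity mapping).
#'
#' @format `PATH_KINDS` is the character vector of the six kind labels.
#' @export
PATH_KINDS <- c("TOP_DOWN", "BOTTOM_UP", "SCALE_BALANCED", "FUSE_SPLIT",
                "NULL", "SKIP")

#' @rdname PATH_KINDS
#' @format `PARAM_PATH_KINDS` is the subset of `PATH_KINDS` that carries
#'   parameters.
#' @export
PARAM_PATH_KINDS <- PATH_KINDS[1:4]

pname <- function(prefix, local) {
  if (nzchar(prefix)) paste0(prefix, ".", local) else local
}

he_kernel <- function(out_ch, in_ch, kh = 3L, kw = 3L) {
  array(rnorm(out_ch * in_ch * kh * kw, sd = sqrt(2 / (in_ch * kh * kw))),
        dim = c(out_ch, in_ch, kh, kw))
}

# Register one conv (plus, optionally, its zero-initialized offset
# predictor) under `prefix` in a parameter store.
init_conv_params <- function(ps, prefix, out_ch, in_ch, deformable) {
  ps_add(ps, pname(prefix, "w"), he_kernel(out_ch, in_ch))
  ps_add(ps, pname(prefix, "b"), numeric(out_ch))
  if (deformable) {
    ps_add(ps, pname(prefix, "ow"), array(0, dim = c(18L, in_ch, 3L, 3L)))
    ps_add(ps, pname(prefix, "ob"), numeric(18L))
  }
  invisible(ps)
}

# Register all parameters of one path instance.  Levels 3..5 use deformable
# convolutions, level 2 a regular one; the scale-balanced path shares its
# three convs across levels and applies deformable sampling when the operand
# level is >= 3 (the kernel is shared, the offsets come from the shared
# per-conv predictor).
init_path_params <- function(ps, prefix, kind, channels) {
  C <- channels
  switch(kind,
    TOP_DOWN = ,
    BOTTOM_UP = {
      for (i in 2:5)
        init_conv_params(ps, pname(prefix, paste0("l", i)), C, C, deformable = i >= 3)
    },
    SCALE_BALANCED = {
      for (nm in c("w1", "w0", "wm1"))
        init_conv_params(ps, pname(prefix, nm), C, C, deformable = TRUE)
    },
    FUSE_SPLIT = {
      init_conv_params(ps, pname(prefix, "ws"), C, 2L * C, deformable = TRUE)
      init_conv_params(ps, pname(prefix, "wl"), C, 2L * C, deformable = TRUE)
    },
    stop("kind carries no parameters: ", kind)
  )
  invisible(ps)
}

#' Closed-form parameter count of one information path
#'
#' @param kind one of `PATH_KINDS`.
#' @param channels shared pyramid channel width.
#' @return integer number of scalar parameters (kernels, biases and offset
#'   predictors); 0 for the parameter-free kinds.
#' @export
path_param_count <- function(kind, channels) {
  C <- channels
  conv <- 9 * C * C + C          # C -> C 3x3 kernel + bias
  offp <- 9 * 18 * C + 18        # offset predictor on a C-channel operand
  conv2 <- 9 * C * 2 * C + C     # 2C -> C fusion conv
  offp2 <- 9 * 18 * 2 * C + 18
  switch(kind,
    TOP_DOWN = ,
    BOTTOM_UP = 4 * conv + 3 * offp,
    SCALE_BALANCED = 3 * (conv + offp),
    FUSE_SPLIT = 2 * (conv2 + offp2),
    `NULL` = ,
    SKIP = 0,
    stop("unknown path kind: ", kind)
  )
}

# ---- differentiable path builders ----------------------------------------
# These operate on lists of 4 tape nodes named "2".."5" and are shared by
# the user-facing numeric functions and by detector training.

path_conv_ad <- function(cx, tape, x, prefix, deformable) {
  w <- ad_param(cx, pname(prefix, "w"))
  b <- ad_param(cx, pname(prefix, "b"))
  if (deformable) {
    ow <- ad_param(cx, pname(prefix, "ow"))
    ob <- ad_param(cx, pname(prefix, "ob"))
    off <- ad_conv2d(tape, x, ow, ob)
    ad_deform_conv(tape, x, w, b, off, sampling_grid(3L))
  } else {
    ad_conv2d(tape, x, w, b)
  }
}

top_down_ad <- function(cx, tape, pyr, prefix) {
  out <- list()
  out[["5"]] <- path_conv_ad(cx, tape, pyr[["5"]], pname(prefix, "l5"), TRUE)
  for (i in 4:2) {
    s <- ad_add(tape, ad_upnn2(tape, out[[as.character(i + 1)]]), pyr[[as.character(i)]])
    out[[as.character(i)]] <-
      path_conv_ad(cx, tape, s, pname(prefix, paste0("l", i)), deformable = i >= 3)
  }
  out[as.character(2:5)]
}

bottom_up_ad <- function(cx, tape, pyr, prefix) {
  out <- list()
  out[["2"]] <- path_conv_ad(cx, tape, pyr[["2"]], pname(prefix, "l2"), FALSE)
  for (i in 3:5) {
    s <- ad_add(tape, ad_maxpool2(tape, out[[as.character(i - 1)]]), pyr[[as.character(i)]])
    out[[as.character(i)]] <-
      path_conv_ad(cx, tape, s, pname(prefix, paste0("l", i)), deformable = TRUE)
  }
  out
}

scale_balanced_ad <- function(cx, tape, pyr, prefix) {
  out <- list()
  for (i in 2:5) {
    terms <- list()
    if (i < 5) {
      a <- path_conv_ad(cx, tape, pyr[[as.character(i + 1)]], pname(prefix, "w1"),
                        deformable = (i + 1) >= 3)
      terms <- c(terms, list(ad_upnn2(tape, a)))
    }
    terms <- c(terms, list(path_conv_ad(cx, tape, pyr[[as.character(i)]],
                                        pname(prefix, "w0"), deformable = i >= 3)))
    if (i > 2) {
      bl <- path_conv_ad(cx, tape, pyr[[as.character(i - 1)]], pname(prefix, "wm1"),
                         deformable = (i - 1) >= 3)
      terms <- c(terms, list(ad_maxpool2(tape, bl)))
    }
    out[[as.character(i)]] <- do.call(ad_add, c(list(tape), terms))
  }
  out
}

fuse_split_ad <- function(cx, tape, pyr, prefix) {
  alpha_s <- ad_add(tape, pyr[["4"]], ad_upnn2(tape, pyr[["5"]]))
  alpha_l <- ad_add(tape, ad_maxpool2(tape, pyr[["2"]]), pyr[["3"]])
  beta_s <- path_conv_ad(cx, tape,
                         ad_concat_ch(tape, alpha_s, ad_maxpool2(tape, alpha_l)),
                         pname(prefix, "ws"), TRUE)
  beta_l <- path_conv_ad(cx, tape,
                         ad_concat_ch(tape, ad_upnn2(tape, alpha_s), alpha_l),
                         pname(prefix, "wl"), TRUE)
  list(`2` = ad_upnn2(tape, beta_l), `3` = beta_l,
       `4` = beta_s, `5` = ad_maxpool2(tape, beta_s))
}

apply_path_ad <- function(cx, tape, kind, pyr, prefix) {
  switch(kind,
    TOP_DOWN = top_down_ad(cx, tape, pyr, prefix),
    BOTTOM_UP = bottom_up_ad(cx, tape, pyr, prefix),
    SCALE_BALANCED = scale_balanced_ad(cx, tape, pyr, prefix),
    FUSE_SPLIT = fuse_split_ad(cx, tape, pyr, prefix),
    `NULL` = lapply(pyr, function(nd) ad_const(tape, array(0, dim = dim(ad_val(nd))))),
    SKIP = pyr,
    stop("unknown path kind: ", kind)
  )
}

# ---- user-facing numeric surface -----------------------------------------

#' Create the parameters of one information path
#'
#' Kernels get He-scaled normal initialization; biases and all deformable
#' offset predictors start at zero, so a freshly initialized path behaves
#' like its plain-convolution twin.
#'
#' @param kind one of the parameterized `PATH_KINDS`.
#' @param channels pyramid channel width.
#' @param seed optional integer seed for the kernel initialization.
#' @return a `path_params` object (the parameters live in an internal store
#'   and can be inspected with `path_param_names()` / `path_param_get()`).
#' @export
make_path_params <- function(kind, channels, seed = NULL) {
  kind <- match.arg(kind, PARAM_PATH_KINDS)
  if (!is.null(seed)) set.seed(seed)
  ps <- param_store()
  init_path_params(ps, "", kind, channels)
  structure(list(kind = kind, channels = as.integer(channels), ps = ps),
            class = "path_params")
}

#' @rdname make_path_params
#' @param params a `path_params` object.
#' @export
path_param_names <- function(params) ps_names(params$ps)

#' @rdname make_path_params
#' @param name parameter name (see `path_param_names`).
#' @export
path_param_get <- function(params, name) ps_get(params$ps, name)

#' @rdname make_path_params
#' @param value replacement array of identical shape.
#' @export
path_param_set <- function(params, name, value) {
  old <- ps_get(params$ps, name)
  stopifnot(length(old) == length(value))
  value <- if (is.null(dim(old))) as.numeric(value) else array(value, dim = dim(old))
  ps_add(params$ps, name, value)
  invisible(params)
}

run_path_numeric <- function(kind, pyr, params) {
  stopifnot(inherits(pyr, "feature_pyramid"))
  if (kind %in% PARAM_PATH_KINDS) {
    stopifnot(inherits(params, "path_params"), params$kind == kind)
    if (dim(pyr[["2"]]$values)[1] != params$channels)
      stop("pyramid channels do not match path parameters")
  }
  tape <- ad_tape()
  cx <- if (is.null(params)) NULL else ad_ctx(params$ps, tape)
  nodes <- lapply(pyr, function(m) ad_const(tape, m$values))
  out <- apply_path_ad(cx, tape, kind, nodes, "")
  feature_pyramid(lapply(out, ad_val))
}

#' Nearest-neighbour 2x upsampling of a feature map
#' @param map a [feature_map] (or array / matrix).
#' @return a `feature_map` with doubled spatial size and halved stride.
#' @export
upsample <- function(map) {
  map <- if (inherits(map, "feature_map")) map else feature_map(map)
  x <- map$values
  y <- x[, rep(seq_len(dim(x)[2]), each = 2L), rep(seq_len(dim(x)[3]), each = 2L),
         drop = FALSE]
  feature_map(y, stride = max(1L, map$stride %/% 2L))
}

#' 2x2 max-pool downsampling of a feature map
#' @param map a [feature_map] with even spatial dimensions.
#' @return a `feature_map` with halved spatial size and doubled stride.
#' @export
downsample <- function(map) {
  map <- if (inherits(map, "feature_map")) map else feature_map(map)
  d <- dim(map$values)
  if (d[2] %% 2L != 0L || d[3] %% 2L != 0L)
    stop("downsample requires even spatial dimensions")
  feature_map(cpp_maxpool2_fwd(map$values, d)$y, stride = map$stride * 2L)
}

#' Apply one information path to a feature pyramid
#'
#' `top_down_path` builds outputs from level 5 down
#' (`F_i = W_i (U(F_{i+1}) + P_i)`, with `F_5 = W_5 P_5`); `bottom_up_path`
#' mirrors it from level 2 up with max-pool downsampling;
#' `scale_balanced_path` sums, per level, the upsampled convolution of the
#' level above, the convolution of the level itself and the downsampled
#' convolution of the level below (missing neighbours at the boundary
#' levels are dropped); `fuse_split_path` fuses the pyramid into two
#' intermediate maps at levels 4 and 3 by channel concatenation and splits
#' them back to four levels; `null_path` returns a zero pyramid and
#' `skip_path` the identity.  `apply_path` dispatches on the kind label.
#'
#' @param pyr a [feature_pyramid].
#' @param params a `path_params` of the matching kind.
#' @return a `feature_pyramid` with the same per-level shapes as `pyr`.
#' @export
top_down_path <- function(pyr, params) run_path_numeric("TOP_DOWN", pyr, params)

#' @rdname top_down_path
#' @export
bottom_up_path <- function(pyr, params) run_path_numeric("BOTTOM_UP", pyr, params)

#' @rdname top_down_path
#' @export
scale_balanced_path <- function(pyr, params) run_path_numeric("SCALE_BALANCED", pyr, params)

#' @rdname top_down_path
#' @export
fuse_split_path <- function(pyr, params) run_path_numeric("FUSE_SPLIT", pyr, params)

#' @rdname top_down_path
#' @export
null_path <- function(pyr) run_path_numeric("NULL", pyr, NULL)

#' @rdname top_down_path
#' @export
skip_path <- function(pyr) run_path_numeric("SKIP", pyr, NULL)

#' @rdname top_down_path
#' @param kind one of `PATH_KINDS`.
#' @export
apply_path <- function(kind, pyr, params = NULL) {
  kind <- match.arg(kind, PATH_KINDS)
  if (kind %in% c("NULL", "SKIP")) {
    if (!is.null(params)) stop("parameter-free path kinds take no params")
  } else if (is.null(params)) {
    stop("parameterized path kind requires params")
  }
  run_path_numeric(kind, pyr, params)
}
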