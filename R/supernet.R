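#' Edge enumeration of the fully connected aggregation DAG
#'
#' The neck's search space is a fully connected directed acyclic graph over
#' the node sequence `P, X_1, ..., X_N, O` (`P` is the backbone pyramid, `O`
#' the output).  Every forward-ordered node pair is an edge and carries one
#' of the six information-path kinds; the edge order fixed here is the
#' genotype ordering used by subnet codes.
#'
#' @param N number of intermediate nodes (>= 0).
#' @return character matrix `[n_edges, 2]` with columns `from`, `to`, in
#'   lexicographic (forward) order; `(N+2)(N+1)/2` rows.
#' @examples
#' enumerate_edges(1) # (P,X1), (P,O), (X1,O)
#' @export
enumerate_edges <- function(N) {
  if (N < 0) stop("N must be >= 0")
  nodes <- c("P", if (N > 0) paste0("X", seq_len(N)), "O")
  n <- length(nodes)
  from <- character(0); to <- character(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    from <- c(from, nodes[i]); to <- c(to, nodes[j])
  }
  cbind(from = from, to = to)
}

edge_labels <- function(edges) paste(edges[, 1], edges[, 2], sep = ">")

#' Size of the subnet search space
#'
#' @param N number of intermediate nodes.
#' @param kinds number of candidate path kinds per edge (default 6).
#' @return `kinds ^ n_edges`, before filtering for validity.
#' @export
count_subnets <- function(N, kinds = 6L) {
  kinds^nrow(enumerate_edges(N))
}

#' Build a one-shot supernet over the aggregation DAG
#'
#' Every edge holds independently initialized parameters for each of the
#' four parameterized path kinds; the null and skip kinds carry none.  All
#' subnets share these per-edge parameter bundles (weight sharing), which is
#' what allows candidate subnets to be ranked later without retraining.
#'
#' @param N number of intermediate nodes (default 5).
#' @param channels pyramid channel width (default 112).
#' @param seed optional seed for parameter initialization.
#' @param ps optional existing parameter store to register into.
#' @param prefix parameter-name prefix (default `"neck"`).
#' @return a `supernet` object.
#' @export
build_supernet <- function(N = 5L, channels = 112L, seed = NULL,
                           ps = NULL, prefix = "neck") {
  stopifnot(N >= 1L, channels >= 1L)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ps)) ps <- param_store()
  edges <- enumerate_edges(N)
  labs <- edge_labels(edges)
  for (e in labs) {
    for (kind in PARAM_PATH_KINDS) {
      init_path_params(ps, pname(prefix, paste0(e, ".", kind)), kind, channels)
    }
  }
  structure(list(N = as.integer(N), channels = as.integer(channels),
                 edges = edges, edge_labels = labs, ps = ps, prefix = prefix),
            class = "supernet")
}

#' @export
print.supernet <- function(x, ...) {
  cat(sprintf("<supernet N=%d, channels=%d, %d edges, %s parameters>\n",
              x$N, x$channels, nrow(x$edges),
              format(ps_n_params(x$ps, x$prefix), big.mark = ",")))
  invisible(x)
}

#' Total parameter count of a supernet (closed form)
#' @param dag a `supernet`.
#' @return number of scalar parameters over all edges and parameterized kinds.
#' @export
supernet_param_count <- function(dag) {
  nrow(dag$edges) * sum(vapply(PARAM_PATH_KINDS, path_param_count, 1,
                               channels = dag$channels))
}

#' Subnet code validity
#'
#' A subnet code (one path kind per edge) is valid when at least one
#' directed route from `P` to `O` uses only non-null edges; otherwise the
#' output node receives no information.
#'
#' @param code named character vector, one of `PATH_KINDS` per edge label.
#' @return `TRUE`/`FALSE`.
#' @export
is_valid_code <- function(code) {
  edges <- do.call(rbind, strsplit(names(code), ">", fixed = TRUE))
  keep <- code != "NULL"
  reach <- "P"
  repeat {
    new <- unique(edges[keep & edges[, 1] %in% reach, 2])
    new <- setdiff(new, reach)
    if (length(new) == 0L) break
    reach <- c(reach, new)
  }
  "O" %in% reach
}

#' Uniform single-path subnet sampling
#'
#' Draws each edge's kind uniformly from the six candidates; codes without a
#' non-null route from input to output are re-drawn.  This is the sampling
#' rule used for single-path one-shot supernet training.
#'
#' @param dag a `supernet`.
#' @param seed optional integer seed for reproducibility.
#' @return a named character vector (a subnet code).
#' @export
sample_subnet <- function(dag, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    code <- setNames(sample(PATH_KINDS, length(dag$edge_labels), replace = TRUE),
                     dag$edge_labels)
    if (is_valid_code(code)) return(code)
  }
}

# Differentiable subnet forward: nodes evaluated in topological order, each
# node the element-wise sum of its incoming paths' pyramids.
forward_subnet_ad <- function(cx, tape, dag, code, pyr_nodes) {
  node_names <- c("P", if (dag$N > 0) paste0("X", seq_len(dag$N)), "O")
  vals <- list(P = pyr_nodes)
  for (nn in node_names[-1]) {
    terms <- list()
    for (ei in which(dag$edges[, 2] == nn)) {
      kind <- code[[dag$edge_labels[ei]]]
      if (kind == "NULL") next
      src <- vals[[dag$edges[ei, 1]]]
      terms <- c(terms, list(apply_path_ad(cx, tape, kind, src,
        pname(dag$prefix, paste0(dag$edge_labels[ei], ".", kind)))))
    }
    if (length(terms) == 0L) {
      # a node all of whose incoming edges are null holds a zero pyramid
      vals[[nn]] <- lapply(pyr_nodes, function(nd)
        ad_const(tape, array(0, dim = dim(ad_val(nd)))))
    } else if (length(terms) == 1L) {
      vals[[nn]] <- terms[[1]]
    } else {
      vals[[nn]] <- lapply(as.character(2:5), function(l) {
        do.call(ad_add, c(list(tape), lapply(terms, `[[`, l)))
      })
      names(vals[[nn]]) <- as.character(2:5)
    }
  }
  vals$O
}

#' Forward a subnet of the supernet
#'
#' Evaluates the DAG in topological order for a fixed subnet code: each
#' node's pyramid is the element-wise sum of its incoming information
#' paths applied to their source nodes; the output node's pyramid is
#' returned.  Only the parameter bundles named by the code are read.
#'
#' @param dag a `supernet`.
#' @param code a valid subnet code (see [sample_subnet]).
#' @param input a [feature_pyramid] with `dag$channels` channels.
#' @return a `feature_pyramid`.
#' @export
forward_subnet <- function(dag, code, input) {
  stopifnot(inherits(input, "feature_pyramid"))
  if (!identical(sort(names(code)), sort(dag$edge_labels)))
    stop("code edges do not match the supernet")
  if (!all(code %in% PATH_KINDS)) stop("invalid path kind in code")
  if (!is_valid_code(code)) stop("invalid subnet code: no non-null route P -> O")
  if (dim(input[["2"]]$values)[1] != dag$channels)
    stop("input channels do not match the supernet")
  tape <- ad_tape()
  cx <- ad_ctx(dag$ps, tape)
  nodes <- lapply(input, function(m) ad_const(tape, m$values))
  out <- forward_subnet_ad(cx, tape, dag, code, nodes)
  feature_pyramid(lapply(out, ad_val))
}
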