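#' Evolutionary search configuration
#'
#' Defaults follow the search setup used for the detector: population
#' `S = 50`, elite size `k = 10`, per-edge mutation probability `p = 0.1`;
#' the number of rounds `n` defaults to 20.
#'
#' @param S population size.
#' @param k elite size (`1 <= k <= S`).
#' @param p per-edge mutation probability in `[0, 1]`.
#' @param n number of evolution rounds.
#' @param seed integer seed driving all randomness of the search.
#' @param mutation `"per-edge"` (each edge resampled independently with
#'   probability `p`) or `"single-edge"` (exactly one uniformly chosen edge
#'   resampled, with probability `p` per child).
#' @return a `search_config`.
#' @export
search_config <- function(S = 50L, k = 10L, p = 0.1, n = 20L, seed = 1L,
                          mutation = c("per-edge", "single-edge")) {
  stopifnot(S >= 1L, k >= 1L, k <= S, p >= 0, p <= 1, n >= 0L)
  structure(list(S = as.integer(S), k = as.integer(k), p = p,
                 n = as.integer(n), seed = as.integer(seed),
                 mutation = match.arg(mutation)),
            class = "search_config")
}

redraw_until_valid <- function(make, fallback, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    code <- make()
    if (is_valid_code(code)) return(code)
  }
  fallback
}

#' Crossover of two subnet codes
#'
#' Each edge's kind is taken from either parent with probability one half;
#' children without a non-null input-to-output route are re-drawn (bounded
#' retries, falling back to the first parent).
#'
#' @param a,b valid subnet codes over the same edge set.
#' @param seed optional seed.
#' @return a valid subnet code.
#' @export
crossover <- function(a, b, seed = NULL) {
  if (!identical(names(a), names(b))) stop("codes must share one edge set")
  if (!is.null(seed)) set.seed(seed)
  redraw_until_valid(function() {
    pick <- runif(length(a)) < 0.5
    out <- a
    out[!pick] <- b[!pick]
    out
  }, fallback = a)
}

#' Mutation of a subnet code
#'
#' In the default per-edge mode each edge is independently resampled
#' uniformly over all six kinds with probability `p` (resampling may repeat
#' the current kind, so the expected fraction of changed edges under `p = 1`
#' is 5/6).  Validity is enforced by re-drawing.
#'
#' @param code a valid subnet code.
#' @param p mutation probability in `[0, 1]`.
#' @param seed optional seed.
#' @param mode `"per-edge"` or `"single-edge"`.
#' @return a valid subnet code.
#' @export
mutate <- function(code, p, seed = NULL, mode = c("per-edge", "single-edge")) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  redraw_until_valid(function() {
    out <- code
    if (mode == "per-edge") {
      hit <- runif(length(code)) < p
      if (any(hit)) out[hit] <- sample(PATH_KINDS, sum(hit), replace = TRUE)
    } else if (runif(1) < p) {
      e <- sample.int(length(code), 1L)
      out[e] <- sample(PATH_KINDS, 1L)
    }
    out
  }, fallback = code)
}

random_valid_code <- function(edge_labs) {
  redraw_until_valid(function() {
    setNames(sample(PATH_KINDS, length(edge_labs), replace = TRUE), edge_labs)
  }, fallback = setNames(rep("SKIP", length(edge_labs)), edge_labs))
}

#' Rank one subnet on a validation set
#'
#' Runs inference with a fixed subnet code on every validation image and
#' scores the pooled detections with COCO-style AP at IoU 0.5.  The result
#' is deterministic given the detector weights and the data, which is what
#' allows subnets to be ranked without retraining.
#'
#' @param detector either a trained detector (see [build_detector]) or a
#'   function `f(image, code)` returning a detection data frame (used for
#'   rigged oracles in testing).
#' @param code subnet code to evaluate.
#' @param val_set list of `list(image, boxes)` items, `boxes` a data frame
#'   with `x_min, y_min, x_max, y_max` ground-truth columns.
#' @param score_threshold detections below this score are dropped.
#' @return AP50 in `[0, 1]`.
#' @export
evaluate_candidate <- function(detector, code, val_set, score_threshold = 0.05) {
  if (length(val_set) == 0L) stop("validation set is empty")
  infer_fn <- if (is.function(detector)) {
    detector
  } else {
    function(image, code) infer(detector, image, score_threshold = score_threshold,
                                code = code)
  }
  dets <- lapply(val_set, function(item) infer_fn(item$image, code))
  gts <- lapply(val_set, `[[`, "boxes")
  average_precision_50(dets, gts)
}

#' Evolutionary search over subnet codes
#'
#' Generation 0 holds `S` random valid codes.  Each round the population is
#' evaluated and ranked, the best `k` elites are carried over unmodified,
#' and the population is refilled to `S` with
#' `mutate(crossover(elite, elite), p)` children.  The best candidate ever
#' evaluated is returned together with a per-generation history (so the
#' best-so-far fitness is non-decreasing by construction).
#'
#' @param fitness function `f(code) -> number`; see [evolve_detector] for
#'   the detector-backed wrapper.
#' @param edge_labs character vector of edge labels (e.g.
#'   `edge_labels(enumerate_edges(N))` or a supernet's `$edge_labels`).
#' @param cfg a [search_config].
#' @return list with `best` (`list(code, fitness)`), `history` (data frame
#'   with one row per generation 0..n) and `log` (every evaluated candidate:
#'   generation, code string, fitness).
#' @export
evolve <- function(fitness, edge_labs, cfg = search_config()) {
  set.seed(cfg$seed)
  if (inherits(edge_labs, "supernet")) edge_labs <- edge_labs$edge_labels
  pop <- replicate(cfg$S, random_valid_code(edge_labs), simplify = FALSE)
  best <- NULL
  history <- data.frame()
  log <- list()
  cache <- new.env(parent = emptyenv())
  eval_code <- function(code) {
    key <- paste(code, collapse = "|")
    if (is.null(cache[[key]])) cache[[key]] <- fitness(code)
    cache[[key]]
  }
  for (gen in 0:cfg$n) {
    fit <- vapply(pop, eval_code, 1)
    ord <- order(fit, decreasing = TRUE)
    if (is.null(best) || fit[ord[1]] > best$fitness)
      best <- list(code = pop[[ord[1]]], fitness = fit[ord[1]])
    history <- rbind(history, data.frame(
      generation = gen, gen_best = fit[ord[1]],
      gen_mean = mean(fit), best_so_far = best$fitness))
    log[[gen + 1L]] <- data.frame(
      generation = gen,
      code = vapply(pop, paste, "", collapse = "|"),
      fitness = fit)
    if (gen == cfg$n) break
    elite <- pop[ord[seq_len(cfg$k)]]
    # children that duplicate an existing population member are re-drawn
    # (bounded tries) to keep the population diverse
    seen <- vapply(elite, paste, "", collapse = "|")
    children <- list()
    while (length(children) < cfg$S - cfg$k) {
      child <- NULL
      for (try in 1:20) {
        pair <- sample.int(cfg$k, 2L, replace = TRUE)
        cand <- mutate(crossover(elite[[pair[1]]], elite[[pair[2]]]), cfg$p,
                       mode = cfg$mutation)
        key <- paste(cand, collapse = "|")
        if (!(key %in% seen)) { child <- cand; seen <- c(seen, key); break }
        child <- cand
      }
      children[[length(children) + 1L]] <- child
    }
    pop <- c(elite, children)
  }
  list(best = best, history = history, log = do.call(rbind, log))
}

#' @rdname evolve
#' @inheritParams evaluate_candidate
#' @param detector a detector whose neck is the supernet being searched.
#' @param dag the `supernet` (defaults to the detector's neck).
#' @param log_file optional path; every evaluated candidate is appended as a
#'   JSON line `{generation, code, fitness}`.
#' @export
evolve_detector <- function(detector, val_set, cfg = search_config(),
                            dag = detector$neck, log_file = NULL) {
  res <- evolve(function(code) evaluate_candidate(detector, code, val_set),
                dag$edge_labels, cfg)
  if (!is.null(log_file)) {
    con <- file(log_file, open = "wt")
    on.exit(close(con))
    for (i in seq_len(nrow(res$log))) {
      writeLines(jsonlite::toJSON(as.list(res$log[i, ]), auto_unbox = TRUE), con)
    }
  }
  res
}
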