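#' Intersection over union of two boxes
#'
#' Boxes are `(x_min, y_min, x_max, y_max)` in pixels (continuous
#' coordinates, half-open, so area is `(x_max - x_min) * (y_max - y_min)`).
#'
#' @param a,b numeric 4-vectors.
#' @return IoU in `[0, 1]`.
#' @examples
#' iou(c(0, 0, 2, 2), c(1, 0, 3, 2)) # 1/3
#' @export
iou <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (a[1] >= a[3] || a[2] >= a[4] || b[1] >= b[3] || b[2] >= b[4])
    stop("degenerate box")
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter)
}

boxes_matrix <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return(matrix(0, 0, 4))
  as.matrix(df[, c("x_min", "y_min", "x_max", "y_max")])
}

#' Greedy matching of detections to ground truths
#'
#' Detections are processed in descending score order; each one matches the
#' highest-IoU not-yet-matched ground truth provided the IoU reaches the
#' threshold, otherwise it is a false positive.  Each ground truth can be
#' matched at most once.
#'
#' @param dets data frame with `x_min, y_min, x_max, y_max, score`.
#' @param gts data frame with `x_min, y_min, x_max, y_max`.
#' @param iou_threshold matching threshold (default 0.5).
#' @return a `match_result`: list with logical `tp` (per detection, in
#'   descending score order), `score` (the matching order), `fn` count and
#'   `n_gt`.
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5) {
  db <- boxes_matrix(dets)
  gb <- boxes_matrix(gts)
  ord <- if (nrow(db) > 0L) order(dets$score, decreasing = TRUE) else integer(0)
  tp <- logical(length(ord))
  gt_used <- logical(nrow(gb))
  for (k in seq_along(ord)) {
    d <- db[ord[k], ]
    best <- 0; best_g <- 0L
    for (g in seq_len(nrow(gb))) {
      if (gt_used[g]) next
      v <- iou(d, gb[g, ])
      if (v > best) { best <- v; best_g <- g }
    }
    if (best_g > 0L && best >= iou_threshold) {
      tp[k] <- TRUE
      gt_used[best_g] <- TRUE
    }
  }
  structure(list(tp = tp, score = if (length(ord)) dets$score[ord] else numeric(0),
                 fn = sum(!gt_used), n_gt = nrow(gb)),
            class = "match_result")
}

#' COCO-style average precision at IoU 0.5
#'
#' Detections of all images are matched per image (greedy, IoU >= 0.5),
#' pooled, sorted by descending score, and the precision-recall curve is
#' averaged at the 101 recall points `0, 0.01, ..., 1` using interpolated
#' (running-maximum) precision — the COCO convention.
#'
#' @param dets a detection data frame or a list of them (one per image).
#' @param gts a ground-truth data frame or a list of them (one per image).
#' @param iou_threshold matching threshold (default 0.5).
#' @return AP in `[0, 1]`; `NA` if there are no ground truths anywhere.
#' @export
average_precision_50 <- function(dets, gts, iou_threshold = 0.5) {
  if (is.data.frame(dets)) dets <- list(dets)
  if (is.data.frame(gts)) gts <- list(gts)
  stopifnot(length(dets) == length(gts))
  matches <- Map(match_detections, dets, gts, iou_threshold = iou_threshold)
  n_gt <- sum(vapply(matches, `[[`, 1, "n_gt"))
  if (n_gt == 0L) {
    warning("no ground truths: AP undefined")
    return(NA_real_)
  }
  score <- unlist(lapply(matches, `[[`, "score"))
  tp <- unlist(lapply(matches, `[[`, "tp"))
  if (length(score) == 0L) return(0)
  ord <- order(score, decreasing = TRUE)
  tp <- tp[ord]
  cum_tp <- cumsum(tp)
  prec <- cum_tp / seq_along(tp)
  rec <- cum_tp / n_gt
  # interpolated precision: running max from the right
  ip <- rev(cummax(rev(prec)))
  r_grid <- seq(0, 1, by = 0.01)
  p_at <- vapply(r_grid, function(r) {
    i <- which(rec >= r)
    if (length(i) == 0L) 0 else ip[i[1]]
  }, 1)
  mean(p_at)
}

#' Recall of a match result
#' @param match a `match_result` from [match_detections].
#' @return `TP / (TP + FN)`.
#' @export
recall_rate <- function(match) {
  tp <- sum(match$tp)
  if (tp + match$fn == 0) stop("recall undefined without ground truths")
  tp / (tp + match$fn)
}

round_half_up <- function(x, digits = 1L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' F1 measure on the percent scale
#'
#' Harmonic mean `2 P R / (P + R)` of a precision-like and a recall-like
#' quantity given in percent, rounded half-up to one decimal — the
#' convention used in the detector's summary tables, where AP50 serves as
#' the precision surrogate.
#'
#' @param precision_pct,recall_pct values in `[0, 100]`, not both zero.
#' @return F1 in percent, one decimal.
#' @examples
#' f1_score(90.6, 95.1) # 92.8
#' f1_score(84.9, 91.7) # 88.2
#' @export
f1_score <- function(precision_pct, recall_pct) {
  stopifnot(precision_pct >= 0, precision_pct <= 100,
            recall_pct >= 0, recall_pct <= 100)
  if (precision_pct == 0 && recall_pct == 0) stop("F1 undefined for P = R = 0")
  round_half_up(2 * precision_pct * recall_pct / (precision_pct + recall_pct), 1L)
}

#' Thresholded precision / recall / F1 report
#'
#' Complementary to the AP50-based summary: keeps detections at or above a
#' score threshold, matches them at IoU 0.5 and reports plain precision,
#' recall and their harmonic mean, in percent.
#'
#' @inheritParams average_precision_50
#' @param score_threshold minimum detection score (default 0.5).
#' @return data frame with `precision`, `recall`, `f1` (percent), and the
#'   `tp`, `fp`, `fn` counts.
#' @export
detection_report <- function(dets, gts, score_threshold = 0.5,
                             iou_threshold = 0.5) {
  if (is.data.frame(dets)) dets <- list(dets)
  if (is.data.frame(gts)) gts <- list(gts)
  dets <- lapply(dets, function(d) d[d$score >= score_threshold, , drop = FALSE])
  matches <- Map(match_detections, dets, gts, iou_threshold = iou_threshold)
  tp <- sum(vapply(matches, function(m) sum(m$tp), 1))
  fp <- sum(vapply(matches, function(m) sum(!m$tp), 1))
  fn <- sum(vapply(matches, `[[`, 1, "fn"))
  prec <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) round_half_up(2 * prec * rec / (prec + rec), 1L) else 0
  data.frame(precision = prec, recall = rec, f1 = f1, tp = tp, fp = fp, fn = fn)
}
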