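# Detection evaluation: greedy matching of predictions to ground truth and
# the precision / recall / F1 / mAP / FPS indices.

#' Match predicted boxes to ground truth
#'
#' Greedy class-strict matching within one image: per class, predictions are
#' visited in descending confidence; each prediction claims the unmatched
#' same-class ground-truth box of highest IoU, and counts as a true positive
#' when that IoU clears the threshold. Every ground truth can be matched at
#' most once, so duplicate detections of one object are false positives.
#' Unmatched ground truths are false negatives.
#'
#' The threshold comparison is `>=` by default (a detection exactly at the
#' threshold counts); set `strict = TRUE` for `>`. With `class_agnostic_pods
#' = TRUE` the five pod types are pooled into a single "pod" class before
#' matching, mirroring a two-stage protocol that first detects pods and only
#' then types them.
#'
#' @param preds Data frame of predictions: `class`, `x_min`, `y_min`,
#'   `x_max`, `y_max`, `confidence`.
#' @param gts Data frame of ground truth: same columns minus `confidence`.
#' @param iou_thresh IoU threshold in (0, 1); default 0.5.
#' @param strict Use `>` instead of `>=` at the threshold.
#' @param class_agnostic_pods Pool pod1..pod5 into one class.
#' @return A `match_counts` data frame: one row per class plus an `overall`
#'   row, columns `class`, `tp`, `fp`, `fn`.
#' @export
match_detections <- function(preds, gts, iou_thresh = 0.5, strict = FALSE,
                             class_agnostic_pods = FALSE) {
  if (iou_thresh <= 0 || iou_thresh >= 1) stop("iou_thresh must be in (0, 1)")
  if (is.null(preds)) preds <- empty_boxes(confidence = TRUE)
  if (is.null(gts)) gts <- empty_boxes()
  check_classes(preds$class); check_classes(gts$class)
  classes <- class_vocabulary()
  pcls <- as.character(preds$class); gcls <- as.character(gts$class)
  if (class_agnostic_pods) {
    classes <- c("leaf", "pod")
    pcls[pcls != "leaf"] <- "pod"
    gcls[gcls != "leaf"] <- "pod"
  }
  rows <- lapply(classes, function(cl) {
    p <- preds[pcls == cl, , drop = FALSE]
    g <- gts[gcls == cl, , drop = FALSE]
    np <- nrow(p); ng <- nrow(g)
    if (np == 0L)
      return(data.frame(class = cl, tp = 0L, fp = 0L, fn = ng))
    p <- p[order(-p$confidence), , drop = FALSE]
    tp <- 0L
    if (ng > 0L) {
      im <- iou_matrix(p, g)
      taken <- rep(FALSE, ng)
      for (i in seq_len(np)) {
        ious <- im[i, ]
        ious[taken] <- -1
        j <- which.max(ious)
        hit <- if (strict) ious[j] > iou_thresh else ious[j] >= iou_thresh
        if (hit) { tp <- tp + 1L; taken[j] <- TRUE }
      }
    }
    data.frame(class = cl, tp = tp, fp = np - tp, fn = ng - tp)
  })
  counts <- do.call(rbind, rows)
  counts <- rbind(counts,
                  data.frame(class = "overall", tp = sum(counts$tp),
                             fp = sum(counts$fp), fn = sum(counts$fn)))
  class(counts) <- c("match_counts", class(counts))
  counts
}

#' Sum match counts over images
#'
#' Micro-averaging aggregates raw counts over a dataset before computing
#' ratios, so each detected object carries equal weight regardless of which
#' image it sits in.
#'
#' @param counts_list List of `match_counts` from [match_detections()].
#' @return A single pooled `match_counts`.
#' @export
pool_match_counts <- function(counts_list) {
  stopifnot(length(counts_list) > 0L)
  out <- counts_list[[1L]]
  for (m in counts_list[-1L]) {
    stopifnot(identical(m$class, out$class))
    out$tp <- out$tp + m$tp; out$fp <- out$fp + m$fp; out$fn <- out$fn + m$fn
  }
  out
}

prf_one <- function(tp, fp, fn) {
  p <- if (tp + fp > 0L) tp / (tp + fp) else 0
  r <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- f1_score(p, r)
  c(precision = p, recall = r, f1 = f1)
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2PR / (P + R)`, 0 when both are 0.
#'
#' @param precision,recall Fractions in \[0, 1\].
#' @return F1 in \[0, 1\].
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Precision, recall and F1 from match counts
#'
#' `P = TP / (TP + FP)` (how trustworthy detections are), `R = TP / (TP +
#' FN)` (how completely objects are found), `F1 = 2PR / (P + R)`. A zero
#' denominator (no predictions, or no ground truth) yields 0 by convention,
#' with a note sent to the log.
#'
#' @param counts A `match_counts` data frame.
#' @return Data frame with one row per class (plus overall) and columns
#'   `class`, `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(counts) {
  if (any(counts$tp + counts$fp == 0L | counts$tp + counts$fn == 0L))
    message("note: zero-denominator precision or recall reported as 0")
  m <- t(mapply(prf_one, counts$tp, counts$fp, counts$fn))
  cbind(counts[, c("class", "tp", "fp", "fn")], as.data.frame(m))
}

#' Mean average precision, per-class-precision sense
#'
#' The multi-class summary used here is the arithmetic mean of the per-class
#' detection precisions, `MAP = sum(P_k) / N`. Note this is *not* the
#' ranked-retrieval average precision of the COCO/VOC benchmarks; for
#' interoperability that quantity is available as
#' [average_precision_11pt()].
#'
#' @param per_class_precision Non-empty numeric vector of per-class
#'   precisions.
#' @return Mean precision in \[0, 1\].
#' @export
mean_average_precision <- function(per_class_precision) {
  if (length(per_class_precision) == 0L)
    stop("per_class_precision must be non-empty")
  mean(per_class_precision)
}

#' 11-point interpolated average precision (single class)
#'
#' The classic VOC-style alternative to the per-class-precision mean:
#' predictions pooled over images are swept by descending confidence, and
#' interpolated precision is averaged at recalls 0, 0.1, ..., 1.
#'
#' @param preds,gts Lists of per-image box data frames (or single data
#'   frames), all of one class.
#' @param iou_thresh IoU threshold.
#' @return AP in \[0, 1\].
#' @export
average_precision_11pt <- function(preds, gts, iou_thresh = 0.5) {
  if (is.data.frame(preds)) preds <- list(preds)
  if (is.data.frame(gts)) gts <- list(gts)
  stopifnot(length(preds) == length(gts))
  n_gt <- sum(vapply(gts, nrow, integer(1)))
  if (n_gt == 0L) return(0)
  scored <- list()
  for (i in seq_along(preds)) {
    p <- preds[[i]]; g <- gts[[i]]
    if (nrow(p) == 0L) next
    p <- p[order(-p$confidence), , drop = FALSE]
    hit <- logical(nrow(p))
    if (nrow(g) > 0L) {
      im <- iou_matrix(p, g)
      taken <- rep(FALSE, nrow(g))
      for (r in seq_len(nrow(p))) {
        ious <- im[r, ]; ious[taken] <- -1
        j <- which.max(ious)
        if (ious[j] >= iou_thresh) { hit[r] <- TRUE; taken[j] <- TRUE }
      }
    }
    scored[[length(scored) + 1L]] <- data.frame(conf = p$confidence, hit = hit)
  }
  if (length(scored) == 0L) return(0)
  s <- do.call(rbind, scored)
  s <- s[order(-s$conf), , drop = FALSE]
  tp_cum <- cumsum(s$hit)
  prec <- tp_cum / seq_along(tp_cum)
  rec <- tp_cum / n_gt
  mean(vapply(seq(0, 1, by = 0.1), function(rt) {
    ok <- rec >= rt
    if (any(ok)) max(prec[ok]) else 0
  }, numeric(1)))
}

#' Frames-per-second throughput
#'
#' `FPS = N / T` for N processed samples in T seconds. An informational
#' index only: it depends on the hardware it is measured on.
#'
#' @param n_samples Number of samples processed (>= 0).
#' @param elapsed Wall time in seconds (> 0).
#' @return Rate in frames per second.
#' @export
fps <- function(n_samples, elapsed) {
  if (elapsed <= 0) stop("elapsed time must be positive")
  if (n_samples < 0) stop("n_samples must be non-negative")
  n_samples / elapsed
}

#' Evaluate detections over a dataset
#'
#' Matches per image, pools counts (micro-averaging), and reports per-class
#' and overall precision/recall/F1 along with the per-class-precision mAP.
#'
#' @param pred_list,gt_list Parallel lists of per-image box data frames.
#' @param iou_thresh IoU threshold.
#' @param ... Passed to [match_detections()].
#' @return List with `per_class` (metrics data frame), `map`, and `counts`.
#' @export
evaluate_detections <- function(pred_list, gt_list, iou_thresh = 0.5, ...) {
  stopifnot(length(pred_list) == length(gt_list))
  counts <- pool_match_counts(lapply(seq_along(pred_list), function(i)
    match_detections(pred_list[[i]], gt_list[[i]], iou_thresh, ...)))
  metrics <- suppressMessages(precision_recall_f1(counts))
  per_class <- metrics[metrics$class != "overall", , drop = FALSE]
  present <- per_class$tp + per_class$fn > 0L  # classes with ground truth
  list(per_class = metrics,
       map = mean_average_precision(per_class$precision[present]),
       counts = counts)
}
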