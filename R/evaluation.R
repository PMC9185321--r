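# Frame-level detection metrics: rank-statistic AUC, the fall/non-fall
# score gap, and confusion counts at a threshold.

#' Frame-level ROC AUC
#'
#' The probability that a uniformly chosen fall frame outscores a
#' uniformly chosen normal frame, ties counted one half (the rank-sum
#' definition, exact and invariant under strictly increasing score
#' transforms).
#'
#' @param scores numeric per-frame scores.
#' @param labels 0/1 per-frame labels, aligned with `scores`.
#' @return AUC in `[0, 1]`.
#' @export
frame_auc <- function(scores, labels) {
  ok <- !is.na(scores)
  scores <- scores[ok]
  labels <- as.integer(labels[ok])
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("frame_auc: need both classes among scored frames", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fall/non-fall score gap
#'
#' Mean score of fall-labelled frames minus mean score of normal frames;
#' positive gaps mean the classes separate in the right direction. For the
#' offline variant this is computed on per-clip normalised scores.
#'
#' @param scores numeric per-frame scores.
#' @param labels 0/1 per-frame labels.
#' @return The score gap.
#' @export
score_gap <- function(scores, labels) {
  ok <- !is.na(scores)
  scores <- scores[ok]
  labels <- as.integer(labels[ok])
  if (!any(labels == 1L) || !any(labels == 0L))
    stop("score_gap: need both classes among scored frames", call. = FALSE)
  mean(scores[labels == 1L]) - mean(scores[labels == 0L])
}

#' Confusion counts and rates at a threshold
#'
#' The alarm fires strictly above the threshold (conservative toward fewer
#' alarms at the boundary).
#'
#' @param scores numeric per-frame scores.
#' @param labels 0/1 per-frame labels.
#' @param threshold alarm threshold.
#' @return List with `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`.
#' @export
confusion_at <- function(scores, labels, threshold) {
  ok <- !is.na(scores)
  scores <- scores[ok]
  labels <- as.integer(labels[ok])
  alarm <- scores > threshold
  tp <- sum(alarm & labels == 1L)
  fp <- sum(alarm & labels == 0L)
  tn <- sum(!alarm & labels == 0L)
  fn <- sum(!alarm & labels == 1L)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Evaluate a set of score tracks
#'
#' Pools scored, labelled frames across clips (the dataset-level
#' convention: one AUC per dataset, not an average of per-clip AUCs) and
#' computes frame-level AUC, the score gap, and optionally confusion rates
#' at a threshold. Offline mode min-max normalises each track first.
#'
#' @param tracks list of labelled `score_track`s.
#' @param mode `"offline"` (per-clip normalised scores) or `"online"`
#'   (raw scores).
#' @param threshold optional alarm threshold.
#' @return An `evaluation_result`: `auc`, `score_gap`, `n_fall_frames`,
#'   `n_normal_frames`, `n_unscored_frames`, and at a threshold also
#'   `sensitivity`/`specificity`.
#' @export
evaluate_tracks <- function(tracks, mode = c("offline", "online"),
                            threshold = NULL) {
  mode <- match.arg(mode)
  pool <- .pool_tracks(tracks, mode)
  unscored <- sum(vapply(tracks, function(tr) sum(is.na(tr$raw)), numeric(1)))
  res <- list(auc = frame_auc(pool$score, pool$label),
              score_gap = score_gap(pool$score, pool$label),
              n_fall_frames = sum(pool$label == 1L),
              n_normal_frames = sum(pool$label == 0L),
              n_unscored_frames = unscored,
              mode = mode, threshold = threshold)
  if (!is.null(threshold)) {
    cm <- confusion_at(pool$score, pool$label, threshold)
    res$sensitivity <- cm$sensitivity
    res$specificity <- cm$specificity
  }
  structure(res, class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> mode %s: AUC %.4f, score gap %.4f (N1 = %d, N0 = %d)\n",
              x$mode, x$auc, x$score_gap, x$n_fall_frames, x$n_normal_frames))
  if (!is.null(x$threshold))
    cat(sprintf("  threshold %.3f: sensitivity %.3f, specificity %.3f\n",
                x$threshold, x$sensitivity, x$specificity))
  invisible(x)
}
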