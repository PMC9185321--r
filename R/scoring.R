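# Anomaly scoring: the angle between bottleneck encodings of the
# reconstructed and authentic frame sequences, mapped onto frames and
# optionally min-max normalised per clip (the offline variant).

#' Angular distance between two encoded feature vectors
#'
#' `theta = arccos( (v1 . v2) / (||v1|| ||v2||) )`, with the cosine
#' argument clamped to `[-1, 1]` against rounding. Symmetric and invariant
#' to positive rescaling of either vector.
#'
#' @param v1,v2 non-zero numeric vectors of equal length.
#' @return Angle in radians, in `[0, pi]`.
#' @export
angular_score <- function(v1, v2) {
  if (length(v1) != length(v2))
    stop("angular_score: length mismatch", call. = FALSE)
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0)
    stop("angular_score: zero-norm encoded feature", call. = FALSE)
  acos(max(-1, min(1, sum(v1 * v2) / (n1 * n2))))
}

#' Score one sequence sample
#'
#' Reconstructs the target window from the input window, re-encodes the
#' reconstruction (V1) and the authentic target window (V2) through the
#' same encoder, and returns their angular distance. With
#' `method = "mse"` the per-pixel mean squared reconstruction error over
#' the 4 future frames is returned instead (the baseline that angular
#' scoring is designed to beat on jittery depth input).
#'
#' @param gen a trained `fg_generator`.
#' @param sample a `sequence_sample` from [window_sequences()].
#' @param method `"angle"` (encoded-feature comparison) or `"mse"`.
#' @param v1_source what is re-encoded as V1: the full 8-frame
#'   reconstruction (`"full"`, default -- whole-sequence feedback), or the
#'   4 predicted future frames with the authentic first 4 frames
#'   prepended (`"future"`).
#' @return Scalar anomaly score (radians for `"angle"`).
#' @export
score_sample <- function(gen, sample, method = c("angle", "mse"),
                         v1_source = c("full", "future")) {
  method <- match.arg(method)
  v1_source <- match.arg(v1_source)
  stopifnot(inherits(sample, "sequence_sample"))
  recon <- generate(gen, sample$input_window)
  if (method == "mse")
    return(l2_loss(sample$target_window[, , 5:8], recon[, , 5:8]))
  if (v1_source == "future") {
    mixed <- sample$target_window
    mixed[, , 5:8] <- recon[, , 5:8]
    recon <- mixed
  }
  angular_score(encode(gen, recon), encode(gen, sample$target_window))
}

#' Score every frame of a clip
#'
#' Windows are taken at `inference_stride` (3 in the real-time deployment,
#' 1 for dataset evaluation); each window's score is assigned to its four
#' predicted-future frame indices and overlaps are averaged. Frames never
#' covered by a window (at least the first 8 of every clip) carry `NA` and
#' are excluded from evaluation.
#'
#' @param gen a trained `fg_generator`.
#' @param clip a preprocessed [video_clip()].
#' @param inference_stride anchor step between scored windows.
#' @param method `"angle"` or `"mse"` (see [score_sample()]).
#' @param v1_source V1 variant, see [score_sample()].
#' @return A `score_track`: per-frame `raw` scores (NA where uncovered),
#'   `normalized` scores (filled by [normalize_track()]), `labels`, and
#'   `clip_id`.
#' @export
score_clip <- function(gen, clip, inference_stride = 3L,
                       method = c("angle", "mse"),
                       v1_source = c("full", "future")) {
  method <- match.arg(method)
  v1_source <- match.arg(v1_source)
  stopifnot(inherits(clip, "video_clip"))
  n <- n_frames(clip)
  raw <- rep(NA_real_, n)
  cover <- integer(n)
  if (n >= 12L) {
    anchors <- seq(8L, n - 4L, by = as.integer(inference_stride))
    acc <- numeric(n)
    for (t in anchors) {
      sample <- structure(
        list(input_window = clip$frames[, , (t - 7L):t, drop = FALSE],
             target_window = clip$frames[, , (t - 3L):(t + 4L), drop = FALSE],
             anchor_index = t),
        class = "sequence_sample")
      s <- score_sample(gen, sample, method, v1_source)
      pred <- (t + 1L):(t + 4L)
      acc[pred] <- acc[pred] + s
      cover[pred] <- cover[pred] + 1L
    }
    raw[cover > 0L] <- acc[cover > 0L] / cover[cover > 0L]
  } else {
    message("score_clip: clip '", clip$clip_id,
            "' too short to score (", n, " frames)")
  }
  structure(list(clip_id = clip$clip_id, raw = raw, normalized = NULL,
                 labels = clip$labels, threshold = NULL, method = method),
            class = "score_track")
}

#' @export
print.score_track <- function(x, ...) {
  cat(sprintf("<score_track '%s'> %d frames, %d scored%s\n", x$clip_id,
              length(x$raw), sum(!is.na(x$raw)),
              if (is.null(x$normalized)) "" else ", normalized"))
  invisible(x)
}

#' Min-max normalise a score track (offline variant)
#'
#' Rescales the clip's raw scores to `[0, 1]`; a constant track maps to
#' all zeros (no anomaly evidence). Normalisation preserves within-clip
#' ranking, so single-clip AUC is unchanged.
#'
#' @param track a `score_track` with at least one scored frame.
#' @return The track with `normalized` filled in.
#' @export
normalize_track <- function(track) {
  stopifnot(inherits(track, "score_track"))
  sc <- track$raw[!is.na(track$raw)]
  if (length(sc) == 0L)
    stop("normalize_track: track '", track$clip_id, "' has no scored frames",
         call. = FALSE)
  lo <- min(sc)
  hi <- max(sc)
  track$normalized <- if (hi > lo) (track$raw - lo) / (hi - lo)
                      else ifelse(is.na(track$raw), NA_real_, 0)
  track
}

# Pooled (score, label) frames across tracks; offline mode uses normalized
# scores (normalising on demand), online mode raw scores.
.pool_tracks <- function(tracks, mode = c("offline", "online")) {
  mode <- match.arg(mode)
  out <- lapply(tracks, function(tr) {
    if (is.null(tr$labels))
      stop("pooling: track '", tr$clip_id, "' has no labels", call. = FALSE)
    s <- if (mode == "offline") {
      if (is.null(tr$normalized)) tr <- normalize_track(tr)
      tr$normalized
    } else tr$raw
    ok <- !is.na(s)
    data.frame(clip_id = tr$clip_id, score = s[ok], label = tr$labels[ok])
  })
  do.call(rbind, out)
}

#' Grid search for the alarm threshold
#'
#' Evaluates each candidate threshold on the pooled scored frames and
#' returns the maximiser of the objective; ties break toward the larger
#' threshold (fewer alarms). `objective = "youden"` (sensitivity +
#' specificity - 1) requires both classes among the pooled frames;
#' `objective = "normal_quantile"` needs no fall labels and returns the
#' grid value closest from above to the `q`-quantile of the normal-frame
#' scores. The protocol leaves open whether threshold selection may see
#' fall labels, so the caller must pick the objective explicitly.
#'
#' @param tracks list of labelled `score_track`s.
#' @param grid numeric vector of candidate thresholds.
#' @param objective `"youden"` or `"normal_quantile"`.
#' @param mode pooled score variant: `"offline"` (normalised) or
#'   `"online"` (raw).
#' @param q quantile for the `normal_quantile` objective.
#' @return The selected threshold.
#' @export
grid_search_threshold <- function(tracks, grid,
                                  objective = c("youden", "normal_quantile"),
                                  mode = c("offline", "online"), q = 0.95) {
  objective <- match.arg(objective)
  mode <- match.arg(mode)
  if (length(grid) == 0L)
    stop("grid_search_threshold: empty grid", call. = FALSE)
  pool <- .pool_tracks(tracks, mode)
  grid <- sort(grid)
  if (objective == "normal_quantile") {
    qn <- quantile(pool$score[pool$label == 0L], q, names = FALSE)
    above <- grid[grid >= qn]
    return(if (length(above) > 0L) above[1L] else grid[length(grid)])
  }
  if (length(unique(pool$label)) < 2L)
    stop("grid_search_threshold: Youden objective needs both classes",
         call. = FALSE)
  j <- vapply(grid, function(th) {
    cm <- confusion_at(pool$score, pool$label, th)
    cm$sensitivity + cm$specificity - 1
  }, numeric(1))
  grid[max(which(j == max(j)))]
}

#' Write a score track to CSV
#'
#' Columns: `frame_index` (1-based), `raw_theta`, `normalized_score`,
#' `label` (empty when the clip is unlabelled).
#'
#' @param track a `score_track`.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_scores <- function(track, path) {
  n <- length(track$raw)
  df <- data.frame(frame_index = seq_len(n), raw_theta = track$raw,
                   normalized_score = track$normalized %||%
                     rep(NA_real_, n),
                   label = track$labels %||% rep(NA_integer_, n))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a score track written by [write_scores()]
#'
#' @param path CSV file.
#' @param clip_id identifier to attach.
#' @return A `score_track`.
#' @export
read_scores <- function(path, clip_id = basename(path)) {
  df <- read.csv(path)
  labels <- if (all(is.na(df$label))) NULL else as.integer(df$label)
  norm <- if (all(is.na(df$normalized_score))) NULL else df$normalized_score
  structure(list(clip_id = clip_id, raw = df$raw_theta, normalized = norm,
                 labels = labels, threshold = NULL, method = "angle"),
            class = "score_track")
}
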