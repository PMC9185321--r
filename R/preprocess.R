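#' Preprocessing configuration
#'
#' @param target_size output side length in pixels; frames are resized to
#'   `target_size x target_size` (256 at full scale, 64 for the desk-scale
#'   presets).
#' @param invalid_value pixel value that marks an undefined depth reading
#'   (hole); default 0.
#' @param fill_max_iters cap on diffusion passes in [fill_holes()] before
#'   the nearest-valid-neighbour fallback takes over.
#' @param source_range optional length-2 numeric, the pixel range mapped to
#'   `[-1, 1]`; defaults to the clip's declared `value_range`.
#' @param fill_holes logical; disable for hole-free (e.g. thermal) input.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(target_size = 64L, invalid_value = 0,
                              fill_max_iters = 50L, source_range = NULL,
                              fill_holes = TRUE) {
  stopifnot(target_size >= 16L, fill_max_iters >= 1L)
  structure(list(target_size = as.integer(target_size),
                 invalid_value = invalid_value,
                 fill_max_iters = as.integer(fill_max_iters),
                 source_range = source_range,
                 fill_holes = isTRUE(fill_holes)),
            class = "preprocess_config")
}

#' Fill undefined depth pixels
#'
#' Depth sensors leave holes (occlusion, scattering, transparency) stored
#' as a sentinel value. Holes are repaired by iterative diffusion: every
#' invalid pixel with at least one valid 8-neighbour takes the mean of its
#' valid neighbours, repeatedly, until no holes remain or `max_iters`
#' passes have run; any stragglers take the value of their nearest valid
#' pixel. Valid pixels are never altered, and filled values always lie
#' within the range of the valid input pixels.
#'
#' @param frame numeric matrix.
#' @param invalid_value sentinel marking holes.
#' @param max_iters diffusion pass cap.
#' @return Matrix with no pixel equal to `invalid_value`'s hole mask.
#' @export
fill_holes <- function(frame, invalid_value = 0, max_iters = 50L) {
  stopifnot(is.matrix(frame))
  hole <- frame == invalid_value
  if (all(hole))
    stop("fill_holes: frame contains no valid pixels", call. = FALSE)
  if (!any(hole)) return(frame)
  .fill_holes_cpp(frame, hole, as.integer(max_iters))
}

#' Resize a frame and rescale intensities to [-1, 1]
#'
#' Bilinear resampling to `target_size x target_size`, then the affine map
#' sending `source_range[1]` to -1 and `source_range[2]` to +1, clipped.
#'
#' @param frame numeric matrix (already hole-filled).
#' @param config a [preprocess_config()].
#' @param source_range length-2 numeric `(lo, hi)`, `hi > lo`.
#' @return `target_size x target_size` matrix with values in `[-1, 1]`.
#' @export
resize_normalize <- function(frame, config = preprocess_config(),
                             source_range) {
  lo <- source_range[1]
  hi <- source_range[2]
  if (!(hi > lo))
    stop("resize_normalize: degenerate source range [", lo, ", ", hi, "]",
         call. = FALSE)
  s <- config$target_size
  out <- if (all(dim(frame) == c(s, s))) frame
         else .resize_bilinear_cpp(frame, s, s)
  out <- 2 * (out - lo) / (hi - lo) - 1
  out[out > 1] <- 1
  out[out < -1] <- -1
  out
}

#' Preprocess every frame of a clip
#'
#' Applies [fill_holes()] (unless disabled) then [resize_normalize()] to
#' each frame; labels and fps carry through unchanged and the resulting
#' clip declares `value_range = c(-1, 1)`.
#'
#' @param clip a [video_clip()].
#' @param config a [preprocess_config()].
#' @return A preprocessed [video_clip()].
#' @export
preprocess_clip <- function(clip, config = preprocess_config()) {
  stopifnot(inherits(clip, "video_clip"))
  n <- n_frames(clip)
  if (n == 0L) stop("preprocess_clip: empty clip", call. = FALSE)
  sr <- config$source_range %||% clip$value_range
  s <- config$target_size
  out <- array(0, c(s, s, n))
  for (t in seq_len(n)) {
    f <- clip$frames[, , t]
    if (config$fill_holes) {
      f <- tryCatch(
        fill_holes(f, config$invalid_value, config$fill_max_iters),
        error = function(e) stop("preprocess_clip: frame ", t, " of '",
                                 clip$clip_id, "': ", conditionMessage(e),
                                 call. = FALSE))
    }
    out[, , t] <- resize_normalize(f, config, sr)
  }
  video_clip(out, labels = clip$labels, fps = clip$fps,
             clip_id = clip$clip_id, value_range = c(-1, 1))
}
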