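#' Construct a video clip
#'
#' A clip is an ordered stack of single-channel frames with optional
#' per-frame binary fall labels. Frames are stored as an `H x W x T` numeric
#' array; `value_range` declares the pixel range the values live in (e.g.
#' `c(0, 255)` for 8-bit files, `c(0, 1)` for synthetic clips, `c(-1, 1)`
#' after preprocessing).
#'
#' @param frames `H x W x T` numeric array, or a list of equally sized
#'   matrices (one per frame, in temporal order).
#' @param labels optional integer vector of 0/1 flags, one per frame
#'   (1 = fall).
#' @param fps frames per second of the source video.
#' @param clip_id identifier string.
#' @param value_range length-2 numeric, declared pixel range.
#' @return An object of class `video_clip`.
#' @export
video_clip <- function(frames, labels = NULL, fps = 30, clip_id = "clip",
                       value_range = c(0, 1)) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L)
      stop("video_clip: frames have inconsistent sizes", call. = FALSE)
    frames <- array(unlist(frames), c(dims[[1]], length(frames)))
  }
  if (length(dim(frames)) != 3L)
    stop("video_clip: frames must be an H x W x T array", call. = FALSE)
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != dim(frames)[3])
      stop("video_clip: ", length(labels), " labels for ",
           dim(frames)[3], " frames", call. = FALSE)
    if (!all(labels %in% c(0L, 1L)))
      stop("video_clip: labels must be 0/1", call. = FALSE)
  }
  structure(list(frames = frames, labels = labels, fps = fps,
                 clip_id = clip_id,
                 value_range = as.numeric(value_range)),
            class = "video_clip")
}

#' @export
print.video_clip <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<video_clip '%s'> %d frames of %dx%d, range [%g, %g]%s\n",
              x$clip_id, d[3], d[1], d[2], x$value_range[1], x$value_range[2],
              if (is.null(x$labels)) ""
              else sprintf(", %d fall frame(s)", sum(x$labels))))
  invisible(x)
}

#' Number of frames in a clip
#' @param clip a `video_clip`.
#' @return integer frame count.
#' @export
n_frames <- function(clip) dim(clip$frames)[3]

.png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 25L)
  if (length(hdr) < 25L) stop("not a PNG file: ", path, call. = FALSE)
  as.integer(hdr[25L])
}

#' Load a clip from a directory of PNG frames
#'
#' Frames are single-channel 8- or 16-bit PNG files whose names sort into
#' temporal order (the writer uses zero-padded 6-digit indices). Pixel
#' values are returned in the file's native integer range (0..255 or
#' 0..65535), recorded in `value_range`.
#'
#' @param path directory containing the frame images.
#' @param label_path optional text file with one 0/1 flag per line, line i
#'   labelling frame i.
#' @param fps frames per second to record on the clip.
#' @return A [video_clip()].
#' @export
load_clip <- function(path, label_path = NULL, fps = 30) {
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L)
    stop("load_clip: no PNG frames in ", path, call. = FALSE)
  depth <- .png_bit_depth(files[[1L]])
  maxval <- 2^depth - 1
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) {
      if (dim(img)[3] > 2L)
        stop("load_clip: ", f, " is not single-channel", call. = FALSE)
      img <- img[, , 1L]
    }
    round(img * maxval)
  })
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1L)
    stop("load_clip: inconsistent frame sizes in ", path, call. = FALSE)
  labels <- NULL
  if (!is.null(label_path)) {
    labels <- as.integer(readLines(label_path))
    if (length(labels) != length(frames))
      stop("load_clip: ", length(labels), " labels for ",
           length(frames), " frames", call. = FALSE)
  } else {
    default_labels <- file.path(path, "labels.txt")
    if (file.exists(default_labels))
      labels <- as.integer(readLines(default_labels))
  }
  video_clip(frames, labels = labels, fps = fps, clip_id = basename(path),
             value_range = c(0, maxval))
}

#' Write a clip as a directory of PNG frames
#'
#' Values are affinely mapped from the clip's `value_range` to the target
#' bit depth and rounded. Frames become `000000.png`, `000001.png`, ...;
#' labels, when present, are written to `labels.txt` (one 0/1 per line).
#'
#' @param clip a [video_clip()].
#' @param path output directory (created if missing).
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_clip <- function(clip, path, bit_depth = 8L) {
  stopifnot(inherits(clip, "video_clip"), bit_depth %in% c(8L, 16L))
  if (n_frames(clip) == 0L) stop("write_clip: empty clip", call. = FALSE)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path))
    stop("write_clip: cannot create ", path, call. = FALSE)
  vr <- clip$value_range
  maxval <- 2^bit_depth - 1
  for (t in seq_len(n_frames(clip))) {
    f <- clip$frames[, , t]
    q <- round((f - vr[1]) / (vr[2] - vr[1]) * maxval)
    storage.mode(q) <- "integer"
    .write_png_gray_cpp(q, file.path(path, sprintf("%06d.png", t - 1L)),
                        as.integer(bit_depth))
  }
  if (!is.null(clip$labels))
    writeLines(as.character(clip$labels), file.path(path, "labels.txt"))
  invisible(path)
}

#' Cut a clip into 8-in / 8-out training windows
#'
#' Each sample pairs an input window of 8 consecutive frames
#' (`F[t-7] .. F[t]`) with a target window shifted 4 frames forward
#' (`F[t-3] .. F[t+4]`), so the last 4 target frames are the future the
#' generator must predict. Windows that would cross the clip boundary are
#' dropped, never padded. Anchors (the index of `F[t]`, 1-based) run
#' 8, 8+stride, ... while `t + 4 <= n_frames`.
#'
#' @param clip a [video_clip()].
#' @param stride anchor step between consecutive samples.
#' @return List of `sequence_sample` objects, each with `input_window` and
#'   `target_window` (`H x W x 8` arrays) and `anchor_index`. Clips shorter
#'   than 12 frames yield an empty list.
#' @export
window_sequences <- function(clip, stride = 1L) {
  stopifnot(inherits(clip, "video_clip"), stride >= 1L)
  n <- n_frames(clip)
  if (n < 12L) {
    message("window_sequences: clip '", clip$clip_id, "' has ", n,
            " frames (< 12), no windows")
    return(list())
  }
  anchors <- seq(8L, n - 4L, by = as.integer(stride))
  lapply(anchors, function(t) {
    structure(list(input_window = clip$frames[, , (t - 7L):t, drop = FALSE],
                   target_window = clip$frames[, , (t - 3L):(t + 4L),
                                               drop = FALSE],
                   anchor_index = t),
              class = "sequence_sample")
  })
}
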