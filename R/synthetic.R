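# Synthetic depth-like video: a bright elliptical subject over a darker
# static ramp background, with depth-sensor hole pixels and frame jitter.
# Normal behaviours (walk / sit / idle) move smoothly; a fall is a fast
# simultaneous rotation-and-drop of the ellipse -- the detector must learn
# that falls are fast, unusual motions, not unusual poses.

#' Scene parameters for the synthetic simulator
#'
#' @param frame_size side length in pixels.
#' @param background_range value range of the static vertical background
#'   ramp (darker than the subject).
#' @param furniture optional opaque rectangle drawn over the subject:
#'   `list(x0, y0, w, h, value)` in pixel units (x = column, y = row).
#' @param subject_value fill intensity of the subject ellipse.
#' @param second_subject draw an independent second person (a walking
#'   ellipse with its own seed-derived start) for multi-person scenes.
#' @param seed RNG seed controlling the subject's start position and phase.
#' @return A `scene_params` list.
#' @export
scene_params <- function(frame_size = 64L, background_range = c(0.1, 0.4),
                         furniture = NULL, subject_value = 0.8,
                         second_subject = FALSE, seed = 1L) {
  stopifnot(frame_size >= 16L,
            subject_value > max(background_range) ||
              subject_value < min(background_range))
  if (!is.null(furniture)) {
    stopifnot(all(c("x0", "y0", "w", "h", "value") %in% names(furniture)),
              furniture$x0 >= 1, furniture$y0 >= 1,
              furniture$x0 + furniture$w - 1 <= frame_size,
              furniture$y0 + furniture$h - 1 <= frame_size)
  }
  structure(list(frame_size = as.integer(frame_size),
                 background_range = as.numeric(background_range),
                 furniture = furniture,
                 subject_value = subject_value,
                 second_subject = isTRUE(second_subject),
                 seed = as.integer(seed)),
            class = "scene_params")
}

#' Sensor-noise parameters for the synthetic simulator
#'
#' @param p_hole per-pixel probability (per frame) of an undefined depth
#'   reading, stored as value 0; must lie in `[0, 0.3]`.
#' @param jitter_sigma standard deviation of additive per-pixel Gaussian
#'   frame jitter, in pixel-value units (frames live in `[0, 1]`).
#' @param seed RNG seed for the noise draws.
#' @return A `noise_params` list.
#' @export
noise_params <- function(p_hole = 0.05, jitter_sigma = 0.02, seed = 1L) {
  stopifnot(p_hole >= 0, p_hole <= 0.3, jitter_sigma >= 0)
  structure(list(p_hole = p_hole, jitter_sigma = jitter_sigma,
                 seed = as.integer(seed)),
            class = "noise_params")
}

.background <- function(scene) {
  s <- scene$frame_size
  br <- scene$background_range
  matrix(rep(br[1] + (seq_len(s) - 1) / (s - 1) * (br[2] - br[1]), s), s, s)
}

# Anti-aliased filled ellipse; state = list(cx, cy, a, b, phi) with a the
# semi-axis along the body's width, b along its height, phi the body tilt
# (0 = standing upright, pi/2 = lying).
.draw_ellipse <- function(scene, f, state) {
  s <- scene$frame_size
  xs <- matrix(rep(seq_len(s), each = s), s, s) - state$cx   # columns
  ys <- matrix(rep(seq_len(s), s), s, s) - state$cy          # rows
  cp <- cos(state$phi)
  sp <- sin(state$phi)
  q <- ((xs * cp + ys * sp) / state$a)^2 +
       ((-xs * sp + ys * cp) / state$b)^2
  alpha <- pmin(1, pmax(0, (1 - sqrt(q)) * min(state$a, state$b) + 0.5))
  f * (1 - alpha) + scene$subject_value * alpha
}

.render_frame <- function(scene, state, bg = NULL, furniture = NULL,
                          state2 = NULL) {
  f <- if (is.null(bg)) .background(scene) else bg
  if (!is.null(state2)) f <- .draw_ellipse(scene, f, state2)
  if (!is.null(state)) f <- .draw_ellipse(scene, f, state)
  fur <- furniture %||% scene$furniture
  if (!is.null(fur)) {
    rows <- fur$y0:(fur$y0 + fur$h - 1)
    cols <- fur$x0:(fur$x0 + fur$w - 1)
    f[rows, cols] <- fur$value
  }
  f
}

.apply_noise <- function(frames, noise) {
  if (noise$jitter_sigma == 0 && noise$p_hole == 0) return(frames)
  with_seed(noise$seed, {
    if (noise$jitter_sigma > 0) {
      frames <- frames + array(rnorm(length(frames), sd = noise$jitter_sigma),
                               dim(frames))
      frames[frames > 1] <- 1
      frames[frames < 0.02] <- 0.02   # keep clear of the hole sentinel 0
    }
    if (noise$p_hole > 0) {
      holes <- array(runif(length(frames)) < noise$p_hole, dim(frames))
      frames[holes] <- 0
    }
    frames
  })
}

# Start state of the subject, drawn from the scene seed.
.subject_start <- function(scene) {
  s <- scene$frame_size
  with_seed(scene$seed, {
    list(cx = s * runif(1, 0.35, 0.65), cy = s * runif(1, 0.45, 0.55),
         a = 0.10 * s, b = 0.22 * s, phi = 0,
         phase = runif(1, 0, 2 * pi))
  })
}

# Independent second walker for multi-person scenes (NULL states when off).
.second_trajectory <- function(scene, n_frames) {
  if (!isTRUE(scene$second_subject)) return(vector("list", n_frames))
  sc2 <- scene
  sc2$seed <- scene$seed + 7717L
  sc2$second_subject <- FALSE
  .normal_trajectory(sc2, "walk", n_frames)
}

.normal_trajectory <- function(scene, behavior, n_frames) {
  st <- .subject_start(scene)
  s <- scene$frame_size
  lapply(seq_len(n_frames), function(t) {
    out <- st
    if (behavior == "walk") {
      # horizontal sinusoid; max per-frame step = 2*pi*A/T = 0.0135 * s px,
      # well under the fall's minimum drop rate of 0.05 * s px per frame
      out$cx <- st$cx + 0.12 * s * sin(2 * pi * (t - 1) / 56 + st$phase)
    } else if (behavior == "sit") {
      dur <- max(20L, round(0.6 * n_frames))
      u <- min(1, (t - 1) / dur)
      out$cy <- st$cy + 0.18 * s * u
      out$b <- st$b - 0.07 * s * u
      out$a <- st$a + 0.03 * s * u
    }
    # idle: static
    out
  })
}

#' Generate a synthetic normal-activity clip
#'
#' The subject moves smoothly: `walk` follows a horizontal sinusoid with a
#' per-frame centroid step below 2 px (at the 64 px default), `sit` is a
#' slow vertical descent with aspect change, `idle` is static. All labels
#' are 0. Deterministic given the scene and noise seeds.
#'
#' @param scene a [scene_params()].
#' @param behavior one of `"walk"`, `"sit"`, `"idle"`.
#' @param n_frames clip length (>= 12).
#' @param noise a [noise_params()].
#' @param clip_id identifier for the clip.
#' @return A labelled [video_clip()] with `value_range = c(0, 1)`.
#' @export
generate_normal_clip <- function(scene, behavior = c("walk", "sit", "idle"),
                                 n_frames = 48L, noise = noise_params(),
                                 clip_id = paste0("normal_", behavior[1])) {
  behavior <- match.arg(behavior)
  stopifnot(n_frames >= 12L)
  traj <- .normal_trajectory(scene, behavior, n_frames)
  traj2 <- .second_trajectory(scene, n_frames)
  bg <- .background(scene)
  frames <- array(0, c(scene$frame_size, scene$frame_size, n_frames))
  for (t in seq_len(n_frames))
    frames[, , t] <- .render_frame(scene, traj[[t]], bg = bg,
                                   state2 = traj2[[t]])
  frames <- .apply_noise(frames, noise)
  video_clip(frames, labels = rep(0L, n_frames), clip_id = clip_id,
             value_range = c(0, 1))
}

#' Generate a synthetic fall clip
#'
#' Frames before `fall_onset` follow a normal behaviour; during the fall
#' the ellipse rotates from upright to horizontal while its centroid drops
#' by 0.3 of the frame height within `fall_duration` frames; afterwards the
#' subject lies still, optionally partially covered by a furniture
#' rectangle. Labels are 1 on the fall-motion frames
#' (`fall_onset .. fall_onset + fall_duration - 1`), and optionally on the
#' post-fall frames.
#'
#' @param scene a [scene_params()].
#' @param n_frames clip length.
#' @param fall_onset 1-based index of the first fall frame; must be >= 9 so
#'   at least one full input window precedes the fall.
#' @param fall_duration number of fall-motion frames, 3..6.
#' @param noise a [noise_params()].
#' @param occlude_after draw an opaque rectangle over part of the lying
#'   subject on post-fall frames.
#' @param pre_behavior behaviour before the fall.
#' @param label_post_fall extend label 1 to the lying-still frames.
#' @param clip_id identifier for the clip.
#' @return A labelled [video_clip()].
#' @export
generate_fall_clip <- function(scene, n_frames = 48L, fall_onset = 24L,
                               fall_duration = 4L, noise = noise_params(),
                               occlude_after = FALSE,
                               pre_behavior = "walk",
                               label_post_fall = FALSE,
                               clip_id = "fall") {
  stopifnot(fall_duration >= 3L, fall_duration <= 6L)
  if (fall_onset < 9L || fall_onset + fall_duration > n_frames)
    stop("generate_fall_clip: infeasible fall_onset/fall_duration for ",
         n_frames, " frames", call. = FALSE)
  s <- scene$frame_size
  traj <- .normal_trajectory(scene, pre_behavior, n_frames)
  pre <- traj[[fall_onset - 1L]]
  drop_px <- 0.3 * s
  for (t in fall_onset:n_frames) {
    u <- min(1, (t - fall_onset + 1) / fall_duration)
    st <- pre
    st$phi <- u * pi / 2
    st$cy <- min(pre$cy + u * drop_px, s - st$a - 1)
    st$cx <- pre$cx + 0.08 * s * u
    traj[[t]] <- st
  }
  fur <- NULL
  if (occlude_after) {
    ly <- traj[[n_frames]]
    x0 <- max(1L, round(ly$cx - ly$b))
    fur <- list(x0 = x0, y0 = max(1L, round(ly$cy - ly$a - 2)),
                w = min(round(1.1 * ly$b), s - x0),
                h = min(round(2 * ly$a + 4), s - round(ly$cy - ly$a - 2)),
                value = 0.55)
  }
  bg <- .background(scene)
  frames <- array(0, c(s, s, n_frames))
  fall_end <- fall_onset + fall_duration - 1L
  traj2 <- .second_trajectory(scene, n_frames)
  for (t in seq_len(n_frames)) {
    f_fur <- if (!is.null(fur) && t > fall_end) fur else NULL
    frames[, , t] <- .render_frame(scene, traj[[t]], bg = bg,
                                   furniture = f_fur,
                                   state2 = traj2[[t]])
  }
  frames <- .apply_noise(frames, noise)
  labels <- integer(n_frames)
  labels[fall_onset:fall_end] <- 1L
  if (label_post_fall && fall_end < n_frames)
    labels[(fall_end + 1L):n_frames] <- 1L
  video_clip(frames, labels = labels, clip_id = clip_id,
             value_range = c(0, 1))
}

#' Generate a reproducible train/test dataset
#'
#' The training split contains only normal-activity clips (the unsupervised
#' protocol trains on normal cases alone); the test split mixes normal and
#' fall clips. Per-clip seeds derive deterministically from `master_seed`,
#' so regeneration is bit-identical.
#'
#' @param n_train_clips,n_test_normal,n_test_fall split sizes (all >= 1).
#' @param scene base [scene_params()] (per-clip seeds are overridden).
#' @param noise base [noise_params()] (per-clip seeds are overridden).
#' @param master_seed integer master seed.
#' @param n_frames frames per clip.
#' @return `list(train = <clips>, test = <clips>)`.
#' @export
make_dataset <- function(n_train_clips = 30L, n_test_normal = 10L,
                         n_test_fall = 10L, scene = scene_params(),
                         noise = noise_params(), master_seed = 1L,
                         n_frames = 48L) {
  stopifnot(n_train_clips >= 1L, n_test_normal >= 1L, n_test_fall >= 1L,
            n_frames >= 16L)  # fall clips need onset >= 9 plus the fall
  behaviors <- c("walk", "sit", "idle")
  dseed <- function(k) (as.double(master_seed) * 100003 + k * 7919) %%
    2147483647
  mk_scene <- function(k) {
    sc <- scene
    sc$seed <- as.integer(dseed(k))
    sc
  }
  mk_noise <- function(k) {
    nz <- noise
    nz$seed <- as.integer(dseed(k) + 1)
    nz
  }
  train <- lapply(seq_len(n_train_clips), function(i) {
    generate_normal_clip(mk_scene(i), behaviors[(i - 1L) %% 3L + 1L],
                         n_frames, mk_noise(i),
                         clip_id = sprintf("train_%03d", i))
  })
  test_n <- lapply(seq_len(n_test_normal), function(i) {
    k <- n_train_clips + i
    generate_normal_clip(mk_scene(k), behaviors[(i - 1L) %% 3L + 1L],
                         n_frames, mk_noise(k),
                         clip_id = sprintf("test_normal_%03d", i))
  })
  test_f <- lapply(seq_len(n_test_fall), function(i) {
    k <- n_train_clips + n_test_normal + i
    dur <- min(3L + as.integer(dseed(k + 31) %% 4L), n_frames - 10L)
    lo <- min(16L, n_frames - dur - 1L)   # prefer mid-clip onsets
    hi <- n_frames - dur - 1L             # leave >= 1 post-fall frame
    onset <- lo + as.integer(dseed(k + 17) %% (hi - lo + 1L))
    generate_fall_clip(mk_scene(k), n_frames, fall_onset = onset,
                       fall_duration = dur, noise = mk_noise(k),
                       clip_id = sprintf("test_fall_%03d", i))
  })
  list(train = train, test = c(test_n, test_f))
}
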