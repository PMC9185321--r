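test_that("idle clips with noise off are static", {
  cl <- generate_normal_clip(tiny_scene(), "idle", 12L, noise_off())
  for (t in 2:12)
    expect_identical(cl$frames[, , t], cl$frames[, , 1])
  expect_identical(cl$labels, rep(0L, 12L))
})

test_that("normal motion is smooth (centroid tracking oracle)", {
  s <- 64L
  walk <- generate_normal_clip(tiny_scene(seed = 2L, size = s), "walk", 40L,
                               noise_off())
  expect_lte(max_centroid_step(walk), 2)
  sit <- generate_normal_clip(tiny_scene(seed = 3L, size = s), "sit", 30L,
                              noise_off())
  expect_lte(max_centroid_step(sit), 2)
  idle <- generate_normal_clip(tiny_scene(seed = 4L, size = s), "idle", 15L,
                               noise_off())
  expect_lte(max_centroid_step(idle), 0.5)
})

test_that("hole fraction concentrates around p_hole", {
  cl <- generate_normal_clip(tiny_scene(seed = 5L, size = 64L), "walk", 30L,
                             noise_params(p_hole = 0.1, jitter_sigma = 0,
                                          seed = 6L))
  frac <- mean(cl$frames == 0)
  expect_lt(abs(frac - 0.1), 0.02)
})

test_that("falls are fast: rotation + drop dominates pre-fall motion", {
  s <- 64L
  cl <- generate_fall_clip(tiny_scene(seed = 7L, size = s), n_frames = 40L,
                           fall_onset = 20L, fall_duration = 5L,
                           noise = noise_off())
  pre_max <- max_centroid_step(cl, 1:19)
  fall_max <- max_centroid_step(cl, 19:25)
  expect_gt(fall_max, 3 * pre_max)

  # centroid drops by at least a quarter of the frame height
  c_before <- subject_centroid(cl$frames[, , 19])
  c_after <- subject_centroid(cl$frames[, , 25])
  expect_gte(c_after[1] - c_before[1], s / 4)

  # labels cover exactly the fall motion frames
  expect_identical(which(cl$labels == 1L), 20:24)
})

test_that("fall onset/duration feasibility is validated", {
  sc <- tiny_scene()
  expect_error(generate_fall_clip(sc, 20L, fall_onset = 5L), "infeasible")
  expect_error(generate_fall_clip(sc, 20L, fall_onset = 18L,
                                  fall_duration = 4L), "infeasible")
  expect_error(generate_fall_clip(sc, 40L, fall_onset = 20L,
                                  fall_duration = 10L))
})

test_that("post-fall occlusion covers a third of the subject", {
  s <- 64L
  base <- generate_fall_clip(tiny_scene(seed = 8L, size = s), n_frames = 36L,
                             fall_onset = 20L, fall_duration = 4L,
                             noise = noise_off(), occlude_after = FALSE)
  occl <- generate_fall_clip(tiny_scene(seed = 8L, size = s), n_frames = 36L,
                             fall_onset = 20L, fall_duration = 4L,
                             noise = noise_off(), occlude_after = TRUE)
  last_clear <- base$frames[, , 36]
  last_occl <- occl$frames[, , 36]
  subj <- last_clear > 0.6
  covered <- subj & (last_occl == 0.55)
  expect_gte(sum(covered) / sum(subj), 0.3)
})

test_that("multi-person scenes add a second moving subject", {
  one <- generate_normal_clip(tiny_scene(seed = 11L, size = 64L), "idle",
                              16L, noise_off())
  sc2 <- tiny_scene(seed = 11L, size = 64L)
  sc2$second_subject <- TRUE
  two <- generate_normal_clip(sc2, "idle", 16L, noise_off())
  # more bright pixels, and the extra subject moves while the first idles
  expect_gt(sum(two$frames[, , 1] > 0.6), sum(one$frames[, , 1] > 0.6))
  expect_false(identical(two$frames[, , 1], two$frames[, , 10]))
  # off by default
  expect_false(scene_params()$second_subject)
})

test_that("datasets are deterministic, leak-free and normal-only in train", {
  ds1 <- make_dataset(3L, 2L, 2L, tiny_scene(), noise_params(0.05, 0.02),
                      master_seed = 42L, n_frames = 16L)
  ds2 <- make_dataset(3L, 2L, 2L, tiny_scene(), noise_params(0.05, 0.02),
                      master_seed = 42L, n_frames = 16L)
  expect_identical(ds1, ds2)

  ids_train <- vapply(ds1$train, `[[`, character(1), "clip_id")
  ids_test <- vapply(ds1$test, `[[`, character(1), "clip_id")
  expect_length(intersect(ids_train, ids_test), 0L)

  expect_true(all(vapply(ds1$train, function(cl) all(cl$labels == 0L),
                         logical(1))))
  n_fall <- sum(vapply(ds1$test, function(cl) any(cl$labels == 1L),
                       logical(1)))
  expect_identical(n_fall, 2L)
})

test_that("noise-free normal motion is strictly slower than fall motion", {
  ds <- make_dataset(3L, 3L, 3L, tiny_scene(size = 64L), noise_off(),
                     master_seed = 7L, n_frames = 32L)
  normal_max <- vapply(c(ds$train, Filter(function(cl) all(cl$labels == 0L),
                                          ds$test)),
                       max_centroid_step, numeric(1))
  fall_max <- vapply(Filter(function(cl) any(cl$labels == 1L), ds$test),
                     max_centroid_step, numeric(1))
  expect_lt(max(normal_max), min(fall_max))
})
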