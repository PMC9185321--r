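test_that("angular_score anchors, symmetry and scale invariance", {
  expect_equal(angular_score(c(1, 0), c(1, 0)), 0)
  expect_equal(angular_score(c(1, 0), c(0, 1)), pi / 2)
  expect_equal(angular_score(c(1, 0), c(-1, 0)), pi)
  expect_error(angular_score(c(0, 0), c(1, 0)), "zero-norm")
  expect_error(angular_score(c(1, 0), c(1, 0, 0)), "length")

  set.seed(41)
  for (k in 1:1000) {
    a <- rnorm(8)
    b <- rnorm(8)
    c_pos <- runif(1, 0.01, 100)
    th <- angular_score(a, b)
    expect_gte(th, 0)
    expect_lte(th, pi)
    expect_equal(angular_score(b, a), th, tolerance = 1e-12)
    expect_equal(angular_score(a, c_pos * b), th, tolerance = 1e-9)
  }
})

test_that("score_sample follows the encode-compare recipe", {
  g <- build_generator(tiny_gen_config(), seed = 51L)
  cl <- generate_normal_clip(tiny_scene(seed = 52L), "walk", 16L, noise_off())
  pp <- preprocess_clip(cl, preprocess_config(target_size = 32L))
  s <- window_sequences(pp)[[1]]

  th <- score_sample(g, s)
  expect_gte(th, 0)
  expect_lte(th, pi)
  # identity reconstruction scores zero (up to acos roundoff)
  v <- encode(g, s$target_window)
  expect_equal(angular_score(v, v), 0, tolerance = 1e-6)
  # matches the manual recipe
  manual <- angular_score(encode(g, generate(g, s$input_window)),
                          encode(g, s$target_window))
  expect_equal(th, manual)

  mse <- score_sample(g, s, method = "mse")
  expect_equal(mse, l2_loss(s$target_window[, , 5:8],
                            generate(g, s$input_window)[, , 5:8]))

  # future-frames-only V1 variant: authentic first 4 + predicted last 4
  th_f <- score_sample(g, s, v1_source = "future")
  mixed <- s$target_window
  mixed[, , 5:8] <- generate(g, s$input_window)[, , 5:8]
  expect_equal(th_f, angular_score(encode(g, mixed),
                                   encode(g, s$target_window)))
})

test_that("score_clip covers exactly the predicted-future frames", {
  g <- build_generator(tiny_gen_config(), seed = 53L)
  mk <- function(n) {
    cl <- generate_normal_clip(tiny_scene(seed = n), "walk", n, noise_off())
    preprocess_clip(cl, preprocess_config(target_size = 32L))
  }
  # 12 frames, stride 1: single window -> scores on frames 9..12 (1-based)
  tr <- score_clip(g, mk(12L), inference_stride = 1L)
  expect_identical(which(!is.na(tr$raw)), 9:12)

  # 16 frames: per-frame mean over covering windows equals the brute force
  cl16 <- mk(16L)
  tr16 <- score_clip(g, cl16, inference_stride = 1L)
  samples <- window_sequences(cl16, stride = 1L)
  acc <- numeric(16)
  cnt <- integer(16)
  for (s in samples) {
    th <- score_sample(g, s)
    idx <- (s$anchor_index + 1L):(s$anchor_index + 4L)
    acc[idx] <- acc[idx] + th
    cnt[idx] <- cnt[idx] + 1L
  }
  expect_equal(tr16$raw[cnt > 0], (acc / pmax(cnt, 1))[cnt > 0])
  expect_true(all(is.na(tr16$raw[cnt == 0])))

  # stride 3 coverage equals the enumeration oracle
  cl30 <- mk(30L)
  tr3 <- score_clip(g, cl30, inference_stride = 3L)
  anchors <- oracle_anchors(30L, 3L)
  covered <- sort(unique(unlist(lapply(anchors, function(t) (t + 1):(t + 4)))))
  expect_identical(which(!is.na(tr3$raw)), covered)
})

test_that("normalize_track rescales to [0, 1] and preserves ranks", {
  tr <- structure(list(clip_id = "x", raw = c(NA, 0.2, 0.5, 0.8),
                       normalized = NULL, labels = c(0L, 0L, 0L, 1L),
                       threshold = NULL, method = "angle"),
                  class = "score_track")
  out <- normalize_track(tr)
  expect_equal(out$normalized, c(NA, 0, 0.5, 1))

  const <- tr
  const$raw <- c(NA, 0.4, 0.4, 0.4)
  expect_equal(normalize_track(const)$normalized, c(NA, 0, 0, 0))

  set.seed(42)
  tr$raw <- c(NA, runif(3))
  out <- normalize_track(tr)
  ok <- !is.na(tr$raw)
  expect_equal(frame_auc(out$normalized[ok], tr$labels[ok]),
               frame_auc(tr$raw[ok], tr$labels[ok]))

  empty <- tr
  empty$raw <- rep(NA_real_, 4)
  expect_error(normalize_track(empty), "no scored frames")
})

test_that("grid_search_threshold matches the exhaustive oracle", {
  mk_track <- function(raw, labels, id = "t") {
    normalize_track(structure(
      list(clip_id = id, raw = raw, normalized = NULL, labels = labels,
           threshold = NULL, method = "angle"),
      class = "score_track"))
  }
  # perfectly separated: with the strictly-above alarm rule every
  # threshold in [0.2, 0.8) attains J = 1; ties break toward the largest
  sep <- mk_track(c(0.1, 0.2, 0.15, 0.8, 0.9, 1.0),
                  c(0L, 0L, 0L, 1L, 1L, 1L))
  grid <- seq(0.1, 0.9, by = 0.1)
  expect_equal(grid_search_threshold(list(sep), grid, "youden", "online"),
               0.7)

  one_class <- mk_track(runif(6), rep(0L, 6))
  expect_error(grid_search_threshold(list(one_class), grid, "youden",
                                     "online"), "both classes")
  expect_error(grid_search_threshold(list(sep), numeric(0)), "empty grid")

  set.seed(43)
  rnd <- mk_track(runif(50), sample(0:1, 50, replace = TRUE))
  got <- grid_search_threshold(list(rnd), grid, "youden", "online")
  j <- sapply(grid, function(th) {
    cm <- confusion_at(rnd$raw, rnd$labels, th)
    cm$sensitivity + cm$specificity - 1
  })
  expect_equal(got, max(grid[j == max(j)]))

  # normal-quantile fallback needs no fall labels
  thr <- grid_search_threshold(list(one_class), grid, "normal_quantile",
                               "online", q = 0.9)
  expect_true(thr %in% grid)
  expect_gte(thr, quantile(one_class$raw, 0.9) - 0.1)
})

test_that("score CSV round-trips", {
  tr <- normalize_track(structure(
    list(clip_id = "rt", raw = c(NA, 0.3, 0.6), normalized = NULL,
         labels = c(0L, 0L, 1L), threshold = NULL, method = "angle"),
    class = "score_track"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_scores(tr, f)
  back <- read_scores(f, clip_id = "rt")
  expect_equal(back$raw, tr$raw)
  expect_equal(back$normalized, tr$normalized)
  expect_identical(back$labels, tr$labels)
  expect_identical(colnames(read.csv(f)),
                   c("frame_index", "raw_theta", "normalized_score", "label"))
})
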