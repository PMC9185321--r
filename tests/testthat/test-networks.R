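test_that("generator obeys its shape, range and determinism contracts", {
  cfg <- tiny_gen_config()
  g1 <- build_generator(cfg, seed = 5L)
  g2 <- build_generator(cfg, seed = 5L)
  expect_identical(g1$enc, g2$enc)
  expect_identical(g1$dec, g2$dec)

  set.seed(6)
  x <- array(runif(32 * 32 * 8, -1, 1), c(32, 32, 8))
  y <- generate(g1, x)
  expect_equal(dim(y), c(32, 32, 8))
  expect_true(all(y >= -1 & y <= 1))
  expect_identical(generate(g1, x), y)   # reproducible across calls

  expect_error(generate(g1, x[, , 1:5]), "8")
  expect_error(generator_config(frames_in = 6L))
  expect_error(generator_config(latent_dim = 4L), "latent_dim")
})

test_that("parameter counts depend on config only", {
  n1 <- sum(sapply(build_generator(tiny_gen_config(), seed = 1L)$enc,
                   function(l) length(l$W) + length(l$b)))
  n2 <- sum(sapply(build_generator(tiny_gen_config(), seed = 99L)$enc,
                   function(l) length(l$W) + length(l$b)))
  expect_identical(n1, n2)
  d1 <- build_discriminator(discriminator_config(), seed = 1L)
  d2 <- build_discriminator(discriminator_config(), seed = 2L)
  expect_identical(lapply(d1$layers, function(l) dim(l$W)),
                   lapply(d2$layers, function(l) dim(l$W)))
})

test_that("encode returns the bottleneck vector and composes with generate", {
  g <- build_generator(tiny_gen_config(), seed = 7L)
  set.seed(8)
  w <- array(runif(32 * 32 * 8, -1, 1), c(32, 32, 8))
  v <- encode(g, w)
  expect_length(v, g$config$latent_dim)
  expect_identical(encode(g, w), v)
  expect_true(all(is.finite(v)))

  # encode(generate(...)) type-checks: the scoring path is well-defined
  v2 <- encode(g, generate(g, w))
  expect_length(v2, g$config$latent_dim)

  # very different windows produce a non-zero angle even untrained
  lo <- array(-1 + 0.01 * runif(32 * 32 * 8), c(32, 32, 8))
  hi <- array(1 - 0.01 * runif(32 * 32 * 8), c(32, 32, 8))
  expect_gt(angular_score(encode(g, lo), encode(g, hi)), 0)
})

test_that("discriminator receptive field matches the analytic arithmetic", {
  d70 <- build_discriminator(discriminator_config(70L), seed = 1L)
  expect_identical(d70$receptive_field, 70L)
  expect_identical(receptive_field(d70), 70L)
  # manual arithmetic over the layer stack: rf = 1 + sum (k-1) * prod strides
  rf <- 1L
  jump <- 1L
  for (l in d70$layers) {
    rf <- rf + (l$k - 1L) * jump
    jump <- jump * l$stride
  }
  expect_identical(rf, 70L)

  for (target in c(16L, 34L, 142L)) {
    d <- build_discriminator(discriminator_config(target), seed = 1L)
    expect_identical(d$receptive_field, target)
  }
  # off-grid request lands on the nearest family member
  d50 <- build_discriminator(discriminator_config(50L), seed = 1L)
  expect_true(d50$receptive_field %in% c(34L, 70L))

  expect_error(discriminator_config(10L))
})

test_that("discriminator outputs a patch score map", {
  d <- build_discriminator(discriminator_config(70L, base_channels = 4L),
                           seed = 3L)
  f <- matrix(runif(64 * 64, -1, 1), 64, 64)
  m <- discriminate(d, f)
  expect_true(is.matrix(m))
  expect_true(all(dim(m) > 1) && all(dim(m) < 64))
  d2 <- build_discriminator(discriminator_config(70L, base_channels = 4L),
                            seed = 3L)
  expect_equal(discriminate(d2, f), m)   # seed reproducibility
})

test_that("flow estimator satisfies its oracles", {
  est <- flow_estimator()
  S <- 64L
  xg <- outer(rep(1, S), seq_len(S))
  yg <- outer(seq_len(S), rep(1, S))
  tex <- function(x, y) 0.5 + 0.25 * sin(2 * pi * x / 24) +
    0.2 * cos(2 * pi * y / 20)
  b <- tex(xg, yg)

  f0 <- flow_estimate(est, b, b)
  expect_equal(dim(f0), c(S, S, 2L))
  expect_lt(mean(abs(f0)), 0.05)

  a <- tex(xg - 2, yg)   # content translated +2 px in x
  fl <- flow_estimate(est, a, b)
  interior <- 10:(S - 10)
  expect_lt(abs(mean(fl[interior, interior, 1]) - 2), 0.5)
  expect_lt(abs(mean(fl[interior, interior, 2])), 0.5)
})

test_that("a custom flow function can be plugged in", {
  fn <- function(a, b) array(1, c(dim(a), 2L))
  est <- flow_estimator(fn = fn)
  expect_equal(flow_estimate(est, matrix(0, 4, 4), matrix(0, 4, 4)),
               array(1, c(4, 4, 2)))
})

test_that("all four loss terms push gradient into every generator layer", {
  g <- build_generator(tiny_gen_config(), seed = 21L)
  d <- build_discriminator(discriminator_config(34L, base_channels = 4L),
                           seed = 22L)
  est <- flow_estimator()
  set.seed(23)
  x <- array(runif(32 * 32 * 8 * 2, -1, 1), c(32, 32, 8, 2))
  y <- array(runif(32 * 32 * 8 * 2, -1, 1), c(32, 32, 8, 2))
  fg <- fallgan:::.gen_forward(g, x, keep_cache = TRUE)
  yhat <- fg$out

  dys <- list(
    l2 = fallgan:::.l2_grad(y, yhat),
    gradient = {
      y3 <- yhat; dim(y3) <- c(32, 32, 16)
      t3 <- y; dim(t3) <- c(32, 32, 16)
      gg <- fallgan:::.gradient_loss_grad(y3, t3)
      dim(gg) <- dim(yhat)
      gg
    },
    flow = {
      dy <- array(0, dim(yhat))
      r <- fallgan:::.flow_loss_grad(est, yhat[, , 5, 1], y[, , 5, 1],
                                     x[, , 8, 1])
      dy[, , 5, 1] <- r$grad
      dy
    },
    adversarial = {
      fb <- fallgan:::.frames_as_batch(yhat)
      ff <- fallgan:::net_forward(d$layers, fb)
      bf <- fallgan:::net_backward(d$layers, ff$caches,
                                   (ff$out - 1) / length(ff$out),
                                   need_input_grad = TRUE)
      da <- bf$dx
      dim(da) <- dim(yhat)
      da
    })

  for (term in names(dys)) {
    bd <- fallgan:::net_backward(g$dec, fg$dec_caches, dys[[term]],
                                 need_input_grad = TRUE)
    be <- fallgan:::net_backward(g$enc, fg$enc_caches, bd$dx)
    norms <- c(
      vapply(be$grads, function(gr)
        if (is.null(gr)) NA_real_ else sum(abs(gr$dW)), numeric(1)),
      vapply(bd$grads, function(gr)
        if (is.null(gr)) NA_real_ else sum(abs(gr$dW)), numeric(1)))
    expect_true(all(norms[!is.na(norms)] > 0),
                label = paste("gradient reaches all layers for", term))
  }
})
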