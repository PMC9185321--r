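test_that("l2_loss hits its anchors and the brute-force oracle", {
  expect_equal(l2_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(l2_loss(c(0, 0), c(1, 1)), 1.0)
  set.seed(31)
  a <- matrix(rnorm(25), 5)
  b <- matrix(rnorm(25), 5)
  expect_equal(l2_loss(a, b), oracle_l2(a, b), tolerance = 1e-12)
  expect_error(l2_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("gradient_loss matches the double-loop oracle and is offset-invariant", {
  set.seed(32)
  for (rep in 1:5) {
    p <- matrix(rnorm(36), 6)
    y <- matrix(rnorm(36), 6)
    expect_equal(gradient_loss(p, y), oracle_gradient_loss(p, y),
                 tolerance = 1e-12)
  }
  y <- matrix(rnorm(64), 8)
  expect_equal(gradient_loss(y, y), 0)
  expect_equal(gradient_loss(y + 3.7, y), 0)        # offset one image
  expect_equal(gradient_loss(y + 1.1, y + 1.1), 0)  # offset both
  expect_gte(gradient_loss(matrix(rnorm(64), 8), y), 0)
})

test_that("adversarial losses hit their anchors and the looped oracle", {
  # stub discriminators with constant outputs
  const_d <- function(value) {
    d <- build_discriminator(discriminator_config(16L, base_channels = 2L),
                             seed = 1L)
    for (i in seq_along(d$layers)) {
      d$layers[[i]]$W[] <- 0
      d$layers[[i]]$b[] <- 0
    }
    d$layers[[length(d$layers)]]$b[] <- value
    d
  }
  w <- array(runif(32 * 32 * 8, -1, 1), c(32, 32, 8))
  w2 <- array(runif(32 * 32 * 8, -1, 1), c(32, 32, 8))

  expect_equal(adversarial_d_loss(const_d(0.5), w, w2), 0.25)
  expect_equal(adversarial_g_loss(const_d(1), w), 0)
  expect_equal(adversarial_g_loss(const_d(0), w), 0.5)

  # random maps vs the looped oracle (via a real discriminator)
  d <- build_discriminator(discriminator_config(16L, base_channels = 2L),
                           seed = 2L)
  real_maps <- lapply(1:8, function(f) discriminate(d, w[, , f]))
  fake_maps <- lapply(1:8, function(f) discriminate(d, w2[, , f]))
  expect_equal(adversarial_d_loss(d, w, w2),
               oracle_adv_d(real_maps, fake_maps), tolerance = 1e-12)
  expect_equal(adversarial_g_loss(d, w2), oracle_adv_g(fake_maps),
               tolerance = 1e-12)

  # a perfect discriminator reaches 0: real -> 1, fake -> 0
  expect_equal(oracle_adv_d(list(matrix(1, 3, 3)), list(matrix(0, 3, 3))), 0)
})

test_that("flow_loss is zero on identical inputs and positive on motion", {
  est <- flow_estimator()
  S <- 48L
  xg <- outer(rep(1, S), seq_len(S))
  yg <- outer(seq_len(S), rep(1, S))
  tex <- 0.5 + 0.3 * sin(2 * pi * xg / 20) * cos(2 * pi * yg / 24)
  nxt <- 0.5 + 0.3 * sin(2 * pi * (xg - 2) / 20) * cos(2 * pi * yg / 24)

  expect_equal(flow_loss(est, nxt, nxt, tex), 0)
  expect_gt(flow_loss(est, tex, nxt, tex), 0)   # predicted "no motion"

  # compositional oracle: equals direct recomputation from flow_estimate
  f1 <- flow_estimate(est, tex, tex)
  f2 <- flow_estimate(est, nxt, tex)
  expect_equal(flow_loss(est, tex, nxt, tex), mean(abs(f1 - f2)),
               tolerance = 1e-12)
})

test_that("flow loss gradient matches finite differences", {
  est <- flow_estimator()
  set.seed(33)
  S <- 24L
  a <- matrix(runif(S * S), S)
  b <- matrix(runif(S * S), S)
  cur <- matrix(runif(S * S), S)
  r <- fallgan:::.flow_loss_grad(est, a, b, cur)
  expect_equal(r$loss, flow_loss(est, a, b, cur), tolerance = 1e-12)
  eps <- 1e-6
  for (k in sample(S * S, 4)) {
    a2 <- a
    a2[k] <- a2[k] + eps
    num <- (flow_loss(est, a2, b, cur) - r$loss) / eps
    expect_equal(num, r$grad[k], tolerance = 1e-3)
  }
})

test_that("hybrid_g_loss combines terms with its weights", {
  w <- loss_weights(1, 1, 2, 0.05)
  total <- hybrid_g_loss(w, 0.1, 0.2, 0.05, 0.4)
  expect_equal(as.numeric(total), 0.42)
  expect_equal(attr(total, "breakdown"),
               c(l2 = 0.1, gradient = 0.2, flow = 0.05, adversarial = 0.4))

  only_l2 <- loss_weights(1, 0, 0, 0)
  expect_equal(as.numeric(hybrid_g_loss(only_l2, 0.3, 9, 9, 9)), 0.3)
  expect_equal(as.numeric(hybrid_g_loss(w, 0, 0, 0, 0)), 0)
  expect_error(hybrid_g_loss(w, NaN, 0, 0, 0), "l2")
  expect_error(loss_weights(0, 0, 0, 0))
  expect_error(loss_weights(-1, 1, 1, 1))
})
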