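# Minimal CNN framework: plain-R layer lists over C++ im2col/GEMM kernels.
# Tensors are R arrays with dim (H, W, C, N); weights (kh, kw, Cin, Cout).
# Only what the generator/discriminator need: conv2d (stride 1/2), leaky
# ReLU, tanh, nearest x2 upsampling, global average pooling, and Adam.

nn_conv <- function(cin, cout, k = 3L, stride = 1L, pad = 1L,
                    act = c("lrelu", "tanh", "linear")) {
  act <- match.arg(act)
  list(kind = "conv", cin = cin, cout = cout, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad), act = act,
       W = NULL, b = NULL)
}

nn_up <- function() list(kind = "up")

# He initialisation for leaky-ReLU layers, Glorot for the tanh output.
nn_init <- function(layers) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$kind != "conv") next
    fan_in <- l$k * l$k * l$cin
    sd <- if (l$act == "tanh") sqrt(1 / fan_in) else sqrt(2 / fan_in)
    layers[[i]]$W <- array(rnorm(l$k * l$k * l$cin * l$cout, sd = sd),
                           c(l$k, l$k, l$cin, l$cout))
    layers[[i]]$b <- numeric(l$cout)
  }
  layers
}

.lrelu <- function(x) .lrelu_fwd(x, FALSE)$y

.upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
    drop = FALSE]
}

.downsum2 <- function(dy) {
  d <- dim(dy)
  o <- seq(1L, d[1], by = 2L)
  e <- seq(2L, d[1], by = 2L)
  ow <- seq(1L, d[2], by = 2L)
  ew <- seq(2L, d[2], by = 2L)
  dy[o, ow, , , drop = FALSE] + dy[e, ow, , , drop = FALSE] +
    dy[o, ew, , , drop = FALSE] + dy[e, ew, , , drop = FALSE]
}

# Forward pass. Returns list(out, caches); caches hold per-layer inputs and
# pre-activations needed by net_backward.
net_forward <- function(layers, x, keep_cache = TRUE) {
  caches <- if (keep_cache) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$kind == "up") {
      if (keep_cache) caches[[i]] <- list()
      x <- .upsample2(x)
    } else {
      pre <- .conv2d_fwd(x, l$W, l$b, l$stride, l$pad)
      if (l$act == "lrelu") {
        lr <- .lrelu_fwd(pre, keep_cache)
        if (keep_cache) caches[[i]] <- list(x = x, g = lr$g)
        x <- lr$y
      } else if (l$act == "tanh") {
        out <- tanh(pre)
        if (keep_cache) caches[[i]] <- list(x = x, g = 1 - out * out)
        x <- out
      } else {
        if (keep_cache) caches[[i]] <- list(x = x, g = NULL)
        x <- pre
      }
    }
  }
  list(out = x, caches = caches)
}

# Backward pass from dout at the network output. Returns per-layer gradients
# (same list shape as layers; NULL for non-parametric layers) and, when
# need_input_grad, the gradient w.r.t. the network input.
net_backward <- function(layers, caches, dout, need_input_grad = FALSE) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    if (l$kind == "up") {
      dout <- .downsum2(dout)
      next
    }
    cc <- caches[[i]]
    dpre <- if (is.null(cc$g)) dout else dout * cc$g
    dim(dpre) <- dim(dout)
    need_dx <- need_input_grad || i > 1L
    bw <- .conv2d_bwd(cc$x, l$W, dpre, l$stride, l$pad, need_dx)
    grads[[i]] <- list(dW = bw$dw, db = bw$db)
    dout <- bw$dx
  }
  list(grads = grads, dx = if (need_input_grad) dout else NULL)
}

adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (l$kind != "conv") return(NULL)
    list(mW = array(0, dim(l$W)), vW = array(0, dim(l$W)),
         mb = numeric(length(l$b)), vb = numeric(length(l$b)), t = 0L)
  })
}

adam_step <- function(layers, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    if (layers[[i]]$kind != "conv") next
    s <- state[[i]]
    g <- grads[[i]]
    s$t <- s$t + 1L
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    bc1 <- 1 - beta1^s$t
    bc2 <- 1 - beta2^s$t
    layers[[i]]$W <- layers[[i]]$W - lr * (s$mW / bc1) /
      (sqrt(s$vW / bc2) + eps)
    layers[[i]]$b <- layers[[i]]$b - lr * (s$mb / bc1) /
      (sqrt(s$vb / bc2) + eps)
    state[[i]] <- s
  }
  list(layers = layers, state = state)
}

# Global average pool over H, W: (H, W, C, N) -> C x N matrix.
.gap <- function(x) {
  d <- dim(x)
  apply(x, c(3, 4), mean)
}

# Analytic receptive field of a conv stack (single centred output unit).
.stack_receptive_field <- function(layers) {
  rf <- 1L
  jump <- 1L
  for (l in layers) {
    if (l$kind != "conv") next
    rf <- rf + (l$k - 1L) * jump
    jump <- jump * l$stride
  }
  as.integer(rf)
}

.param_count <- function(layers) {
  sum(vapply(layers, function(l) {
    if (l$kind != "conv") return(0L)
    length(l$W) + length(l$b)
  }, integer(1)))
}
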