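# The four training loss terms and their weighted combination. Public
# functions return scalars; the .*_grad internals also return the gradient
# w.r.t. the prediction, used by the training loop. All losses are
# per-element means so their magnitudes are resolution independent (the
# printed sums of the source formulations are absorbed into the weights).

#' Loss weights for the hybrid generator objective
#'
#' @param w_l2 weight of the mean-squared reconstruction error.
#' @param w_gradient weight of the gradient-difference loss.
#' @param w_flow weight of the optical-flow consistency loss.
#' @param w_adversarial weight of the least-squares adversarial term.
#' @return A `loss_weights` list; at least one weight must be positive.
#' @export
loss_weights <- function(w_l2 = 1, w_gradient = 1, w_flow = 2,
                         w_adversarial = 0.05) {
  w <- c(w_l2 = w_l2, w_gradient = w_gradient, w_flow = w_flow,
         w_adversarial = w_adversarial)
  if (any(w < 0) || !any(w > 0))
    stop("loss_weights: weights must be non-negative, at least one positive",
         call. = FALSE)
  structure(as.list(w), class = "loss_weights")
}

#' Mean squared reconstruction error
#'
#' `(1/N) * sum_p (y_p - pred_p)^2` over all pixels (and frames) of the
#' target.
#'
#' @param target,prediction numeric arrays of identical shape.
#' @return Non-negative scalar.
#' @export
l2_loss <- function(target, prediction) {
  if (!identical(dim(target) %||% length(target),
                 dim(prediction) %||% length(prediction)))
    stop("l2_loss: shape mismatch", call. = FALSE)
  mean((target - prediction)^2)
}

.l2_grad <- function(target, prediction) {
  2 * (prediction - target) / length(target)
}

# Absolute forward differences along rows and columns of a matrix or of
# every frame of a stack, as used by the gradient-difference loss.
.grad_pairs <- function(x) {
  d <- dim(x)
  if (length(d) == 2L) dim(x) <- d <- c(d, 1L)
  list(dv = abs(x[2:d[1], , , drop = FALSE] -
                x[1:(d[1] - 1), , , drop = FALSE]),
       dh = abs(x[, 1:(d[2] - 1), , drop = FALSE] -
                x[, 2:d[2], , drop = FALSE]))
}

#' Gradient-difference loss
#'
#' Compares the magnitudes of adjacent-pixel intensity differences between
#' prediction and target:
#' `sum_ij | |Y_ij - Y_(i-1)j| - |Yhat_ij - Yhat_(i-1)j| | + (horizontal
#' analogue)`, with out-of-range neighbours skipped, divided by the pixel
#' count. The outer absolute value bounds the loss below by zero (the
#' standard gradient-difference form); it is invariant to adding a
#' constant offset to either image.
#'
#' @param prediction,target numeric matrices or `H x W x F` stacks of
#'   identical shape, side >= 2.
#' @return Non-negative scalar.
#' @export
gradient_loss <- function(prediction, target) {
  if (!identical(dim(prediction) %||% length(prediction),
                 dim(target) %||% length(target)))
    stop("gradient_loss: shape mismatch", call. = FALSE)
  gp <- .grad_pairs(prediction)
  gt <- .grad_pairs(target)
  (sum(abs(gt$dv - gp$dv)) + sum(abs(gt$dh - gp$dh))) / length(prediction)
}

.gradient_loss_grad <- function(prediction, target) {
  d <- dim(prediction)
  if (length(d) == 2L) dim(prediction) <- dim(target) <- d <- c(d, 1L)
  n <- length(prediction)
  dv_p <- prediction[2:d[1], , , drop = FALSE] -
    prediction[1:(d[1] - 1), , , drop = FALSE]
  dv_t <- target[2:d[1], , , drop = FALSE] -
    target[1:(d[1] - 1), , , drop = FALSE]
  dh_p <- prediction[, 1:(d[2] - 1), , drop = FALSE] -
    prediction[, 2:d[2], , drop = FALSE]
  dh_t <- target[, 1:(d[2] - 1), , drop = FALSE] -
    target[, 2:d[2], , drop = FALSE]
  # d/d|dv_p| of |  |dv_t| - |dv_p| | = -sign(|dv_t| - |dv_p|)
  sv <- -sign(abs(dv_t) - abs(dv_p)) * sign(dv_p)
  sh <- -sign(abs(dh_t) - abs(dh_p)) * sign(dh_p)
  g <- array(0, d)
  g[2:d[1], , ] <- g[2:d[1], , , drop = FALSE] + sv
  g[1:(d[1] - 1), , ] <- g[1:(d[1] - 1), , , drop = FALSE] - sv
  g[, 1:(d[2] - 1), ] <- g[, 1:(d[2] - 1), , drop = FALSE] + sh
  g[, 2:d[2], ] <- g[, 2:d[2], , drop = FALSE] - sh
  g / n
}

#' Optical-flow consistency loss
#'
#' Compares the dense flow of the (predicted next frame, current frame)
#' pair against the flow of the (true next frame, current frame) pair, as
#' the mean absolute difference over pixels and the two flow components.
#'
#' @param estimator an [flow_estimator()].
#' @param pred_next predicted frame at t+1.
#' @param true_next authentic frame at t+1.
#' @param current authentic frame at t.
#' @return Non-negative scalar.
#' @export
flow_loss <- function(estimator, pred_next, true_next, current) {
  if (!all(dim(pred_next) == dim(true_next)) ||
      !all(dim(pred_next) == dim(current)))
    stop("flow_loss: shape mismatch", call. = FALSE)
  f1 <- flow_estimate(estimator, pred_next, current)
  f2 <- flow_estimate(estimator, true_next, current)
  mean(abs(f1 - f2))
}

# Flow loss value + gradient w.r.t. pred_next (training path; LK only).
.flow_loss_grad <- function(estimator, pred_next, true_next, current) {
  r1 <- .lk_flow(estimator, pred_next, current, keep_cache = TRUE)
  r2 <- .lk_flow(estimator, true_next, current)
  diff <- r1$flow - r2$flow
  n <- length(diff)
  s <- sign(diff) / n
  dpred <- .lk_flow_backward(r1$cache, s[, , 1L], s[, , 2L])
  list(loss = mean(abs(diff)), grad = dpred)
}

# Least-squares patch losses over a precomputed score map. Shared by the
# public adversarial losses and the training loop.
.ls_real <- function(map) mean(0.5 * (map - 1)^2)
.ls_fake <- function(map) mean(0.5 * map^2)

#' Discriminator adversarial loss (least squares)
#'
#' Mean over frames and patch positions of
#' `0.5 * (D(real) - 1)^2 + 0.5 * D(fake)^2`. The fake window carries no
#' generator gradients (arrays are plain values here).
#'
#' @param d an `fg_discriminator`.
#' @param real_window,fake_window `H x W x F` frame stacks.
#' @return Non-negative scalar.
#' @export
adversarial_d_loss <- function(d, real_window, fake_window) {
  if (!identical(dim(real_window), dim(fake_window)))
    stop("adversarial_d_loss: shape mismatch", call. = FALSE)
  .ls_real(discriminate(d, .frames_as_batch(real_window))) +
    .ls_fake(discriminate(d, .frames_as_batch(fake_window)))
}

#' Generator adversarial loss (least squares)
#'
#' Mean over frames and patch positions of `0.5 * (D(fake) - 1)^2`: the
#' generator is rewarded when the discriminator labels its reconstruction
#' as real.
#'
#' @param d an `fg_discriminator`.
#' @param fake_window `H x W x F` frame stack from the generator.
#' @return Non-negative scalar.
#' @export
adversarial_g_loss <- function(d, fake_window) {
  .ls_real(discriminate(d, .frames_as_batch(fake_window)))
}

# (H, W, F) or (H, W, F, N) stack -> (H, W, 1, F*N) batch of single frames.
.frames_as_batch <- function(stack) {
  d <- dim(stack)
  if (length(d) == 2L) d <- c(d, 1L)
  dim(stack) <- c(d[1], d[2], 1L, prod(d[-(1:2)]))
  stack
}

#' Hybrid generator loss
#'
#' Weighted sum `w_l2 * L2 + w_gradient * Lgd + w_flow * Lop +
#' w_adversarial * Ladv` with the per-term breakdown attached for logging.
#'
#' @param weights a [loss_weights()].
#' @param l2,gradient,flow,adversarial the four scalar terms.
#' @return Scalar total with attribute `breakdown`.
#' @export
hybrid_g_loss <- function(weights, l2, gradient, flow, adversarial) {
  terms <- c(l2 = l2, gradient = gradient, flow = flow,
             adversarial = adversarial)
  if (any(!is.finite(terms)))
    stop("hybrid_g_loss: non-finite term(s): ",
         paste(names(terms)[!is.finite(terms)], collapse = ", "),
         call. = FALSE)
  total <- weights$w_l2 * l2 + weights$w_gradient * gradient +
    weights$w_flow * flow + weights$w_adversarial * adversarial
  structure(total, breakdown = terms)
}
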