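# Classical dense optical flow: windowed Lucas-Kanade on pre-smoothed
# frames. Spatial gradients come from the reference frame only, which makes
# the flow field a *linear* function of the moving frame -- so the flow
# consistency loss backpropagates into the generator exactly, with no
# pretrained flow network.
#
# Separable blur/box filtering uses a symmetric 1-D kernel with zero
# padding, so the adjoint needed in the backward pass is the same operator.

.gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(2 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

.shift_diff_x <- function(m) {   # central difference along columns (x)
  n <- ncol(m)
  d <- matrix(0, nrow(m), n)
  d[, 2:(n - 1)] <- (m[, 3:n] - m[, 1:(n - 2)]) / 2
  d
}

.shift_diff_y <- function(m) {   # central difference along rows (y)
  n <- nrow(m)
  d <- matrix(0, n, ncol(m))
  d[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / 2
  d
}

#' Create a dense optical-flow estimator
#'
#' The default is a classical windowed Lucas--Kanade estimator: both frames
#' are Gaussian-smoothed, spatial gradients are taken on the reference
#' frame, and per-pixel normal equations are solved over a box window. It
#' is treated as a fixed (non-trained) function during GAN training, and is
#' differentiable with respect to the moving frame. A custom estimator
#' function `fn(frame_a, frame_b) -> H x W x 2` (e.g. a learned network)
#' can be plugged in; custom estimators are used as-is for inference and
#' scoring but do not provide gradients for the flow loss.
#'
#' @param window box window side (odd) for the local normal equations.
#' @param blur_sigma Gaussian pre-smoothing standard deviation in pixels.
#' @param eps regulariser added to the normal-equation determinant.
#' @param fn optional custom estimator function.
#' @return An `fg_flow` estimator.
#' @export
flow_estimator <- function(window = 9L, blur_sigma = 1.5, eps = 1e-3,
                           fn = NULL) {
  stopifnot(window %% 2L == 1L, window >= 3L, blur_sigma > 0, eps > 0)
  structure(list(window = as.integer(window), blur_sigma = blur_sigma,
                 eps = eps, fn = fn),
            class = "fg_flow")
}

# Core LK solve; returns flow and (optionally) the linearisation cache
# needed to backpropagate into frame_a.
.lk_flow <- function(est, frame_a, frame_b, keep_cache = FALSE) {
  gk <- .gauss_kernel(est$blur_sigma)
  bk <- rep(1, est$window)
  ab <- .sep_conv2_cpp(frame_a, gk)
  bb <- .sep_conv2_cpp(frame_b, gk)
  Ix <- .shift_diff_x(bb)
  Iy <- .shift_diff_y(bb)
  It <- ab - bb
  Sxx <- .sep_conv2_cpp(Ix * Ix, bk)
  Sxy <- .sep_conv2_cpp(Ix * Iy, bk)
  Syy <- .sep_conv2_cpp(Iy * Iy, bk)
  Sxt <- .sep_conv2_cpp(Ix * It, bk)
  Syt <- .sep_conv2_cpp(Iy * It, bk)
  det <- Sxx * Syy - Sxy * Sxy + est$eps
  u <- (-Syy * Sxt + Sxy * Syt) / det
  v <- (Sxy * Sxt - Sxx * Syt) / det
  flow <- array(c(u, v), c(nrow(frame_a), ncol(frame_a), 2L))
  if (!keep_cache) return(list(flow = flow))
  list(flow = flow,
       cache = list(Ix = Ix, Iy = Iy, Sxx = Sxx, Sxy = Sxy, Syy = Syy,
                    det = det, gk = gk, bk = bk))
}

# Gradient of a scalar loss w.r.t. frame_a, given dL/du and dL/dv.
.lk_flow_backward <- function(cache, du, dv) {
  dSxt <- (-cache$Syy * du + cache$Sxy * dv) / cache$det
  dSyt <- (cache$Sxy * du - cache$Sxx * dv) / cache$det
  dIt <- cache$Ix * .sep_conv2_cpp(dSxt, cache$bk) +
         cache$Iy * .sep_conv2_cpp(dSyt, cache$bk)
  .sep_conv2_cpp(dIt, cache$gk)
}

#' Estimate dense optical flow between two frames
#'
#' Returns the per-pixel displacement carrying `frame_b` onto `frame_a`
#' (the moving/later frame first, matching the flow-loss convention).
#'
#' @param estimator an [flow_estimator()].
#' @param frame_a moving (later or predicted) frame, `S x S` matrix.
#' @param frame_b reference (earlier) frame of the same size.
#' @return `S x S x 2` array; `[, , 1]` is the x (column) displacement,
#'   `[, , 2]` the y (row) displacement.
#' @export
flow_estimate <- function(estimator, frame_a, frame_b) {
  stopifnot(inherits(estimator, "fg_flow"),
            all(dim(frame_a) == dim(frame_b)))
  if (!is.null(estimator$fn)) return(estimator$fn(frame_a, frame_b))
  .lk_flow(estimator, frame_a, frame_b)$flow
}
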