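# Independent brute-force oracles used to pin expected values. These stay
# deliberately naive (explicit loops) and separate from the implementation
# paths they check.

oracle_l2 <- function(target, prediction) {
  s <- 0
  n <- 0
  for (k in seq_along(target)) {
    s <- s + (target[[k]] - prediction[[k]])^2
    n <- n + 1
  }
  s / n
}

# Double-loop gradient-difference loss on a single matrix pair,
# per-pixel-mean convention, out-of-range neighbours skipped.
oracle_gradient_loss <- function(pred, targ) {
  H <- nrow(pred)
  W <- ncol(pred)
  s <- 0
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      if (i > 1)
        s <- s + abs(abs(targ[i, j] - targ[i - 1, j]) -
                     abs(pred[i, j] - pred[i - 1, j]))
      if (j < W)
        s <- s + abs(abs(targ[i, j] - targ[i, j + 1]) -
                     abs(pred[i, j] - pred[i, j + 1]))
    }
  }
  s / (H * W)
}

# Mean over frames and patch positions of the least-squares terms, looped.
oracle_adv_d <- function(real_maps, fake_maps) {
  sr <- 0; nr <- 0; sf <- 0; nf <- 0
  for (m in real_maps) for (v in m) { sr <- sr + 0.5 * (v - 1)^2; nr <- nr + 1 }
  for (m in fake_maps) for (v in m) { sf <- sf + 0.5 * v^2; nf <- nf + 1 }
  sr / nr + sf / nf
}

oracle_adv_g <- function(fake_maps) {
  s <- 0; n <- 0
  for (m in fake_maps) for (v in m) { s <- s + 0.5 * (v - 1)^2; n <- n + 1 }
  s / n
}

# All-pairs AUC with ties counted one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Valid window anchors by explicit enumeration (1-based anchor = index of
# F[t]; needs 7 frames before and 4 after).
oracle_anchors <- function(n_frames, stride) {
  out <- integer()
  t <- 8L
  while (t + 4L <= n_frames) {
    out <- c(out, t)
    t <- t + stride
  }
  out
}

# Nearest-valid-neighbour hole fill (Euclidean nearest valid pixel).
oracle_nn_fill <- function(frame, hole) {
  H <- nrow(frame)
  W <- ncol(frame)
  out <- frame
  valid <- which(!hole, arr.ind = TRUE)
  for (k in which(hole)) {
    i <- (k - 1) %% H + 1
    j <- (k - 1) %/% H + 1
    d2 <- (valid[, 1] - i)^2 + (valid[, 2] - j)^2
    nn <- valid[which.min(d2), ]
    out[i, j] <- frame[nn[1], nn[2]]
  }
  out
}

# Thresholded centroid of the bright subject (subject 0.8 vs background
# <= 0.4 at the simulator defaults).
subject_centroid <- function(frame, thr = 0.6) {
  idx <- which(frame > thr, arr.ind = TRUE)
  if (nrow(idx) == 0) return(c(NA_real_, NA_real_))
  c(mean(idx[, 1]), mean(idx[, 2]))
}

max_centroid_step <- function(clip, frames = seq_len(n_frames(clip))) {
  cents <- t(vapply(frames, function(t)
    subject_centroid(clip$frames[, , t]), numeric(2)))
  steps <- sqrt(rowSums(diff(cents)^2))
  max(steps)
}
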