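#' Training configuration
#'
#' Defaults are the desk-scale schedule (tiny nets, 64 px frames, one CPU).
#' The full-scale schedule of the source system (batch 7, initial learning
#' rate 1e-4 decaying to one tenth every 70,000 iterations) is available
#' via `preset = "paper"`; at desk scale the learning rate is raised and
#' the decay horizon shortened in proportion to the much smaller model and
#' iteration budget.
#'
#' @param batch_size sequence samples per iteration.
#' @param lr_initial initial Adam learning rate.
#' @param lr_decay_factor multiplicative decay factor (in (0, 1]).
#' @param lr_decay_every iterations between decays.
#' @param max_iterations total iterations to run.
#' @param seed RNG seed controlling batching and initial shuffling.
#' @param d_steps_per_g_step discriminator updates per generator update.
#' @param preset `"desk"` (default) or `"paper"`; explicit arguments
#'   override preset values.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = NULL, lr_initial = NULL,
                         lr_decay_factor = NULL, lr_decay_every = NULL,
                         max_iterations = NULL, seed = 1L,
                         d_steps_per_g_step = 1L,
                         preset = c("desk", "paper")) {
  preset <- match.arg(preset)
  def <- if (preset == "paper")
    list(batch_size = 7L, lr_initial = 1e-4, lr_decay_factor = 0.1,
         lr_decay_every = 70000L, max_iterations = 210000L)
  else
    list(batch_size = 4L, lr_initial = 2e-3, lr_decay_factor = 0.1,
         lr_decay_every = 1000L, max_iterations = 2000L)
  cfg <- list(batch_size = as.integer(batch_size %||% def$batch_size),
              lr_initial = lr_initial %||% def$lr_initial,
              lr_decay_factor = lr_decay_factor %||% def$lr_decay_factor,
              lr_decay_every = as.integer(lr_decay_every %||%
                                            def$lr_decay_every),
              max_iterations = as.integer(max_iterations %||%
                                            def$max_iterations),
              seed = as.integer(seed),
              d_steps_per_g_step = as.integer(d_steps_per_g_step))
  stopifnot(cfg$batch_size >= 1L, cfg$lr_initial > 0,
            cfg$lr_decay_factor > 0, cfg$lr_decay_factor <= 1,
            cfg$lr_decay_every >= 1L, cfg$max_iterations >= 0L,
            cfg$d_steps_per_g_step >= 1L)
  structure(cfg, class = "train_config")
}

#' Learning rate at a given iteration
#'
#' `lr_initial * lr_decay_factor ^ floor(n / lr_decay_every)` where `n` is
#' the number of completed iterations (the first update uses `n = 0`).
#'
#' @param n completed iteration count (0-based).
#' @param config a [train_config()].
#' @return Learning rate.
#' @export
lr_schedule <- function(n, config) {
  config$lr_initial * config$lr_decay_factor^floor(n / config$lr_decay_every)
}

# Window index over a list of preprocessed clips: one row per valid anchor.
.window_index <- function(clips) {
  idx <- do.call(rbind, lapply(seq_along(clips), function(ci) {
    n <- n_frames(clips[[ci]])
    if (n < 12L) return(NULL)
    data.frame(clip = ci, anchor = seq(8L, n - 4L))
  }))
  if (is.null(idx) || nrow(idx) == 0L)
    stop("train: no clip yields a sequence sample (need >= 12 frames)",
         call. = FALSE)
  idx
}

.gather_batch <- function(clips, idx, rows) {
  s <- dim(clips[[idx$clip[rows[1]]]]$frames)[1:2]
  B <- length(rows)
  x <- array(0, c(s[1], s[2], 8L, B))
  y <- array(0, c(s[1], s[2], 8L, B))
  for (b in seq_len(B)) {
    fr <- clips[[idx$clip[rows[b]]]]$frames
    t <- idx$anchor[rows[b]]
    x[, , , b] <- fr[, , (t - 7L):t]
    y[, , , b] <- fr[, , (t - 3L):(t + 4L)]
  }
  list(x = x, y = y)
}

# One full training loop from state$iter + 1 to config$max_iterations.
.train_loop <- function(state, clips, config, weights, flow,
                        checkpoint_dir = NULL, checkpoint_every = NULL,
                        verbose = FALSE) {
  idx <- .window_index(clips)
  nw <- nrow(idx)
  B <- min(config$batch_size, nw)
  gen <- state$gen
  disc <- state$disc
  g_opt <- state$g_opt
  d_opt <- state$d_opt
  perm <- state$perm
  pos <- state$pos
  log_rows <- state$log

  first <- state$iter + 1L
  if (first > config$max_iterations) return(state)
  for (iter in first:config$max_iterations) {
    if (is.null(perm) || pos + B - 1L > nw) {
      perm <- sample.int(nw)
      pos <- 1L
    }
    rows <- perm[pos:(pos + B - 1L)]
    pos <- pos + B
    batch <- .gather_batch(clips, idx, rows)
    lr <- lr_schedule(iter - 1L, config)

    fg <- .gen_forward(gen, batch$x, keep_cache = TRUE)
    yhat <- fg$out
    real_b <- .frames_as_batch(batch$y)
    fake_b <- .frames_as_batch(yhat)

    # --- discriminator step(s): fakes are plain values (detached) ---
    d_loss <- NA_real_
    for (k in seq_len(config$d_steps_per_g_step)) {
      fr <- net_forward(disc$layers, real_b)
      ff <- net_forward(disc$layers, fake_b)
      d_loss <- .ls_real(fr$out) + .ls_fake(ff$out)
      if (!is.finite(d_loss))
        stop("train: non-finite discriminator loss at iteration ", iter,
             call. = FALSE)
      br <- net_backward(disc$layers, fr$caches, (fr$out - 1) /
                           length(fr$out))
      bf <- net_backward(disc$layers, ff$caches, ff$out / length(ff$out))
      dg <- mapply(function(a, b) {
        if (is.null(a)) NULL else list(dW = a$dW + b$dW, db = a$db + b$db)
      }, br$grads, bf$grads, SIMPLIFY = FALSE)
      up <- adam_step(disc$layers, dg, d_opt, lr)
      disc$layers <- up$layers
      d_opt <- up$state
    }

    # --- generator step ---
    l2 <- l2_loss(batch$y, yhat)
    dy <- weights$w_l2 * .l2_grad(batch$y, yhat)

    gd <- 0
    if (weights$w_gradient > 0) {
      yh3 <- yhat
      dim(yh3) <- c(dim(yhat)[1:2], prod(dim(yhat)[3:4]))
      yt3 <- batch$y
      dim(yt3) <- dim(yh3)
      gd <- gradient_loss(yh3, yt3)
      ggd <- .gradient_loss_grad(yh3, yt3)
      dim(ggd) <- dim(yhat)
      dy <- dy + weights$w_gradient * ggd
    }

    fl <- 0
    if (weights$w_flow > 0) {
      nt <- 4L * dim(yhat)[4]
      for (b in seq_len(dim(yhat)[4])) {
        for (k in 1:4) {
          prev <- if (k == 1L) batch$x[, , 8L, b] else batch$y[, , 3L + k, b]
          r <- .flow_loss_grad(flow, yhat[, , 4L + k, b],
                               batch$y[, , 4L + k, b], prev)
          fl <- fl + r$loss / nt
          dy[, , 4L + k, b] <- dy[, , 4L + k, b] +
            weights$w_flow * r$grad / nt
        }
      }
    }

    adv <- 0
    if (weights$w_adversarial > 0) {
      ff2 <- net_forward(disc$layers, fake_b)
      adv <- .ls_real(ff2$out)
      bf2 <- net_backward(disc$layers, ff2$caches,
                          (ff2$out - 1) / length(ff2$out),
                          need_input_grad = TRUE)
      dadv <- bf2$dx
      dim(dadv) <- dim(yhat)
      dy <- dy + weights$w_adversarial * dadv
    }

    g_total <- as.numeric(hybrid_g_loss(weights, l2, gd, fl, adv))
    if (!is.finite(g_total))
      stop("train: non-finite generator loss at iteration ", iter,
           call. = FALSE)

    bd <- net_backward(gen$dec, fg$dec_caches, dy, need_input_grad = TRUE)
    be <- net_backward(gen$enc, fg$enc_caches, bd$dx)
    upe <- adam_step(gen$enc, be$grads, g_opt$enc, lr)
    upd <- adam_step(gen$dec, bd$grads, g_opt$dec, lr)
    gen$enc <- upe$layers
    gen$dec <- upd$layers
    g_opt <- list(enc = upe$state, dec = upd$state)

    log_rows[[length(log_rows) + 1L]] <-
      data.frame(iteration = iter, lr = lr, l2 = l2, gradient = gd,
                 flow = fl, adversarial = adv, g_total = g_total,
                 d_loss = d_loss)
    if (verbose && iter %% 100L == 0L)
      message(sprintf("iter %d  lr %.2g  L2 %.4f  gd %.4f  flow %.4f  adv %.4f  D %.4f",
                      iter, lr, l2, gd, fl, adv, d_loss))

    state <- list(gen = gen, disc = disc, g_opt = g_opt, d_opt = d_opt,
                  iter = iter, perm = perm, pos = pos, log = log_rows,
                  config = config, weights = weights,
                  rng = get(".Random.seed", envir = globalenv()))
    if (!is.null(checkpoint_dir) && !is.null(checkpoint_every) &&
        iter %% checkpoint_every == 0L)
      save_checkpoint(structure(state, class = "fg_fit"),
                      file.path(checkpoint_dir,
                                sprintf("checkpoint_%06d.rds", iter)))
  }
  state
}

.assert_normal_only <- function(clips) {
  for (cl in clips) {
    if (!is.null(cl$labels) && any(cl$labels == 1L))
      stop("train: clip '", cl$clip_id, "' contains fall-labelled frames; ",
           "the unsupervised protocol trains on normal activity only",
           call. = FALSE)
  }
}

#' Train the GAN on normal-activity clips
#'
#' Alternating adversarial training: per iteration a batch of sequence
#' samples is drawn (all stride-1 windows, shuffled per epoch), the
#' discriminator is updated on real versus detached reconstructed frames
#' under the least-squares patch loss, then the generator is updated under
#' the hybrid loss (L2 + gradient + optical flow + adversarial). Fully
#' reproducible under a fixed `config$seed`. Training clips must be free
#' of fall labels.
#'
#' @param gen an `fg_generator` (freshly built or from a checkpoint).
#' @param disc an `fg_discriminator`.
#' @param flow an [flow_estimator()].
#' @param train_clips list of preprocessed [video_clip()]s in `[-1, 1]`.
#' @param config a [train_config()].
#' @param weights a [loss_weights()].
#' @param checkpoint_dir optional directory for periodic checkpoints.
#' @param checkpoint_every iterations between checkpoints.
#' @param verbose print progress every 100 iterations.
#' @return An `fg_fit`: trained `gen`/`disc`, per-iteration `log`
#'   data.frame, optimiser and RNG state (resumable).
#' @export
train <- function(gen, disc, flow, train_clips, config = train_config(),
                  weights = loss_weights(), checkpoint_dir = NULL,
                  checkpoint_every = NULL, verbose = FALSE) {
  stopifnot(inherits(gen, "fg_generator"), inherits(disc, "fg_discriminator"),
            inherits(flow, "fg_flow"), inherits(config, "train_config"))
  .assert_normal_only(train_clips)
  set.seed(config$seed)
  rng0 <- get(".Random.seed", envir = globalenv())
  state <- list(rng = rng0, gen = gen, disc = disc,
                g_opt = list(enc = adam_init(gen$enc),
                             dec = adam_init(gen$dec)),
                d_opt = adam_init(disc$layers),
                iter = 0L, perm = NULL, pos = 1L, log = list(),
                config = config, weights = weights)
  state <- .train_loop(state, train_clips, config, weights, flow,
                       checkpoint_dir, checkpoint_every, verbose)
  structure(c(state, list(log_df = do.call(rbind, state$log))),
            class = "fg_fit")
}

#' @export
print.fg_fit <- function(x, ...) {
  cat(sprintf("<fg_fit> %d iterations trained\n", x$iter))
  invisible(x)
}

#' Save a training checkpoint
#'
#' @param fit an `fg_fit` (or internal training state).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(unclass(fit), path)
  invisible(path)
}

#' Load a training checkpoint
#'
#' @param path file written by [save_checkpoint()].
#' @return An `fg_fit`.
#' @export
load_checkpoint <- function(path) {
  structure(readRDS(path), class = "fg_fit")
}

#' Resume training from a checkpoint
#'
#' Restores parameters, optimiser state, the mid-epoch window permutation
#' and the RNG state, so a split run reproduces an unbroken run exactly.
#' The resumed `config` may only differ from the checkpointed one in
#' `max_iterations`.
#'
#' @param checkpoint an `fg_fit` or a path to one.
#' @param train_clips the same training clips used originally.
#' @param config a [train_config()] with a larger `max_iterations`.
#' @param flow an [flow_estimator()].
#' @param checkpoint_dir,checkpoint_every,verbose as in [train()].
#' @return An `fg_fit` advanced to `config$max_iterations`.
#' @export
resume <- function(checkpoint, train_clips, config, flow = flow_estimator(),
                   checkpoint_dir = NULL, checkpoint_every = NULL,
                   verbose = FALSE) {
  state <- if (is.character(checkpoint)) unclass(load_checkpoint(checkpoint))
           else unclass(checkpoint)
  old <- state$config
  fixed <- setdiff(names(old), "max_iterations")
  differs <- fixed[!vapply(fixed, function(k)
    identical(old[[k]], config[[k]]), logical(1))]
  if (length(differs) > 0L)
    stop("resume: config differs from checkpoint in: ",
         paste(differs, collapse = ", "), call. = FALSE)
  .assert_normal_only(train_clips)
  assign(".Random.seed", state$rng, envir = globalenv())
  state$log_df <- NULL
  state$config <- config
  state <- .train_loop(state, train_clips, config, state$weights, flow,
                       checkpoint_dir, checkpoint_every, verbose)
  structure(c(state, list(log_df = do.call(rbind, state$log))),
            class = "fg_fit")
}
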