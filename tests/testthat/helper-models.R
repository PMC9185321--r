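# Shared tiny fixtures. Expensive trained models are built once per test
# run and memoised here; everything is generated in code (no stored data).

.fixtures <- new.env(parent = emptyenv())

tiny_scene <- function(seed = 1L, size = 32L) {
  scene_params(frame_size = size, seed = seed)
}

noise_off <- function(seed = 1L) noise_params(0, 0, seed = seed)

# Small preprocessed training set of normal clips (32 px, noise-free).
tiny_train_clips <- function(n = 4L, n_frames = 24L, size = 32L) {
  behaviors <- c("walk", "sit", "idle")
  lapply(seq_len(n), function(i) {
    cl <- generate_normal_clip(tiny_scene(seed = 100L + i, size = size),
                               behaviors[(i - 1L) %% 3L + 1L], n_frames,
                               noise_off(i),
                               clip_id = sprintf("tiny_train_%02d", i))
    preprocess_clip(cl, preprocess_config(target_size = size))
  })
}

tiny_gen_config <- function(size = 32L) {
  generator_config(base_channels = 8L, depth = 3L, input_size = size)
}

# A generator trained briefly on tiny normal clips; enough training for
# scored falls to separate from scored normals, cached across tests.
trained_tiny_fit <- function() {
  if (!is.null(.fixtures$tiny_fit)) return(.fixtures$tiny_fit)
  clips <- tiny_train_clips(n = 6L)
  gen <- build_generator(tiny_gen_config(), seed = 11L)
  disc <- build_discriminator(
    discriminator_config(patch_receptive_field = 34L, base_channels = 4L),
    seed = 12L)
  fit <- train(gen, disc, flow_estimator(), clips,
               train_config(max_iterations = 250L, lr_decay_every = 200L,
                            seed = 13L),
               loss_weights())
  .fixtures$tiny_fit <- fit
  fit
}

tiny_test_clips <- function(n_normal = 3L, n_fall = 3L, size = 32L,
                            noise = NULL) {
  nz <- noise %||% noise_off
  norm <- lapply(seq_len(n_normal), function(i) {
    cl <- generate_normal_clip(tiny_scene(seed = 500L + i, size = size),
                               c("walk", "sit", "idle")[(i - 1L) %% 3L + 1L],
                               32L, nz(600L + i),
                               clip_id = sprintf("tiny_tn_%02d", i))
    preprocess_clip(cl, preprocess_config(target_size = size))
  })
  fall <- lapply(seq_len(n_fall), function(i) {
    cl <- generate_fall_clip(tiny_scene(seed = 700L + i, size = size),
                             n_frames = 32L, fall_onset = 14L + 2L * i,
                             fall_duration = 3L + (i %% 4L),
                             noise = nz(800L + i),
                             clip_id = sprintf("tiny_tf_%02d", i))
    preprocess_clip(cl, preprocess_config(target_size = size))
  })
  c(norm, fall)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
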