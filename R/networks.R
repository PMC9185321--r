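#' Generator configuration
#'
#' The generator is a 2-D convolutional encoder--decoder over stacked frame
#' sequences: the 8 input frames enter as 8 channels, and the 8 output
#' frames (the input window shifted 4 frames into the future) leave as 8
#' channels through a saturating tanh. The deepest encoder activation is
#' the bottleneck whose global-average-pooled vector is the encoded feature
#' used for anomaly scoring.
#'
#' @param frames_in,frames_out frames per input/output sequence (both 8).
#' @param base_channels channels of the first encoder stage; later stages
#'   double per downsampling.
#' @param depth number of stride-2 down/up-sampling stages (>= 2).
#' @param latent_dim length of the encoded feature vector (= bottleneck
#'   channels); defaults to `base_channels * 2^(depth - 1)`.
#' @param input_size expected square input side; must be divisible by
#'   `2^depth`.
#' @return A `generator_config` list.
#' @export
generator_config <- function(frames_in = 8L, frames_out = 8L,
                             base_channels = 16L, depth = 3L,
                             latent_dim = NULL, input_size = 64L) {
  if (frames_in != 8L || frames_out != 8L)
    stop("generator_config: the sequence model uses 8 frames in and out",
         call. = FALSE)
  stopifnot(depth >= 2L, base_channels >= 4L)
  latent_dim <- as.integer(latent_dim %||% (base_channels * 2^(depth - 1)))
  if (latent_dim < 8L)
    stop("generator_config: latent_dim must be >= 8", call. = FALSE)
  if (input_size %% 2^depth != 0L)
    stop("generator_config: input_size must be divisible by 2^depth",
         call. = FALSE)
  structure(list(frames_in = 8L, frames_out = 8L,
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth), latent_dim = latent_dim,
                 input_size = as.integer(input_size)),
            class = "generator_config")
}

#' Build a generator
#'
#' @param config a [generator_config()].
#' @param seed seed for the (deterministic) weight initialisation.
#' @return An object of class `fg_generator`.
#' @export
build_generator <- function(config = generator_config(), seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  ch <- config$base_channels * 2^(seq_len(config$depth) - 1L)
  enc <- list(nn_conv(config$frames_in, ch[1], k = 3, stride = 2, pad = 1))
  for (i in seq_len(config$depth)[-1])
    enc <- c(enc, list(nn_conv(ch[i - 1], ch[i], k = 3, stride = 2, pad = 1)))
  enc <- c(enc, list(nn_conv(ch[config$depth], config$latent_dim,
                             k = 3, stride = 1, pad = 1)))
  dec <- list()
  cur <- config$latent_dim
  for (i in rev(seq_len(config$depth))[-config$depth]) {
    dec <- c(dec, list(nn_up(), nn_conv(cur, ch[i - 1], k = 3, stride = 1,
                                        pad = 1)))
    cur <- ch[i - 1]
  }
  dec <- c(dec, list(nn_up(), nn_conv(cur, config$frames_out, k = 3,
                                      stride = 1, pad = 1, act = "tanh")))
  with_seed(seed, {
    enc <- nn_init(enc)
    dec <- nn_init(dec)
  })
  structure(list(config = config, enc = enc, dec = dec), class = "fg_generator")
}

#' @export
print.fg_generator <- function(x, ...) {
  cat(sprintf(paste0("<fg_generator> depth %d, base %d, latent %d, ",
                     "%d parameters\n"),
              x$config$depth, x$config$base_channels, x$config$latent_dim,
              .param_count(x$enc) + .param_count(x$dec)))
  invisible(x)
}

.check_window <- function(window, frames, what) {
  d <- dim(window)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)) || d[3] != frames)
    stop(what, ": expected an H x W x ", frames, " frame stack", call. = FALSE)
  if (length(d) == 3L) dim(window) <- c(d, 1L)
  window
}

# Full forward with caches (training path).
.gen_forward <- function(g, x, keep_cache = TRUE) {
  fe <- net_forward(g$enc, x, keep_cache)
  fd <- net_forward(g$dec, fe$out, keep_cache)
  list(out = fd$out, bottleneck = fe$out,
       enc_caches = fe$caches, dec_caches = fd$caches)
}

#' Reconstruct / predict a frame sequence
#'
#' Maps an 8-frame input window `F[t-7] .. F[t]` (values in `[-1, 1]`) to
#' the reconstructed target window `Fhat[t-3] .. Fhat[t+4]`; output frames
#' 5..8 are the four future predictions.
#'
#' @param g an `fg_generator`.
#' @param input_window `H x W x 8` array (or `H x W x 8 x N` batch).
#' @return Array of the same shape with values in `[-1, 1]`.
#' @export
generate <- function(g, input_window) {
  stopifnot(inherits(g, "fg_generator"))
  single <- length(dim(input_window)) == 3L
  x <- .check_window(input_window, g$config$frames_in, "generate")
  out <- .gen_forward(g, x, keep_cache = FALSE)$out
  if (single) dim(out) <- dim(out)[1:3]
  out
}

#' Encode a frame sequence into the bottleneck feature vector
#'
#' Runs the encoder only and global-average-pools the deepest activation,
#' yielding the vector compared by [angular_score()]. Uses the same
#' weights as [generate()].
#'
#' @param g an `fg_generator`.
#' @param window `H x W x 8` array (or batch).
#' @return Numeric vector of length `latent_dim` (or a `latent_dim x N`
#'   matrix for a batch).
#' @export
encode <- function(g, window) {
  stopifnot(inherits(g, "fg_generator"))
  single <- length(dim(window)) == 3L
  x <- .check_window(window, g$config$frames_in, "encode")
  z <- net_forward(g$enc, x, keep_cache = FALSE)$out
  v <- .gap(z)
  if (single) as.numeric(v) else v
}

#' Discriminator configuration
#'
#' A patch-based least-squares discriminator: a stack of 4x4 convolutions
#' whose output is a 2-D map of linear scores, each judging one receptive
#' field patch of about `patch_receptive_field` pixels. The achievable
#' receptive fields of the stack family are `9 * 2^m - 2` (16, 34, 70,
#' 142, ...); the builder picks the closest.
#'
#' @param patch_receptive_field requested patch size in pixels (>= 16; 70
#'   at full scale).
#' @param base_channels channels of the first layer.
#' @param in_channels input channels (frames are judged one at a time).
#' @return A `discriminator_config` list.
#' @export
discriminator_config <- function(patch_receptive_field = 70L,
                                 base_channels = 8L, in_channels = 1L) {
  stopifnot(patch_receptive_field >= 16L, base_channels >= 2L)
  structure(list(patch_receptive_field = as.integer(patch_receptive_field),
                 base_channels = as.integer(base_channels),
                 in_channels = as.integer(in_channels)),
            class = "discriminator_config")
}

#' Build a patch discriminator
#'
#' @param config a [discriminator_config()].
#' @param seed seed for weight initialisation.
#' @return An `fg_discriminator` with the achieved receptive field in
#'   `$receptive_field`.
#' @export
build_discriminator <- function(config = discriminator_config(), seed = 1L) {
  stopifnot(inherits(config, "discriminator_config"))
  m_grid <- 1:5
  rf_grid <- 9L * 2L^m_grid - 2L
  m <- m_grid[which.min(abs(rf_grid - config$patch_receptive_field))]
  bc <- config$base_channels
  layers <- list()
  cin <- config$in_channels
  for (i in seq_len(m)) {
    cout <- min(bc * 2^(i - 1L), bc * 8L)
    layers <- c(layers, list(nn_conv(cin, cout, k = 4, stride = 2, pad = 1)))
    cin <- cout
  }
  cout <- min(cin * 2L, bc * 8L)
  layers <- c(layers, list(nn_conv(cin, cout, k = 4, stride = 1, pad = 1)))
  layers <- c(layers, list(nn_conv(cout, 1L, k = 4, stride = 1, pad = 1,
                                   act = "linear")))
  layers <- with_seed(seed, nn_init(layers))
  structure(list(config = config, layers = layers,
                 receptive_field = .stack_receptive_field(layers)),
            class = "fg_discriminator")
}

#' @export
print.fg_discriminator <- function(x, ...) {
  cat(sprintf("<fg_discriminator> receptive field %d px, %d parameters\n",
              x$receptive_field, .param_count(x$layers)))
  invisible(x)
}

#' Apply the discriminator to frames
#'
#' @param d an `fg_discriminator`.
#' @param frames a single `H x W` matrix or an `H x W x 1 x N` array.
#' @return The patch score map: `oH x oW` matrix (single frame) or
#'   `oH x oW x 1 x N` array.
#' @export
discriminate <- function(d, frames) {
  stopifnot(inherits(d, "fg_discriminator"))
  single <- is.matrix(frames)
  if (single) dim(frames) <- c(dim(frames), 1L, 1L)
  out <- net_forward(d$layers, frames, keep_cache = FALSE)$out
  if (single) out <- out[, , 1L, 1L]
  out
}

#' Analytic receptive field of a conv stack
#'
#' @param d an `fg_discriminator` (or a raw layer list).
#' @return Receptive field in input pixels of one output unit.
#' @export
receptive_field <- function(d) {
  layers <- if (inherits(d, "fg_discriminator")) d$layers else d
  .stack_receptive_field(layers)
}
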