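#' Architecture hyperparameters for the GANCMLAE networks
#'
#' Describes the shared-weight convolutional encoder (one convolution followed
#' by `n_down_blocks` downsampling residual blocks with filter counts doubling
#' each block, then a fully connected map to the latent code), the decoder
#' (a dense map back to the bottleneck grid, then two convolutions and four
#' upsampling residual blocks realizing `decoder_filter_groups`), and the
#' fully connected latent critic.
#'
#' With the defaults the encoder reduces a 128 x 128 slice to an 8 x 8 x 256
#' feature map (16,384 features) and then to a 128-dimensional latent vector.
#'
#' @param input_size Side length of the square model input, in pixels.
#'   Must be divisible by `2^n_down_blocks`.
#' @param base_filters Filter count of the first encoder convolution; doubled
#'   by every downsampling block.
#' @param n_down_blocks Number of stride-2 residual blocks in the encoder.
#' @param latent_dim Width of the latent code `z`.
#' @param decoder_filter_groups Filter counts (2 * n_down_blocks + 2 entries) for the decoder's
#'   convolutional/deconvolutional layers, last entry 1 (single-channel
#'   output). Defaults scale with `base_filters`; for `base_filters = 16`
#'   they are 128, 128, 64, 64, 32, 32, 16, 16, 8, 1.
#' @param kernel_size Convolution kernel side (square kernels).
#' @param discriminator_widths Fully connected widths of the latent critic.
#' @param leaky_slope Negative slope of the critic's LeakyReLU activations.
#' @param final_sigmoid If `TRUE` the critic ends in a sigmoid so scores lie
#'   in (0, 1); the default `FALSE` leaves an unbounded Wasserstein critic.
#' @return An object of class `gancmlae_arch`.
#' @export
architecture_spec <- function(input_size = 128L, base_filters = 16L,
                              n_down_blocks = 4L, latent_dim = 128L,
                              decoder_filter_groups = NULL, kernel_size = 3L,
                              discriminator_widths = c(256L, 128L, 1L),
                              leaky_slope = 0.2, final_sigmoid = FALSE) {
  input_size <- as.integer(input_size)
  stopifnot(input_size >= 1, base_filters >= 1, n_down_blocks >= 1,
            latent_dim >= 1, kernel_size >= 1, leaky_slope >= 0,
            length(discriminator_widths) >= 1)
  if (input_size %% 2L^n_down_blocks != 0L)
    stop("input_size (", input_size, ") must be divisible by 2^n_down_blocks (",
         2L^n_down_blocks, ")")
  if (is.null(decoder_filter_groups)) {
    decoder_filter_groups <- c(base_filters * rep(2^((n_down_blocks - 1):0),
                                                  each = 2),
                               max(1L, base_filters %/% 2L), 1L)
  }
  decoder_filter_groups <- as.integer(decoder_filter_groups)
  if (length(decoder_filter_groups) != 2L * n_down_blocks + 2L)
    stop("decoder_filter_groups must have 2 * n_down_blocks + 2 entries ",
         "(one first convolution, deconvolution/convolution pairs for each ",
         "upsampling block, one output convolution)")
  if (utils::tail(decoder_filter_groups, 1L) != 1L)
    stop("last decoder filter group must be 1 (single-channel output)")
  if (utils::tail(discriminator_widths, 1L) != 1L)
    stop("last discriminator width must be 1 (scalar score)")
  structure(list(
    input_size = input_size, base_filters = as.integer(base_filters),
    n_down_blocks = as.integer(n_down_blocks), latent_dim = as.integer(latent_dim),
    decoder_filter_groups = decoder_filter_groups,
    kernel_size = as.integer(kernel_size),
    discriminator_widths = as.integer(discriminator_widths),
    leaky_slope = leaky_slope, final_sigmoid = isTRUE(final_sigmoid)
  ), class = "gancmlae_arch")
}

#' Encoder bottleneck accounting for an architecture
#'
#' @param spec A [architecture_spec()].
#' @return A list with the bottleneck spatial side, channel count and the
#'   flattened feature count fed to the latent fully connected layer
#'   (`side^2 * channels`).
#' @export
encoder_flatten_info <- function(spec) {
  side <- spec$input_size %/% as.integer(2L^spec$n_down_blocks)
  channels <- spec$base_filters * as.integer(2L^spec$n_down_blocks)
  list(side = side, channels = channels,
       n_features = as.integer(side^2 * channels))
}

.build_encoder <- function(spec) {
  k <- spec$kernel_size
  f <- spec$base_filters
  layers <- list(nn_conv(1L, f, k = k))
  for (i in seq_len(spec$n_down_blocks)) {
    cin <- f * 2L^(i - 1L)
    cout <- 2L * cin
    # pre-activation residual block with a stride-2 projection shortcut
    main <- list(nn_bn(cin), nn_relu(), nn_conv(cin, cout, k = k, stride = 2L),
                 nn_bn(cout), nn_relu(), nn_conv(cout, cout, k = k))
    shortcut <- list(nn_conv(cin, cout, k = 1L, stride = 2L, pad = 0L))
    layers <- c(layers, list(nn_resblock(main, shortcut)))
  }
  info <- encoder_flatten_info(spec)
  c(layers, list(nn_flatten(),
                 nn_dense(info$n_features, spec$latent_dim,
                          init_sd = sqrt(1 / info$n_features))))
}

.build_decoder <- function(spec) {
  k <- spec$kernel_size
  g <- spec$decoder_filter_groups
  info <- encoder_flatten_info(spec)
  layers <- list(
    nn_dense(spec$latent_dim, info$n_features, init_sd = sqrt(1 / spec$latent_dim)),
    nn_reshape(info$side, info$side, info$channels),
    nn_conv(info$channels, g[1], k = k), nn_bn(g[1]), nn_relu())
  cin <- g[1]
  for (j in seq_len(spec$n_down_blocks)) {
    gd <- g[2L * j]
    gc <- g[2L * j + 1L]
    main <- list(nn_bn(cin), nn_relu(), nn_tconv(cin, gd, k = k),
                 nn_bn(gd), nn_relu(), nn_conv(gd, gc, k = k))
    shortcut <- list(nn_upsample(), nn_conv(cin, gc, k = 1L, pad = 0L))
    layers <- c(layers, list(nn_resblock(main, shortcut)))
    cin <- gc
  }
  c(layers, list(nn_conv(cin, g[length(g)], k = k), nn_tanh()))
}

.build_critic <- function(spec) {
  widths <- spec$discriminator_widths
  din <- spec$latent_dim
  layers <- list()
  for (i in seq_along(widths)) {
    layers <- c(layers, list(nn_dense(din, widths[i])))
    if (i < length(widths)) layers <- c(layers, list(nn_lrelu(spec$leaky_slope)))
    din <- widths[i]
  }
  if (spec$final_sigmoid) layers <- c(layers, list(nn_sigmoid()))
  layers
}

#' Build a GANCMLAE model
#'
#' Constructs the shared-weight encoder (used both as Encoder1, on inputs, and
#' Encoder2, on reconstructions), the decoder and the latent critic, with
#' deterministic weight initialization.
#'
#' @param spec An [architecture_spec()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `gancmlae_model`.
#' @examples
#' m <- build_model(architecture_spec(input_size = 32, base_filters = 2,
#'                                    latent_dim = 8), seed = 1)
#' glance(m)
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "gancmlae_arch"))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  model <- structure(list(
    spec = spec,
    encoder = .build_encoder(spec),
    decoder = .build_decoder(spec),
    critic = .build_critic(spec),
    step = 0L, trained = FALSE, seed = as.integer(seed)
  ), class = "gancmlae_model")
  model
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible()
}

# Coerce slices to the internal channels-first [1, H, W, N] batch layout.
# Accepted user-facing layouts: H x W matrix, H x W x N array, H x W x 1 x N
# array, or a list of matrices. Single-channel data in (h, w, n) order has the
# same linear layout as (c=1, h, w, n), so only the dim attribute changes.
.as_batch <- function(x, input_size) {
  if (is.list(x) && !is.null(x$slices)) x <- x$slices
  if (is.list(x)) x <- simplify2array(x)
  d <- dim(x)
  if (is.null(d) || length(d) < 2L || length(d) > 4L)
    stop("batch must be a 2D/3D/4D array of slices")
  if (length(d) == 4L && d[3] != 1L)
    stop("slices must be single-channel; got ", d[3], " channels")
  if (d[1] != input_size || d[2] != input_size)
    stop("slices are ", d[1], " x ", d[2], " but the model expects ",
         input_size, " x ", input_size)
  n <- if (length(d) == 2L) 1L else d[length(d)]
  dim(x) <- c(1L, d[1], d[2], n)
  x
}

#' Encode slices to latent vectors
#'
#' Runs Encoder1 in evaluation mode (batch-norm uses running statistics, so
#' repeated calls are deterministic).
#'
#' @param model A [build_model()] object.
#' @param x Slices: a `H x W` matrix, `H x W x N` array, `H x W x 1 x N`
#'   array, or a list of matrices.
#' @return An `N x latent_dim` matrix.
#' @export
encode <- function(model, x) {
  stopifnot(inherits(model, "gancmlae_model"))
  b <- .as_batch(x, model$spec$input_size)
  net_forward(model$encoder, b, training = FALSE)$out
}

#' Decode latent vectors to reconstructed slices
#'
#' @param model A [build_model()] object.
#' @param z An `N x latent_dim` matrix (or a vector for a single code).
#' @return A `H x W x N` array of reconstructed slices with values in
#'   \[-1, 1\] (tanh output).
#' @export
decode <- function(model, z) {
  stopifnot(inherits(model, "gancmlae_model"))
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  if (ncol(z) != model$spec$latent_dim)
    stop("latent width ", ncol(z), " does not match latent_dim ",
         model$spec$latent_dim)
  out <- net_forward(model$decoder, z, training = FALSE)$out
  d <- dim(out) # (1, H, W, N): same linear layout as (H, W, N)
  array(out, c(d[2], d[3], d[4]))
}

#' Score latent vectors with the critic
#'
#' Unbounded Wasserstein critic scores by default; in (0, 1) when the
#' architecture was built with `final_sigmoid = TRUE`.
#'
#' @inheritParams decode
#' @return A numeric vector with one score per row of `z`.
#' @export
discriminate <- function(model, z) {
  stopifnot(inherits(model, "gancmlae_model"))
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  if (ncol(z) != model$spec$latent_dim)
    stop("latent width ", ncol(z), " does not match latent_dim ",
         model$spec$latent_dim)
  drop(net_forward(model$critic, z, training = FALSE)$out)
}

#' Reconstruct slices and both latent codes
#'
#' Computes `z = encode(x)`, `x' = decode(z)` and `z' = encode(x')`, the
#' second encoding using the same (shared) encoder parameters; `z` and `z'`
#' feed the latent-consistency loss.
#'
#' @inheritParams encode
#' @return A list with `x_prime` (`H x W x N` array), `z` and `z_prime`
#'   (`N x latent_dim` matrices).
#' @export
reconstruct <- function(model, x) {
  z <- encode(model, x)
  xp <- decode(model, z)
  zp <- encode(model, xp)
  list(x_prime = xp, z = z, z_prime = zp)
}

#' @export
print.gancmlae_model <- function(x, ...) {
  info <- encoder_flatten_info(x$spec)
  np <- sum(vapply(c(net_params(x$encoder), net_params(x$decoder),
                     net_params(x$critic)), length, integer(1)))
  cat("GANCMLAE model\n",
      "  input: ", x$spec$input_size, " x ", x$spec$input_size, "\n",
      "  bottleneck: ", info$side, " x ", info$side, " x ", info$channels,
      " (", info$n_features, " features) -> latent ", x$spec$latent_dim, "\n",
      "  parameters: ", np, "\n",
      "  trained: ", x$trained, " (step ", x$step, ")\n", sep = "")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Stores all parameters, batch-norm running statistics, the architecture
#' spec and the training step in one portable file.
#'
#' @param model A `gancmlae_model`.
#' @param path File path for the checkpoint.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "gancmlae_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "gancmlae_model"))
  m
}
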