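#' 3D cycleGAN configuration
#'
#' Defaults follow the reference cycleGAN recipe with the modifications used
#' for tissue-velocity sequences: generator width halved (32 first-layer
#' features), ResNet-6 generators, 3D PatchGAN discriminators, least-squares
#' adversarial objective, temporal stride 1 to preserve the temporal
#' receptive field, stochastic noise injection in the A-to-B generator's
#' residual blocks, identity regularization, Adam (beta1 = 0.5) at a constant
#' learning rate 2e-4 for 80 epochs with batch size 2 and 32-frame crops.
#'
#' @param base_features generator width at the first layer (default 32).
#' @param n_resnet_blocks number of residual blocks (default 6).
#' @param temporal_stride 1 or 2; temporal stride of the downsampling
#'   convolutions in generator and discriminator (default 1).
#' @param noise_injection add learned per-channel noise (broadcast across the
#'   temporal axis) after every convolution inside the A-to-B generator's
#'   residual blocks (default TRUE).
#' @param lambda_a,lambda_b cycle-consistency weights (default 10).
#' @param lambda_idt identity-loss weight (default 0.5 * lambda_a = 5).
#' @param adversarial_mode "lsgan" (default) or "logistic".
#' @param idt_b_norm "l1" (default) or "l2" norm for the domain-B identity
#'   term.
#' @param lr learning rate (default 2e-4), constant.
#' @param beta1 Adam first-moment decay (default 0.5).
#' @param epochs training epochs (default 80).
#' @param batch_size crops per update (default 2).
#' @param frames_per_crop temporal crop length; must divide the training
#'   sequence length (default 32).
#' @param ndf discriminator width at the first layer (default 64; the width
#'   halving applies to the generator only).
#' @param d_layers number of strided discriminator layers (default 3; with
#'   the two stride-1 layers this is the 5-conv PatchGAN).
#' @param buffer_size discriminator image-buffer capacity (default 50).
#' @param precision_mode "single" (default, fully deterministic) or "mixed"
#'   (activations of convolutions rounded to float32; normalization stays in
#'   double).
#' @param seed optional training seed.
#' @return a `gan_config` list.
#' @export
gan_config <- function(base_features = 32L, n_resnet_blocks = 6L,
                       temporal_stride = 1L, noise_injection = TRUE,
                       lambda_a = 10, lambda_b = 10,
                       lambda_idt = 0.5 * lambda_a,
                       adversarial_mode = c("lsgan", "logistic"),
                       idt_b_norm = c("l1", "l2"),
                       lr = 2e-4, beta1 = 0.5, epochs = 80L, batch_size = 2L,
                       frames_per_crop = 32L, ndf = 64L, d_layers = 3L,
                       buffer_size = 50L,
                       precision_mode = c("single", "mixed"), seed = NULL) {
  if (!temporal_stride %in% c(1L, 2L)) stop("temporal_stride must be 1 or 2")
  if (lambda_a < 0 || lambda_b < 0 || lambda_idt < 0)
    stop("loss weights must be nonnegative")
  structure(list(base_features = as.integer(base_features),
                 n_resnet_blocks = as.integer(n_resnet_blocks),
                 temporal_stride = as.integer(temporal_stride),
                 noise_injection = isTRUE(noise_injection),
                 lambda_a = lambda_a, lambda_b = lambda_b,
                 lambda_idt = lambda_idt,
                 adversarial_mode = match.arg(adversarial_mode),
                 idt_b_norm = match.arg(idt_b_norm),
                 lr = lr, beta1 = beta1, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 frames_per_crop = as.integer(frames_per_crop),
                 ndf = as.integer(ndf), d_layers = as.integer(d_layers),
                 buffer_size = as.integer(buffer_size),
                 precision_mode = match.arg(precision_mode), seed = seed),
            class = "gan_config")
}

#' Build a 3D ResNet generator
#'
#' Encoder (7x7x7 entry convolution; two downsampling convolutions with
#' spatial stride 2 and temporal stride `cfg$temporal_stride`), residual
#' blocks, mirrored decoder (nearest-neighbour upsampling + convolution),
#' single-channel linear output. All padding is 3D reflection; normalization
#' is 3D instance norm. When `stochastic`, per-location Gaussian noise with a
#' learned per-channel scale (initialized at 0) is added after each
#' convolution inside every residual block, with the same noise value
#' broadcast across the temporal axis.
#'
#' @param cfg a [gan_config()].
#' @param stochastic build the noise-injecting variant.
#' @return object of class `tvi_generator`.
#' @export
build_generator <- function(cfg = gan_config(), stochastic = FALSE) {
  nf <- cfg$base_features; ts <- cfg$temporal_stride
  layers <- list(
    nn_conv(1L, nf, 7L),
    nn_in(), nn_relu(),
    nn_conv(nf, 2L * nf, 3L, s = c(2L, 2L, ts)),
    nn_in(), nn_relu(),
    nn_conv(2L * nf, 4L * nf, 3L, s = c(2L, 2L, ts)),
    nn_in(), nn_relu())
  for (i in seq_len(cfg$n_resnet_blocks))
    layers <- c(layers, list(nn_resblock(4L * nf, stochastic)))
  layers <- c(layers, list(
    nn_upsample(c(2L, 2L, ts)),
    nn_conv(4L * nf, 2L * nf, 3L),
    nn_in(), nn_relu(),
    nn_upsample(c(2L, 2L, ts)),
    nn_conv(2L * nf, nf, 3L),
    nn_in(), nn_relu(),
    nn_conv(nf, 1L, 7L)))
  structure(list(layers = layers, stochastic = stochastic,
                 temporal_stride = ts, precision = cfg$precision_mode),
            class = "tvi_generator")
}

#' Build a 3D PatchGAN discriminator
#'
#' Stacked strided 3D convolutions (kernel 4, spatial stride 2, temporal
#' stride `cfg$temporal_stride` in the downsampling layers) producing a grid
#' of patch scores; no global pooling.
#'
#' @param cfg a [gan_config()].
#' @return object of class `tvi_discriminator`.
#' @export
build_discriminator <- function(cfg = gan_config()) {
  ndf <- cfg$ndf; ts <- cfg$temporal_stride
  layers <- list(nn_conv(1L, ndf, 4L, s = c(2L, 2L, ts), pad = 1L,
                         pad_hi = 1L, reflect = FALSE),
                 nn_lrelu())
  cin <- ndf
  for (i in seq_len(cfg$d_layers - 1L)) {
    cout <- min(cin * 2L, 8L * ndf)
    layers <- c(layers, list(
      nn_conv(cin, cout, 4L, s = c(2L, 2L, ts), pad = 1L, pad_hi = 1L,
              reflect = FALSE),
      nn_in(), nn_lrelu()))
    cin <- cout
  }
  cout <- min(cin * 2L, 8L * ndf)
  layers <- c(layers, list(
    nn_conv(cin, cout, 4L, s = 1L, pad = 1L, pad_hi = 2L, reflect = FALSE),
    nn_in(), nn_lrelu(),
    nn_conv(cout, 1L, 4L, s = 1L, pad = 1L, pad_hi = 2L, reflect = FALSE)))
  structure(list(layers = layers, temporal_stride = ts,
                 precision = cfg$precision_mode),
            class = "tvi_discriminator")
}

#' Per-axis receptive field of a network
#'
#' Closed-form recursion r <- r + (k - 1) * prod(earlier strides) over the
#' convolutional layers (upsampling divides the jump).
#'
#' @param net a `tvi_generator` or `tvi_discriminator`.
#' @return integer length-3 receptive field (rows, cols, frames) of one
#'   output element.
#' @export
receptive_field <- function(net) {
  r <- c(1, 1, 1); jump <- c(1, 1, 1)
  walk <- function(layers) {
    for (layer in layers) {
      if (layer$type == "conv") {
        r <<- r + (layer$k - 1) * jump
        jump <<- jump * layer$s
      } else if (layer$type == "upsample") {
        jump <<- jump / layer$f
      } else if (layer$type == "resblock") {
        walk(layer$sub)
      }
    }
  }
  walk(net$layers)
  as.integer(ceiling(r))
}

# Validate a (h, w, t) grid against the generator's down/up-sampling factors.
check_generator_shape <- function(net, sdim) {
  ts <- net$temporal_stride
  if (any(sdim[1:2] %% 4L != 0L) || any(sdim[1:2] < 8L))
    stop("shape error: spatial dims must be multiples of 4 and >= 8, got ",
         paste(sdim, collapse = "x"))
  if (sdim[3] %% (ts * ts) != 0L || sdim[3] < 4L)
    stop("shape error: temporal length must be a multiple of ", ts * ts,
         " and >= 4, got ", sdim[3])
  invisible(TRUE)
}

#' Run a generator on a 3D grid
#'
#' @param net a `tvi_generator`.
#' @param v 3D array (h x w x t); spatial dims must be multiples of 4.
#' @param noise_seed optional seed controlling the injected noise of a
#'   stochastic generator.
#' @return 3D array of the same shape (temporal stride 1) or with the
#'   temporal length preserved through symmetric down/up-sampling.
#' @export
generator_apply <- function(net, v, noise_seed = NULL) {
  sdim <- dim(v)
  check_generator_shape(net, sdim)
  x <- matrix(as.vector(v), 1L)
  run <- function() net_fwd(net, x, sdim, keep_cache = FALSE,
                            precision = net$precision)
  r <- if (net$stochastic) with_seed(noise_seed, run()) else run()
  array(r$y, r$sdim)
}

#' Translate a TVI sequence with a trained model
#'
#' Fully convolutional inference on arbitrary-length sequences. The default
#' runs the whole sequence through the generator in one pass: convolutions
#' gather their inputs in bounded-memory chunks internally, so the sequence
#' length is limited only by the footprint of one feature map. An optional
#' overlap-tiled mode (`tile_frames`) caps that footprint too; it pads each
#' tile by at least the generator's temporal receptive-field half-width and
#' stitches tile centers. Because instance normalization uses per-pass
#' statistics, tiled output approximates (rather than reproduces) the
#' single-pass result; the approximation tightens as tiles lengthen.
#'
#' @param model a `trained_translator` from [train_translator()] (or a list
#'   with generators `G_B`, `G_A`).
#' @param seq a `tvi_sequence` (standardized scale recommended).
#' @param direction "AtoB" (generator G_B) or "BtoA" (generator G_A).
#' @param stochastic_seed seed for the injected noise of a stochastic
#'   generator; the same seed is replayed on every tile so the spatial noise
#'   pattern is shared across the sequence.
#' @param tile_frames temporal tile length for the memory-capped mode
#'   (default NULL: single exact pass).
#' @param tile_margin tile overlap margin in frames (default: half the
#'   generator's temporal receptive field).
#' @return translated `tvi_sequence` (`domain_label = "translated"`).
#' @export
translate <- function(model, seq, direction = c("AtoB", "BtoA"),
                      stochastic_seed = NULL, tile_frames = NULL,
                      tile_margin = NULL) {
  direction <- match.arg(direction)
  gen <- if (direction == "AtoB") model$generators$G_B else model$generators$G_A
  stopifnot(inherits(seq, "tvi_sequence"))
  v <- seq$velocity
  d <- dim(v)
  res <- seq
  res$domain_label <- "translated"
  if (is.null(tile_frames) || tile_frames >= d[3]) {
    res$velocity <- generator_apply(gen, v, noise_seed = stochastic_seed)
    return(res)
  }
  if (is.null(tile_margin))
    tile_margin <- as.integer(ceiling((receptive_field(gen)[3] - 1) / 2))
  ts2 <- gen$temporal_stride^2
  out <- array(0, d)
  start <- 1L
  while (start <= d[3]) {
    stop_ <- min(start + tile_frames - 1L, d[3])
    lo <- max(1L, start - tile_margin)
    hi <- min(d[3], stop_ + tile_margin)
    # round the padded window to the stride-compatible length
    while ((hi - lo + 1L) %% ts2 != 0L && lo > 1L) lo <- lo - 1L
    while ((hi - lo + 1L) %% ts2 != 0L && hi < d[3]) hi <- hi + 1L
    y <- generator_apply(gen, v[, , lo:hi, drop = FALSE],
                         noise_seed = stochastic_seed)
    out[, , start:stop_] <- y[, , (start - lo + 1L):(stop_ - lo + 1L)]
    start <- stop_ + 1L
  }
  res$velocity <- out
  res
}

#' Save / load a trained translator
#'
#' Checkpoints are self-describing: the configuration snapshot and training
#' history travel with the weights.
#'
#' @param model a `trained_translator`.
#' @param path file path (RDS container).
#' @export
save_translator <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_translator
#' @export
load_translator <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "trained_translator"))
    stop("not a trained_translator checkpoint: ", path)
  m
}
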