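# Generator and discriminator computation graphs.
#
# Generator: Convolution-InstanceNorm-ReLU encoder (3x3 first layer, then two
# stride-2 layers doubling the channels), a residual path, and a bilinear-
# upsample + convolution decoder with skip connections (channel concatenation
# followed by a 1x1 fusion convolution) between matching levels; tanh head so
# outputs live in [-1, 1]. Discriminator: five blocks of two 3x3 convolutions
# with leaky-ReLU (channel doubling) followed by stride-2 average pooling,
# then two fully connected layers to a single unbounded score (least-squares
# GAN convention: no terminal squashing); input optionally subdivided into
# subtiles whose scores are averaged.

#' Generator architecture hyperparameters
#'
#' @param in_channels,out_channels image channels (3 on both sides; grayscale
#'   tiles are replicated to 3 channels so the two generators stay
#'   shape-symmetric)
#' @param base_channels channels after the first convolution (64 at full
#'   scale; smaller for CPU-sized configurations)
#' @param n_residual_blocks residual blocks on the bottleneck (9 at full scale)
#' @param skip_connections use encoder-decoder skip connections
#' @return object of class `generator_spec`
#' @export
generator_spec <- function(in_channels = 3L, base_channels = 64L,
                           n_residual_blocks = 9L, skip_connections = TRUE,
                           out_channels = 3L) {
  stopifnot(n_residual_blocks >= 1, base_channels >= 1)
  structure(list(in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels),
                 n_downsampling = 2L,
                 n_residual_blocks = as.integer(n_residual_blocks),
                 skip_connections = isTRUE(skip_connections),
                 out_channels = as.integer(out_channels)),
            class = "generator_spec")
}

#' Discriminator architecture hyperparameters
#'
#' @param in_channels input channels
#' @param base_channels channels after the first block (doubled by each
#'   further block)
#' @param n_blocks conv-conv-pool blocks (5 at full scale; each halves the
#'   spatial size)
#' @param fc_width width of the first fully connected layer
#' @param input_size spatial side the fully connected head is built for;
#'   larger inputs must be scored through `n_tiles` subdivision
#' @return object of class `discriminator_spec`
#' @export
discriminator_spec <- function(in_channels = 3L, base_channels = 64L,
                               n_blocks = 5L, fc_width = 512L,
                               input_size = 256L) {
  if (input_size %% (2^n_blocks) != 0) {
    stop(sprintf("input_size %d not divisible by 2^%d pooling stages", input_size, n_blocks))
  }
  structure(list(in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels),
                 n_blocks = as.integer(n_blocks),
                 fc_width = as.integer(fc_width),
                 input_size = as.integer(input_size)),
            class = "discriminator_spec")
}

# weight init: N(0, 0.02), biases zero (consumes the caller's RNG stream)
.conv_w <- function(k, cin, cout, sd = 0.02) {
  w <- matrix(stats::rnorm(k * k * cin * cout, sd = sd), k * k * cin, cout)
  attr(w, "k") <- as.integer(k)
  w
}

#' Initialise generator parameters
#' @param spec a [generator_spec]
#' @return named list of parameter arrays
#' @export
init_generator <- function(spec) {
  bc <- spec$base_channels
  p <- list()
  p$enc0_w <- .conv_w(3, spec$in_channels, bc);      p$enc0_b <- numeric(bc)
  p$down1_w <- .conv_w(3, bc, 2 * bc);               p$down1_b <- numeric(2 * bc)
  p$down2_w <- .conv_w(3, 2 * bc, 4 * bc);           p$down2_b <- numeric(4 * bc)
  for (i in seq_len(spec$n_residual_blocks)) {
    p[[sprintf("res%d_c1_w", i)]] <- .conv_w(3, 4 * bc, 4 * bc)
    p[[sprintf("res%d_c1_b", i)]] <- numeric(4 * bc)
    p[[sprintf("res%d_c2_w", i)]] <- .conv_w(3, 4 * bc, 4 * bc)
    p[[sprintf("res%d_c2_b", i)]] <- numeric(4 * bc)
  }
  p$up1_w <- .conv_w(3, 4 * bc, 2 * bc);             p$up1_b <- numeric(2 * bc)
  p$up2_w <- .conv_w(3, 2 * bc, bc);                 p$up2_b <- numeric(bc)
  if (spec$skip_connections) {
    p$fuse1_w <- .conv_w(1, 4 * bc, 2 * bc);         p$fuse1_b <- numeric(2 * bc)
    p$fuse0_w <- .conv_w(1, 2 * bc, bc);             p$fuse0_b <- numeric(bc)
  }
  p$out_w <- .conv_w(3, bc, spec$out_channels);      p$out_b <- numeric(spec$out_channels)
  p
}

#' Initialise discriminator parameters
#' @param spec a [discriminator_spec]
#' @return named list of parameter arrays
#' @export
init_discriminator <- function(spec) {
  p <- list()
  cin <- spec$in_channels
  ch <- spec$base_channels
  for (i in seq_len(spec$n_blocks)) {
    p[[sprintf("blk%d_c1_w", i)]] <- .conv_w(3, cin, ch)
    p[[sprintf("blk%d_c1_b", i)]] <- numeric(ch)
    p[[sprintf("blk%d_c2_w", i)]] <- .conv_w(3, ch, ch)
    p[[sprintf("blk%d_c2_b", i)]] <- numeric(ch)
    cin <- ch
    ch <- ch * 2L
  }
  final_ch <- cin
  side <- spec$input_size %/% (2^spec$n_blocks)
  d_in <- side * side * final_ch
  p$fc1_w <- matrix(stats::rnorm(d_in * spec$fc_width, sd = 0.02), d_in, spec$fc_width)
  p$fc1_b <- numeric(spec$fc_width)
  p$fc2_w <- matrix(stats::rnorm(spec$fc_width, sd = 0.02), spec$fc_width, 1L)
  p$fc2_b <- numeric(1L)
  p
}

# graph-level generator forward; x is an ad node with (H, W, C) value
gen_forward_graph <- function(g, params, spec, x, record_residuals = FALSE) {
  d <- dim(x$value)
  if (d[1] %% 4 != 0 || d[2] %% 4 != 0) {
    stop(sprintf(paste0("generator input %dx%d: spatial size must be divisible by 4 ",
                        "(two stride-2 stages); pad the image first"), d[1], d[2]))
  }
  if (d[3] != spec$in_channels) {
    stop(sprintf("generator expects %d channels, got %d", spec$in_channels, d[3]))
  }
  cir <- function(h, w, b, stride = 1, pad = 1) {
    ad_relu(g, ad_instance_norm(g, ad_conv2d(g, h, w, b, stride, pad)))
  }
  # params may be plain arrays (inference) or live graph nodes (training)
  lf <- function(nm) {
    p <- params[[nm]]
    if (is.environment(p)) p else ad_leaf(g, p)
  }
  h0 <- cir(x, lf("enc0_w"), lf("enc0_b"))
  h1 <- cir(h0, lf("down1_w"), lf("down1_b"), stride = 2)
  h2 <- cir(h1, lf("down2_w"), lf("down2_b"), stride = 2)
  r <- h2
  res_nodes <- vector("list", spec$n_residual_blocks)
  for (i in seq_len(spec$n_residual_blocks)) {
    t1 <- cir(r, lf(sprintf("res%d_c1_w", i)), lf(sprintf("res%d_c1_b", i)))
    t2 <- ad_instance_norm(g, ad_conv2d(g, t1,
            lf(sprintf("res%d_c2_w", i)), lf(sprintf("res%d_c2_b", i)), 1, 1))
    r <- ad_add(g, r, t2)
    if (record_residuals) res_nodes[[i]] <- r
  }
  u1 <- cir(ad_upsample2(g, r), lf("up1_w"), lf("up1_b"))
  if (spec$skip_connections) {
    u1 <- ad_conv2d(g, ad_concat_c(g, u1, h1), lf("fuse1_w"), lf("fuse1_b"), 1, 0)
  }
  u2 <- cir(ad_upsample2(g, u1), lf("up2_w"), lf("up2_b"))
  if (spec$skip_connections) {
    u2 <- ad_conv2d(g, ad_concat_c(g, u2, h0), lf("fuse0_w"), lf("fuse0_b"), 1, 0)
  }
  out <- ad_tanh(g, ad_conv2d(g, u2, lf("out_w"), lf("out_b"), 1, 1))
  list(out = out, residuals = res_nodes, enc = list(h0, h1, h2))
}

#' Generator forward pass (inference)
#'
#' @param model_part list with `params` and `spec` (one generator of a
#'   [translation_model])
#' @param x (H, W, 3) array in `[-1, 1]`, H and W divisible by 4
#' @param trace if `TRUE`, also return the activation shapes along the
#'   downsampling path
#' @return (H, W, 3) array in `[-1, 1]`; with `trace`, a list `out`, `trace`
#' @export
generator_forward <- function(model_part, x, trace = FALSE) {
  g <- ad_graph(keep = FALSE)
  fw <- gen_forward_graph(g, model_part$params, model_part$spec, ad_leaf(g, x))
  if (!trace) return(fw$out$value)
  list(out = fw$out$value,
       trace = lapply(fw$enc, function(nd) dim(nd$value)))
}

# graph-level discriminator on one subtile (must match spec$input_size)
disc_forward_one <- function(g, params, spec, x) {
  d <- dim(x$value)
  if (d[1] != spec$input_size || d[2] != spec$input_size) {
    stop(sprintf("discriminator head built for %dx%d input, got %dx%d",
                 spec$input_size, spec$input_size, d[1], d[2]))
  }
  if (d[1] < 2^spec$n_blocks) {
    stop(sprintf("input %dx%d too small for %d pooling stages", d[1], d[2], spec$n_blocks))
  }
  lf <- function(nm) {
    p <- params[[nm]]
    if (is.environment(p)) p else ad_leaf(g, p)
  }
  h <- x
  for (i in seq_len(spec$n_blocks)) {
    h <- ad_lrelu(g, ad_conv2d(g, h, lf(sprintf("blk%d_c1_w", i)),
                               lf(sprintf("blk%d_c1_b", i)), 1, 1))
    h <- ad_lrelu(g, ad_conv2d(g, h, lf(sprintf("blk%d_c2_w", i)),
                               lf(sprintf("blk%d_c2_b", i)), 1, 1))
    h <- ad_avgpool2(g, h)
  }
  h <- ad_lrelu(g, ad_dense(g, ad_flatten(g, h), lf("fc1_w"), lf("fc1_b")))
  ad_dense(g, h, lf("fc2_w"), lf("fc2_b"))
}

# graph-level score with optional subdivision into an n x n subtile mosaic;
# the image score is the mean of the per-subtile scalars
disc_forward_graph <- function(g, params, spec, x, n_tiles = 1L) {
  d <- dim(x$value)
  if (n_tiles == 1L) return(disc_forward_one(g, params, spec, x))
  ts <- d[1] %/% n_tiles
  stopifnot(d[1] %% n_tiles == 0, d[2] %% n_tiles == 0)
  acc <- NULL
  for (i in seq_len(n_tiles)) for (j in seq_len(n_tiles)) {
    sub <- ad_crop(g, x, (i - 1L) * ts + seq_len(ts), (j - 1L) * ts + seq_len(ts))
    s <- disc_forward_one(g, params, spec, sub)
    acc <- if (is.null(acc)) s else ad_add(g, acc, s)
  }
  ad_affine(g, acc, 1 / n_tiles^2, 0)
}

#' Discriminator forward pass (inference)
#'
#' @param model_part list with `params` and `spec` (one discriminator of a
#'   [translation_model])
#' @param x (H, W, C) array, or list of such arrays (a batch)
#' @param n_tiles subdivide the input into an `n_tiles` x `n_tiles` mosaic of
#'   subtiles, score each, and return the mean
#' @return one numeric score per image
#' @export
discriminator_forward <- function(model_part, x, n_tiles = 1L) {
  xs <- if (is.list(x) && !is.array(x)) x else list(x)
  vapply(xs, function(xi) {
    g <- ad_graph(keep = FALSE)
    disc_forward_graph(g, model_part$params, model_part$spec, ad_leaf(g, xi), n_tiles)$value
  }, 1.0)
}

#' Assemble a translation model (two generators, two discriminators)
#'
#' @param gen_spec a [generator_spec] shared by `G_A` (A to B) and `G_B`
#'   (B to A)
#' @param disc_spec a [discriminator_spec] shared by `D_A` and `D_B`
#' @param seed seed for weight initialisation
#' @param domains channel semantics of the two image domains, e.g.
#'   `list(A = "gray1", B = "stain2")`
#' @return object of class `translation_model`
#' @export
translation_model <- function(gen_spec, disc_spec, seed = 1L,
                              domains = list(A = "gray1", B = "stain2")) {
  params <- with_local_seed(seed, list(
    G_A = init_generator(gen_spec),
    G_B = init_generator(gen_spec),
    D_A = init_discriminator(disc_spec),
    D_B = init_discriminator(disc_spec)))
  structure(list(gen_spec = gen_spec, disc_spec = disc_spec,
                 G_A = list(params = params$G_A, spec = gen_spec),
                 G_B = list(params = params$G_B, spec = gen_spec),
                 D_A = list(params = params$D_A, spec = disc_spec),
                 D_B = list(params = params$D_B, spec = disc_spec),
                 domains = domains, seed = as.integer(seed), kind = "cyclegan"),
            class = "translation_model")
}

#' Identity translation model (for pipeline stubs and composition tests)
#' @param domains channel semantics of the two domains
#' @return object of class `translation_model` with `kind = "identity"`
#' @export
identity_model <- function(domains = list(A = "gray1", B = "gray1")) {
  structure(list(kind = "identity", domains = domains),
            class = "translation_model")
}

#' Count generator parameters
#' @param model_part list with `params`
#' @return integer
#' @export
n_parameters <- function(model_part) {
  sum(vapply(model_part$params, length, 1L))
}

#' Save a model checkpoint
#'
#' A single serialised archive holding both generators, both discriminators,
#' their specs, the seed record and (optionally) optimiser state.
#'
#' @param model a [translation_model]
#' @param path output file (.rds)
#' @param extra optional named list stored alongside (e.g. optimiser state)
#' @export
save_checkpoint <- function(model, path, extra = NULL) {
  saveRDS(list(model = model, extra = extra,
               package_version = as.character(utils::packageVersion("cyclestain"))),
          path)
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint]
#' @param path .rds file
#' @return list with `model` and `extra`
#' @export
load_checkpoint <- function(path) {
  readRDS(path)
}
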