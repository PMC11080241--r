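# Customized 1-D convolutional GAN for sequence representation learning.
#
# The generator maps Gaussian noise through three stride-2 transpose
# convolutions (ReLU, ReLU, tanh) to a fake sequence tensor; the discriminator
# scores sequences with five stride-1 same-padding ReLU convolutions followed
# by flatten and a single tanh unit. Neither network uses batch normalization.
# Because the discriminator head is tanh (range [-1, 1]), training minimizes a
# least-squares loss against +1 (real) / -1 (fake) targets. After adversarial
# pre-training the discriminator's fifth convolution is kept frozen and serves
# as a per-position feature extractor for the affinity predictor.

#' Configuration for a 1-D convolutional GAN
#'
#' Defaults follow the customized sequence DCGAN: generator filters
#' (128, 64, in_channels), discriminator filters (4, 8, 16, 32, 64), kernel
#' size 3 everywhere, Adam with learning rate 0.001. \code{seq_len} must be
#' divisible by 8 because the generator upsamples x2 three times.
#'
#' @param seq_len sequence length the networks operate on (divisible by 8).
#' @param in_channels 1 for scaled label encodings, 25 for scaled BLOSUM rows.
#' @param noise_dim channels of the Gaussian noise tensor, laid out as
#'   (seq_len/8, noise_dim).
#' @param gen_filters integer triple of transpose-conv filter counts; the last
#'   entry must equal \code{in_channels}.
#' @param disc_filters integer quintuple of conv filter counts; the last entry
#'   is the width of extracted feature maps.
#' @param kernel_size convolution kernel length.
#' @param learning_rate,batch_size,epochs Adam step size and training loop.
#' @param seed RNG seed controlling initialization, batching and noise.
#' @return an object of class \code{gan_config}.
#' @export
gan_config <- function(seq_len, in_channels = 1L, noise_dim = 100L,
                       gen_filters = c(128L, 64L, in_channels),
                       disc_filters = c(4L, 8L, 16L, 32L, 64L),
                       kernel_size = 3L, learning_rate = 0.001,
                       batch_size = 256L, epochs = 30L, seed = 1L) {
  check_that(seq_len %% 8 == 0, "seq_len must be divisible by 8 (three stride-2 upsamplings)",
             "gandta_config_error")
  check_that(length(gen_filters) == 3, "gen_filters must have 3 entries", "gandta_config_error")
  check_that(length(disc_filters) == 5, "disc_filters must have 5 entries", "gandta_config_error")
  check_that(gen_filters[3] == in_channels,
             "last generator filter count must equal in_channels", "gandta_config_error")
  structure(list(seq_len = as.integer(seq_len), in_channels = as.integer(in_channels),
                 noise_dim = as.integer(noise_dim), gen_filters = as.integer(gen_filters),
                 disc_filters = as.integer(disc_filters), kernel_size = as.integer(kernel_size),
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "gan_config")
}

#' Build the generator network
#'
#' Noise of shape (seq_len/8, noise_dim) passes through three stride-2
#' transpose convolutions with activations (ReLU, ReLU, tanh), tripling the
#' temporal resolution to seq_len and ending with \code{in_channels} output
#' channels in [-1, 1]. No batch normalization.
#'
#' @param config a \code{\link{gan_config}}.
#' @return an object of class \code{gan_generator} with a \code{spec} field
#'   (ordered layer descriptions) and the constructed layers.
#' @export
build_generator <- function(config) {
  check_that(inherits(config, "gan_config"), "config must be a gan_config", "gandta_config_error")
  k <- config$kernel_size
  f <- config$gen_filters
  acts <- c("relu", "relu", "tanh")
  in_ch <- c(config$noise_dim, f[1], f[2])
  layers <- list()
  spec <- list()
  for (i in 1:3) {
    layers[[i]] <- nn_tconv1d(in_ch[i], f[i], k, acts[i])
    spec[[i]] <- list(layer = "conv1d_transpose", filters = f[i], kernel = k,
                      stride = 2L, activation = acts[i], batchnorm = FALSE)
  }
  layers[[1]]$entry <- TRUE  # noise input carries no gradient
  structure(list(spec = spec, layers = layers, config = config), class = "gan_generator")
}

#' Build the discriminator network
#'
#' Five stride-1 same-padding ReLU convolutions with filters (4, 8, 16, 32,
#' 64) and kernel 3, then flatten and a single-unit dense layer with tanh: a
#' scalar realness score in [-1, 1]. No batch normalization.
#'
#' @param config a \code{\link{gan_config}}.
#' @return an object of class \code{gan_discriminator} with a \code{spec}
#'   field and the constructed layers.
#' @export
build_discriminator <- function(config) {
  check_that(inherits(config, "gan_config"), "config must be a gan_config", "gandta_config_error")
  k <- config$kernel_size
  f <- config$disc_filters
  in_ch <- c(config$in_channels, f[-5])
  layers <- list()
  spec <- list()
  for (i in 1:5) {
    layers[[i]] <- nn_conv1d(in_ch[i], f[i], k, "relu")
    spec[[i]] <- list(layer = "conv1d", filters = f[i], kernel = k, stride = 1L,
                      padding = "same", activation = "relu", batchnorm = FALSE)
  }
  layers[[6]] <- nn_dense(config$seq_len * f[5], 1L, "tanh")
  spec[[6]] <- list(layer = "flatten", batchnorm = FALSE)
  spec[[7]] <- list(layer = "dense", units = 1L, activation = "tanh", batchnorm = FALSE)
  structure(list(spec = spec, layers = layers, config = config), class = "gan_discriminator")
}

# Coerce a corpus (matrix B x L for 1 channel, or array B x L x C) to the
# 3-d tensor the networks consume, validating against the config.
as_gan_tensor <- function(corpus, config) {
  if (is.matrix(corpus)) corpus <- array(corpus, c(nrow(corpus), ncol(corpus), 1L))
  check_that(is.array(corpus) && length(dim(corpus)) == 3, "corpus must be a matrix or 3-d array")
  d <- dim(corpus)
  check_that(d[1] > 0, "corpus must be non-empty")
  check_that(d[2] == config$seq_len,
             sprintf("corpus length %d does not match config seq_len %d", d[2], config$seq_len))
  check_that(d[3] == config$in_channels,
             sprintf("corpus has %d channels, config expects %d", d[3], config$in_channels))
  corpus
}

gan_noise <- function(n, config) {
  array(stats::rnorm(n * (config$seq_len %/% 8L) * config$noise_dim),
        c(n, config$seq_len %/% 8L, config$noise_dim))
}

#' Adversarially pre-train the GAN on an unlabeled sequence corpus
#'
#' Alternating 1:1 updates: the discriminator minimizes the least-squares loss
#' mean((D(real) - 1)^2 + (D(fake) + 1)^2), the generator minimizes
#' mean((D(G(z)) - 1)^2). Both use Adam at \code{config$learning_rate}. Fully
#' deterministic given \code{config$seed}.
#'
#' @param corpus numeric matrix (n x seq_len) of scaled label encodings, or
#'   array (n x seq_len x channels) of scaled BLOSUM encodings; values in
#'   [-1, 1].
#' @param config a \code{\link{gan_config}}.
#' @return a \code{gan_checkpoint}: generator and discriminator parameters,
#'   the config, the per-epoch loss history, and a corpus fingerprint.
#' @export
train_gan <- function(corpus, config) {
  x <- as_gan_tensor(corpus, config)
  n <- dim(x)[1]
  set.seed(config$seed)
  gen <- build_generator(config)
  disc <- build_discriminator(config)
  opt_g <- adam_state(gen$layers, lr = config$learning_rate)
  opt_d <- adam_state(disc$layers, lr = config$learning_rate)
  bs <- min(config$batch_size, n)
  history <- data.frame(epoch = integer(0), d_loss = numeric(0), g_loss = numeric(0))
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    d_losses <- g_losses <- c()
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      b <- length(idx)
      xr <- x[idx, , , drop = FALSE]
      # --- discriminator step on real + fake with targets +1 / -1
      z <- gan_noise(b, config)
      xf <- seq_forward(gen$layers, z, training = FALSE)
      xb <- array(0, c(2L * b, config$seq_len, config$in_channels))
      xb[seq_len(b), , ] <- xr
      xb[b + seq_len(b), , ] <- xf
      tgt <- c(rep(1, b), rep(-1, b))
      zero_grads(disc$layers)
      disc$layers[[1]]$entry <- TRUE  # no input gradient needed for the D step
      s <- seq_forward(disc$layers, xb, training = TRUE)
      d_loss <- mean((as.vector(s) - tgt)^2)
      seq_backward(disc$layers, matrix(2 * (as.vector(s) - tgt) / (2 * b), 2L * b, 1L))
      adam_step(opt_d, disc$layers)
      disc$layers[[1]]$entry <- FALSE  # the G step backpropagates into the fake batch
      # --- generator step: push D(G(z)) toward +1
      z <- gan_noise(b, config)
      zero_grads(gen$layers)
      zero_grads(disc$layers)
      xf <- seq_forward(gen$layers, z, training = TRUE)
      s <- seq_forward(disc$layers, xf, training = TRUE)
      g_loss <- mean((as.vector(s) - 1)^2)
      dxf <- seq_backward(disc$layers, matrix(2 * (as.vector(s) - 1) / b, b, 1L))
      seq_backward(gen$layers, array(dxf, dim(xf)))
      adam_step(opt_g, gen$layers)
      check_that(is.finite(d_loss) && is.finite(g_loss),
                 "GAN training diverged (non-finite loss)", "gandta_numeric_error")
      d_losses <- c(d_losses, d_loss); g_losses <- c(g_losses, g_loss)
    }
    history <- rbind(history, data.frame(epoch = epoch, d_loss = mean(d_losses),
                                         g_loss = mean(g_losses)))
  }
  structure(list(generator = collect_params(gen$layers),
                 discriminator = collect_params(disc$layers),
                 config = config, history = history,
                 corpus_fingerprint = fingerprint_strings(format_full(as.vector(x)[seq_len(min(1000, length(x)))]))),
            class = "gan_checkpoint")
}

# Rebuild networks from a checkpoint (parameters restored, RNG untouched).
gan_networks <- function(checkpoint) {
  check_that(inherits(checkpoint, "gan_checkpoint"), "need a gan_checkpoint")
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv))
  }
  gen <- build_generator(checkpoint$config)
  disc <- build_discriminator(checkpoint$config)
  # build_* initializes randomly without seeding; overwrite everything
  restore_params(gen$layers, checkpoint$generator)
  restore_params(disc$layers, checkpoint$discriminator)
  list(gen = gen, disc = disc)
}

#' Sample sequences from a trained generator
#' @param checkpoint a \code{gan_checkpoint}.
#' @param n number of sequences.
#' @param seed RNG seed for the noise draw.
#' @return array (n, seq_len, in_channels) with values in [-1, 1].
#' @export
generate_sequences <- function(checkpoint, n, seed = 1L) {
  nets <- gan_networks(checkpoint)
  set.seed(seed)
  z <- gan_noise(n, checkpoint$config)
  seq_forward(nets$gen$layers, z, training = FALSE)
}

#' Score sequences with the trained discriminator
#' @param checkpoint a \code{gan_checkpoint}.
#' @param batch matrix (n x seq_len) or array (n, seq_len, channels).
#' @return numeric vector of realness scores in [-1, 1].
#' @export
discriminator_score <- function(checkpoint, batch) {
  x <- as_gan_tensor(batch, checkpoint$config)
  nets <- gan_networks(checkpoint)
  as.vector(seq_forward(nets$disc$layers, x, training = FALSE))
}

#' Extract frozen per-position features from the discriminator
#'
#' Runs the batch through the trained discriminator's five convolutions and
#' returns the activations of the fifth (pre-flatten), the representation the
#' affinity predictor consumes. Parameters are frozen; output is
#' deterministic.
#'
#' @param checkpoint a \code{gan_checkpoint}.
#' @param batch matrix (n x seq_len) or array (n, seq_len, channels) matching
#'   the checkpoint's encoding config.
#' @return array (n, seq_len, last discriminator filter count).
#' @export
extract_features <- function(checkpoint, batch) {
  x <- as_gan_tensor(batch, checkpoint$config)
  nets <- gan_networks(checkpoint)
  seq_forward(nets$disc$layers[1:5], x, training = FALSE)
}

#' Save / load a GAN checkpoint as plain text
#'
#' Writes \code{generator.txt} and \code{discriminator.txt} (full-precision
#' parameter dumps) plus \code{config.json} with the configuration, corpus
#' fingerprint and loss history. Reloading reproduces bit-identical forward
#' passes.
#'
#' @param checkpoint a \code{gan_checkpoint}.
#' @param dir directory to create.
#' @return \code{dir}, invisibly (save); a \code{gan_checkpoint} (load).
#' @export
save_gan_checkpoint <- function(checkpoint, dir) {
  check_that(inherits(checkpoint, "gan_checkpoint"), "need a gan_checkpoint")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_params_txt(checkpoint$generator, file.path(dir, "generator.txt"))
  write_params_txt(checkpoint$discriminator, file.path(dir, "discriminator.txt"))
  side <- list(config = unclass(checkpoint$config),
               corpus_fingerprint = checkpoint$corpus_fingerprint,
               history = checkpoint$history)
  jsonlite::write_json(side, file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_gan_checkpoint
#' @export
load_gan_checkpoint <- function(dir) {
  check_that(dir.exists(dir), "checkpoint directory not found")
  side <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  cfg <- do.call(gan_config, side$config[c("seq_len", "in_channels", "noise_dim",
                                           "gen_filters", "disc_filters", "kernel_size",
                                           "learning_rate", "batch_size", "epochs", "seed")])
  structure(list(generator = read_params_txt(file.path(dir, "generator.txt")),
                 discriminator = read_params_txt(file.path(dir, "discriminator.txt")),
                 config = cfg, history = as.data.frame(side$history),
                 corpus_fingerprint = side$corpus_fingerprint),
            class = "gan_checkpoint")
}
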