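test_that("gan_config enforces the architectural invariants", {
  cfg <- gan_config(seq_len = 64L)
  expect_identical(cfg$gen_filters, c(128L, 64L, 1L))
  expect_identical(cfg$disc_filters, c(4L, 8L, 16L, 32L, 64L))
  expect_identical(cfg$kernel_size, 3L)
  expect_error(gan_config(seq_len = 30L), class = "gandta_config_error")
  expect_error(gan_config(seq_len = 64L, in_channels = 25L,
                          gen_filters = c(128L, 64L, 1L)),
               class = "gandta_config_error")  # last gen filter must match channels
})

test_that("the generator is three transpose convolutions ending in tanh", {
  gen <- build_generator(gan_config(seq_len = 64L))
  expect_length(gen$spec, 3)
  expect_true(all(vapply(gen$spec, `[[`, "", "layer") == "conv1d_transpose"))
  expect_identical(vapply(gen$spec, `[[`, "", "activation"), c("relu", "relu", "tanh"))
  expect_identical(vapply(gen$spec, function(s) s$filters, 0L), c(128L, 64L, 1L))
  expect_true(all(vapply(gen$spec, function(s) s$stride, 0L) == 2L))
  # upsampling: noise (seq_len/8, noise_dim) -> (seq_len, channels) in [-1, 1]
  set.seed(1)
  z <- array(rnorm(2 * 8 * 100), c(2, 8, 100))
  out <- gandta:::seq_forward(gen$layers, z)
  expect_identical(dim(out), c(2L, 64L, 1L))
  expect_true(all(out >= -1 & out <= 1))
})

test_that("the discriminator is five ReLU convs plus a tanh unit, kernel 3", {
  disc <- build_discriminator(gan_config(seq_len = 64L))
  convs <- Filter(function(s) s$layer == "conv1d", disc$spec)
  expect_length(convs, 5)
  expect_identical(vapply(convs, function(s) s$filters, 0L), c(4L, 8L, 16L, 32L, 64L))
  expect_true(all(vapply(convs, function(s) s$kernel, 0L) == 3L))
  expect_true(all(vapply(convs, `[[`, "", "activation") == "relu"))
  tail_spec <- disc$spec[[length(disc$spec)]]
  expect_identical(tail_spec$layer, "dense")
  expect_identical(tail_spec$units, 1L)
  expect_identical(tail_spec$activation, "tanh")
  set.seed(2)
  x <- array(runif(3 * 64 * 1, -1, 1), c(3, 64, 1))
  s <- gandta:::seq_forward(disc$layers, x)
  expect_identical(dim(s), c(3L, 1L))
  expect_true(all(abs(s) <= 1))
})

test_that("neither GAN network contains batch normalization", {
  cfg <- gan_config(seq_len = 64L)
  specs <- c(build_generator(cfg)$spec, build_discriminator(cfg)$spec)
  expect_true(all(vapply(specs, function(s) isFALSE(s$batchnorm), TRUE)))
})

test_that("train_gan produces finite, deterministic checkpoints", {
  set.seed(9)
  corpus <- matrix(runif(64 * 32, -1, 1), 64, 32)
  cfg <- tiny_gan_config(32L, epochs = 5L, seed = 21L)
  ck <- train_gan(corpus, cfg)
  expect_s3_class(ck, "gan_checkpoint")
  expect_true(all(is.finite(ck$history$d_loss)))
  expect_true(all(is.finite(ck$history$g_loss)))
  expect_identical(nrow(ck$history), 5L)
  # determinism: identical run -> identical parameters
  ck2 <- train_gan(corpus, cfg)
  expect_identical(ck$generator, ck2$generator)
  expect_identical(ck$discriminator, ck2$discriminator)
  # shape validation
  expect_error(train_gan(array(0, c(4, 32, 2)), cfg), class = "gandta_input_error")
  expect_error(train_gan(matrix(0, 4, 24), cfg), class = "gandta_input_error")
  expect_error(train_gan(corpus[0, , drop = FALSE], cfg), class = "gandta_input_error")
})

test_that("extract_features taps the fifth convolution deterministically", {
  ck <- small_drug_gan()
  ds <- small_dataset()
  enc <- small_encoders()
  x <- scale_to_gan_range(label_encode_matrix(ds$drug_seqs[1:6], enc$drug_vocab, 40L),
                          enc$drug_vocab)
  f <- extract_features(ck, x)
  expect_identical(dim(f), c(6L, 40L, ck$config$disc_filters[5]))
  expect_identical(extract_features(ck, x), f)
  # duplicated input rows -> identical feature maps
  xdup <- x[c(1, 1), , drop = FALSE]
  fdup <- extract_features(ck, xdup)
  expect_identical(fdup[1, , ], fdup[2, , ])
  expect_error(extract_features(ck, x[, 1:24]), class = "gandta_input_error")
})

test_that("checkpoints save and load to bit-identical forward passes", {
  ck <- small_drug_gan()
  dir <- withr::local_tempdir()
  save_gan_checkpoint(ck, dir)
  back <- load_gan_checkpoint(dir)
  expect_identical(back$generator, ck$generator)
  expect_identical(back$discriminator, ck$discriminator)
  expect_identical(back$corpus_fingerprint, ck$corpus_fingerprint)
  set.seed(5)
  x <- array(runif(4 * 40, -1, 1), c(4, 40, 1))
  expect_identical(discriminator_score(back, x), discriminator_score(ck, x))
  expect_identical(extract_features(back, x), extract_features(ck, x))
})

test_that("the trained discriminator rates real sequences above fresh fakes", {
  # small corpora, several seeds; the ordering must hold for a clear majority
  set.seed(31)
  wins <- 0L
  for (seed in 1:5) {
    corpus <- matrix(runif(64 * 32, -1, 1), 64, 32)
    # give the real data structure a GAN can learn to separate: smooth signals
    for (i in seq_len(nrow(corpus))) corpus[i, ] <- sin(seq(0, 4 * pi, length.out = 32) + runif(1, 0, 2 * pi)) * 0.8
    ck <- train_gan(corpus, tiny_gan_config(32L, epochs = 6L, seed = seed))
    real_score <- mean(discriminator_score(ck, corpus))
    fake <- generate_sequences(ck, 64, seed = seed + 100)
    fake_score <- mean(discriminator_score(ck, fake))
    if (real_score > fake_score) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})
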