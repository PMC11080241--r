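# Shared fixtures, built once per test run and memoized. All are generated in
# code; nothing is read from disk except the bundled substitution matrix.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# small labeled dataset for unit tests (400 pairs keeps them fast)
small_dataset <- function() memo("small_ds", generate_dataset(
  synthetic_config(n_proteins = 25L, n_drugs = 40L, n_pairs = 400L, seed = 101L)))

small_encoders <- function() memo("small_enc", build_encoders(small_dataset()))

# reduced-width GAN configs used throughout the tests
tiny_gan_config <- function(seq_len, in_channels = 1L, epochs = 10L, seed = 7L,
                            batch_size = 32L) {
  gan_config(seq_len = seq_len, in_channels = in_channels, noise_dim = 8L,
             gen_filters = c(8L, 4L, in_channels),
             disc_filters = c(4L, 4L, 8L, 8L, 8L),
             batch_size = batch_size, epochs = epochs, seed = seed)
}

# drug GAN trained on the small dataset's SMILES (label encoding, seq_len 40)
small_drug_gan <- function() memo("small_drug_gan", {
  ds <- small_dataset()
  enc <- small_encoders()
  x <- scale_to_gan_range(label_encode_matrix(ds$drug_seqs, enc$drug_vocab, 40L),
                          enc$drug_vocab)
  train_gan(x, tiny_gan_config(40L, epochs = 8L))
})

# reduced-width predictor config matching the small dataset's lengths;
# ... overrides any default
small_predictor_config <- function(...) {
  args <- utils::modifyList(
    list(protein_len = 64L, smiles_len = 40L,
         cnn_filters = c(8L, 16L, 16L), fc_units = c(32L, 32L, 32L),
         learning_rate = 0.003, batch_size = 64L,
         max_epochs = 15L, patience = 5L, seed = 5L),
    list(...))
  do.call(predictor_config, args)
}

dataset_slice <- function(ds, idx) {
  out <- ds
  out$records <- ds$records[idx, ]
  out
}

pairs_of <- function(ds, records = ds$records) {
  data.frame(protein = unname(ds$protein_seqs[records$protein_id]),
             smiles = unname(ds$drug_seqs[records$drug_id]))
}

# full-scale synthetic world for the acceptance criteria and variant checks:
# the stated 2000-pair planted-signal dataset plus reduced-width GANs
full_world <- function() memo("full_world", {
  ds <- generate_dataset(synthetic_config(seed = 1L))
  enc <- build_encoders(ds)
  x <- scale_to_gan_range(label_encode_matrix(ds$drug_seqs, enc$drug_vocab, 40L),
                          enc$drug_vocab)
  drug_gan <- train_gan(x, gan_config(seq_len = 40L, in_channels = 1L, noise_dim = 16L,
                                      gen_filters = c(16L, 8L, 1L),
                                      disc_filters = c(4L, 4L, 8L, 8L, 16L),
                                      batch_size = 50L, epochs = 20L, seed = 7L))
  list(ds = ds, enc = enc, drug_gan = drug_gan)
})

# protein GANs for variants A (label encoding) and C (BLOSUM channels)
protein_gan_label <- function() memo("protein_gan_label", {
  w <- full_world()
  x <- scale_to_gan_range(label_encode_matrix(w$ds$protein_seqs, w$enc$protein_vocab, 64L),
                          w$enc$protein_vocab)
  train_gan(x, gan_config(seq_len = 64L, in_channels = 1L, noise_dim = 16L,
                          gen_filters = c(16L, 8L, 1L),
                          disc_filters = c(4L, 4L, 8L, 8L, 16L),
                          batch_size = 30L, epochs = 20L, seed = 8L))
})

protein_gan_blosum <- function() memo("protein_gan_blosum", {
  w <- full_world()
  x <- blosum_encode_array(w$ds$protein_seqs, max_len = 64L, scale = TRUE)
  train_gan(x, gan_config(seq_len = 64L, in_channels = 25L, noise_dim = 16L,
                          gen_filters = c(16L, 8L, 25L),
                          disc_filters = c(4L, 4L, 8L, 8L, 16L),
                          batch_size = 30L, epochs = 20L, seed = 9L))
})

# reduced-width training configuration for the full-scale world
acceptance_config <- function(seed, ...) {
  args <- utils::modifyList(
    list(protein_len = 64L, smiles_len = 40L,
         cnn_filters = c(8L, 16L, 16L), fc_units = c(32L, 32L, 32L),
         learning_rate = 0.003, batch_size = 64L,
         max_epochs = 40L, patience = 8L, seed = seed),
    list(...))
  do.call(predictor_config, args)
}

# train a variant on explicit train/test record frames, return the test CI
fit_variant_ci <- function(world, variant, records_train, records_test, cfg) {
  tr <- world$ds; tr$records <- records_train
  te <- world$ds; te$records <- records_test
  pg <- switch(variant$protein_input,
               dcgan_features_on_label = protein_gan_label(),
               dcgan_features_on_blosum = protein_gan_blosum(),
               NULL)
  m <- assemble_model(variant, cfg, world$enc, protein_gan = pg,
                      drug_gan = world$drug_gan)
  train_predictor(m, tr, te, cfg)
  pred <- predict_affinity(m, pairs_of(world$ds, records_test))
  as.numeric(concordance_index(records_test$affinity, pred))
}

# brute-force O(n^2) concordance-index oracle (kept deliberately naive)
ci_oracle <- function(y, f) {
  s <- 0; z <- 0
  for (i in seq_along(y)) for (j in seq_along(y)) {
    if (y[i] > y[j]) {
      z <- z + 1
      d <- f[i] - f[j]
      s <- s + (d > 0) + 0.5 * (d == 0)
    }
  }
  list(ci = s / z, z = z)
}
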