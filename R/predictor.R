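# Two-branch affinity regressor. Each branch runs a CNN block (three ReLU
# convolutions, then one global max-pooling) over its sequence representation;
# the branch latents are merged with an elementwise add layer (or
# concatenation, for the ablation) and passed to a three-layer fully-connected
# head with dropout, ending in a single linear output (pKd). Branch inputs are
# either raw encodings (BLOSUM rows, embedded label encodings) or frozen
# feature maps from a pre-trained GAN discriminator.

#' Configuration for the affinity predictor
#'
#' Defaults are the reference hyperparameters: input lengths 2000 (protein) /
#' 200 (SMILES), convolution filters (128, 256, 384) with kernel 8 for the
#' protein branch and 4 for the drug branch, fully-connected units
#' (1024, 512, 512), dropout 0.25 after each FC layer, add fusion, Adam with
#' learning rate 0.001, batch size 256, up to 300 epochs with early stopping
#' (patience 10 on validation MSE, best weights restored).
#'
#' @param protein_len,smiles_len fixed encoded lengths.
#' @param cnn_filters integer triple of conv filters per branch.
#' @param protein_kernel,drug_kernel kernel lengths of the two branches.
#' @param fc_units integer triple of fully-connected widths.
#' @param dropout dropout rate after each FC layer.
#' @param fusion \code{"add"} or \code{"concat"}.
#' @param learning_rate,batch_size,max_epochs Adam step size and loop bounds.
#' @param patience early-stopping patience in epochs (validation MSE).
#' @param embedding_dim embedding width for branches that consume raw label
#'   encodings (not used by GAN-feature or BLOSUM branches).
#' @param seed RNG seed for initialization, batching and dropout.
#' @return an object of class \code{predictor_config}.
#' @export
predictor_config <- function(protein_len = 2000L, smiles_len = 200L,
                             cnn_filters = c(128L, 256L, 384L),
                             protein_kernel = 8L, drug_kernel = 4L,
                             fc_units = c(1024L, 512L, 512L), dropout = 0.25,
                             fusion = c("add", "concat"), learning_rate = 0.001,
                             batch_size = 256L, max_epochs = 300L, patience = 10L,
                             embedding_dim = 128L, seed = 1L) {
  fusion <- match.arg(fusion)
  check_that(length(cnn_filters) == 3, "cnn_filters must have 3 entries", "gandta_config_error")
  check_that(length(fc_units) == 3, "fc_units must have 3 entries", "gandta_config_error")
  check_that(dropout >= 0 && dropout < 1, "dropout must be in [0, 1)", "gandta_config_error")
  structure(list(protein_len = as.integer(protein_len), smiles_len = as.integer(smiles_len),
                 cnn_filters = as.integer(cnn_filters),
                 protein_kernel = as.integer(protein_kernel),
                 drug_kernel = as.integer(drug_kernel),
                 fc_units = as.integer(fc_units), dropout = dropout, fusion = fusion,
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 embedding_dim = as.integer(embedding_dim), seed = as.integer(seed)),
            class = "predictor_config")
}

#' Model variants A, B and C
#'
#' The three published variants differ in the protein representation; all use
#' GAN discriminator features over label-encoded SMILES for the drug branch:
#' \itemize{
#'   \item A: GAN features over label-encoded proteins.
#'   \item B: raw BLOSUM row encoding (no protein GAN).
#'   \item C: GAN features over BLOSUM-encoded proteins (25-channel GAN).
#' }
#' The mapping is declared here and can be overridden by constructing the
#' list directly with custom \code{protein_input} / \code{drug_input} modes
#' (\code{"label"} selects an embedded label encoding).
#'
#' @param name \code{"A"}, \code{"B"} or \code{"C"}.
#' @return an object of class \code{model_variant}.
#' @export
model_variant <- function(name = c("A", "B", "C")) {
  name <- match.arg(name)
  protein_input <- switch(name,
                          A = "dcgan_features_on_label",
                          B = "blosum",
                          C = "dcgan_features_on_blosum")
  structure(list(name = name, protein_input = protein_input,
                 drug_input = "dcgan_features_on_label"),
            class = "model_variant")
}

#' Build a branch CNN block specification
#'
#' Three stride-1 same-padding ReLU convolutions with filters
#' \code{cnn_filters} and the branch's kernel length, followed by one global
#' max-pooling that reduces any input length to a vector of
#' \code{cnn_filters[3]} features. Global pooling makes both branch latents
#' the same width, which the add fusion requires.
#'
#' @param branch \code{"protein"} or \code{"drug"}.
#' @param config a \code{\link{predictor_config}}.
#' @param in_channels channels of the branch input representation.
#' @return list with \code{spec} (layer descriptions) and \code{layers}.
#' @export
build_cnn_block <- function(branch = c("protein", "drug"), config, in_channels) {
  branch <- match.arg(branch)
  check_that(inherits(config, "predictor_config"), "config must be a predictor_config",
             "gandta_config_error")
  k <- if (branch == "protein") config$protein_kernel else config$drug_kernel
  f <- config$cnn_filters
  in_ch <- c(in_channels, f[1], f[2])
  layers <- list()
  spec <- list()
  for (i in 1:3) {
    layers[[i]] <- nn_conv1d(in_ch[i], f[i], k, "relu")
    spec[[i]] <- list(layer = "conv1d", filters = f[i], kernel = k,
                      activation = "relu")
  }
  layers[[4]] <- nn_gmaxpool()
  spec[[4]] <- list(layer = "global_max_pooling")
  layers[[1]]$entry <- TRUE  # input is data; unset when an embedding precedes
  list(spec = spec, layers = layers, out_dim = f[3])
}

#' Fuse two branch latent vectors
#'
#' \code{add} returns the elementwise sum (a linear combination that keeps the
#' latent width, hence fewer downstream parameters); \code{concat} juxtaposes
#' the vectors. Row-wise for matrices (rows = samples).
#'
#' @param protein_vec,drug_vec numeric vectors, or matrices with one row per
#'   sample.
#' @param mode \code{"add"} or \code{"concat"}.
#' @return the fused vector/matrix.
#' @export
fuse_latents <- function(protein_vec, drug_vec, mode = c("add", "concat")) {
  mode <- match.arg(mode)
  pm <- if (is.matrix(protein_vec)) protein_vec else matrix(protein_vec, 1)
  dm <- if (is.matrix(drug_vec)) drug_vec else matrix(drug_vec, 1)
  check_that(nrow(pm) == nrow(dm), "branch outputs must have equal sample counts",
             "gandta_shape_error")
  if (mode == "add") {
    check_that(ncol(pm) == ncol(dm), "add fusion requires equal latent widths",
               "gandta_shape_error")
    out <- pm + dm
  } else {
    out <- cbind(pm, dm)
  }
  if (!is.matrix(protein_vec) && !is.matrix(drug_vec)) as.vector(out) else out
}

branch_in_channels <- function(input_mode, config, gan) {
  switch(input_mode,
         blosum = 25L,
         label = config$embedding_dim,
         dcgan_features_on_label = gan$config$disc_filters[5],
         dcgan_features_on_blosum = gan$config$disc_filters[5],
         abort(paste("unknown branch input mode", input_mode), "gandta_config_error"))
}

needs_gan <- function(input_mode) grepl("^dcgan", input_mode)

#' Assemble an affinity model
#'
#' Wires the variant's branch inputs through CNN blocks, the fusion layer and
#' the FC head. GAN checkpoints must be supplied for every branch whose input
#' mode consumes discriminator features; their parameters stay frozen (they
#' are applied as fixed feature extractors, never updated). Layer parameters
#' are initialized deterministically from \code{config$seed}.
#'
#' @param variant a \code{\link{model_variant}} (or compatible list).
#' @param config a \code{\link{predictor_config}}.
#' @param encoders encoder bundle from \code{\link{build_encoders}}.
#' @param protein_gan,drug_gan \code{gan_checkpoint}s where required.
#' @return an object of class \code{affinity_model} (an environment).
#' @export
assemble_model <- function(variant, config, encoders, protein_gan = NULL, drug_gan = NULL) {
  check_that(inherits(config, "predictor_config"), "config must be a predictor_config",
             "gandta_config_error")
  check_that(!is.null(variant$protein_input) && !is.null(variant$drug_input),
             "variant must define protein_input and drug_input", "gandta_config_error")
  if (needs_gan(variant$protein_input)) {
    check_that(inherits(protein_gan, "gan_checkpoint"),
               sprintf("variant %s requires a protein GAN checkpoint", variant$name %||% "?"),
               "gandta_config_error")
    check_that(protein_gan$config$seq_len == config$protein_len,
               "protein GAN seq_len does not match protein_len", "gandta_config_error")
  }
  if (needs_gan(variant$drug_input)) {
    check_that(inherits(drug_gan, "gan_checkpoint"),
               sprintf("variant %s requires a drug GAN checkpoint", variant$name %||% "?"),
               "gandta_config_error")
    check_that(drug_gan$config$seq_len == config$smiles_len,
               "drug GAN seq_len does not match smiles_len", "gandta_config_error")
  }
  set.seed(derive_seed(config$seed, "model_init"))
  p_pre <- if (variant$protein_input == "label")
    list(nn_embed(encoders$protein_vocab$unknown_index, config$embedding_dim)) else list()
  d_pre <- if (variant$drug_input == "label")
    list(nn_embed(encoders$drug_vocab$unknown_index, config$embedding_dim)) else list()
  p_block <- build_cnn_block("protein", config,
                             branch_in_channels(variant$protein_input, config, protein_gan))
  d_block <- build_cnn_block("drug", config,
                             branch_in_channels(variant$drug_input, config, drug_gan))
  if (length(p_pre)) p_block$layers[[1]]$entry <- FALSE  # embedding needs dX
  if (length(d_pre)) d_block$layers[[1]]$entry <- FALSE
  fused_dim <- if (config$fusion == "add") config$cnn_filters[3] else 2L * config$cnn_filters[3]
  head <- list()
  in_dim <- fused_dim
  for (u in config$fc_units) {
    head <- c(head, list(nn_dense(in_dim, u, "relu"), nn_dropout(config$dropout)))
    in_dim <- u
  }
  head <- c(head, list(nn_dense(in_dim, 1L, "linear")))
  m <- new.env(parent = emptyenv())
  m$variant <- variant
  m$config <- config
  m$encoders <- encoders
  m$protein_gan <- protein_gan
  m$drug_gan <- drug_gan
  m$p_branch <- c(p_pre, p_block$layers)
  m$d_branch <- c(d_pre, d_block$layers)
  m$head <- head
  m$spec <- list(protein = p_block$spec, drug = d_block$spec,
                 fusion = config$fusion, fc_units = config$fc_units,
                 dropout = config$dropout)
  m$init_params <- collect_params(c(m$p_branch, m$d_branch, m$head))
  m$trained <- FALSE
  class(m) <- "affinity_model"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.affinity_model <- function(x, ...) {
  cat(sprintf("<affinity_model %s: protein=%s, drug=%s, fusion=%s, %s, %d trainable parameters>\n",
              x$variant$name %||% "custom", x$variant$protein_input, x$variant$drug_input,
              x$config$fusion, if (x$trained) "trained" else "untrained",
              count_parameters(x)))
  invisible(x)
}

#' Count trainable parameters of an affinity model
#' @param model an \code{affinity_model}.
#' @return integer parameter count (frozen GAN weights excluded).
#' @export
count_parameters <- function(model) {
  count_layer_params(c(model$p_branch, model$d_branch, model$head))
}

#' Build the encoder bundle for a dataset
#'
#' Vocabularies are built from the dataset's own sequence tables (sorted
#' character order, deterministic) and bundled with the substitution matrix.
#'
#' @param dataset an \code{\link{affinity_dataset}}.
#' @param blosum a \code{\link{blosum_matrix}}.
#' @return list with \code{protein_vocab}, \code{drug_vocab}, \code{blosum}.
#' @export
build_encoders <- function(dataset, blosum = blosum_matrix()) {
  list(protein_vocab = build_vocabulary(unname(dataset$protein_seqs), "protein"),
       drug_vocab = build_vocabulary(unname(dataset$drug_seqs), "smiles"),
       blosum = blosum)
}

# Encode sequences into the tensor a branch consumes. Returns an integer
# matrix for mode "label" (the embedding layer does the lookup) and a numeric
# (n, L, C) array otherwise.
branch_input_tensor <- function(model, side = c("protein", "drug"), seqs) {
  side <- match.arg(side)
  cfg <- model$config
  if (side == "protein") {
    mode <- model$variant$protein_input
    vocab <- model$encoders$protein_vocab
    len <- cfg$protein_len
    gan <- model$protein_gan
  } else {
    mode <- model$variant$drug_input
    vocab <- model$encoders$drug_vocab
    len <- cfg$smiles_len
    gan <- model$drug_gan
  }
  switch(mode,
         blosum = blosum_encode_array(seqs, model$encoders$blosum, len, scale = FALSE),
         label = label_encode_matrix(seqs, vocab, len),
         dcgan_features_on_label = extract_features(
           gan, scale_to_gan_range(label_encode_matrix(seqs, vocab, len), vocab)),
         dcgan_features_on_blosum = extract_features(
           gan, blosum_encode_array(seqs, model$encoders$blosum, len, scale = TRUE)))
}

subset_rows <- function(x, idx) {
  if (is.matrix(x)) x[idx, , drop = FALSE] else x[idx, , , drop = FALSE]
}

# Inference pass over records given entity tensors and per-record entity
# indices; branches run once per unique entity.
entity_forward <- function(model, ptens, dtens, pi, di) {
  pu <- unique(pi); du <- unique(di)
  pv <- seq_forward(model$p_branch, subset_rows(ptens, pu), FALSE)[match(pi, pu), , drop = FALSE]
  dv <- seq_forward(model$d_branch, subset_rows(dtens, du), FALSE)[match(di, du), , drop = FALSE]
  fused <- if (model$config$fusion == "add") pv + dv else cbind(pv, dv)
  as.vector(seq_forward(model$head, fused, FALSE))
}

model_forward <- function(model, xp, xd, training = FALSE) {
  pv <- seq_forward(model$p_branch, xp, training)
  dv <- seq_forward(model$d_branch, xd, training)
  fused <- if (model$config$fusion == "add") pv + dv else cbind(pv, dv)
  out <- seq_forward(model$head, fused, training)
  list(pred = as.vector(out), p_dim = ncol(pv))
}

model_backward <- function(model, dpred, p_dim) {
  dfused <- seq_backward(model$head, matrix(dpred, ncol = 1))
  if (model$config$fusion == "add") {
    dp <- dfused; dd <- dfused
  } else {
    dp <- dfused[, seq_len(p_dim), drop = FALSE]
    dd <- dfused[, p_dim + seq_len(ncol(dfused) - p_dim), drop = FALSE]
  }
  seq_backward(model$p_branch, dp)
  seq_backward(model$d_branch, dd)
  invisible(NULL)
}

#' Train the affinity predictor
#'
#' Minimizes MSE with Adam; monitors validation MSE each epoch, stops when it
#' has not improved for \code{config$patience} epochs, and restores the
#' best-validation parameters. Parameters are reset to their deterministic
#' initialization first, so repeated calls with the same data and seed yield
#' identical histories. GAN feature extractors are frozen throughout (their
#' checkpoints are never modified).
#'
#' @param model an \code{\link{assemble_model}} result.
#' @param train,val non-empty \code{\link{affinity_dataset}}s (no NaN
#'   affinities).
#' @param config optional \code{\link{predictor_config}} overriding the
#'   model's training settings (architecture fields are taken from the model).
#' @return the model (trained in place, invisibly returned) with a
#'   \code{history} data.frame (epoch, train_mse, val_mse) attached.
#' @export
train_predictor <- function(model, train, val, config = model$config) {
  check_that(inherits(model, "affinity_model"), "model must be an affinity_model")
  for (ds in list(train, val)) {
    check_that(inherits(ds, "affinity_dataset") && nrow(ds$records) > 0,
               "datasets must be non-empty affinity_datasets")
    check_that(!anyNA(ds$records$affinity) && all(is.finite(ds$records$affinity)),
               "affinities must not contain NaN/NA")
  }
  layers <- c(model$p_branch, model$d_branch, model$head)
  restore_params(layers, model$init_params)
  set.seed(derive_seed(config$seed, "predictor_train"))

  # precompute branch inputs once per unique entity, then gather per record
  prot_ids <- unique(c(train$records$protein_id, val$records$protein_id))
  drug_ids <- unique(c(train$records$drug_id, val$records$drug_id))
  seqs <- c(train$protein_seqs, val$protein_seqs)
  dseq <- c(train$drug_seqs, val$drug_seqs)
  ptens <- branch_input_tensor(model, "protein", seqs[prot_ids])
  dtens <- branch_input_tensor(model, "drug", dseq[drug_ids])
  tr_p <- match(train$records$protein_id, prot_ids)
  tr_d <- match(train$records$drug_id, drug_ids)
  va_p <- match(val$records$protein_id, prot_ids)
  va_d <- match(val$records$drug_id, drug_ids)
  y_tr <- train$records$affinity
  y_va <- val$records$affinity

  # start the output unit at the training-label mean so no epochs are spent
  # learning the pKd offset
  out_layer <- model$head[[length(model$head)]]
  out_layer$b <- mean(y_tr)

  opt <- adam_state(layers, lr = config$learning_rate)
  n <- length(y_tr)
  bs <- min(config$batch_size, n)
  best_val <- Inf
  best_params <- NULL
  best_epoch <- 0L
  wait <- 0L
  history <- data.frame(epoch = integer(0), train_mse = numeric(0), val_mse = numeric(0))
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    tr_losses <- numeric(0)
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      # branch outputs depend only on the entity, so run the convolutional
      # branches over the unique proteins/drugs of the batch and gather;
      # gradients are scattered back by summation over duplicate entities
      pu <- unique(tr_p[idx]); pg <- match(tr_p[idx], pu)
      du <- unique(tr_d[idx]); dg <- match(tr_d[idx], du)
      zero_grads(layers)
      pv_u <- seq_forward(model$p_branch, subset_rows(ptens, pu), training = TRUE)
      dv_u <- seq_forward(model$d_branch, subset_rows(dtens, du), training = TRUE)
      pv <- pv_u[pg, , drop = FALSE]
      dv <- dv_u[dg, , drop = FALSE]
      fused <- if (config$fusion == "add") pv + dv else cbind(pv, dv)
      pred <- as.vector(seq_forward(model$head, fused, training = TRUE))
      err <- pred - y_tr[idx]
      tr_losses <- c(tr_losses, mean(err^2))
      dfused <- seq_backward(model$head, matrix(2 * err / length(idx), ncol = 1))
      if (config$fusion == "add") {
        dp <- dfused; dd <- dfused
      } else {
        dp <- dfused[, seq_len(ncol(pv)), drop = FALSE]
        dd <- dfused[, ncol(pv) + seq_len(ncol(dv)), drop = FALSE]
      }
      # rowsum groups 1..n_unique come back in ascending order, matching pu/du
      seq_backward(model$p_branch, rowsum(dp, pg))
      seq_backward(model$d_branch, rowsum(dd, dg))
      adam_step(opt, layers)
    }
    val_pred <- entity_forward(model, ptens, dtens, va_p, va_d)
    val_mse <- mean((val_pred - y_va)^2)
    check_that(is.finite(val_mse), "training diverged (non-finite validation MSE)",
               "gandta_numeric_error")
    history <- rbind(history, data.frame(epoch = epoch, train_mse = mean(tr_losses),
                                         val_mse = val_mse))
    if (val_mse < best_val - 1e-12) {
      best_val <- val_mse
      best_params <- collect_params(layers)
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  restore_params(layers, best_params)
  model$history <- history
  model$best_epoch <- best_epoch
  model$trained <- TRUE
  invisible(model)
}

#' Predict binding affinity for raw (protein, SMILES) pairs
#'
#' @param model a trained \code{affinity_model}.
#' @param pairs data.frame with columns \code{protein} and \code{smiles}
#'   (raw sequence strings), one row per pair.
#' @return numeric vector of predicted pKd, one per pair.
#' @export
predict_affinity <- function(model, pairs) {
  check_that(inherits(model, "affinity_model"), "model must be an affinity_model")
  if (!isTRUE(model$trained)) abort("model has not been trained", "gandta_state_error")
  check_that(is.data.frame(pairs) && all(c("protein", "smiles") %in% names(pairs)),
             "pairs needs columns protein and smiles")
  up <- unique(pairs$protein)
  ud <- unique(pairs$smiles)
  names(up) <- paste0("p", seq_along(up))
  names(ud) <- paste0("d", seq_along(ud))
  ptens <- branch_input_tensor(model, "protein", up)
  dtens <- branch_input_tensor(model, "drug", ud)
  pred <- entity_forward(model, ptens, dtens,
                         match(pairs$protein, up), match(pairs$smiles, ud))
  check_that(all(is.finite(pred)), "non-finite prediction", "gandta_numeric_error")
  pred
}

#' Straw-model baselines: fully-connected net and k-nearest neighbours
#'
#' Both operate on concatenated fixed-length label encodings of the protein
#' and the SMILES (scaled to [-1, 1]). \code{"fc"} trains the FC head alone
#' (units \code{fc_units}, ReLU + dropout, linear output) with Adam/MSE;
#' \code{"knn"} predicts the mean affinity of the k nearest training pairs
#' under Euclidean distance.
#'
#' @param kind \code{"fc"} or \code{"knn"}.
#' @param train,test \code{\link{affinity_dataset}}s.
#' @param k neighbour count for \code{"knn"} (must not exceed nrow(train)).
#' @param config a \code{\link{predictor_config}} supplying encoding lengths
#'   and, for \code{"fc"}, the head architecture and optimizer settings.
#' @param epochs training epochs for the FC baseline.
#' @return numeric predictions for the test records.
#' @export
train_baseline <- function(kind = c("fc", "knn"), train, test, k = 5L,
                           config = predictor_config(), epochs = 30L) {
  kind <- match.arg(kind)
  enc <- build_encoders(train)
  encode_all <- function(ds) {
    xp <- scale_to_gan_range(label_encode_matrix(ds$protein_seqs[ds$records$protein_id],
                                                 enc$protein_vocab, config$protein_len),
                             enc$protein_vocab)
    xd <- scale_to_gan_range(label_encode_matrix(ds$drug_seqs[ds$records$drug_id],
                                                 enc$drug_vocab, config$smiles_len),
                             enc$drug_vocab)
    cbind(xp, xd)
  }
  Xtr <- encode_all(train)
  Xte <- encode_all(test)
  y <- train$records$affinity
  if (kind == "knn") {
    check_that(k <= nrow(Xtr), sprintf("k = %d exceeds the %d training records", k, nrow(Xtr)),
               "gandta_config_error")
    d2 <- outer(rowSums(Xte^2), rowSums(Xtr^2), "+") - 2 * tcrossprod(Xte, Xtr)
    unname(apply(d2, 1, function(row) mean(y[order(row)[seq_len(k)]])))
  } else {
    set.seed(derive_seed(config$seed, "fc_baseline"))
    layers <- list()
    in_dim <- ncol(Xtr)
    for (u in config$fc_units) {
      layers <- c(layers, list(nn_dense(in_dim, u, "relu"), nn_dropout(config$dropout)))
      in_dim <- u
    }
    layers <- c(layers, list(nn_dense(in_dim, 1L, "linear")))
    opt <- adam_state(layers, lr = config$learning_rate)
    n <- nrow(Xtr)
    bs <- min(config$batch_size, n)
    for (epoch in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        zero_grads(layers)
        pred <- as.vector(seq_forward(layers, Xtr[idx, , drop = FALSE], training = TRUE))
        seq_backward(layers, matrix(2 * (pred - y[idx]) / length(idx), ncol = 1))
        adam_step(opt, layers)
      }
    }
    as.vector(seq_forward(layers, Xte, training = FALSE))
  }
}

#' Save / load an affinity model as plain text
#'
#' Writes full-precision parameter dumps plus a JSON sidecar with the variant,
#' configuration and provenance (GAN corpus fingerprints). GAN checkpoints are
#' stored alongside in subdirectories when present.
#'
#' @param model a trained \code{affinity_model}.
#' @param dir directory to create.
#' @return \code{dir} invisibly (save); an \code{affinity_model} (load
#'   requires the encoder bundle to be rebuilt from the same dataset).
#' @export
save_affinity_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_params_txt(collect_params(c(model$p_branch, model$d_branch, model$head)),
                   file.path(dir, "params.txt"))
  side <- list(variant = unclass(model$variant), config = unclass(model$config),
               trained = model$trained,
               protein_gan_fingerprint = model$protein_gan$corpus_fingerprint,
               drug_gan_fingerprint = model$drug_gan$corpus_fingerprint)
  jsonlite::write_json(side, file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(model$protein_gan)) save_gan_checkpoint(model$protein_gan, file.path(dir, "protein_gan"))
  if (!is.null(model$drug_gan)) save_gan_checkpoint(model$drug_gan, file.path(dir, "drug_gan"))
  if (!is.null(model$history)) {
    utils::write.table(model$history, file.path(dir, "history.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname save_affinity_model
#' @param encoders encoder bundle (see \code{\link{build_encoders}}) matching
#'   the one the model was assembled with.
#' @export
load_affinity_model <- function(dir, encoders) {
  side <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  cfg <- do.call(predictor_config, side$config[names(side$config) != "fusion"])
  cfg$fusion <- side$config$fusion
  variant <- structure(side$variant, class = "model_variant")
  pg <- if (dir.exists(file.path(dir, "protein_gan"))) load_gan_checkpoint(file.path(dir, "protein_gan"))
  dg <- if (dir.exists(file.path(dir, "drug_gan"))) load_gan_checkpoint(file.path(dir, "drug_gan"))
  m <- assemble_model(variant, cfg, encoders, protein_gan = pg, drug_gan = dg)
  restore_params(c(m$p_branch, m$d_branch, m$head),
                 read_params_txt(file.path(dir, "params.txt")))
  m$trained <- isTRUE(side$trained)
  hist_path <- file.path(dir, "history.tsv")
  if (file.exists(hist_path)) m$history <- utils::read.delim(hist_path)
  m
}
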