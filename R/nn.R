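# Minimal 1-D neural-network engine.
#
# Tensors are base-R arrays, batch-first: (batch, length, channels). Each layer
# is an environment carrying parameters, gradients, Adam state and forward /
# backward closures. Convolutions are im2col reshapes followed by one BLAS
# matmul per layer, which is fast enough for desk-scale corpora on one CPU and
# keeps the package free of compiled dependencies. All randomness goes through
# R's RNG so a single set.seed() makes initialization, batching, dropout and
# noise sampling reproducible.

act_forward <- function(z, activation) {
  switch(activation,
         relu = pmax(z, 0),
         tanh = tanh(z),
         linear = z,
         abort(paste("unknown activation", activation), "gandta_config_error"))
}

# derivative wrt z given cached post-activation a
act_backward <- function(da, a, activation) {
  switch(activation,
         relu = da * (a > 0),
         tanh = da * (1 - a * a),
         linear = da)
}

new_layer <- function(kind, ...) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e$params <- character(0)
  class(e) <- "nn_layer"
  e
}

init_param <- function(layer, name, dims, scale) {
  assign(name, array(stats::rnorm(prod(dims), 0, scale), dims), envir = layer)
  assign(paste0("g_", name), array(0, dims), envir = layer)
  layer$params <- union(layer$params, name)
}

init_bias <- function(layer, name, n) {
  assign(name, numeric(n), envir = layer)
  assign(paste0("g_", name), numeric(n), envir = layer)
  layer$params <- union(layer$params, name)
}

# ---- conv1d, stride 1, same padding -----------------------------------------

nn_conv1d <- function(in_ch, out_ch, kernel, activation = "relu") {
  l <- new_layer("conv1d", in_ch = in_ch, out_ch = out_ch, kernel = kernel,
                 activation = activation, stride = 1L, padding = "same")
  init_param(l, "W", c(kernel * in_ch, out_ch), sqrt(2 / (kernel * in_ch)))
  init_bias(l, "b", out_ch)
  l
}

# Gather indices mapping the padded input tensor (B, L+k-1, C) onto the
# im2col matrix (B*L, k*C), cached per shape in the layer environment: one
# C-level gather replaces k strided slice copies.
im2col_idx <- function(l, B, L, C, k) {
  key <- paste0("i2c_", B, "_", L, "_", C, "_", k)
  cached <- l[[key]]
  if (!is.null(cached)) return(cached)
  Lp <- B * (L + k - 1L)
  base <- rep(seq_len(B), L) + (rep(seq_len(L), each = B) - 1L) * B  # (b, l) block
  idx <- unlist(lapply(seq_len(k), function(o) {
    bo <- base + (o - 1L) * B
    lapply(seq_len(C), function(ch) bo + (ch - 1L) * Lp)
  }), use.names = FALSE)
  assign(key, idx, envir = l)
  idx
}

im2col <- function(l, x, k) {
  d <- dim(x); B <- d[1]; L <- d[2]; C <- d[3]
  pl <- (k - 1L) %/% 2L
  xp <- array(0, c(B, L + k - 1L, C))
  xp[, pl + seq_len(L), ] <- x
  M <- xp[im2col_idx(l, B, L, C, k)]
  dim(M) <- c(B * L, k * C)
  M
}

# Adjoint of im2col. Indices are unique within one kernel offset, so the
# scatter-add runs as k vectorized accumulations.
col2im <- function(l, dM, B, L, C, k) {
  pl <- (k - 1L) %/% 2L
  idx <- im2col_idx(l, B, L, C, k)
  blk <- B * L * C
  dxp <- numeric(B * (L + k - 1L) * C)
  for (o in seq_len(k)) {
    sel <- idx[((o - 1L) * blk + 1L):(o * blk)]
    dxp[sel] <- dxp[sel] + dM[((o - 1L) * blk + 1L):(o * blk)]
  }
  dim(dxp) <- c(B, L + k - 1L, C)
  dxp[, pl + seq_len(L), , drop = FALSE]
}

conv1d_forward <- function(l, x, training) {
  d <- dim(x)
  M <- im2col(l, x, l$kernel)
  Z <- M %*% l$W
  Z <- Z + rep(l$b, each = nrow(Z))
  A <- act_forward(Z, l$activation)
  if (training) { l$M <- M; l$A <- A; l$in_dim <- d }
  array(A, c(d[1], d[2], l$out_ch))
}

conv1d_backward <- function(l, dY) {
  d <- l$in_dim
  dA <- matrix(dY, d[1] * d[2], l$out_ch)
  dZ <- act_backward(dA, l$A, l$activation)
  l$g_W <- l$g_W + crossprod(l$M, dZ)
  l$g_b <- l$g_b + colSums(dZ)
  if (isTRUE(l$entry)) return(NULL)  # no input gradient needed at data layers
  dM <- tcrossprod(dZ, l$W)
  col2im(l, dM, d[1], d[2], l$in_ch, l$kernel)
}

# ---- transpose conv1d, stride 2 ----------------------------------------------
# Parameterized as zero-stuffing upsample (length doubles) followed by a
# stride-1 same-padding convolution; the adjoint of a stride-2 convolution.

nn_tconv1d <- function(in_ch, out_ch, kernel, activation = "relu") {
  l <- new_layer("tconv1d", in_ch = in_ch, out_ch = out_ch, kernel = kernel,
                 activation = activation, stride = 2L)
  init_param(l, "W", c(kernel * in_ch, out_ch), sqrt(2 / (kernel * in_ch)))
  init_bias(l, "b", out_ch)
  l
}

tconv1d_forward <- function(l, x, training) {
  d <- dim(x); B <- d[1]; L <- d[2]; C <- d[3]
  z <- array(0, c(B, 2L * L, C))
  z[, seq(1L, 2L * L, by = 2L), ] <- x
  M <- im2col(l, z, l$kernel)
  Z <- M %*% l$W + rep(l$b, each = B * 2L * L)
  A <- act_forward(Z, l$activation)
  if (training) { l$M <- M; l$A <- A; l$in_dim <- d }
  array(A, c(B, 2L * L, l$out_ch))
}

tconv1d_backward <- function(l, dY) {
  d <- l$in_dim; B <- d[1]; L <- d[2]
  dA <- matrix(dY, B * 2L * L, l$out_ch)
  dZ <- act_backward(dA, l$A, l$activation)
  l$g_W <- l$g_W + crossprod(l$M, dZ)
  l$g_b <- l$g_b + colSums(dZ)
  if (isTRUE(l$entry)) return(NULL)
  dz <- col2im(l, tcrossprod(dZ, l$W), B, 2L * L, l$in_ch, l$kernel)
  dz[, seq(1L, 2L * L, by = 2L), , drop = FALSE]
}

# ---- dense -------------------------------------------------------------------

nn_dense <- function(in_dim, out_dim, activation = "relu") {
  l <- new_layer("dense", in_dim = in_dim, out_dim = out_dim, activation = activation)
  init_param(l, "W", c(in_dim, out_dim), sqrt(2 / in_dim))
  init_bias(l, "b", out_dim)
  l
}

dense_forward <- function(l, x, training) {
  if (length(dim(x)) == 3) x <- matrix(x, dim(x)[1], prod(dim(x)[-1]))  # flatten
  Z <- x %*% l$W + rep(l$b, each = nrow(x))
  A <- act_forward(Z, l$activation)
  if (training) { l$X <- x; l$A <- A }
  A
}

dense_backward <- function(l, dY) {
  dZ <- act_backward(dY, l$A, l$activation)
  l$g_W <- l$g_W + crossprod(l$X, dZ)
  l$g_b <- l$g_b + colSums(dZ)
  tcrossprod(dZ, l$W)
}

# ---- embedding ---------------------------------------------------------------
# Input: integer matrix (B x L), values in [0, vocab_size]; row 0 (padding)
# has its own trainable vector like any other index.

nn_embed <- function(vocab_size, dim) {
  l <- new_layer("embed", vocab_size = vocab_size, dim = dim)
  init_param(l, "W", c(vocab_size + 1L, dim), 0.05)
  l
}

embed_forward <- function(l, x, training) {
  idx <- as.vector(x) + 1L
  Y <- l$W[idx, , drop = FALSE]
  if (training) l$idx <- idx
  array(Y, c(nrow(x), ncol(x), l$dim))
}

embed_backward <- function(l, dY) {
  dY2 <- matrix(dY, length(l$idx), l$dim)
  agg <- rowsum(dY2, group = l$idx)
  rows <- as.integer(rownames(agg))
  l$g_W[rows, ] <- l$g_W[rows, , drop = FALSE] + agg
  NULL  # integer inputs carry no gradient
}

# ---- global max pooling ------------------------------------------------------

nn_gmaxpool <- function() new_layer("gmaxpool")

gmaxpool_forward <- function(l, x, training) {
  d <- dim(x); B <- d[1]; L <- d[2]; C <- d[3]
  y <- matrix(x[, 1, ], B, C)
  idx <- matrix(1L, B, C)
  if (L > 1) for (j in 2:L) {
    xj <- matrix(x[, j, ], B, C)
    upd <- xj > y
    y[upd] <- xj[upd]
    idx[upd] <- j
  }
  if (training) { l$idx <- idx; l$in_dim <- d }
  y
}

gmaxpool_backward <- function(l, dY) {
  d <- l$in_dim; B <- d[1]; L <- d[2]; C <- d[3]
  dx <- array(0, d)
  pos <- rep(seq_len(B), C) + (as.vector(l$idx) - 1L) * B +
    (rep(seq_len(C), each = B) - 1L) * B * L
  dx[pos] <- as.vector(dY)
  dx
}

# ---- dropout (inverted) ------------------------------------------------------

nn_dropout <- function(rate) new_layer("dropout", rate = rate)

dropout_forward <- function(l, x, training) {
  if (!training || l$rate <= 0) return(x)
  mask <- (stats::runif(length(x)) >= l$rate) / (1 - l$rate)
  l$mask <- mask
  x * mask
}

dropout_backward <- function(l, dY) dY * l$mask

# ---- dispatch ----------------------------------------------------------------

layer_forward <- function(l, x, training = FALSE) {
  switch(l$kind,
         conv1d = conv1d_forward(l, x, training),
         tconv1d = tconv1d_forward(l, x, training),
         dense = dense_forward(l, x, training),
         embed = embed_forward(l, x, training),
         gmaxpool = gmaxpool_forward(l, x, training),
         dropout = dropout_forward(l, x, training))
}

layer_backward <- function(l, dY) {
  switch(l$kind,
         conv1d = conv1d_backward(l, dY),
         tconv1d = tconv1d_backward(l, dY),
         dense = dense_backward(l, dY),
         embed = embed_backward(l, dY),
         gmaxpool = gmaxpool_backward(l, dY),
         dropout = dropout_backward(l, dY))
}

seq_forward <- function(layers, x, training = FALSE) {
  for (l in layers) x <- layer_forward(l, x, training)
  x
}

seq_backward <- function(layers, dY) {
  for (l in rev(layers)) dY <- layer_backward(l, dY)
  dY
}

zero_grads <- function(layers) {
  for (l in layers) for (p in l$params) assign(paste0("g_", p), 0 * get(p, envir = l), envir = l)
  invisible(NULL)
}

# ---- Adam --------------------------------------------------------------------

adam_state <- function(layers, lr = 0.001, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps; st$t <- 0L
  st$m <- list(); st$v <- list()
  for (i in seq_along(layers)) for (p in layers[[i]]$params) {
    key <- paste0(i, ".", p)
    st$m[[key]] <- 0 * get(p, envir = layers[[i]])
    st$v[[key]] <- st$m[[key]]
  }
  st
}

adam_step <- function(st, layers) {
  st$t <- st$t + 1L
  c1 <- 1 - st$beta1^st$t
  c2 <- 1 - st$beta2^st$t
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (p in l$params) {
      key <- paste0(i, ".", p)
      g <- get(paste0("g_", p), envir = l)
      st$m[[key]] <- st$beta1 * st$m[[key]] + (1 - st$beta1) * g
      st$v[[key]] <- st$beta2 * st$v[[key]] + (1 - st$beta2) * g * g
      upd <- st$lr * (st$m[[key]] / c1) / (sqrt(st$v[[key]] / c2) + st$eps)
      assign(p, get(p, envir = l) - upd, envir = l)
    }
  }
  invisible(NULL)
}

# ---- parameter (de)serialization --------------------------------------------

collect_params <- function(layers) {
  out <- list()
  for (i in seq_along(layers)) for (p in layers[[i]]$params) {
    out[[paste0("layer", i, ".", p)]] <- get(p, envir = layers[[i]])
  }
  out
}

restore_params <- function(layers, params) {
  for (i in seq_along(layers)) for (p in layers[[i]]$params) {
    key <- paste0("layer", i, ".", p)
    check_that(!is.null(params[[key]]), paste("missing parameter", key))
    assign(p, params[[key]], envir = layers[[i]])
  }
  invisible(NULL)
}

count_layer_params <- function(layers) {
  sum(vapply(layers, function(l) sum(vapply(l$params, function(p) length(get(p, envir = l)), 0)), 0))
}

# Write a named list of numeric arrays as plain text (dims header + %.17g
# values, one per line); round-trips doubles exactly.
write_params_txt <- function(params, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(params)) {
    x <- params[[nm]]
    d <- dim(x); if (is.null(d)) d <- length(x)
    writeLines(paste0("@", nm, " ", paste(d, collapse = " ")), con)
    writeLines(format_full(as.vector(x)), con)
  }
}

read_params_txt <- function(path) {
  lines <- readLines(path)
  heads <- grep("^@", lines)
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    hdr <- strsplit(sub("^@", "", lines[heads[i]]), " ")[[1]]
    vals <- as.numeric(lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)])
    d <- as.integer(hdr[-1])
    out[[hdr[1]]] <- if (length(d) > 1) array(vals, d) else vals
  }
  out
}
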