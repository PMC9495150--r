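## Classifier assembly: (optional) coordinate attention over the fused
## feature map -> the 801-step sequence of 148-vectors -> stacked LSTM ->
## last-step hidden state -> FC + activation -> FC -> softmax.

#' Construct a bird-call classifier
#'
#' @param n_species Number of output classes.
#' @param input_dim Feature rows per timestep (148 for fused features).
#' @param hidden Hidden units per LSTM layer (paper scale 512; desk runs
#'   use smaller values).
#' @param n_layers Number of stacked LSTM layers (default 2).
#' @param dropout Dropout rate between LSTM layers and after FC1, active in
#'   training only (default 0.3).
#' @param use_ca Apply coordinate attention to the input map? Default `TRUE`.
#' @param activation `"silu"` (default) or `"relu"` for the FC head and the
#'   CA block switchover.
#' @param bidirectional Run each LSTM layer in both time directions?
#'   Default `FALSE`.
#' @param readout How the LSTM output sequence feeds the FC head:
#'   `"mean"` (default) averages the top layer's hidden states over all
#'   timesteps, `"last"` uses the final timestep's state only.
#' @param r_mid CA intermediate channel width (default 8).
#' @param seed Integer seed for parameter initialization (uniform
#'   `+/- 1/sqrt(fan_in)`).
#' @return A `bc_model` list with `config` and `params`.
#' @export
bc_model <- function(n_species, input_dim = 148L, hidden = 512L,
                     n_layers = 2L, dropout = 0.3, use_ca = TRUE,
                     activation = c("silu", "relu"), bidirectional = FALSE,
                     readout = c("mean", "last"), r_mid = 8L, seed = 1L) {
  activation <- match.arg(activation)
  readout <- match.arg(readout)
  cfg <- list(n_species = as.integer(n_species),
              input_dim = as.integer(input_dim), hidden = as.integer(hidden),
              n_layers = as.integer(n_layers), dropout = dropout,
              use_ca = use_ca, activation = activation,
              bidirectional = bidirectional, readout = readout,
              r_mid = as.integer(r_mid), seed = as.integer(seed))
  D <- if (bidirectional) 2L else 1L
  params <- list()
  if (use_ca) params$ca <- ca_init(r_mid, derive_seed(seed, 99))
  for (l in seq_len(n_layers)) {
    in_l <- if (l == 1) input_dim else hidden * D
    for (d in seq_len(D)) {
      params[[sprintf("lstm_l%d_d%d", l, d)]] <-
        lstm_layer_init(in_l, hidden, derive_seed(seed, l, d))
    }
  }
  s1 <- 1 / sqrt(hidden * D)
  params$fc1 <- with_seed(derive_seed(seed, 201), list(
    W = matrix(stats::runif(hidden * D * hidden, -s1, s1), hidden * D, hidden),
    b = numeric(hidden)))
  s2 <- 1 / sqrt(hidden)
  params$fc2 <- with_seed(derive_seed(seed, 202), list(
    W = matrix(stats::runif(hidden * n_species, -s2, s2), hidden, n_species),
    b = numeric(n_species)))
  structure(list(config = cfg, params = params), class = "bc_model")
}

#' @export
print.bc_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<bc_model: %d species, input %d, hidden %d x %d ",
                     "layer(s)%s, CA %s, activation %s, dropout %.2f>\n"),
              cfg$n_species, cfg$input_dim, cfg$hidden, cfg$n_layers,
              if (cfg$bidirectional) " (bidirectional)" else "",
              if (cfg$use_ca) "on" else "off", cfg$activation, cfg$dropout))
  invisible(x)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Full forward pass over a batch.
# X: array (n, H, W) of feature matrices.  When training, dropout masks are
# drawn from `rng_seed` and all caches needed for the backward pass are kept.
model_forward <- function(model, X, training = FALSE, rng_seed = NULL) {
  cfg <- model$config; p <- model$params
  dims <- dim(X)
  n <- dims[1]; H <- dims[2]; W_ <- dims[3]
  if (H != cfg$input_dim) {
    stop("model_forward: input has ", H, " feature rows, model expects ",
         cfg$input_dim)
  }
  D <- if (cfg$bidirectional) 2L else 1L
  hd <- cfg$hidden
  M <- matrix(X, n * H, W_)                       # row (b,i), col j
  ca_cache <- NULL
  if (cfg$use_ca) {
    ca_cache <- ca_batch_forward(M, n, H, W_, p$ca)
    Xseq <- ca_cache$Y
  } else {
    Xseq <- M
  }
  keep <- training
  layer_in <- Xseq; in_dim <- H
  layers <- list(); drop_masks <- list()
  rng_k <- 0
  for (l in seq_len(cfg$n_layers)) {
    dirs <- list()
    for (d in seq_len(D)) {
      dirs[[d]] <- lstm_dir_forward(layer_in, n, in_dim, hd,
                                    p[[sprintf("lstm_l%d_d%d", l, d)]]$W,
                                    p[[sprintf("lstm_l%d_d%d", l, d)]]$b,
                                    reverse = (d == 2), keep_cache = keep)
    }
    H_cat <- if (D == 1) dirs[[1]]$H else {
      out <- matrix(0, n * hd * 2, W_)
      for (t in seq_len(W_)) {
        out[, t] <- c(dirs[[1]]$H[, t], dirs[[2]]$H[, t])
      }
      out
    }
    layers[[l]] <- list(dirs = dirs, input = layer_in, in_dim = in_dim,
                        H_cat = H_cat)
    if (l < cfg$n_layers && training && cfg$dropout > 0) {
      rng_k <- rng_k + 1
      mask <- with_seed(derive_seed(rng_seed, rng_k), {
        matrix(stats::rbinom(length(H_cat), 1, 1 - cfg$dropout) /
                 (1 - cfg$dropout), nrow(H_cat), ncol(H_cat))
      })
      drop_masks[[l]] <- mask
      layer_in <- H_cat * mask
    } else {
      layer_in <- H_cat
    }
    in_dim <- hd * D
  }
  # readout of the top layer: time-mean of hidden states, or the final
  # timestep's state (both directions' states at T)
  h_last <- if (identical(cfg$readout, "last")) {
    matrix(layer_in[, W_], n, hd * D)
  } else {
    matrix(rowMeans(layer_in), n, hd * D)
  }
  z1 <- h_last %*% p$fc1$W + matrix(p$fc1$b, n, length(p$fc1$b), byrow = TRUE)
  a1 <- act_fun(cfg$activation)(z1)
  fc_mask <- NULL
  if (training && cfg$dropout > 0) {
    fc_mask <- with_seed(derive_seed(rng_seed, 777), {
      matrix(stats::rbinom(length(a1), 1, 1 - cfg$dropout) /
               (1 - cfg$dropout), nrow(a1), ncol(a1))
    })
    a1d <- a1 * fc_mask
  } else a1d <- a1
  z2 <- a1d %*% p$fc2$W + matrix(p$fc2$b, n, cfg$n_species, byrow = TRUE)
  probs <- softmax_rows(z2)
  cache <- if (keep) {
    list(M = M, ca = ca_cache, layers = layers, drop_masks = drop_masks,
         h_last = h_last, z1 = z1, a1 = a1, a1d = a1d, fc_mask = fc_mask,
         n = n, H = H, W = W_)
  } else NULL
  list(probs = probs, cache = cache)
}

# Backward pass given d(loss)/d(logits).  Returns gradients in the same
# structure as model$params.
model_backward <- function(model, cache, dZ2) {
  cfg <- model$config; p <- model$params
  n <- cache$n; H <- cache$H; W_ <- cache$W
  D <- if (cfg$bidirectional) 2L else 1L
  hd <- cfg$hidden
  grads <- list()
  grads$fc2 <- list(W = crossprod(cache$a1d, dZ2), b = colSums(dZ2))
  dA1d <- dZ2 %*% t(p$fc2$W)
  dA1 <- if (!is.null(cache$fc_mask)) dA1d * cache$fc_mask else dA1d
  dZ1 <- dA1 * act_grad(cfg$activation)(cache$z1)
  grads$fc1 <- list(W = crossprod(cache$h_last, dZ1), b = colSums(dZ1))
  dH_last <- dZ1 %*% t(p$fc1$W)                  # (n, hd*D)
  # upstream gradient on the top layer's (possibly dropped-out) output
  dTop <- matrix(0, n * hd * D, W_)
  if (identical(cfg$readout, "last")) {
    dTop[, W_] <- as.vector(dH_last)
  } else {
    dTop[] <- as.vector(dH_last) / W_
  }
  for (l in rev(seq_len(cfg$n_layers))) {
    lay <- cache$layers[[l]]
    dH_cat <- dTop
    if (l <= length(cache$drop_masks) && !is.null(cache$drop_masks[[l]])) {
      dH_cat <- dH_cat * cache$drop_masks[[l]]
    }
    dX_sum <- matrix(0, n * lay$in_dim, W_)
    for (d in seq_len(D)) {
      dH_d <- if (D == 1) dH_cat else {
        seg <- if (d == 1) seq_len(n * hd) else n * hd + seq_len(n * hd)
        dH_cat[seg, , drop = FALSE]
      }
      bk <- lstm_dir_backward(dH_d, lay$input, lay$dirs[[d]], n, lay$in_dim,
                              hd, p[[sprintf("lstm_l%d_d%d", l, d)]]$W)
      grads[[sprintf("lstm_l%d_d%d", l, d)]] <- list(W = bk$dW, b = bk$db)
      dX_sum <- dX_sum + bk$dX
    }
    dTop <- dX_sum
  }
  if (cfg$use_ca) {
    grads$ca <- ca_batch_backward(dTop, cache$M, cache$ca, n, H, W_, p$ca)
  }
  grads
}

#' Class probabilities for a batch of feature matrices
#'
#' Runs the network in evaluation mode (no dropout); deterministic for
#' fixed parameters.
#'
#' @param model A `bc_model`.
#' @param X Either one feature matrix, a list of feature matrices, or an
#'   array `(n, rows, cols)`.
#' @param batch_size Clips processed per forward pass (default 64).
#' @return `n x n_species` matrix of softmax probabilities (rows sum to 1).
#' @export
predict_model <- function(model, X, batch_size = 64L) {
  X <- as_feature_array(X)
  n <- dim(X)[1]
  out <- matrix(0, n, model$config$n_species)
  for (i0 in seq(1, n, by = batch_size)) {
    idx <- i0:min(n, i0 + batch_size - 1)
    out[idx, ] <- model_forward(model,
                                X[idx, , , drop = FALSE])$probs
  }
  colnames(out) <- model_classes(model)
  out
}

model_classes <- function(model) {
  if (!is.null(model$classes)) model$classes else
    as.character(seq_len(model$config$n_species))
}

as_feature_array <- function(X) {
  if (is.array(X) && length(dim(X)) == 3) return(X)
  if (is.matrix(X)) {
    arr <- array(0, c(1, nrow(X), ncol(X)))
    arr[1, , ] <- X
    return(arr)
  }
  if (is.list(X)) {
    d1 <- dim(X[[1]])
    arr <- array(0, c(length(X), d1[1], d1[2]))
    for (k in seq_along(X)) arr[k, , ] <- X[[k]]
    return(arr)
  }
  stop("expected a matrix, list of matrices, or (n, rows, cols) array")
}

#' Save / load a model checkpoint
#'
#' The checkpoint directory holds `config.json` (architecture + class
#' labels) and `params.rds` (the parameter list).
#'
#' @param model A `bc_model`.
#' @param dir Checkpoint directory.
#' @return `dir` (for `save_model`) or the restored `bc_model`.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(c(model$config, list(classes = model$classes)),
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  saveRDS(model$params, file.path(dir, "params.rds"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  classes <- cfg$classes
  cfg$classes <- NULL
  params <- readRDS(file.path(dir, "params.rds"))
  structure(list(config = cfg, params = params, classes = classes),
            class = "bc_model")
}
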