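## Training: stratified 4:1 splitting, the cross-entropy objective, and the
## AdamW mini-batch loop with step learning-rate decay.

#' Stratified train/test split
#'
#' Shuffles each class independently (seeded) and assigns the first
#' `floor(ratio * n_class)` records to the training set, so every class
#' keeps the same train:test proportion (4:1 by default).
#'
#' @param manifest A `dataset_manifest` (or a data frame with a
#'   `species_id` column).
#' @param ratio Training fraction (default 0.8).
#' @param seed Integer seed; the partition is deterministic given the seed.
#' @return List with `train` and `test` record data frames.
#' @export
stratified_split <- function(manifest, ratio = 0.8, seed = 1L) {
  records <- if (inherits(manifest, "dataset_manifest")) manifest$records
             else manifest
  counts <- table(records$species_id)
  if (any(counts < 2)) {
    stop("stratified_split: every class needs >= 2 records; offending: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  train_idx <- integer(0)
  classes <- sort(unique(records$species_id))
  for (ci in seq_along(classes)) {
    idx <- which(records$species_id == classes[ci])
    idx <- with_seed(derive_seed(seed, ci), sample(idx))
    n_train <- floor(ratio * length(idx))
    train_idx <- c(train_idx, idx[seq_len(n_train)])
  }
  list(train = records[sort(train_idx), , drop = FALSE],
       test = records[sort(setdiff(seq_len(nrow(records)), train_idx)), ,
                      drop = FALSE])
}

#' Cross-entropy loss
#'
#' Default form is the summed binary cross-entropy over classes,
#' `-sum_n [ y_n log p_n + (1 - y_n) log(1 - p_n) ]`, averaged over the
#' batch; `form = "softmax_ce"` gives the canonical multiclass
#' `-log p_true`.  Probabilities are clamped to `[1e-12, 1 - 1e-12]`
#' before the logarithms.
#'
#' @param pred Probability vector, or `n x K` matrix of row-stochastic
#'   predictions.
#' @param target One-hot vector / matrix of the same shape, or an integer
#'   vector of true class indices when `pred` is a matrix.
#' @param form `"bce_sum"` (default) or `"softmax_ce"`.
#' @return Mean loss over the batch (non-negative scalar).
#' @export
cross_entropy_loss <- function(pred, target, form = c("bce_sum", "softmax_ce")) {
  form <- match.arg(form)
  if (is.vector(pred)) pred <- matrix(pred, 1)
  if (is.vector(target) && length(target) == ncol(pred) && nrow(pred) == 1) {
    target <- matrix(target, 1)
  } else if (!is.matrix(target)) {
    target <- one_hot(as.integer(target), ncol(pred))
  }
  eps <- 1e-12
  p <- pmin(pmax(pred, eps), 1 - eps)
  if (form == "bce_sum") {
    mean(-rowSums(target * log(p) + (1 - target) * log(1 - p)))
  } else {
    mean(-log(p)[cbind(seq_len(nrow(p)), max.col(target, "first"))])
  }
}

one_hot <- function(idx, K) {
  Y <- matrix(0, length(idx), K)
  Y[cbind(seq_along(idx), idx)] <- 1
  Y
}

# d(mean loss)/d(logits) for a softmax output under either loss form.
loss_logit_grad <- function(probs, Y, form) {
  n <- nrow(probs)
  if (form == "softmax_ce") return((probs - Y) / n)
  eps <- 1e-12
  p <- pmin(pmax(probs, eps), 1 - eps)
  dLdp <- (-Y / p + (1 - Y) / (1 - p)) / n
  probs * (dLdp - rowSums(dLdp * probs))
}

adamw_init <- function(params) {
  lapply(params, function(grp) lapply(grp, function(x) list(m = x * 0,
                                                            v = x * 0)))
}

# One AdamW update over the nested parameter/gradient lists.
adamw_step <- function(params, grads, state, lr, wd, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, s) {
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- s$m / (1 - beta1^t)
    vhat <- s$v / (1 - beta2^t)
    p <- p - lr * (mhat / (sqrt(vhat) + eps) + wd * p)
    list(p = p, s = s)
  }
  for (grp in names(grads)) {
    for (nm in names(grads[[grp]])) {
      r <- upd(params[[grp]][[nm]], grads[[grp]][[nm]], state[[grp]][[nm]])
      params[[grp]][[nm]] <- r$p
      state[[grp]][[nm]] <- r$s
    }
  }
  list(params = params, state = state)
}

#' Training configuration
#'
#' Defaults follow the full-scale recipe (70 epochs, batch 256, learning
#' rate 1e-4 decayed by 0.1 every 10 epochs, AdamW); desk-scale runs
#' override `epochs`, `batch_size`, `hidden` and use a larger learning rate
#' suited to small corpora.
#'
#' @param epochs Training epochs (default 70).
#' @param batch_size Mini-batch size (default 256).
#' @param learning_rate Initial learning rate (default 1e-4).
#' @param lr_decay_factor Multiplier applied every `lr_decay_every` epochs
#'   (default 0.1).
#' @param lr_decay_every Decay period in epochs (default 10).
#' @param weight_decay AdamW decoupled weight decay (default 0.01).
#' @param loss `"bce_sum"` (default) or `"softmax_ce"`.
#' @param seed Integer seed controlling shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 70L, batch_size = 256L,
                         learning_rate = 1e-4, lr_decay_factor = 0.1,
                         lr_decay_every = 10L, weight_decay = 0.01,
                         loss = c("bce_sum", "softmax_ce"), seed = 1L) {
  loss <- match.arg(loss)
  if (epochs < 1) stop("train_config: epochs must be >= 1")
  if (learning_rate <= 0) stop("train_config: learning_rate must be > 0")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every),
                 weight_decay = weight_decay, loss = loss,
                 seed = as.integer(seed)), class = "train_config")
}

epoch_lr <- function(config, epoch) {
  config$learning_rate *
    config$lr_decay_factor^((epoch - 1) %/% config$lr_decay_every)
}

#' Train a classifier
#'
#' Mini-batch AdamW optimization of the cross-entropy objective with step
#' learning-rate decay.  Deterministic for a fixed seed under
#' single-threaded BLAS.
#'
#' @param model A freshly constructed [bc_model()] (or one to fine-tune).
#' @param X Training features: array `(n, rows, cols)` or list of matrices.
#' @param y Class labels (factor or character); levels define the output
#'   order.
#' @param config A [train_config()].
#' @param X_val,y_val Optional held-out set; when given, per-epoch accuracy
#'   and mAP are logged.
#' @param verbose Print one line per epoch?
#' @return The trained `bc_model`, with a `log` data frame
#'   (`epoch,lr,train_loss[,val_acc,val_map]`) and `classes` attached.
#' @export
train_model <- function(model, X, y, config = train_config(),
                        X_val = NULL, y_val = NULL, verbose = FALSE) {
  X <- as_feature_array(X)
  n <- dim(X)[1]
  if (n == 0) stop("train_model: empty training set")
  y <- factor(y)
  classes <- levels(y)
  if (length(classes) != model$config$n_species) {
    stop("train_model: ", length(classes), " classes but model outputs ",
         model$config$n_species)
  }
  y_idx <- as.integer(y)
  Y <- one_hot(y_idx, model$config$n_species)
  params <- model$params
  opt <- adamw_init(params)
  log_rows <- list()
  step <- 0
  for (epoch in seq_len(config$epochs)) {
    lr <- epoch_lr(config, epoch)
    ord <- with_seed(derive_seed(config$seed, epoch), sample(n))
    ep_loss <- 0; n_batches <- 0
    for (i0 in seq(1, n, by = config$batch_size)) {
      idx <- ord[i0:min(n, i0 + config$batch_size - 1)]
      model$params <- params
      fw <- model_forward(model, X[idx, , , drop = FALSE], training = TRUE,
                          rng_seed = derive_seed(config$seed, epoch, i0))
      ep_loss <- ep_loss + cross_entropy_loss(fw$probs,
                                              Y[idx, , drop = FALSE],
                                              config$loss)
      n_batches <- n_batches + 1
      dZ2 <- loss_logit_grad(fw$probs, Y[idx, , drop = FALSE], config$loss)
      grads <- model_backward(model, fw$cache, dZ2)
      step <- step + 1
      st <- adamw_step(params, grads, opt, lr, config$weight_decay, step)
      params <- st$params; opt <- st$state
    }
    model$params <- params
    row <- data.frame(epoch = epoch, lr = lr, train_loss = ep_loss / n_batches)
    if (!is.null(X_val)) {
      pv <- predict_model(model, X_val)
      colnames(pv) <- classes
      yv <- factor(y_val, levels = classes)
      row$val_acc <- mean(classes[max.col(pv, "first")] == as.character(yv))
      row$val_map <- map_score(pv, yv)
    }
    log_rows[[epoch]] <- row
    if (verbose) {
      msg <- sprintf("epoch %3d  lr %.2e  loss %.4f", epoch, lr,
                     row$train_loss)
      if (!is.null(X_val)) {
        msg <- paste0(msg, sprintf("  val_acc %.3f  val_mAP %.3f",
                                   row$val_acc, row$val_map))
      }
      message(msg)
    }
  }
  model$params <- params
  model$classes <- classes
  model$log <- do.call(rbind, log_rows)
  model
}
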