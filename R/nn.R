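## Neural-network primitives: SiLU, coordinate attention (CA), the LSTM
## cell, and the batched forward/backward passes used for training.
##
## Everything is dense base-R linear algebra.  A batch of fused feature
## matrices is held as an array (n, H, W); for the CA block it is viewed as
## an (n*H, W) matrix in which row (b, i) is sample b's feature row i, so
## row/column gating becomes elementwise products with recycled vectors.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Sigmoid linear unit
#'
#' `silu(x) = x * sigmoid(x)`; smooth, non-monotone near zero, and free of
#' the dead-neuron regime of ReLU.
#'
#' @param x Numeric vector/matrix.
#' @return `x * sigmoid(x)`, same shape.
#' @export
silu <- function(x) x * sigmoid(x)

silu_grad <- function(x) { s <- sigmoid(x); s * (1 + x * (1 - s)) }

act_fun <- function(name) {
  switch(name, silu = silu, relu = function(x) pmax(x, 0),
         stop("unknown activation: ", name))
}
act_grad <- function(name) {
  switch(name, silu = silu_grad, relu = function(x) (x > 0) * 1,
         stop("unknown activation: ", name))
}

## ---------------------------------------------------------------- CA ----

as_feature_map <- function(x) {
  if (is.matrix(x)) return(unclass(x))
  if (is.array(x) && length(dim(x)) == 3 && dim(x)[1] == 1) {
    return(matrix(x, dim(x)[2], dim(x)[3]))
  }
  stop("expected an H x W matrix or a 1 x H x W array")
}

#' Directional average pooling for coordinate attention
#'
#' Pools a feature map along each spatial axis separately: `pooled_h[i]` is
#' the mean of row `i` (over all columns), `pooled_w[j]` the mean of column
#' `j` (over all rows).
#'
#' @param x An `H x W` matrix (one channel) or `1 x H x W` array.
#' @return List with `pooled_h` (length H) and `pooled_w` (length W).
#' @export
ca_pool <- function(x) {
  m <- as_feature_map(x)
  list(pooled_h = rowMeans(m), pooled_w = colMeans(m))
}

#' Initialize coordinate-attention parameters
#'
#' The shared 1x1 transform maps the single input channel to `r_mid`
#' intermediate channels; instance normalization (learned scale/shift per
#' intermediate channel, statistics over the concatenated pooled map)
#' precedes the activation; two per-direction 1x1 transforms map back to one
#' channel each before the sigmoids.
#'
#' @param r_mid Intermediate channel width (default 8).
#' @param seed Integer seed for the uniform `+/- 1/sqrt(fan_in)` init.
#' @return List of CA parameter vectors.
#' @export
ca_init <- function(r_mid = 8L, seed = 1L) {
  with_seed(seed, list(
    W1 = stats::runif(r_mid, -1, 1),           # 1 -> r_mid channel mixing
    b1 = numeric(r_mid),
    gamma = rep(1, r_mid),                     # norm scale
    beta = numeric(r_mid),                     # norm shift
    # output biases start at +2 so gates open near sigmoid(2) ~ 0.88 and the
    # block is close to a no-op at initialization; attention is then learned
    W2h = stats::runif(r_mid, -1, 1) / sqrt(r_mid),  # r_mid -> 1, row gates
    b2h = 2,
    W2w = stats::runif(r_mid, -1, 1) / sqrt(r_mid),  # r_mid -> 1, col gates
    b2w = 2))
}

CA_EPS <- 1e-5

#' Coordinate-attention gate vectors
#'
#' Pipeline: directional average pooling -> concatenation along the spatial
#' axis -> shared 1x1 transform to `r_mid` channels -> per-channel instance
#' normalization over the concatenated map -> SiLU -> split at position H
#' into the row part and column part -> per-direction 1x1 transforms back to
#' one channel -> sigmoid.  All gate entries lie strictly in (0, 1).
#'
#' @param x An `H x W` feature map (or `1 x H x W` array).
#' @param params CA parameters from [ca_init()].
#' @return List with `g_h` (length H) and `g_w` (length W).
#' @export
ca_gates <- function(x, params) {
  m <- as_feature_map(x)
  p <- ca_pool(m)
  z <- c(p$pooled_h, p$pooled_w)                       # length H + W
  r_mid <- length(params$W1)
  sh <- numeric(nrow(m)); sw <- numeric(ncol(m))
  for (r in seq_len(r_mid)) {
    a <- params$W1[r] * z + params$b1[r]
    mu <- mean(a); sd_ <- sqrt(mean((a - mu)^2) + CA_EPS)
    act <- silu(params$gamma[r] * (a - mu) / sd_ + params$beta[r])
    sh <- sh + params$W2h[r] * act[seq_len(nrow(m))]
    sw <- sw + params$W2w[r] * act[nrow(m) + seq_len(ncol(m))]
  }
  list(g_h = sigmoid(sh + params$b2h), g_w = sigmoid(sw + params$b2w))
}

#' Coordinate-attention re-weighting
#'
#' `y[i, j] = x[i, j] * g_h[i] * g_w[j]`: each cell is scaled by its row
#' gate and its column gate.
#'
#' @param x An `H x W` feature map (or `1 x H x W` array).
#' @param gates List with `g_h` (length H), `g_w` (length W) — see
#'   [ca_gates()].
#' @return Re-weighted matrix of the same shape as `x`.
#' @export
ca_reweight <- function(x, gates) {
  m <- as_feature_map(x)
  if (length(gates$g_h) != nrow(m) || length(gates$g_w) != ncol(m)) {
    stop("ca_reweight: gate lengths do not match feature-map shape")
  }
  m * gates$g_h * rep(gates$g_w, each = nrow(m))
}

## -------------------------------------------------------------- LSTM ----

# Combined-gate weight layout: columns [forget | input | candidate | output].
lstm_layer_init <- function(input_dim, hidden, seed) {
  s <- 1 / sqrt(input_dim + hidden)
  with_seed(seed, list(
    W = matrix(stats::runif((input_dim + hidden) * 4 * hidden, -s, s),
               input_dim + hidden, 4 * hidden),
    b = numeric(4 * hidden)))
}

#' One LSTM cell step
#'
#' Implements the gated recurrence
#' `f = sigma(W_f [h, x] + b_f)`, `i = sigma(W_i [h, x] + b_i)`,
#' `c_hat = tanh(W_C [h, x] + b_C)`, `C' = f * C + i * c_hat`,
#' `o = sigma(W_o [h, x] + b_o)`, `h' = o * tanh(C')`.
#'
#' @param x_t Input vector at this timestep.
#' @param state List with `h` (hidden vector) and `C` (cell vector).
#' @param params List with combined `W` (`(input+hidden) x 4*hidden`,
#'   gate blocks ordered forget/input/candidate/output) and `b`.
#' @return New state: list with `h` and `C`.
#' @export
lstm_cell <- function(x_t, state, params) {
  hd <- length(state$h)
  if (length(x_t) + hd != nrow(params$W)) {
    stop("lstm_cell: dimension mismatch between input, state and weights")
  }
  a <- drop(c(x_t, state$h) %*% params$W) + params$b
  f <- sigmoid(a[seq_len(hd)])
  i <- sigmoid(a[hd + seq_len(hd)])
  g <- tanh(a[2 * hd + seq_len(hd)])
  o <- sigmoid(a[3 * hd + seq_len(hd)])
  C <- f * state$C + i * g
  list(h = o * tanh(C), C = C)
}

## --------------------------------------------- batched forward pass ----

# One direction of one layer over the whole batch/sequence.
# X_seq: (n*H_in, T) matrix (column t = flattened (n, H_in) input).
# Returns H_out (n*hd, T) plus caches when keep_cache.
lstm_dir_forward <- function(X_seq, n, input_dim, hd, W, b, reverse,
                             keep_cache) {
  T_ <- ncol(X_seq)
  order_t <- if (reverse) rev(seq_len(T_)) else seq_len(T_)
  H_out <- matrix(0, n * hd, T_)
  cache <- if (keep_cache) {
    list(F = matrix(0, n * hd, T_), I = matrix(0, n * hd, T_),
         G = matrix(0, n * hd, T_), O = matrix(0, n * hd, T_),
         C = matrix(0, n * hd, T_), tanhC = matrix(0, n * hd, T_))
  } else NULL
  h <- matrix(0, n, hd); C <- matrix(0, n, hd)
  bmat <- matrix(b, n, 4 * hd, byrow = TRUE)
  for (t in order_t) {
    XH <- cbind(matrix(X_seq[, t], n, input_dim), h)
    a <- XH %*% W + bmat
    f <- sigmoid(a[, seq_len(hd), drop = FALSE])
    i <- sigmoid(a[, hd + seq_len(hd), drop = FALSE])
    g <- tanh(a[, 2 * hd + seq_len(hd), drop = FALSE])
    o <- sigmoid(a[, 3 * hd + seq_len(hd), drop = FALSE])
    C <- f * C + i * g
    tC <- tanh(C)
    h <- o * tC
    H_out[, t] <- h
    if (keep_cache) {
      cache$F[, t] <- f; cache$I[, t] <- i; cache$G[, t] <- g
      cache$O[, t] <- o; cache$C[, t] <- C; cache$tanhC[, t] <- tC
    }
  }
  list(H = H_out, cache = cache, order_t = order_t)
}

# Backward through one direction.  dH_seq: (n*hd, T) upstream gradient on
# this direction's outputs (in original time indexing).  Returns dX_seq,
# dW, db.
lstm_dir_backward <- function(dH_seq, X_seq, fwd, n, input_dim, hd, W) {
  T_ <- ncol(X_seq)
  order_t <- fwd$order_t
  ch <- fwd$cache
  dW <- matrix(0, nrow(W), ncol(W)); db <- numeric(4 * hd)
  dX_seq <- matrix(0, n * input_dim, T_)
  dh_rec <- matrix(0, n, hd); dC <- matrix(0, n, hd)
  for (k in rev(seq_along(order_t))) {
    t <- order_t[k]
    f <- matrix(ch$F[, t], n, hd); i <- matrix(ch$I[, t], n, hd)
    g <- matrix(ch$G[, t], n, hd); o <- matrix(ch$O[, t], n, hd)
    tC <- matrix(ch$tanhC[, t], n, hd)
    C_prev <- if (k > 1) matrix(ch$C[, order_t[k - 1]], n, hd) else
      matrix(0, n, hd)
    h_prev <- if (k > 1) matrix(fwd$H[, order_t[k - 1]], n, hd) else
      matrix(0, n, hd)
    dh <- matrix(dH_seq[, t], n, hd) + dh_rec
    do_ <- dh * tC
    dC <- dC + dh * o * (1 - tC^2)
    df <- dC * C_prev
    di <- dC * g
    dg <- dC * i
    dA <- cbind(df * f * (1 - f), di * i * (1 - i),
                dg * (1 - g^2), do_ * o * (1 - o))
    XH <- cbind(matrix(X_seq[, t], n, input_dim), h_prev)
    dW <- dW + crossprod(XH, dA)
    db <- db + colSums(dA)
    dXH <- dA %*% t(W)
    dX_seq[, t] <- dXH[, seq_len(input_dim)]
    dh_rec <- dXH[, input_dim + seq_len(hd), drop = FALSE]
    dC <- dC * f
  }
  list(dX = dX_seq, dW = dW, db = db)
}

# Batched CA forward over an (n*H, W)-flattened batch.
# Returns gated output plus caches for backward.
ca_batch_forward <- function(M, n, H, W_, p) {
  group <- rep(seq_len(n), times = H)
  P_h <- matrix(rowMeans(matrix(as.vector(M), n * H, W_)), n, H)  # (n,H)
  P_w <- rowsum(M, group) / H                                     # (n,W)
  z <- cbind(P_h, P_w)                                            # (n,H+W)
  r_mid <- length(p$W1)
  sh <- matrix(p$b2h, n, H); sw <- matrix(p$b2w, n, W_)
  A <- vector("list", r_mid); An <- vector("list", r_mid)
  sd_ <- vector("list", r_mid); pre <- vector("list", r_mid)
  for (r in seq_len(r_mid)) {
    a <- p$W1[r] * z + p$b1[r]
    mu <- rowMeans(a)
    s <- sqrt(rowMeans((a - mu)^2) + CA_EPS)
    an <- (a - mu) / s
    pr <- p$gamma[r] * an + p$beta[r]
    act <- silu(pr)
    sh <- sh + p$W2h[r] * act[, seq_len(H), drop = FALSE]
    sw <- sw + p$W2w[r] * act[, H + seq_len(W_), drop = FALSE]
    A[[r]] <- a; An[[r]] <- an; sd_[[r]] <- s; pre[[r]] <- pr
  }
  g_h <- sigmoid(sh); g_w <- sigmoid(sw)
  gh_flat <- as.vector(g_h)                    # length n*H, matches M rows
  Gw_big <- g_w[group, , drop = FALSE]         # (n*H, W)
  Y <- M * gh_flat * Gw_big
  list(Y = Y, g_h = g_h, g_w = g_w, z = z, A = A, An = An, sd = sd_,
       pre = pre, gh_flat = gh_flat, Gw_big = Gw_big, group = group)
}

# Backward through batched CA.  dY: (n*H, W).  Gradients w.r.t. CA params
# only (the input is data, not a parameter).
ca_batch_backward <- function(dY, M, cf, n, H, W_, p) {
  r_mid <- length(p$W1)
  T1 <- dY * M
  dg_h <- matrix(rowSums(T1 * cf$Gw_big), n, H)
  dg_w <- rowsum(T1 * cf$gh_flat, cf$group)
  dsh <- dg_h * cf$g_h * (1 - cf$g_h)
  dsw <- dg_w * cf$g_w * (1 - cf$g_w)
  g <- list(W1 = numeric(r_mid), b1 = numeric(r_mid),
            gamma = numeric(r_mid), beta = numeric(r_mid),
            W2h = numeric(r_mid), b2h = sum(dsh),
            W2w = numeric(r_mid), b2w = sum(dsw))
  P <- H + W_
  for (r in seq_len(r_mid)) {
    act <- silu(cf$pre[[r]])
    g$W2h[r] <- sum(dsh * act[, seq_len(H), drop = FALSE])
    g$W2w[r] <- sum(dsw * act[, H + seq_len(W_), drop = FALSE])
    dact <- cbind(dsh * p$W2h[r], dsw * p$W2w[r])        # (n, H+W)
    dpre <- dact * silu_grad(cf$pre[[r]])
    g$gamma[r] <- sum(dpre * cf$An[[r]])
    g$beta[r] <- sum(dpre)
    dAn <- dpre * p$gamma[r]
    # instance-norm backward, statistics per sample over the P positions
    an <- cf$An[[r]]
    dA <- (dAn - rowMeans(dAn) - an * rowMeans(dAn * an)) / cf$sd[[r]]
    g$W1[r] <- sum(dA * cf$z)
    g$b1[r] <- sum(dA)
  }
  g
}
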