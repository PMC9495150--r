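# Brute-force reference implementations, kept deliberately naive and
# independent of the package's vectorized code paths.

# Direct DFT magnitude of one frame: |sum_n x_n exp(-i 2 pi k n / N)|.
oracle_dft_magnitude <- function(x) {
  N <- length(x)
  vapply(0:(N %/% 2), function(k) {
    re <- sum(x * cos(-2 * pi * k * (0:(N - 1)) / N))
    im <- sum(x * sin(-2 * pi * k * (0:(N - 1)) / N))
    sqrt(re^2 + im^2)
  }, numeric(1))
}

# Orthonormal DCT-II of one frame by explicit summation.
oracle_dct <- function(x, n_keep) {
  N <- length(x)
  vapply(0:(n_keep - 1), function(k) {
    s <- sum(x * cos(pi * (2 * (0:(N - 1)) + 1) * k / (2 * N)))
    s * if (k == 0) sqrt(1 / N) else sqrt(2 / N)
  }, numeric(1))
}

# Scalar-arithmetic LSTM cell following the six gate equations.
oracle_lstm_cell <- function(x_t, h_prev, C_prev, W, b) {
  hd <- length(h_prev)
  xh <- c(x_t, h_prev)
  sig <- function(z) 1 / (1 + exp(-z))
  lin <- function(block) {
    vapply(seq_len(hd), function(u) {
      col <- (block - 1) * hd + u
      sum(xh * W[, col]) + b[col]
    }, numeric(1))
  }
  f <- sig(lin(1)); i <- sig(lin(2)); g <- tanh(lin(3)); o <- sig(lin(4))
  C <- f * C_prev + i * g
  list(h = o * tanh(C), C = C)
}

# Triple-loop CA re-weighting.
oracle_ca_reweight <- function(x, g_h, g_w) {
  y <- x
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      y[i, j] <- x[i, j] * g_h[i] * g_w[j]
    }
  }
  y
}

# --- metric oracles (loops and sorts only) -------------------------------

oracle_accuracy <- function(pred, truth) {
  sum(pred == truth) / length(truth)
}

oracle_prf1 <- function(pred, truth, classes) {
  out <- list()
  for (k in classes) {
    tp <- sum(pred == k & truth == k)
    fp <- sum(pred == k & truth != k)
    fn <- sum(pred != k & truth == k)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    out[[k]] <- c(precision = p, recall = r, f1 = f)
  }
  out
}

# Literal double-sum AUC with half-credit for ties.
oracle_auc <- function(scores, is_pos) {
  pos <- which(is_pos); neg <- which(!is_pos)
  s <- 0
  for (t1 in pos) {
    for (t0 in neg) {
      s <- s + (scores[t0] < scores[t1]) + 0.5 * (scores[t0] == scores[t1])
    }
  }
  s / (length(pos) * length(neg))
}

oracle_top_k <- function(scores, truth_idx, k = 5) {
  hits <- 0
  for (i in seq_len(nrow(scores))) {
    ord <- order(-scores[i, ], seq_len(ncol(scores)))[seq_len(k)]
    hits <- hits + (truth_idx[i] %in% ord)
  }
  hits / nrow(scores)
}

# AP as the precision/recall staircase sum over ranked samples.
oracle_ap <- function(scores, is_pos) {
  ord <- order(-scores, seq_along(scores))
  lab <- is_pos[ord]
  n_pos <- sum(is_pos)
  ap <- 0; tp <- 0; recall_prev <- 0
  for (s in seq_along(lab)) {
    tp <- tp + lab[s]
    prec <- tp / s
    recall <- tp / n_pos
    ap <- ap + prec * (recall - recall_prev)
    recall_prev <- recall
  }
  ap
}

# --- shared fixtures -----------------------------------------------------

# Random row-stochastic score set with labels, for metric fuzzing.
random_score_set <- function(n, K, seed) {
  withr::with_seed(seed, {
    s <- matrix(stats::rexp(n * K), n, K)
    s <- s / rowSums(s)
    list(scores = s, truth_idx = sample(K, n, replace = TRUE))
  })
}

# One small preprocessed + featurized corpus, built once per test session.
.fixture_env <- new.env(parent = emptyenv())

shared_corpus <- function() {
  if (!is.null(.fixture_env$corpus)) return(.fixture_env$corpus)
  specs <- make_species_specs(3, seed = 11)
  raw_dir <- file.path(tempdir(), "birdcall_fixture_raw")
  man <- build_dataset(specs, 4, raw_dir, seed = 11, noise_db = -30,
                       duration_range_s = c(4, 7))
  pp <- preprocess_manifest(man, file.path(tempdir(), "birdcall_fixture_pp"),
                            gate_db = -20)
  .fixture_env$corpus <- list(specs = specs, manifest = man, pp = pp)
  .fixture_env$corpus
}
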