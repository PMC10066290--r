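# Shared fixtures, built in code and memoised across test files.

.fixtures <- new.env(parent = emptyenv())

# 64 x 64 synthetic dataset, memoised by (n_per_class, seed)
fixture_dataset <- function(n_per_class, seed = 0, size = 64) {
  key <- sprintf("ds_%d_%d_%d", n_per_class, seed, size)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- generate_dataset(n_per_class, n_per_class,
                                         generator_config(size = size), seed = seed)
  }
  .fixtures[[key]]
}

# deterministic non-uniform test image (smooth gradient + channel offsets)
fixture_image <- function(h = 24, w = 24) {
  g <- outer(seq(0, 1, length.out = h), seq(0, 1, length.out = w), function(a, b) {
    0.2 + 0.6 * (a + b) / 2
  })
  arr <- array(0, dim = c(h, w, 3))
  arr[, , 1] <- g
  arr[, , 2] <- g * 0.9
  arr[, , 3] <- g * 0.8
  arr
}

# brute-force valid cross-correlation oracle (quadruple loop), independent of
# the im2col implementation
oracle_conv <- function(x, kernels, biases, act = identity) {
  kh <- dim(kernels)[1]; kw <- dim(kernels)[2]
  m_in <- dim(kernels)[3]; m_out <- dim(kernels)[4]
  oh <- dim(x)[1] - kh + 1; ow <- dim(x)[2] - kw + 1
  out <- array(0, dim = c(oh, ow, m_out))
  for (i in seq_len(m_out)) {
    for (oi in seq_len(oh)) for (oj in seq_len(ow)) {
      acc <- biases[i]
      for (j in seq_len(m_in)) {
        for (di in seq_len(kh)) for (dj in seq_len(kw)) {
          acc <- acc + kernels[di, dj, j, i] * x[oi + di - 1, oj + dj - 1, j]
        }
      }
      out[oi, oj, i] <- acc
    }
  }
  act(out)
}

# brute-force max pooling oracle
oracle_pool <- function(mat, f, s) {
  oh <- (nrow(mat) - f) %/% s + 1
  ow <- (ncol(mat) - f) %/% s + 1
  out <- matrix(0, oh, ow)
  for (i in seq_len(oh)) for (j in seq_len(ow)) {
    ri <- (i - 1) * s + 1; ci <- (j - 1) * s + 1
    out[i, j] <- max(mat[ri:(ri + f - 1), ci:(ci + f - 1)])
  }
  out
}

# brute-force AUC: count positive-negative pairs, ties worth 1/2
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == "cobra"]
  neg <- scores[labels == "other"]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}
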