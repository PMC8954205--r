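# Shared fixtures: all built in code at test time.

# Independent per-pixel MMWF implementation (explicit loops; mirror padding)
# used as the oracle for the vectorised filter.
brute_mmwf <- function(x, w, gamma2 = NULL) {
  n <- nrow(x); m <- ncol(x); h <- w %/% 2
  mir <- function(i, k) {
    while (i < 1 || i > k) { if (i < 1) i <- 1 - i; if (i > k) i <- 2 * k + 1 - i }
    i
  }
  med <- va <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    vals <- numeric(0)
    for (a in -h:h) for (b in -h:h)
      vals <- c(vals, x[mir(i + a, n), mir(j + b, m)])
    med[i, j] <- median(vals)
    va[i, j] <- mean(vals^2) - mean(vals)^2
  }
  if (is.null(gamma2)) gamma2 <- mean(va)
  med + ifelse(va > 0, pmax(va - gamma2, 0) / va, 0) * (x - med)
}

# Piecewise-constant test slice: background plateau, bright square, darker
# inner square.
piecewise_slice <- function(n = 32) {
  f <- matrix(0.2, n, n)
  q <- round(n / 4)
  f[q:(3 * q), q:(3 * q)] <- 1
  f[(2 * q - 2):(2 * q + 2), (2 * q - 2):(2 * q + 2)] <- 0.5
  f
}

# Tiny network configuration used for gradient/shape/determinism checks.
tiny_model_config <- function(seed = 7L)
  model_config(input_shape = c(8, 8, 6), base_channels = 3L,
               stage_channels = c(3L, 4L), fc_width = 5L,
               batch_size = 2L, epochs = 2L, seed = seed)

random_volume <- function(dims, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(abs(rnorm(prod(dims))), dims)
}
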