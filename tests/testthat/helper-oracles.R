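# Independent oracles and fixture builders used across the suite.
# Oracles are deliberately naive (loops, closed forms, direct linear
# algebra) and share no code with the implementation paths they check.

random_gray <- function(m, n, seed, vals = 0:255) {
  set.seed(seed)
  gray_image(matrix(sample(vals, m * n, replace = TRUE), m, n))
}

# One-pass scan over a vector: the run-length oracle.
naive_run_scan <- function(v) {
  vals <- numeric(0)
  cnts <- numeric(0)
  for (x in v) {
    if (length(vals) && x == vals[length(vals)]) {
      cnts[length(cnts)] <- cnts[length(cnts)] + 1
    } else {
      vals <- c(vals, x)
      cnts <- c(cnts, 1)
    }
  }
  list(values = vals, counts = cnts)
}

# Per-pixel brute-force PSNR.
brute_psnr <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  sse <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) sse <- sse + (a[i, j] - b[i, j])^2
  }
  mse <- sse / length(a)
  if (mse == 0) Inf else 10 * log10(255^2 / mse)
}

# Explicit 2x2 orthonormal Haar block transform of an even-dim matrix:
# per block [[a,b],[c,d]] (rows i, i+1; cols j, j+1),
#   LL = (a+b+c+d)/2, LH row-detail = (a+b-c-d)/2,
#   HL col-detail = (a-b+c-d)/2, HH = (a-b-c+d)/2.
haar_block_oracle <- function(X) {
  m <- nrow(X) / 2
  n <- ncol(X) / 2
  out <- list(approx = matrix(0, m, n), horizontal = matrix(0, m, n),
              vertical = matrix(0, m, n), diagonal = matrix(0, m, n))
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      a <- X[2 * i - 1, 2 * j - 1]; b <- X[2 * i - 1, 2 * j]
      c <- X[2 * i, 2 * j - 1]; d <- X[2 * i, 2 * j]
      out$approx[i, j] <- (a + b + c + d) / 2
      out$horizontal[i, j] <- (a + b - c - d) / 2
      out$vertical[i, j] <- (a - b + c - d) / 2
      out$diagonal[i, j] <- (a - b - c + d) / 2
    }
  }
  out
}

# Best rank-k mean squared chunk reconstruction error, by direct SVD.
svd_rank_k_mse <- function(chunks, k) {
  d <- svd(chunks)$d
  sum(d[-seq_len(k)]^2) / length(chunks)
}
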