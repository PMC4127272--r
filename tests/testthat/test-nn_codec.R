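test_that("normalization maps endpoints, pads, and round trips", {
  cn <- chunk_and_normalize(c(0, 255, 255), n = 2, s_max = 255)
  expect_equal(cn$chunks, matrix(c(-1, 1, 1, 0), 2, 2))
  expect_equal(cn$pad, 1L)
  # exactly divisible stream: no padding
  expect_equal(chunk_and_normalize(1:8, n = 4, s_max = 10)$pad, 0L)
  # denormalize(normalize(x)) == x
  set.seed(2)
  for (signed in c(FALSE, TRUE)) {
    x <- if (signed) rnorm(37, sd = 20) else runif(37, 0, 200)
    cn <- chunk_and_normalize(x, n = 8, s_max = 300, signed = signed)
    z <- as.vector(cn$chunks)[seq_along(x)]
    back <- sbpnn:::denormalize_stream(z, 300, signed)
    expect_equal(back, x, tolerance = 1e-12)
  }
  expect_error(chunk_and_normalize(c(0, 500), n = 2, s_max = 255),
               class = "sbpn_argument_error")
  expect_error(chunk_and_normalize(1:4, n = 1, s_max = 10),
               class = "sbpn_argument_error")
})

test_that("Hebbian initialization reproduces known spectra", {
  # rank-1 Gram: the single eigenvector is +/- v/||v||
  v <- c(3, 4, 0, 12)
  chunks <- matrix(rep(v, 5), 4, 5)
  m <- init_weights_hebbian(chunks, k = 1)
  expect_equal(abs(as.vector(m$W_enc)), abs(v / sqrt(sum(v^2))), tolerance = 1e-10)
  expect_equal(as.vector(m$W_dec %*% (m$W_enc %*% v)), v, tolerance = 1e-10)
  # k = n: full eigenbasis gives W_dec W_enc = I
  set.seed(13)
  X <- matrix(rnorm(16 * 40), 16, 40)
  mf <- init_weights_hebbian(X, k = 16)
  expect_equal(mf$W_dec %*% mf$W_enc, diag(16), tolerance = 1e-8)
  # chunks of exact rank r, k = r: every chunk reconstructed (SVD oracle)
  B <- matrix(rnorm(16 * 3), 16, 3)
  Xr <- B %*% matrix(rnorm(3 * 30), 3, 30)
  mr <- init_weights_hebbian(Xr, k = 3, hidden = "linear")
  expect_lt(max(abs(mr$W_dec %*% (mr$W_enc %*% Xr) - Xr)), 1e-8)
  expect_error(init_weights_hebbian(X, k = 17), class = "sbpn_argument_error")
})

test_that("initialization sign convention is deterministic", {
  set.seed(21)
  X <- matrix(rnorm(8 * 30), 8, 30)
  m1 <- init_weights_hebbian(X, 4)
  m2 <- init_weights_hebbian(X, 4)
  expect_identical(m1$W_enc, m2$W_enc)
  for (j in seq_len(4)) {
    row <- m1$W_enc[j, ]
    expect_gt(row[which.max(abs(row))], 0)
  }
})

test_that("an already-converged model returns after zero epochs, unchanged", {
  B <- matrix(rnorm(8 * 2), 8, 2)
  X <- B %*% matrix(rnorm(2 * 20, sd = 0.05), 2, 20)
  m <- init_weights_hebbian(X, k = 4, hidden = "linear")
  expect_lt(model_mse(m, X), 0.1)
  t <- train(m, X)
  expect_equal(t$epochs_run, 0L)
  expect_equal(t$W_enc, m$W_enc, tolerance = 1e-12)
  expect_equal(t$W_dec, m$W_dec, tolerance = 1e-12)
})

test_that("training reaches the goal on rank-1 data and never worsens", {
  set.seed(17)
  v <- rnorm(16)
  X <- v %*% t(runif(40, 0.2, 1))
  m <- train(init_weights_hebbian(X, k = 1), X)
  expect_lte(m$error, 0.1)
  expect_lte(m$epochs_run, 50L)
  expect_lte(m$error, m$error_history[1])
  expect_true(all(diff(m$error_history) <= 1e-12))
})

test_that("training stops at the epoch cap on hard data", {
  set.seed(23)
  X <- matrix(rnorm(16 * 200), 16, 200)
  m <- train(init_weights_hebbian(X, k = 8), X)
  expect_equal(m$epochs_run, 50L)
  expect_gt(m$error, 0.1)  # iid chunks cannot reach the goal at k = n/2
  expect_lte(m$error, m$error_history[1])
})

test_that("training is bit-for-bit reproducible", {
  set.seed(29)
  X <- matrix(rnorm(16 * 100), 16, 100)
  m1 <- train(init_weights_hebbian(X, k = 8, seed = 5), X)
  m2 <- train(init_weights_hebbian(X, k = 8, seed = 5), X)
  expect_identical(m1$W_enc, m2$W_enc)
  expect_identical(m1$W_dec, m2$W_dec)
  expect_identical(m1$error, m2$error)
})

test_that("encoding matches a hand-rolled matrix-multiply + tanh oracle", {
  set.seed(19)
  X <- matrix(rnorm(8 * 6, sd = 0.4), 8, 6)
  m <- init_weights_hebbian(X, k = 3)
  code <- nn_encode(m, X)
  for (c in 1:6) {
    for (j in 1:3) {
      expect_equal(code$H[j, c], tanh(sum(m$W_enc[j, ] * X[, c])),
                   tolerance = 1e-12)
    }
  }
  # zero chunk -> zero hidden vector; tansig keeps codes inside (-1, 1)
  z <- nn_encode(m, matrix(0, 8, 1))
  expect_equal(as.vector(z$H), rep(0, 3))
  expect_true(all(abs(code$H) < 1))
  expect_error(nn_encode(m, matrix(0, 7, 1)), class = "sbpn_shape_error")
})

test_that("decode inverts encode at full capacity and strips padding", {
  # k = n linear regime: identity within one intensity level after rounding
  x <- c(10, 200, 31, 77, 180)  # length 5, n = 4 -> pad 3
  cn <- chunk_and_normalize(x, n = 4, s_max = 255)
  m <- init_weights_hebbian(cn, k = 4, hidden = "linear")
  code <- nn_encode(m, cn)
  y <- nn_decode(m, code, s_max = 255, signed = FALSE, vrange = c(0, 255))
  expect_equal(length(y), 5L)
  expect_lte(max(abs(y - x)), 1)
  # zero code with zero decode weights -> offset-denormalized zeros
  mz <- m; mz$W_dec <- matrix(0, 4, 4)
  zc <- structure(list(H = matrix(0, 4, 2), n_chunks = 2L, pad = 3L),
                  class = "sbpn_hidden_code")
  expect_equal(nn_decode(mz, zc, s_max = 255, signed = FALSE), rep(128, 5))
  # inconsistent pad is a corrupt code
  bad <- code; bad$pad <- 7L
  expect_error(nn_decode(m, bad, s_max = 255), class = "sbpn_corrupt_error")
})

test_that("trained models stay within 2x of the rank-k SVD optimum", {
  set.seed(7)
  X <- matrix(rnorm(16 * 500), 16, 500)
  opt <- svd_rank_k_mse(X, 8)
  init <- init_weights_hebbian(X, k = 8, hidden = "linear")
  # linear-regime lower bound: no model can beat the SVD optimum
  expect_gte(model_mse(init, X), opt - 1e-9)
  trained <- train(init_weights_hebbian(X, k = 8), X)
  expect_lte(trained$error, 2 * opt)
})

test_that("hidden codes survive 8-bit storage within a quantizer step", {
  set.seed(31)
  H <- matrix(runif(40, -1, 1), 5, 8)
  H2 <- hidden_dequantize(hidden_quantize(H), 5, 8)
  expect_lte(max(abs(H2 - H)), 1 / 127.5 + 1e-12)
  expect_error(hidden_dequantize(as.raw(1:7), 2, 4), class = "sbpn_corrupt_error")
})
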