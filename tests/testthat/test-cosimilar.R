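test_that("pair encoding collapses runs as stated", {
  p <- encode_pairs(matrix(5, 2, 2))
  expect_equal(p$values, 5)
  expect_equal(p$counts, 4)
  # row-major raster of [[1,2],[1,2]] is 1,2,1,2: no two adjacent equal
  p2 <- encode_pairs(matrix(c(1, 1, 2, 2), 2, 2))
  expect_equal(p2$values, c(1, 2, 1, 2))
  expect_equal(p2$counts, rep(1, 4))
  expect_error(encode_pairs(matrix(numeric(0), 0, 0)),
               class = "sbpn_argument_error")
})

test_that("pair encoding agrees with the naive one-pass scan oracle", {
  set.seed(3)
  for (i in 1:25) {
    m <- sample(2:40, 1); n <- sample(2:40, 1)
    X <- matrix(sample(0:3, m * n, replace = TRUE), m, n)
    p <- encode_pairs(X)
    oracle <- naive_run_scan(as.vector(t(X)))
    expect_equal(p$values, oracle$values)
    expect_equal(p$counts, oracle$counts)
    expect_equal(sum(p$counts), m * n)
  }
  # 64x64 over a small alphabet, per the canonical example
  X <- matrix(sample(0:3, 4096, replace = TRUE), 64, 64)
  p <- encode_pairs(X)
  oracle <- naive_run_scan(as.vector(t(X)))
  expect_equal(p$values, oracle$values)
  expect_equal(sum(p$counts), 4096)
})

test_that("decode_pairs inverts encode_pairs for assorted dims and orders", {
  p <- pair_sequence(7, 6)
  expect_equal(decode_pairs(p, c(2, 3)), matrix(7, 2, 3))
  set.seed(11)
  for (i in 1:60) {
    m <- sample(1:30, 1); n <- sample(1:30, 1)
    X <- matrix(sample(0:9, m * n, replace = TRUE), m, n)
    for (ord in c("row", "column")) {
      expect_identical(decode_pairs(encode_pairs(X, ord), c(m, n)),
                       matrix(as.numeric(X), m, n))
    }
  }
  expect_error(decode_pairs(pair_sequence(1, 3), c(2, 2)),
               class = "sbpn_corrupt_error")
})

test_that("flatten and unflatten are mutually inverse and order-preserving", {
  p <- pair_sequence(c(3, 9), c(2, 1))
  expect_equal(as.numeric(flatten(p)), c(3, 2, 9, 1))
  set.seed(4)
  for (i in 1:40) {
    np <- sample(1:50, 1)
    vals <- cumsum(sample(c(-3:-1, 1:3), np, replace = TRUE))  # no equal neighbors
    cnts <- sample(1:9, np, replace = TRUE)
    p <- pair_sequence(vals, cnts)
    q <- unflatten(flatten(p))
    expect_equal(q$values, p$values)
    expect_equal(q$counts, p$counts)
  }
  expect_error(unflatten(c(3, 2, 9)), class = "sbpn_corrupt_error")
  expect_error(unflatten(c(3, 0)), class = "sbpn_corrupt_error")
})

test_that("pair sequences enforce maximality, counts and totals", {
  expect_error(pair_sequence(c(4, 4), c(1, 2)), class = "sbpn_argument_error")
  expect_silent(pair_sequence(c(4, 4), c(1, 2), maximal = FALSE))
  expect_error(pair_sequence(3, 0), class = "sbpn_corrupt_error")
  p <- pair_sequence(c(1, 2), c(3, 4))
  expect_equal(p$total, 7)
  expect_lte(length(encode_pairs(random_gray(20, 20, 5))$values), 400)
})

test_that("uniform quantization bounds the reconstruction error by step/2", {
  expect_equal(quantize_plane(matrix(c(0.4, 0.6), 1, 2), 1), matrix(c(0, 1), 1, 2))
  set.seed(8)
  for (step in c(0.25, 0.5, 1, 2.5)) {
    X <- matrix(rnorm(400, sd = 40), 20, 20)
    q <- quantize_plane(X, step)
    expect_true(all(q == floor(q)))
    expect_lte(max(abs(dequantize_plane(q, step) - X)), step / 2 + 1e-12)
  }
  # ties round away from zero
  expect_equal(quantize_plane(matrix(c(0.5, -0.5), 1, 2), 1),
               matrix(c(1, -1), 1, 2))
  # near-zero step recovers an integer plane exactly
  Xi <- matrix(sample(-50:50, 36), 6, 6)
  expect_equal(dequantize_plane(quantize_plane(Xi, 1e-6), 1e-6), Xi,
               tolerance = 1e-9)
  expect_error(quantize_plane(matrix(1, 1, 1), 0), class = "sbpn_argument_error")
  expect_error(dequantize_plane(matrix(1, 1, 1), -1), class = "sbpn_argument_error")
})

test_that("fewer regions means fewer pairs (monotone redundancy payoff)", {
  counts <- sapply(c(0.3, 0.6, 0.9), function(bf) {
    img <- generate_phantom(phantom_spec(dim = c(128, 128),
                                         background_fraction = bf, seed = 6))
    length(encode_pairs(unclass(img))$values)
  })
  expect_true(all(diff(counts) < 0))
})
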