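test_that("a constant image has zero detail and approximate plane 2v", {
  v <- 93
  sb <- decompose(gray_image(matrix(v, 8, 8)), levels = 1, wavelet = "haar")
  for (nm in c("horizontal", "vertical", "diagonal")) {
    expect_equal(max(abs(sb$detail[[1]][[nm]])), 0)
  }
  expect_equal(sb$approx, matrix(2 * v, 4, 4), tolerance = 1e-12)
})

test_that("one-level Haar matches the explicit 2x2 block-transform oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(sample(0:255, 16, replace = TRUE), 4, 4)
    sb <- decompose(gray_image(X), levels = 1, wavelet = "haar")
    oracle <- haar_block_oracle(X)
    expect_equal(sb$approx, oracle$approx, tolerance = 1e-12)
    expect_equal(sb$detail[[1]]$horizontal, oracle$horizontal, tolerance = 1e-12)
    expect_equal(sb$detail[[1]]$vertical, oracle$vertical, tolerance = 1e-12)
    expect_equal(sb$detail[[1]]$diagonal, oracle$diagonal, tolerance = 1e-12)
  }
})

test_that("a horizontal step concentrates energy in one detail orientation", {
  # step between rows 3 and 4 so it falls inside a 2x2 analysis block
  X <- rbind(matrix(0, 3, 8), matrix(200, 5, 8))
  sb <- decompose(gray_image(X), levels = 1, wavelet = "haar")
  expect_gt(sum(sb$detail[[1]]$horizontal^2), 0)
  expect_equal(max(abs(sb$detail[[1]]$vertical)), 0)
  expect_equal(max(abs(sb$detail[[1]]$diagonal)), 0)
})

test_that("decompose/reconstruct is the identity for deep pyramids", {
  img <- random_gray(512, 512, 31)
  sb <- decompose(img, levels = 3, wavelet = "haar")
  expect_lt(max(abs(reconstruct(sb) - unclass(img))), 1e-8)
})

test_that("all-zero subbands reconstruct to an all-zero matrix", {
  sb <- decompose(gray_image(matrix(0L, 8, 8)), levels = 2)
  expect_equal(reconstruct(sb), matrix(0, 8, 8))
})

test_that("odd-sized images round trip exactly after cropping", {
  set.seed(12)
  X <- matrix(sample(0:255, 35, replace = TRUE), 5, 7)
  sb <- decompose(gray_image(X), levels = 1, wavelet = "haar")
  expect_equal(dim(sb$approx), c(3L, 4L))  # ceil(5/2) x ceil(7/2)
  expect_lt(max(abs(reconstruct(sb) - X)), 1e-8)
  # deeper pyramid on odd dims, both wavelets
  for (wav in c("haar", "db2")) {
    Y <- matrix(sample(0:255, 45 * 33, replace = TRUE), 45, 33)
    sb2 <- decompose(gray_image(Y), levels = 3, wavelet = wav)
    expect_lt(max(abs(reconstruct(sb2) - Y)), 1e-8, label = wav)
  }
})

test_that("orthonormal transforms conserve energy on even dims", {
  for (wav in c("haar", "db2")) {
    img <- random_gray(64, 64, 77)
    sb <- decompose(img, levels = 1, wavelet = wav)
    e_sub <- sum(sb$approx^2) + sum(sapply(sb$detail[[1]], function(p) sum(p^2)))
    e_img <- sum(as.numeric(unclass(img))^2)
    expect_equal(e_sub, e_img, tolerance = 1e-6)
  }
})

test_that("decomposition is linear in its input", {
  set.seed(9)
  X <- matrix(rnorm(256), 16, 16)
  Y <- matrix(rnorm(256), 16, 16)
  a <- 2.5; b <- -1.25
  sb_mix <- decompose(a * X + b * Y, levels = 2)
  sb_x <- decompose(X, levels = 2)
  sb_y <- decompose(Y, levels = 2)
  expect_equal(sb_mix$approx, a * sb_x$approx + b * sb_y$approx, tolerance = 1e-8)
  for (l in 1:2) {
    for (nm in c("horizontal", "vertical", "diagonal")) {
      expect_equal(sb_mix$detail[[l]][[nm]],
                   a * sb_x$detail[[l]][[nm]] + b * sb_y$detail[[l]][[nm]],
                   tolerance = 1e-8)
    }
  }
})

test_that("too-deep decompositions report the admissible level", {
  img <- gray_image(matrix(0L, 4, 4))
  expect_error(decompose(img, levels = 3), class = "sbpn_argument_error")
  expect_error(decompose(img, levels = 3), "max admissible level: 2")
  err <- tryCatch(decompose(img, levels = 5), error = identity)
  expect_match(conditionMessage(err), "too deep")
})

test_that("structurally inconsistent subband sets are rejected", {
  sb <- decompose(random_gray(16, 16, 2), levels = 1)
  sb$detail[[1]]$vertical <- sb$detail[[1]]$vertical[1:4, 1:4]
  expect_error(reconstruct(sb), class = "sbpn_shape_error")
})
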