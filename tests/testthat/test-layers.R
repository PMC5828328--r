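test_that("convolve2d implements true convolution (kernel reflected)", {
  # identity and annihilator kernels
  x <- matrix(rnorm(20), 4, 5)
  expect_equal(convolve2d(x, matrix(1)), x)
  expect_equal(convolve2d(x, matrix(0, 3, 3)),
               matrix(0, 2, 3))

  # hand-checkable diagonal kernel, frozen from the brute-force oracle
  input <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3, byrow = TRUE)
  kernel <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  got <- convolve2d(input, kernel, mode = "valid")
  expect_equal(got, matrix(c(6, 8, 12, 14), 2, byrow = TRUE))
  expect_equal(got, oracle_convolve_valid(input, kernel))

  expect_error(convolve2d(matrix(1, 2, 2), matrix(1, 3, 3), "valid"),
               "larger")
  expect_error(convolve2d(matrix(numeric(0), 0, 0), matrix(1)), "non-empty")
})

test_that("convolve2d matches the brute-force double-loop oracle broadly", {
  set.seed(101)
  for (trial in 1:100) {
    h <- sample(2:9, 1)
    w <- sample(2:9, 1)
    kh <- sample(1:min(4, h), 1)
    kw <- sample(1:min(4, w), 1)
    x <- matrix(rnorm(h * w), h, w)
    k <- matrix(rnorm(kh * kw), kh, kw)
    expect_lt(max(abs(convolve2d(x, k, "valid") -
                        oracle_convolve_valid(x, k))), 1e-10)
  }
})

test_that("same-padding convolution preserves dimensions", {
  x <- matrix(rnorm(35), 5, 7)
  k <- matrix(rnorm(9), 3, 3)
  y <- convolve2d(x, k, mode = "same_zero_pad")
  expect_equal(dim(y), dim(x))
  # interior agrees with the valid-mode result
  expect_equal(y[2:4, 2:6], convolve2d(x, k, "valid"))
})

test_that("max pooling takes per-window maxima and k = 1 is the identity", {
  x <- matrix(rnorm(30), 5, 6)
  expect_equal(max_pool(x, k = 1), x)

  x4 <- matrix(c(1, 5, 2, 0,
                 3, 4, 8, 1,
                 0, 2, 1, 7,
                 6, 1, 3, 2), 4, byrow = TRUE)
  got <- max_pool(x4, k = 2, stride = 2)
  # enumerate the four 2x2 blocks
  expected <- matrix(c(max(x4[1:2, 1:2]), max(x4[1:2, 3:4]),
                       max(x4[3:4, 1:2]), max(x4[3:4, 3:4])),
                     2, byrow = TRUE)
  expect_equal(got, expected)

  expect_equal(max_pool(matrix(3, 6, 6), 2), matrix(3, 3, 3))
  expect_error(max_pool(matrix(1, 2, 2), k = 2, stride = 5), "stride")
})

test_that("relu thresholds at zero and is idempotent", {
  expect_equal(relu(c(-1, 0, 2.5)), c(0, 0, 2.5))
  expect_equal(relu(matrix(-abs(rnorm(9)), 3)), matrix(0, 3, 3))
  x <- matrix(abs(rnorm(9)), 3)
  expect_equal(relu(x), x)
  y <- matrix(rnorm(25), 5)
  expect_equal(relu(relu(y)), relu(y))
})

test_that("deconvolution multiplies spatial dims and matches the loop oracle", {
  # factor 1, 1x1 identity kernel: unchanged
  x <- matrix(rnorm(12), 3, 4)
  id <- array(1, c(1, 1, 1, 1))
  expect_equal(deconvolve(x, id, factor = 1), x)

  # factor 2, bilinear kernel on a constant map: doubled dims, constant
  # in the interior (borders attenuate under zero padding)
  const <- matrix(2, 4, 4)
  k <- bilinear_kernel(2, 1)
  y <- deconvolve(const, k, factor = 2)
  expect_equal(dim(y), c(8, 8))
  expect_equal(y[2:7, 2:7], matrix(2, 6, 6))
  # all values, including the border, match the direct loop oracle
  yo <- oracle_deconv(array(const, c(4, 4, 1)), k, stride = 2, pad = 1)
  expect_equal(y, yo[, , 1])

  # random input, random kernel
  set.seed(7)
  x3 <- array(rnorm(3 * 5 * 2), c(3, 5, 2))
  w <- array(rnorm(4 * 4 * 2 * 3), c(4, 4, 2, 3))
  expect_equal(deconvolve(x3, w, factor = 2),
               oracle_deconv(x3, w, stride = 2, pad = 1))

  # upsampling by 2 undoes the dims of a stride-2 pooling
  p <- max_pool(matrix(rnorm(36), 6), 2)
  expect_equal(dim(deconvolve(p, bilinear_kernel(2, 1), 2)), c(6, 6))
  expect_error(deconvolve(x, id, factor = 0), ">= 1")
})

test_that("softmax cross-entropy matches closed forms", {
  # equal logits -> ln(n_cl) exactly
  for (ncl in 2:4) {
    sc <- array(0.7, c(3, 5, ncl))
    lab <- matrix(sample(0:(ncl - 1), 15, TRUE), 3, 5)
    expect_equal(softmax_with_loss(sc, lab), log(ncl))
  }
  # single pixel, logits (2, 0), true class 0 -> ln(1 + e^-2)
  sc <- array(c(2, 0), c(1, 1, 2))
  expect_equal(softmax_with_loss(sc, matrix(0L)), log(1 + exp(-2)))
  # loss -> 0 monotonically as the margin grows
  margins <- c(1, 3, 6, 12)
  losses <- vapply(margins, function(m) {
    sc <- array(0, c(2, 2, 2))
    sc[, , 1] <- m
    softmax_with_loss(sc, matrix(0L, 2, 2))
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_lt(losses[length(losses)], 1e-5)
  # shift invariance: adding a constant to all logits at a pixel
  set.seed(3)
  sc <- array(rnorm(24), c(3, 4, 2))
  lab <- matrix(sample(0:1, 12, TRUE), 3, 4)
  expect_equal(softmax_with_loss(sc, lab), softmax_with_loss(sc + 5, lab))
  expect_error(softmax_with_loss(sc, lab + 5L), "labels")
})

test_that("softmax probabilities sum to one per pixel", {
  set.seed(11)
  sc <- array(rnorm(60), c(4, 5, 3))
  d <- dim(sc)
  m <- matrix(sc, d[1] * d[2], d[3])
  p <- exp(m) / rowSums(exp(m))
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  # gradient identity: rows of (p - onehot)/n recovered from the package
  lab <- matrix(sample(0:2, 20, TRUE), 4, 5)
  g <- vesselfcn:::softmax_loss_grad(sc, lab)$grad
  gm <- matrix(g, d[1] * d[2], d[3])
  onehot <- matrix(0, d[1] * d[2], d[3])
  onehot[cbind(seq_len(20), as.integer(lab) + 1)] <- 1
  expect_equal(gm, (p - onehot) / 20, tolerance = 1e-12)
})

test_that("xavier initialization has the right moments and is seeded", {
  shape <- c(3, 3, 12, 10)  # fan_in = 108
  k <- xavier_init(shape, seed = 42)
  expect_equal(dim(k), shape)
  n <- length(k)  # 10800 draws
  fan_in <- prod(shape[1:3])
  se_mean <- sqrt(1 / fan_in) / sqrt(n)
  expect_lt(abs(mean(k)), 3 * se_mean)
  # variance of uniform(-c, c) is c^2 / 3 = 1 / fan_in
  big <- xavier_init(c(3, 3, 12, 1000), seed = 1)  # ~1e5 draws
  expect_lt(abs(var(as.numeric(big)) - 1 / fan_in) / (1 / fan_in), 0.05)
  expect_true(all(abs(k) <= sqrt(3 / fan_in)))
  expect_identical(xavier_init(shape, 42), k)
  expect_false(identical(xavier_init(shape, 43), k))
})
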