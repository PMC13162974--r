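# Depthwise-separable convolution, adaptive-kernel ECA, channel layer
# norm, and the residual DSConv-ECA block.

test_that("identity kernels make the separable convolution an identity", {
  blk <- wavesam:::with_seed(1, dsconv(3L, 3L, k = 3L))
  # depthwise: centred delta; pointwise: identity; biases zero
  blk$dw$w$value <- matrix(rep(c(0, 0, 0, 0, 1, 0, 0, 0, 0), each = 3), 3, 9)
  blk$dw$b$value <- rep(0, 3)
  blk$pw$w$value <- diag(3)
  blk$pw$b$value <- rep(0, 3)
  x <- rand_array(c(2, 3, 6, 7), 2)
  expect_equal(dsconv_forward(blk, x), x, tolerance = 1e-12)
})

test_that("constant input stays spatially constant away from the border", {
  blk <- wavesam:::with_seed(3, dsconv(3L, 5L, k = 3L))
  x <- array(0.4, c(1, 3, 8, 8))
  y <- dsconv_forward(blk, x)
  interior <- y[1, , 2:7, 2:7]
  for (c in 1:5) expect_lt(diff(range(interior[c, , ])), 1e-12)
  expect_error(dsconv_forward(blk, x[, 1:2, , , drop = FALSE]), "channels")
})

test_that("the closed-form parameter count matches enumerated weights", {
  expect_equal(dsconv_param_count(3, 64), 219)
  expect_equal(dsconv_param_count(1, 1, 1), 2)
  expect_equal(dsconv_param_count(384, 384), 150912)
  # one-ninth compression at C = C' = 384, k = 3
  ratio <- dsconv_param_count(384, 384) / (384 * 384 * 9)
  expect_equal(ratio, 1 / 384 + 1 / 9, tolerance = 1e-12)
  expect_equal(ratio, 1 / 9, tolerance = 0.03)
  set.seed(4)
  for (i in 1:50) {
    C <- sample(1:64, 1); Cp <- sample(1:64, 1); k <- sample(c(1, 3, 5, 7), 1)
    blk <- dsconv(C, Cp, k)
    enumerated <- length(blk$dw$w$value) + length(blk$pw$w$value)
    expect_equal(dsconv_param_count(C, Cp, k), enumerated)
  }
})

test_that("adaptive ECA kernel sizes match direct evaluation of the rule", {
  expect_identical(eca_kernel_size(384), 5L)
  expect_identical(eca_kernel_size(64), 3L)
  expect_identical(eca_kernel_size(2), 1L)
  expect_identical(eca_kernel_size(1), 1L)
  expect_error(eca_kernel_size(0), "positive")
  ks <- vapply(1:2048, eca_kernel_size, integer(1))
  expect_true(all(ks %% 2L == 1L))
  expect_true(all(diff(ks) >= 0L))
  # independent oracle: truncate toward zero, then force odd
  oracle <- function(C) { t <- (log2(C) + 1) / 2; k <- trunc(t)
    if (k %% 2 == 0) k <- k + 1; max(k, 1) }
  expect_equal(ks, vapply(1:2048, oracle, numeric(1)))
})

test_that("ECA gates channels multiplicatively within (0,1)", {
  blk <- wavesam:::with_seed(5, eca(16L))
  x <- abs(rand_array(c(2, 16, 5, 5), 6))
  y <- eca_forward(blk, x)
  expect_equal(dim(y), dim(x))
  expect_true(all(y >= 0 & y <= x))
  blk$conv$w$value <- blk$conv$w$value * 0
  blk$conv$b$value <- 0
  expect_equal(eca_forward(blk, x), x / 2, tolerance = 1e-12)
  expect_error(eca_forward(blk, x[, 1:8, , , drop = FALSE]), "channels")
})

test_that("channel-wise 2-D layer norm standardises every position", {
  x <- rand_array(c(2, 8, 4, 4), 7)
  y <- layer_norm_2d(x)
  for (b in 1:2) for (i in 1:4) for (j in 1:4) {
    v <- y[b, , i, j]
    expect_lt(abs(mean(v)), 1e-9)
    expect_equal(mean(v^2), 1, tolerance = 1e-3)   # eps-deflated variance
  }
  # constant across channels -> zeros; channel-shift invariance
  const <- array(rep(rand_array(c(2, 1, 4, 4), 8), times = 8), c(2, 8, 4, 4))
  xc <- x
  for (c in 1:8) xc[, c, , ] <- x[, c, , ] + 3.21
  expect_equal(layer_norm_2d(xc), y, tolerance = 1e-9)
  const2 <- array(0.3, c(1, 4, 3, 3))
  expect_equal(layer_norm_2d(const2), array(0, c(1, 4, 3, 3)), tolerance = 1e-9)
})

test_that("the residual block reduces to the identity with a dead main path", {
  blk <- wavesam:::with_seed(9, dsconv_eca_block(6L, 6L))
  blk$pw$w$value <- blk$pw$w$value * 0
  blk$pw$b$value <- blk$pw$b$value * 0
  blk$bn2$beta$value <- blk$bn2$beta$value * 0
  x <- rand_array(c(2, 6, 5, 5), 10)
  expect_equal(dsconv_eca_forward(blk, x), x, tolerance = 1e-12)
})

test_that("block channel expansion and parameter budget", {
  blk <- dsconv_eca_block(3L, 64L)
  y <- dsconv_eca_forward(blk, rand_array(c(1, 3, 8, 8), 11))
  expect_equal(dim(y), c(1, 64, 8, 8))
  p384 <- wavesam:::n_params(dsconv_eca_block(384L, 384L))
  expect_gte(p384, 150912)
  expect_lte(p384, 165000)
  for (cfg in list(c(3, 8), c(8, 8), c(16, 4))) {
    b <- dsconv_eca_block(cfg[1], cfg[2])
    y <- dsconv_eca_forward(b, rand_array(c(1, cfg[1], 6, 6), 12))
    expect_equal(dim(y)[3:4], c(6, 6))
  }
})
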