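# The autodiff core is validated against central finite differences:
# every fused backward (convolutions, attention, normalisations, losses)
# must reproduce the numerical derivative.

ag <- function(x, rg = FALSE) wavesam:::ag_tensor(x, requires_grad = rg)

test_that("convolution gradients match finite differences", {
  set.seed(2)
  w <- ag(matrix(rnorm(4 * 18), 4, 18), rg = TRUE)
  b <- ag(rnorm(4), rg = TRUE)
  cst <- rand_array(c(2, 4, 5, 5), seed = 7)
  f <- function(xt) wavesam:::ag_sum(wavesam:::ag_mul(
    wavesam:::ag_conv2d(xt, w, b, k = 3L, stride = 1L, pad = 1L), ag(cst)))
  expect_lt(fd_gradient_error(f, rand_array(c(2, 2, 5, 5), 3)), 1e-6)

  wd <- ag(matrix(rnorm(3 * 9), 3, 9), rg = TRUE)
  cst2 <- rand_array(c(2, 3, 4, 4), seed = 8)
  fd <- function(xt) wavesam:::ag_sum(wavesam:::ag_mul(
    wavesam:::ag_conv2d(xt, wd, NULL, k = 3L, stride = 1L, pad = 1L,
                        groups = 3L), ag(cst2)))
  expect_lt(fd_gradient_error(fd, rand_array(c(2, 3, 4, 4), 4)), 1e-6)

  wt <- ag(matrix(rnorm(3 * 8), 3, 8), rg = TRUE)
  bt <- ag(rnorm(2), rg = TRUE)
  cst3 <- rand_array(c(2, 2, 6, 6), seed = 9)
  ft <- function(xt) wavesam:::ag_sum(wavesam:::ag_mul(
    wavesam:::ag_tconv2x2(xt, wt, bt), ag(cst3)))
  expect_lt(fd_gradient_error(ft, rand_array(c(2, 3, 3, 3), 5)), 1e-6)
})

test_that("attention and normalisation gradients match finite differences", {
  set.seed(11)
  qkvw <- ag(matrix(rnorm(6 * 18) * 0.3, 6, 18), rg = TRUE)
  fm <- function(xt) {
    q <- wavesam:::ag_linear(wavesam:::ag_reshape(xt, c(10, 6)), qkvw)
    o <- wavesam:::ag_mha(q, 2L, 5L, 2L)
    wavesam:::ag_sum(wavesam:::ag_mul(o, o))
  }
  expect_lt(fd_gradient_error(fm, rand_array(c(10, 6), 6)), 1e-6)

  g <- ag(rnorm(3), rg = TRUE); b <- ag(rnorm(3), rg = TRUE)
  cst <- rand_array(c(2, 3, 4, 4), seed = 12)
  fln <- function(xt) wavesam:::ag_sum(wavesam:::ag_mul(
    wavesam:::ag_layernorm2d(xt, g, b), ag(cst)))
  expect_lt(fd_gradient_error(fln, rand_array(c(2, 3, 4, 4), 7)), 1e-6)

  buf <- new.env(); buf$running_mean <- rep(0, 3); buf$running_var <- rep(1, 3)
  fbn <- function(xt) {
    buf$running_mean <- rep(0, 3); buf$running_var <- rep(1, 3)
    wavesam:::ag_sum(wavesam:::ag_mul(
      wavesam:::ag_batchnorm2d(xt, g, b, buf, TRUE), ag(cst)))
  }
  expect_lt(fd_gradient_error(fbn, rand_array(c(2, 3, 4, 4), 8)), 1e-6)
})

test_that("loss gradients match finite differences", {
  set.seed(13)
  tg <- array(rbinom(72, 1, 0.3), c(2, 1, 6, 6))
  fb <- function(xt) wavesam:::ag_composite_loss(xt, tg)
  expect_lt(fd_gradient_error(fb, rand_array(c(2, 1, 6, 6), 9)), 1e-6)
})

test_that("a gradient signal reaches the input of each enhancement block", {
  wtca <- wavesam:::with_seed(7, wtca_block(3L))
  x <- rand_array(c(1, 3, 8, 8), 10)
  xt <- ag(x, rg = TRUE)
  out <- wavesam:::ag_wtca_forward(wtca, xt)
  wavesam:::ag_backward(wavesam:::ag_sum(wavesam:::ag_mul(out, out)))
  expect_true(all(is.finite(xt$grad)))
  expect_gt(max(abs(xt$grad)), 0)

  blk <- wavesam:::with_seed(8, dsconv_eca_block(4L, 4L))
  xt2 <- ag(rand_array(c(2, 4, 6, 6), 11), rg = TRUE)
  out2 <- wavesam:::ag_dsconv_eca_forward(blk, xt2)
  wavesam:::ag_backward(wavesam:::ag_sum(wavesam:::ag_mul(out2, out2)))
  expect_true(all(is.finite(xt2$grad)))
  expect_gt(max(abs(xt2$grad)), 0)

  # gradient passes through the residual even when the main branch is dead
  wavesam:::zero_params(blk)
  xt3 <- ag(rand_array(c(1, 4, 6, 6), 12), rg = TRUE)
  out3 <- wavesam:::ag_dsconv_eca_forward(blk, xt3)
  wavesam:::ag_backward(wavesam:::ag_sum(out3))
  expect_gt(max(abs(xt3$grad)), 0.5)
})
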