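# Depthwise-separable convolution, efficient channel attention (ECA) with
# an adaptive 1-D kernel, channel-wise 2-D layer normalisation, and the
# residual DSConv-ECA block.

#' Parameter count of a depthwise-separable convolution
#'
#' Weight elements of a depthwise k x k convolution followed by a 1x1
#' pointwise convolution: `C*k^2 + C*C'`. Biases are reported separately
#' by the budget functions. Relative to a standard convolution the ratio
#' is `1/C' + 1/k^2`, about one-ninth for k = 3 and large `C'`.
#'
#' @param in_channels C, input channels.
#' @param out_channels C', output channels of the pointwise stage.
#' @param k depthwise kernel size (odd; default 3).
#' @return integer weight count.
#' @examples
#' dsconv_param_count(3, 64)        # 219
#' dsconv_param_count(384, 384)     # 150912
#' @export
dsconv_param_count <- function(in_channels, out_channels, k = 3L) {
  stopifnot(in_channels >= 1L, out_channels >= 1L, k %% 2L == 1L)
  in_channels * k^2 + in_channels * out_channels
}

#' Construct a depthwise-separable convolution
#'
#' A per-channel spatial k x k convolution (one filter per input channel)
#' followed by a 1x1 pointwise convolution mixing channels; padding
#' `(k-1)/2` preserves the spatial size.
#'
#' @inheritParams dsconv_param_count
#' @return a `ws_module`.
#' @export
dsconv <- function(in_channels, out_channels, k = 3L) {
  stopifnot(k %% 2L == 1L)
  ws_module(
    "dsconv",
    cfg = list(cin = in_channels, cout = out_channels, k = k),
    dw = nn_conv2d(in_channels, in_channels, k, stride = 1L,
                   pad = (k - 1L) %/% 2L, groups = in_channels),
    pw = nn_conv1x1(in_channels, out_channels)
  )
}

ag_dsconv_forward <- function(block, x) {
  if (dim(x$value)[2] != block$cfg$cin)
    stop("input has ", dim(x$value)[2], " channels; block expects ", block$cfg$cin)
  fw_conv1x1(block$pw, fw_conv2d(block$dw, x))
}

#' Forward pass of a depthwise-separable convolution
#'
#' @param block a module from [dsconv()].
#' @param x feature map `[batch, C, H, W]`.
#' @return feature map `[batch, C', H, W]`.
#' @export
dsconv_forward <- function(block, x) {
  ag_dsconv_forward(block, ag_tensor(x))$value
}

#' Adaptive ECA kernel size
#'
#' `k = |(log2(C) + b) / gamma|_odd`: the magnitude is truncated toward
#' zero and incremented by one when even, so k is always odd and at least
#' 1. Non-decreasing in the channel count.
#'
#' @param C_out channel count (>= 1).
#' @param gamma,b integers of the adaptive rule (defaults 2 and 1).
#' @return odd integer kernel size.
#' @examples
#' eca_kernel_size(384)  # 5
#' eca_kernel_size(64)   # 3
#' eca_kernel_size(2)    # 1
#' @export
eca_kernel_size <- function(C_out, gamma = 2L, b = 1L) {
  if (C_out < 1L) stop("C_out must be a positive integer")
  t <- (log2(C_out) + b) / gamma
  k <- trunc(t)
  if (k %% 2L == 0L) k <- k + 1L
  as.integer(max(k, 1L))
}

#' Construct an efficient channel attention (ECA) module
#'
#' Channel gating from a 1-D convolution across the vector of per-channel
#' spatial means, with kernel size set by [eca_kernel_size()]; avoids the
#' dimension-reducing dense layers of squeeze-excitation attention.
#'
#' @param channels channel count the module gates.
#' @param gamma,b adaptive-kernel constants (defaults 2 and 1).
#' @return a `ws_module`.
#' @export
eca <- function(channels, gamma = 2L, b = 1L) {
  k <- eca_kernel_size(channels, gamma, b)
  ws_module("eca", cfg = list(channels = channels, k = k),
            conv = nn_conv1d(k))
}

ag_eca_forward <- function(block, x) {
  if (dim(x$value)[2] != block$cfg$channels)
    stop("input has ", dim(x$value)[2], " channels; ECA expects ",
         block$cfg$channels)
  z <- ag_gap(x)                       # [B, C]
  a <- ag_sigmoid(fw_conv1d(block$conv, z))
  ag_scale_channels(x, a)
}

#' Forward pass of efficient channel attention
#'
#' @param block a module from [eca()].
#' @param x feature map `[batch, C, H, W]`.
#' @return gated feature map of the same shape.
#' @export
eca_forward <- function(block, x) {
  ag_eca_forward(block, ag_tensor(x))$value
}

#' Channel-wise 2-D layer normalisation
#'
#' At every spatial position, subtracts the across-channel mean and divides
#' by the across-channel standard deviation (variance stabilised by `eps`),
#' then applies an optional per-channel affine transform.
#'
#' @param x feature map `[batch, C, H, W]`.
#' @param gamma,beta per-channel affine parameters (default identity).
#' @param eps variance floor (default 1e-5).
#' @return normalised array of the same shape.
#' @export
layer_norm_2d <- function(x, gamma = NULL, beta = NULL, eps = 1e-5) {
  C <- dim(x)[2]
  if (is.null(gamma)) gamma <- rep(1, C)
  if (is.null(beta)) beta <- rep(0, C)
  ag_layernorm2d(ag_tensor(x), ag_tensor(gamma), ag_tensor(beta), eps)$value
}

#' Construct a residual DSConv-ECA block
#'
#' Main path: depthwise conv, batch norm, GELU, pointwise conv, batch
#' norm, ECA. Residual path: identity when the channel counts match,
#' otherwise a 1x1 convolution. The output is their sum.
#'
#' @inheritParams dsconv_param_count
#' @param gamma,b ECA adaptive-kernel constants.
#' @return a `ws_module`.
#' @export
dsconv_eca_block <- function(in_channels, out_channels, k = 3L,
                             gamma = 2L, b = 1L) {
  ws_module(
    "dsconv_eca",
    cfg = list(cin = in_channels, cout = out_channels, k = k),
    dw = nn_conv2d(in_channels, in_channels, k, stride = 1L,
                   pad = (k - 1L) %/% 2L, groups = in_channels),
    bn1 = nn_batchnorm2d(in_channels),
    pw = nn_conv1x1(in_channels, out_channels),
    bn2 = nn_batchnorm2d(out_channels),
    att = eca(out_channels, gamma, b),
    residual = if (out_channels != in_channels)
      nn_conv1x1(in_channels, out_channels) else NULL
  )
}

ag_dsconv_eca_forward <- function(block, x, training = FALSE) {
  h <- fw_conv2d(block$dw, x)
  h <- fw_batchnorm2d(block$bn1, h, training)
  h <- ag_gelu(h)
  h <- fw_conv1x1(block$pw, h)
  h <- fw_batchnorm2d(block$bn2, h, training)
  h <- ag_eca_forward(block$att, h)
  res <- if (is.null(block$residual)) x else fw_conv1x1(block$residual, x)
  ag_add(res, h)
}

#' Forward pass of the residual DSConv-ECA block
#'
#' @param block a module from [dsconv_eca_block()].
#' @param x feature map `[batch, C, H, W]`.
#' @param training logical; batch-statistics mode for the batch norms.
#' @return feature map `[batch, C', H, W]`.
#' @export
dsconv_eca_forward <- function(block, x, training = FALSE) {
  ag_dsconv_eca_forward(block, ag_tensor(x), training)$value
}
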