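# Haar wavelet decomposition and the wavelet-transform channel-cooperative
# attention (WTCA) block.
#
# The 2-D Haar DWT uses the orthonormal convention (1/sqrt(2) per 1-D
# filter, net 1/2 in 2-D), so energy is conserved and the transform's
# adjoint equals its inverse -- which also gives the backward pass for
# free. Subbands are stacked blocked by band: [LL_1..LL_C, LH.., HL.., HH..],
# where LH carries horizontal detail and HL vertical detail.

check_even_dims <- function(x) {
  d <- dim(x)
  if (length(d) != 4L) stop("expected a [batch, channels, height, width] array")
  if (d[3] %% 2L != 0L) stop("height (", d[3], ") must be even for the Haar DWT")
  if (d[4] %% 2L != 0L) stop("width (", d[4], ") must be even for the Haar DWT")
  invisible(d)
}

haar_dwt2_core <- function(x) {
  d <- dim(x)
  B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  oy <- seq(1L, H, by = 2L); ey <- oy + 1L
  ox <- seq(1L, W, by = 2L); ex <- ox + 1L
  a <- x[, , oy, ox, drop = FALSE]
  b <- x[, , oy, ex, drop = FALSE]
  cc <- x[, , ey, ox, drop = FALSE]
  dd <- x[, , ey, ex, drop = FALSE]
  out <- array(0, c(B, 4L * C, H %/% 2L, W %/% 2L))
  out[, seq_len(C), , ] <- (a + b + cc + dd) / 2            # LL
  out[, C + seq_len(C), , ] <- (a - b + cc - dd) / 2        # LH
  out[, 2L * C + seq_len(C), , ] <- (a + b - cc - dd) / 2   # HL
  out[, 3L * C + seq_len(C), , ] <- (a - b - cc + dd) / 2   # HH
  out
}

haar_idwt2_core <- function(s) {
  d <- dim(s)
  B <- d[1]; C4 <- d[2]; Hh <- d[3]; Wh <- d[4]
  C <- C4 %/% 4L
  LL <- s[, seq_len(C), , , drop = FALSE]
  LH <- s[, C + seq_len(C), , , drop = FALSE]
  HL <- s[, 2L * C + seq_len(C), , , drop = FALSE]
  HH <- s[, 3L * C + seq_len(C), , , drop = FALSE]
  out <- array(0, c(B, C, 2L * Hh, 2L * Wh))
  oy <- seq(1L, 2L * Hh, by = 2L); ox <- seq(1L, 2L * Wh, by = 2L)
  out[, , oy, ox] <- (LL + LH + HL + HH) / 2
  out[, , oy, ox + 1L] <- (LL - LH + HL - HH) / 2
  out[, , oy + 1L, ox] <- (LL + LH - HL - HH) / 2
  out[, , oy + 1L, ox + 1L] <- (LL - LH - HL + HH) / 2
  out
}

#' Single-level 2-D Haar discrete wavelet transform
#'
#' Decomposes each channel of an image batch into four half-resolution
#' subbands under the orthonormal Haar convention: every non-overlapping
#' 2x2 block `[[a, b], [c, d]]` maps to `LL = (a+b+c+d)/2`,
#' `LH = (a-b+c-d)/2`, `HL = (a+b-c-d)/2`, `HH = (a-b-c+d)/2`, so the sum
#' of squared coefficients equals the sum of squared pixels.
#'
#' @param x numeric array `[batch, channels, height, width]`; height and
#'   width must be even.
#' @return numeric array `[batch, 4*channels, height/2, width/2]` with
#'   channels blocked by band: all LL first, then LH (horizontal detail),
#'   HL (vertical detail), HH (diagonal detail).
#' @examples
#' x <- array(c(1, 3, 2, 4), c(1, 1, 2, 2))  # [[1,2],[3,4]]
#' haar_dwt2(x)[1, , 1, 1]  # LL = 5, LH = -1, HL = -2, HH = 0
#' @seealso [haar_idwt2()] for the exact inverse.
#' @export
haar_dwt2 <- function(x) {
  check_even_dims(x)
  haar_dwt2_core(x)
}

#' Inverse 2-D Haar wavelet transform
#'
#' Exact inverse of [haar_dwt2()]: `haar_idwt2(haar_dwt2(x))` reproduces
#' `x` to machine precision.
#'
#' @param s numeric array `[batch, 4*channels, h, w]`; the channel count
#'   must be divisible by 4, bands blocked as produced by [haar_dwt2()].
#' @return numeric array `[batch, channels, 2h, 2w]`.
#' @export
haar_idwt2 <- function(s) {
  d <- dim(s)
  if (length(d) != 4L) stop("expected a [batch, channels, height, width] array")
  if (d[2] %% 4L != 0L)
    stop("channel count (", d[2], ") must be divisible by 4 (LL/LH/HL/HH blocks)")
  haar_idwt2_core(s)
}

# Differentiable wrappers: the orthonormal transform's adjoint is its inverse.
ag_haar_dwt2 <- function(x) {
  check_even_dims(x$value)
  ag_op(haar_dwt2_core(x$value), list(x), function(g) list(haar_idwt2_core(g)))
}

ag_haar_idwt2 <- function(s) {
  ag_op(haar_idwt2_core(s$value), list(s), function(g) list(haar_dwt2_core(g)))
}

# ---- WTCA block -----------------------------------------------------------

#' Construct a wavelet channel-cooperative attention (WTCA) block
#'
#' The block decomposes its input with a Haar DWT, runs a feature branch
#' (1x1 conv, GELU, batch norm, GELU) and a squeeze-style attention branch
#' (global mean, 1x1 conv to `max(ceiling(4C/r), 1)` hidden channels, GELU,
#' batch norm, 1x1 conv back, sigmoid) over the 4C subband channels,
#' recalibrates the feature branch with the attention weights, fuses with a
#' 1x1 convolution, restores the spatial size with a factor-2 pixel
#' shuffle, and adds a residual branch (identity, or a 1x1 convolution when
#' the channel counts differ).
#'
#' @param in_channels number of input image channels C.
#' @param r channel-reduction ratio of the attention bottleneck (default 16).
#' @param out_channels output channels (default `in_channels`; a 1x1
#'   residual projection is added when different).
#' @return a `ws_module` holding the block parameters.
#' @export
wtca_block <- function(in_channels, r = 16L, out_channels = in_channels) {
  C4 <- 4L * in_channels
  hidden <- max(ceiling(C4 / r), 1L)
  ws_module(
    "wtca",
    cfg = list(in_channels = in_channels, r = r, hidden = hidden,
               out_channels = out_channels),
    feature = nn_conv1x1(C4, C4),
    feature_bn = nn_batchnorm2d(C4),
    att_fc1 = nn_conv1x1(C4, hidden),
    att_bn = nn_batchnorm2d(hidden),
    att_fc2 = nn_conv1x1(hidden, C4),
    fusion = nn_conv1x1(C4, 4L * out_channels),
    residual = if (out_channels != in_channels)
      nn_conv1x1(in_channels, out_channels) else NULL
  )
}

ag_wtca_attention <- function(block, s, training = FALSE) {
  C4 <- 4L * block$cfg$in_channels
  if (dim(s$value)[2] != C4)
    stop("subband stack has ", dim(s$value)[2], " channels; block expects ", C4)
  z <- ag_gap(s)                                   # [B, 4C]
  z <- ag_reshape(z, c(dim(s$value)[1], C4, 1L, 1L))
  h <- fw_conv1x1(block$att_fc1, z)
  h <- ag_gelu(h)
  h <- fw_batchnorm2d(block$att_bn, h, training)
  a <- fw_conv1x1(block$att_fc2, h)
  ag_sigmoid(a)                                    # [B, 4C, 1, 1]
}

#' Channel-attention weights of a WTCA block
#'
#' Computes the per-subband-channel attention vector from the spatial
#' global mean of a subband stack. Entries lie strictly in (0, 1).
#'
#' @param block a module from [wtca_block()].
#' @param s subband stack `[batch, 4C, h, w]` (see [haar_dwt2()]).
#' @param training logical; use batch statistics in the batch norm?
#' @return numeric array `[batch, 4C, 1, 1]`.
#' @export
wtca_attention <- function(block, s, training = FALSE) {
  ag_wtca_attention(block, ag_tensor(s), training)$value
}

ag_wtca_forward <- function(block, x, training = FALSE) {
  s <- ag_haar_dwt2(x)
  f <- fw_conv1x1(block$feature, s)
  f <- ag_gelu(f)
  f <- fw_batchnorm2d(block$feature_bn, f, training)
  f <- ag_gelu(f)
  a <- ag_wtca_attention(block, s, training)
  d <- dim(a$value)
  cw <- ag_reshape(a, d[1:2])
  recal <- ag_scale_channels(f, cw)
  fused <- fw_conv1x1(block$fusion, recal)
  y <- ag_pixel_shuffle(fused, 2L)
  res <- if (is.null(block$residual)) x else fw_conv1x1(block$residual, x)
  ag_add(y, res)
}

#' Forward pass of a WTCA block
#'
#' @param block a module from [wtca_block()].
#' @param x image batch `[batch, C, H, W]` with even spatial dimensions.
#' @param training logical; batch-statistics mode for the batch norms.
#' @return numeric array of the same shape as `x` (or with
#'   `out_channels` channels when the block projects).
#' @export
wtca_forward <- function(block, x, training = FALSE) {
  ag_wtca_forward(block, ag_tensor(x), training)$value
}
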