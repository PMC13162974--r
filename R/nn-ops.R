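# Differentiable network operators built on the autodiff core.
#
# Feature maps are [B, C, H, W] arrays. Token sequences are matrices
# [B*N, d] with batch-major rows (row = (b-1)*N + n). Convolution weights
# are stored as matrices: a k x k conv with Cin inputs per group is
# [Cout, Cin_g*k*k] with column order (c, ky, kx), kx fastest; 1x1 and
# transposed 2x2 convolutions are [Cin, Cout] / [Cin, 4*Cout].

.ws_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  v <- .ws_cache[[key]]
  if (is.null(v)) {
    v <- build()
    .ws_cache[[key]] <- v
  }
  v
}

# im2col gather index over a zero-padded single-image layout (Hp, Wp, Cg),
# plus output geometry. Column l = (oy-1)*Wo + ox (ox fastest).
im2col_index <- function(H, W, Cg, k, stride, pad) {
  key <- paste("i2c", H, W, Cg, k, stride, pad, sep = "_")
  cache_get(key, function() {
    Hp <- H + 2L * pad; Wp <- W + 2L * pad
    Ho <- (Hp - k) %/% stride + 1L
    Wo <- (Wp - k) %/% stride + 1L
    oy <- rep(seq_len(Ho), each = Wo)
    ox <- rep(seq_len(Wo), times = Ho)
    y0 <- (oy - 1L) * stride   # top-left (0-based) of each window
    x0 <- (ox - 1L) * stride
    L <- Ho * Wo
    rows <- Cg * k * k
    IDX <- matrix(0L, rows, L)
    r <- 0L
    for (c in seq_len(Cg)) {
      coff <- (c - 1L) * Hp * Wp
      for (ky in seq_len(k)) for (kx in seq_len(k)) {
        r <- r + 1L
        IDX[r, ] <- coff + (y0 + ky) + (x0 + kx - 1L) * Hp
      }
    }
    list(IDX = IDX, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp, L = L,
         overlap = stride < k)
  })
}

pad_hwcb <- function(x_bchw, pad) {
  d <- dim(x_bchw)  # B C H W
  xh <- aperm(x_bchw, c(3, 4, 2, 1))  # H W C B
  if (pad == 0L) return(xh)
  out <- array(0, c(d[3] + 2L * pad, d[4] + 2L * pad, d[2], d[1]))
  out[pad + seq_len(d[3]), pad + seq_len(d[4]), , ] <- xh
  out
}

#' General 2-D convolution (differentiable)
#'
#' @param x `ag_tensor` feature map `[B, C, H, W]`.
#' @param w `ag_tensor` weight matrix `[Cout, (C/groups)*k*k]`.
#' @param b `ag_tensor` bias `[Cout]` or `NULL`.
#' @param k,stride,pad,groups convolution geometry; `k` odd or `k == stride`.
#' @keywords internal
ag_conv2d <- function(x, w, b = NULL, k, stride = 1L, pad = 0L, groups = 1L) {
  d <- dim(x$value)
  B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  stopifnot(C %% groups == 0L)
  Cg <- C %/% groups
  Cout <- nrow(w$value)
  stopifnot(Cout %% groups == 0L)
  Cog <- Cout %/% groups
  ii <- im2col_index(H, W, Cg, k, stride, pad)
  Hp <- ii$Hp; Wp <- ii$Wp; Ho <- ii$Ho; Wo <- ii$Wo; L <- ii$L
  xp <- pad_hwcb(x$value, pad)          # Hp Wp C B
  plane <- Hp * Wp
  boff <- (seq_len(B) - 1L) * plane * C
  wv <- w$value
  out <- array(0, c(Cout, Wo, Ho, B))
  cols_g <- vector("list", groups)
  for (g in seq_len(groups)) {
    goff <- (g - 1L) * Cg * plane
    idx_full <- as.integer(outer(as.vector(ii$IDX), boff + goff, `+`))
    cols <- matrix(xp[idx_full], Cg * k * k, L * B)
    cols_g[[g]] <- cols
    rows_o <- (g - 1L) * Cog + seq_len(Cog)
    y <- wv[rows_o, , drop = FALSE] %*% cols    # [Cog, L*B]
    dim(y) <- c(Cog, Wo, Ho, B)
    out[rows_o, , , ] <- y
  }
  out <- aperm(out, c(4, 1, 3, 2))             # B Cout Ho Wo
  parents <- list(x, w)
  if (!is.null(b)) parents <- c(parents, list(b))
  node <- ag_op(out, parents, function(g) {
    gp <- aperm(g, c(2, 4, 3, 1))              # Cout Wo Ho B
    dim(gp) <- c(Cout, L * B)
    dw <- matrix(0, nrow(wv), ncol(wv))
    dxp <- numeric(plane * C * B)
    for (gg in seq_len(groups)) {
      goff <- (gg - 1L) * Cg * plane
      rows_o <- (gg - 1L) * Cog + seq_len(Cog)
      g2 <- gp[rows_o, , drop = FALSE]
      dw[rows_o, ] <- g2 %*% t(cols_g[[gg]])
      dcols <- t(wv[rows_o, , drop = FALSE]) %*% g2
      idx_full <- as.integer(outer(as.vector(ii$IDX), boff + goff, `+`))
      if (ii$overlap) {
        s <- rowsum(as.vector(dcols), group = idx_full)
        dxp[as.integer(rownames(s))] <- dxp[as.integer(rownames(s))] + s
      } else {
        dxp[idx_full] <- dxp[idx_full] + as.vector(dcols)
      }
    }
    dim(dxp) <- c(Hp, Wp, C, B)
    dx <- dxp[pad + seq_len(H), pad + seq_len(W), , , drop = FALSE]
    dx <- aperm(dx, c(4, 3, 1, 2))
    gs <- list(dx, dw)
    if (!is.null(b)) {
      gb <- rowSums(matrix(aperm(g, c(2, 1, 3, 4)), Cout, B * Ho * Wo))
      gs <- c(gs, list(gb))
    }
    gs
  })
  node
}

# 1x1 convolution via matrix product; w is [Cin, Cout].
ag_conv1x1 <- function(x, w, b = NULL) {
  d <- dim(x$value)
  m <- ag_reshape(ag_aperm(x, c(1, 3, 4, 2)), c(d[1] * d[3] * d[4], d[2]))
  y <- ag_linear(m, w, b)
  ag_aperm(ag_reshape(y, c(d[1], d[3], d[4], ncol(w$value))), c(1, 4, 2, 3))
}

# Pixel shuffle, upscale r: [B, r^2*C, H, W] -> [B, C, rH, rW].
# Input channel (c-1)*r^2 + dy*r + dx + 1 lands at offset (dy, dx).
pixel_shuffle_index <- function(B, C4, H, W, r) {
  key <- paste("ps", B, C4, H, W, r, sep = "_")
  cache_get(key, function() {
    C <- C4 %/% (r * r)
    Ho <- H * r; Wo <- W * r
    # out linear index order: b, c, y2, x2 (b fastest)
    grid <- expand.grid(b = seq_len(B), c = seq_len(C),
                        y2 = seq_len(Ho), x2 = seq_len(Wo))
    y <- (grid$y2 - 1L) %/% r + 1L; dy <- (grid$y2 - 1L) %% r
    x <- (grid$x2 - 1L) %/% r + 1L; dx <- (grid$x2 - 1L) %% r
    u <- (grid$c - 1L) * r * r + dy * r + dx + 1L
    idx <- grid$b + (u - 1L) * B + (y - 1L) * B * C4 + (x - 1L) * B * C4 * H
    list(idx = as.integer(idx), out_dim = c(B, C, Ho, Wo))
  })
}

ag_pixel_shuffle <- function(x, r = 2L) {
  d <- dim(x$value)
  ps <- pixel_shuffle_index(d[1], d[2], d[3], d[4], r)
  ag_permute_index(x, ps$idx, ps$out_dim)
}

# Transposed convolution, kernel 2, stride 2 (as matmul + pixel shuffle).
# w is [Cin, 4*Cout] with column order (c_out, dy, dx), dx fastest.
ag_tconv2x2 <- function(x, w, b = NULL) {
  y <- ag_conv1x1(x, w, NULL)
  y <- ag_pixel_shuffle(y, 2L)
  if (!is.null(b)) y <- ag_add_channel_bias(y, b)
  y
}

# ---- normalisation --------------------------------------------------------

# Row-wise layer norm on [M, d] with per-column affine.
ag_layernorm_rows <- function(x, gamma, beta, eps = 1e-5) {
  xv <- x$value
  M <- nrow(xv); dd <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  v <- rowMeans(xc * xc)
  invstd <- 1 / sqrt(v + eps)
  xhat <- xc * invstd
  gv <- gamma$value; bv <- beta$value
  y <- sweep(xhat, 2, gv, `*`)
  y <- sweep(y, 2, bv, `+`)
  ag_op(y, list(x, gamma, beta), function(g) {
    dxhat <- sweep(g, 2, gv, `*`)
    t1 <- rowMeans(dxhat)
    t2 <- rowMeans(dxhat * xhat)
    dx <- (dxhat - t1 - xhat * t2) * invstd
    list(dx, colSums(g * xhat), colSums(g))
  })
}

# Channel-wise 2-D layer norm: normalise across C at each (b, y, x).
ag_layernorm2d <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x$value)
  m <- ag_reshape(ag_aperm(x, c(1, 3, 4, 2)), c(d[1] * d[3] * d[4], d[2]))
  y <- ag_layernorm_rows(m, gamma, beta, eps)
  ag_aperm(ag_reshape(y, c(d[1], d[3], d[4], d[2])), c(1, 4, 2, 3))
}

# Column-wise batch norm on [n, C]; buffers env holds running_mean/var.
ag_bn_cols <- function(x, gamma, beta, buffers, training,
                       momentum = 0.1, eps = 1e-5) {
  xv <- x$value
  n <- nrow(xv)
  gv <- gamma$value; bv <- beta$value
  if (training) {
    mu <- colMeans(xv)
    xc <- sweep(xv, 2, mu)
    v <- colMeans(xc * xc)
    if (n > 1) {
      buffers$running_mean <- (1 - momentum) * buffers$running_mean + momentum * mu
      buffers$running_var <- (1 - momentum) * buffers$running_var +
        momentum * v * n / (n - 1)
    }
    invstd <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2, invstd, `*`)
    y <- sweep(sweep(xhat, 2, gv, `*`), 2, bv, `+`)
    ag_op(y, list(x, gamma, beta), function(g) {
      dxhat <- sweep(g, 2, gv, `*`)
      t1 <- colMeans(dxhat)
      t2 <- colMeans(dxhat * xhat)
      # dx = invstd * (dxhat - mean(dxhat) - xhat * mean(dxhat*xhat))
      dx <- sweep(dxhat, 2, t1)
      dx <- dx - sweep(xhat, 2, t2, `*`)
      dx <- sweep(dx, 2, invstd, `*`)
      list(dx, colSums(g * xhat), colSums(g))
    })
  } else {
    invstd <- 1 / sqrt(buffers$running_var + eps)
    xhat <- sweep(sweep(xv, 2, buffers$running_mean), 2, invstd, `*`)
    y <- sweep(sweep(xhat, 2, gv, `*`), 2, bv, `+`)
    ag_op(y, list(x, gamma, beta), function(g) {
      list(sweep(sweep(g, 2, gv, `*`), 2, invstd, `*`),
           colSums(g * xhat), colSums(g))
    })
  }
}

# BatchNorm2d over [B, C, H, W]: statistics over (B, H, W) per channel.
ag_batchnorm2d <- function(x, gamma, beta, buffers, training,
                           momentum = 0.1, eps = 1e-5) {
  d <- dim(x$value)
  m <- ag_reshape(ag_aperm(x, c(1, 3, 4, 2)), c(d[1] * d[3] * d[4], d[2]))
  y <- ag_bn_cols(m, gamma, beta, buffers, training, momentum, eps)
  ag_aperm(ag_reshape(y, c(d[1], d[3], d[4], d[2])), c(1, 4, 2, 3))
}

# ---- attention ------------------------------------------------------------

softmax_rows <- function(s) {
  e <- exp(s - apply(s, 1, max))
  e / rowSums(e)
}

# Fused multi-head self-attention. qkv is [B*N, 3d] (batch-major rows);
# returns [B*N, d]. Scaled dot-product per head, softmax over keys.
ag_mha <- function(qkv, B, N, heads) {
  d3 <- ncol(qkv$value)
  d <- d3 %/% 3L
  stopifnot(d %% heads == 0L)
  dh <- d %/% heads
  scale <- 1 / sqrt(dh)
  qv <- qkv$value
  out <- matrix(0, B * N, d)
  cache <- vector("list", B * heads)
  for (b in seq_len(B)) {
    rb <- (b - 1L) * N + seq_len(N)
    for (h in seq_len(heads)) {
      ch <- (h - 1L) * dh + seq_len(dh)
      Q <- qv[rb, ch, drop = FALSE]
      K <- qv[rb, d + ch, drop = FALSE]
      V <- qv[rb, 2L * d + ch, drop = FALSE]
      P <- softmax_rows((Q %*% t(K)) * scale)
      out[rb, ch] <- P %*% V
      cache[[(b - 1L) * heads + h]] <- list(Q = Q, K = K, V = V, P = P)
    }
  }
  ag_op(out, list(qkv), function(g) {
    dqkv <- matrix(0, B * N, d3)
    for (b in seq_len(B)) {
      rb <- (b - 1L) * N + seq_len(N)
      for (h in seq_len(heads)) {
        ch <- (h - 1L) * dh + seq_len(dh)
        cc <- cache[[(b - 1L) * heads + h]]
        dO <- g[rb, ch, drop = FALSE]
        dV <- t(cc$P) %*% dO
        dP <- dO %*% t(cc$V)
        dS <- cc$P * (dP - rowSums(dP * cc$P))
        dqkv[rb, ch] <- (dS %*% cc$K) * scale
        dqkv[rb, d + ch] <- (t(dS) %*% cc$Q) * scale
        dqkv[rb, 2L * d + ch] <- dV
      }
    }
    list(dqkv)
  })
}

# ---- 1-D channel convolution (ECA) ----------------------------------------

# z [B, C]; single shared filter w [k] (+ scalar bias), zero same-padding
# along the channel axis.
ag_conv1d_channels <- function(z, w, b = NULL) {
  zv <- z$value
  B <- nrow(zv); C <- ncol(zv)
  k <- length(w$value)
  p <- (k - 1L) %/% 2L
  zp <- cbind(matrix(0, B, p), zv, matrix(0, B, p))
  wv <- as.numeric(w$value)
  y <- matrix(0, B, C)
  for (j in seq_len(k)) y <- y + wv[j] * zp[, j:(j + C - 1L), drop = FALSE]
  if (!is.null(b)) y <- y + as.numeric(b$value)
  parents <- if (is.null(b)) list(z, w) else list(z, w, b)
  ag_op(y, parents, function(g) {
    dw <- numeric(k)
    dzp <- matrix(0, B, C + 2L * p)
    for (j in seq_len(k)) {
      cols <- j:(j + C - 1L)
      dw[j] <- sum(g * zp[, cols, drop = FALSE])
      dzp[, cols] <- dzp[, cols] + wv[j] * g
    }
    dz <- dzp[, p + seq_len(C), drop = FALSE]
    gs <- list(dz, dw)
    if (!is.null(b)) gs <- c(gs, list(sum(g)))
    gs
  })
}

# ---- losses ---------------------------------------------------------------

# Numerically stable mean binary cross-entropy from logits; `target` is a
# plain binary array (no gradient flows into it).
ag_bce_with_logits <- function(logits, target) {
  x <- logits$value
  t <- ag_value(target)
  stopifnot(all(dim(x) == dim(t) | is.null(dim(t))))
  n <- length(x)
  val <- sum(pmax(x, 0) - x * t + log1p(exp(-abs(x)))) / n
  ag_op(val, list(logits), function(g) {
    list(as.numeric(g) * (1 / (1 + exp(-x)) - t) / n)
  })
}
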