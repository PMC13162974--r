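# Small inverse-map resampling utilities: bilinear/nearest sampling on a
# regular grid (rotation augmentation, image resizing) and a separable
# Gaussian blur. Coordinates are 0-based (y, x), row-major; samples that
# fall outside the source are filled with 0.

# Sample matrix `m` at fractional 0-based coordinates (ys, xs).
sample_bilinear <- function(m, ys, xs) {
  H <- nrow(m); W <- ncol(m)
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  gv <- function(yy, xx) {
    ok <- yy >= 0 & yy <= H - 1 & xx >= 0 & xx <= W - 1
    v <- numeric(length(yy))
    v[ok] <- m[cbind(yy[ok] + 1, xx[ok] + 1)]
    v
  }
  gv(y0, x0) * (1 - fy) * (1 - fx) +
    gv(y0, x0 + 1) * (1 - fy) * fx +
    gv(y0 + 1, x0) * fy * (1 - fx) +
    gv(y0 + 1, x0 + 1) * fy * fx
}

sample_nearest <- function(m, ys, xs) {
  H <- nrow(m); W <- ncol(m)
  yy <- round(ys); xx <- round(xs)
  ok <- yy >= 0 & yy <= H - 1 & xx >= 0 & xx <= W - 1
  v <- numeric(length(yy))
  v[ok] <- m[cbind(yy[ok] + 1, xx[ok] + 1)]
  v
}

# Rotate a matrix about its centre by `angle` degrees (counter-clockwise
# in (y up)?? -- convention: positive angle rotates image content
# counter-clockwise in standard plot orientation); filter "bilinear" or
# "nearest"; outside filled with 0. Output size equals input size.
rotate_matrix <- function(m, angle, filter = c("bilinear", "nearest")) {
  filter <- match.arg(filter)
  H <- nrow(m); W <- ncol(m)
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  th <- angle * pi / 180
  gy <- rep(seq_len(H) - 1, times = W)
  gx <- rep(seq_len(W) - 1, each = H)
  u <- gy - cy; v <- gx - cx
  # inverse map: source = R(-theta) * dest
  ys <- cos(th) * u + sin(th) * v + cy
  xs <- -sin(th) * u + cos(th) * v + cx
  out <- if (filter == "bilinear") sample_bilinear(m, ys, xs)
         else sample_nearest(m, ys, xs)
  matrix(out, H, W)
}

# Resize with the half-pixel-centre convention.
resize_matrix <- function(m, out_h, out_w, filter = c("bilinear", "nearest")) {
  filter <- match.arg(filter)
  H <- nrow(m); W <- ncol(m)
  sy <- H / out_h; sx <- W / out_w
  ys <- pmin(pmax((seq_len(out_h) - 0.5) * sy - 0.5, 0), H - 1)
  xs <- pmin(pmax((seq_len(out_w) - 0.5) * sx - 0.5, 0), W - 1)
  gy <- rep(ys, times = out_w)
  gx <- rep(xs, each = out_h)
  out <- if (filter == "bilinear") sample_bilinear(m, gy, gx)
         else sample_nearest(m, gy, gx)
  matrix(out, out_h, out_w)
}

# Separable Gaussian blur with zero-padded borders.
blur_gaussian <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  H <- nrow(m); W <- ncol(m)
  band <- function(n) {
    B <- matrix(0, n, n)
    for (j in seq(-r, r)) {
      idx <- seq_len(n)
      src <- idx + j
      ok <- src >= 1 & src <= n
      B[cbind(idx[ok], src[ok])] <- B[cbind(idx[ok], src[ok])] + k[j + r + 1]
    }
    B
  }
  band(H) %*% m %*% t(band(W))
}
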