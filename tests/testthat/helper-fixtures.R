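# Shared test helpers: deterministic random tensors, a central
# finite-difference gradient checker, and scaled-down scene fixtures.

rand_array <- function(dims, seed = 1) {
  set.seed(seed)
  array(stats::rnorm(prod(dims)), dims)
}

# Central finite-difference check of d loss / d x against the autodiff
# gradient, probing a few random coordinates.
fd_gradient_error <- function(fn, x0, n_probe = 6, eps = 1e-5, seed = 99) {
  xt <- wavesam:::ag_tensor(x0, requires_grad = TRUE)
  loss <- fn(xt)
  wavesam:::ag_backward(loss)
  g <- xt$grad
  set.seed(seed)
  idx <- sample(length(x0), n_probe)
  num <- vapply(idx, function(j) {
    xp <- x0; xp[j] <- xp[j] + eps
    xm <- x0; xm[j] <- xm[j] - eps
    (as.numeric(fn(wavesam:::ag_tensor(xp))$value) -
       as.numeric(fn(wavesam:::ag_tensor(xm))$value)) / (2 * eps)
  }, numeric(1))
  max(abs(num - g[idx]))
}

# 64-pixel scene conditions used for the scaled-down training runs
scene_spec_64 <- function() {
  scene_spec(image_size = 64L, area_frac_range = c(0.03, 0.2),
             texture_wavelength = 10, n_specular = 1L)
}

make_scene_batch <- function(n, spec = scene_spec_64(), seed0 = 100L) {
  S <- spec$image_size
  images <- array(0, c(n, 3L, S, S))
  masks <- array(0, c(n, 1L, S, S))
  for (i in seq_len(n)) {
    sc <- sample_polyp_scene(spec, seed = seed0 + i)
    images[i, , , ] <- sc$image
    masks[i, 1L, , ] <- sc$mask
  }
  list(images = images, masks = masks)
}

# Brute-force binary erosion oracle: neighbourhood minimum by loops,
# outside pixels count as background.
erode_oracle <- function(mask, element = matrix(1, 3, 3)) {
  H <- nrow(mask); W <- ncol(mask)
  ry <- (nrow(element) - 1L) %/% 2L; rx <- (ncol(element) - 1L) %/% 2L
  out <- matrix(0, H, W)
  for (y in seq_len(H)) for (x in seq_len(W)) {
    v <- 1
    for (i in seq_len(nrow(element))) for (j in seq_len(ncol(element))) {
      if (element[i, j] == 0) next
      yy <- y + i - 1L - ry; xx <- x + j - 1L - rx
      p <- if (yy < 1 || yy > H || xx < 1 || xx > W) 0 else mask[yy, xx]
      v <- min(v, p)
    }
    out[y, x] <- v
  }
  out
}
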