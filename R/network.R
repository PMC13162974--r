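# Model assembly: patch embedding, compressed ViT image encoder, mask-prompt
# encoder, sinusoidal position encoding, progressive-upsampling mask decoder,
# and the full promptable segmentation model.
#
# Token sequences are stored as matrices [B*N, d] with batch-major rows.

#' Model configuration
#'
#' Hyperparameters of the promptable segmentation network. The defaults
#' are the full published configuration: 352x352 input, 16x16 patches
#' (22x22 = 484 patch tokens), embedding dimension 384, six encoder
#' blocks with six heads (a ViT-S/16 compressed from dim 768 / depth 12 /
#' heads 12), a two-block decoder, and an 88x88 coarse-mask prompt.
#'
#' @param image_size input resolution in pixels (square).
#' @param patch_size patch edge for the strided patch embedding.
#' @param embed_dim token dimension d.
#' @param encoder_depth,encoder_heads transformer blocks / heads in the
#'   image encoder.
#' @param decoder_depth,decoder_heads transformer blocks / heads in the
#'   mask decoder.
#' @param mlp_ratio feedforward expansion ratio inside transformer blocks.
#' @param prompt_size resolution of the binary coarse-mask prompt
#'   (always `image_size / 4`).
#' @param decoder_widths channel schedule of the four 2x transposed-conv
#'   upsampling stages plus the final head input. The default halves the
#'   embedding dimension per stage with a floor of 8 channels: the
#'   channel-wise layer norm after each stage needs a few channels to
#'   normalise over (at 2 channels it would collapse each position to a
#'   sign). At the full configuration this is `c(384, 192, 96, 48, 24)`.
#' @param prompt_widths hidden channel counts of the two strided
#'   convolutions in the three-layer prompt downsampling network.
#' @param use_wtca enable the wavelet channel-attention block on the
#'   raw image.
#' @param use_dsconv_eca enable the DSConv-ECA block on the patch-token
#'   grid after patch embedding.
#' @param dsconv_on_image alternative placement: a 3-to-64-channel
#'   DSConv-ECA stem applied to the image before patch embedding
#'   (off by default; the grid placement reproduces the published
#'   parameter budget).
#' @param wtca_r reduction ratio of the WTCA attention bottleneck.
#' @param dsconv_k depthwise kernel size.
#' @param eca_gamma,eca_b adaptive ECA-kernel constants.
#' @return a list of class `wavesam_config`.
#' @export
model_config <- function(image_size = 352L, patch_size = 16L,
                         embed_dim = 384L, encoder_depth = 6L,
                         encoder_heads = 6L, decoder_depth = 2L,
                         decoder_heads = encoder_heads, mlp_ratio = 4L,
                         prompt_size = image_size %/% 4L,
                         decoder_widths = pmin(pmax(embed_dim %/% c(1L, 2L, 4L, 8L, 16L), 8L), embed_dim),
                         prompt_widths = c(16L, 336L),
                         use_wtca = TRUE, use_dsconv_eca = TRUE,
                         dsconv_on_image = FALSE,
                         wtca_r = 16L, dsconv_k = 3L,
                         eca_gamma = 2L, eca_b = 1L) {
  if (image_size %% patch_size != 0L)
    stop("image_size must be divisible by patch_size")
  if (embed_dim %% encoder_heads != 0L)
    stop("embed_dim must be divisible by encoder_heads")
  if (embed_dim %% 4L != 0L)
    stop("embed_dim must be divisible by 4 (two axes x sin/cos pairs)")
  if (prompt_size != image_size %/% 4L)
    stop("prompt_size must equal image_size / 4")
  if (prompt_size %% 4L != 0L)
    stop("prompt_size must be divisible by 4 (two stride-2 stages)")
  grid <- image_size %/% patch_size
  if (grid * 16L != image_size && image_size %% 16L != 0L)
    stop("image_size must be divisible by 16")
  if (length(decoder_widths) != 5L)
    stop("decoder_widths must list 5 channel counts (4 stages + head input)")
  if (decoder_widths[1] != embed_dim)
    stop("decoder_widths[1] must equal embed_dim")
  cfg <- list(
    image_size = as.integer(image_size), patch_size = as.integer(patch_size),
    embed_dim = as.integer(embed_dim),
    encoder_depth = as.integer(encoder_depth),
    encoder_heads = as.integer(encoder_heads),
    decoder_depth = as.integer(decoder_depth),
    decoder_heads = as.integer(decoder_heads),
    mlp_ratio = as.integer(mlp_ratio),
    prompt_size = as.integer(prompt_size),
    decoder_widths = as.integer(decoder_widths),
    prompt_widths = as.integer(prompt_widths),
    use_wtca = isTRUE(use_wtca), use_dsconv_eca = isTRUE(use_dsconv_eca),
    dsconv_on_image = isTRUE(dsconv_on_image),
    wtca_r = as.integer(wtca_r), dsconv_k = as.integer(dsconv_k),
    eca_gamma = as.integer(eca_gamma), eca_b = as.integer(eca_b),
    token_grid = grid, n_tokens = grid * grid
  )
  class(cfg) <- "wavesam_config"
  cfg
}

#' Reduced configuration for fast experimentation and tests
#'
#' A shape-compatible scaled-down model: 64x64 input, embedding dim 32,
#' two encoder blocks with two heads, 16x16 prompt.
#'
#' @param ... overrides forwarded to [model_config()].
#' @export
test_config <- function(...) {
  args <- list(image_size = 64L, embed_dim = 32L, encoder_depth = 2L,
               encoder_heads = 2L, prompt_widths = c(4L, 8L))
  over <- list(...)
  args[names(over)] <- over
  do.call(model_config, args)
}

# ---- transformer block ----------------------------------------------------

nn_transformer_block <- function(d, heads, mlp_ratio = 4L) {
  ws_module(
    "transformer_block",
    cfg = list(d = d, heads = heads, mlp = mlp_ratio * d),
    ln1 = nn_layernorm(d),
    qkv = nn_linear(d, 3L * d),
    proj = nn_linear(d, d),
    ln2 = nn_layernorm(d),
    fc1 = nn_linear(d, mlp_ratio * d),
    fc2 = nn_linear(mlp_ratio * d, d)
  )
}

# t: [B*N, d] tokens (batch-major rows); pre-norm residual block.
ag_transformer_block <- function(blk, t, B, N) {
  heads <- blk$cfg$heads
  h <- fw_layernorm(blk$ln1, t)
  a <- ag_mha(fw_linear(blk$qkv, h), B, N, heads)
  t <- ag_add(t, fw_linear(blk$proj, a))
  h2 <- fw_layernorm(blk$ln2, t)
  m <- fw_linear(blk$fc2, ag_gelu(fw_linear(blk$fc1, h2)))
  ag_add(t, m)
}

#' Apply a pre-norm transformer block to a token sequence
#'
#' @param blk block from the model's encoder/decoder lists.
#' @param tokens array `[batch, N, d]`.
#' @return array of the same shape.
#' @export
transformer_block_forward <- function(blk, tokens) {
  d <- dim(tokens)
  m <- apply_tokens_3d_to_mat(tokens)
  out <- ag_transformer_block(blk, ag_tensor(m), d[1], d[2])$value
  mat_to_tokens_3d(out, d[1], d[2], d[3])
}

apply_tokens_3d_to_mat <- function(tokens) {
  d <- dim(tokens)
  m <- matrix(0, d[1] * d[2], d[3])
  for (b in seq_len(d[1])) m[(b - 1L) * d[2] + seq_len(d[2]), ] <- tokens[b, , ]
  m
}

mat_to_tokens_3d <- function(m, B, N, d) {
  out <- array(0, c(B, N, d))
  for (b in seq_len(B)) out[b, , ] <- m[(b - 1L) * N + seq_len(N), ]
  out
}

# ---- token/grid conversions ----------------------------------------------

# grid [B, d, G, G] -> tokens [B*G^2, d], token n = (y-1)*G + x (x fastest)
ag_grid_to_tokens <- function(x) {
  d <- dim(x$value)
  ag_reshape(ag_aperm(x, c(4, 3, 1, 2)), c(d[1] * d[3] * d[4], d[2]))
}

ag_tokens_to_grid <- function(t, B, G, d) {
  ag_aperm(ag_reshape(t, c(G, G, B, d)), c(3, 4, 2, 1))
}

# prepend one learnable class token per batch element
ag_cat_cls <- function(tokens, cls, B, N) {
  d <- ncol(tokens$value)
  N1 <- N + 1L
  cls_rows <- (seq_len(B) - 1L) * N1 + 1L
  tok_rows <- setdiff(seq_len(B * N1), cls_rows)
  v <- matrix(0, B * N1, d)
  v[cls_rows, ] <- matrix(cls$value, B, d, byrow = TRUE)
  v[tok_rows, ] <- tokens$value
  ag_op(v, list(tokens, cls), function(g) {
    list(g[tok_rows, , drop = FALSE], colSums(g[cls_rows, , drop = FALSE]))
  })
}

# add a learnable position table [N1, d], tiled across the batch
ag_add_pos <- function(t, pos, B, N1) {
  rep_idx <- rep(seq_len(N1), times = B)
  ag_op(t$value + pos$value[rep_idx, , drop = FALSE], list(t, pos), function(g) {
    list(g, rowsum(g, group = rep_idx))
  })
}

# ---- patch embedding ------------------------------------------------------

nn_patch_embed <- function(cin, d, patch, n_tokens) {
  ws_module(
    "patch_embed",
    cfg = list(cin = cin, d = d, patch = patch, n = n_tokens),
    proj = nn_conv2d(cin, d, patch, stride = patch, pad = 0L),
    cls = ws_param(init_trunc_normal(d)),
    pos = ws_param(matrix(init_trunc_normal((n_tokens + 1L) * d),
                          n_tokens + 1L, d))
  )
}

ag_patch_embed <- function(pe, x) {
  d <- dim(x$value)
  if (d[3] %% pe$cfg$patch != 0L || d[4] %% pe$cfg$patch != 0L)
    stop("image size (", d[3], "x", d[4],
         ") is not divisible by the patch size ", pe$cfg$patch)
  g <- fw_conv2d(pe$proj, x)                    # [B, d, G, G]
  B <- d[1]; N <- pe$cfg$n
  t <- ag_grid_to_tokens(g)
  t <- ag_cat_cls(t, pe$cls, B, N)
  ag_add_pos(t, pe$pos, B, N + 1L)
}

#' Patch-embed an image batch into a token sequence
#'
#' Strided-convolution projection of non-overlapping patches, prepended
#' class token, and learnable position embeddings.
#'
#' @param model a [wavesam_model()].
#' @param x image batch `[batch, C, H, W]`.
#' @return token array `[batch, N+1, d]` (class token at index 1).
#' @export
patch_embed <- function(model, x) {
  t <- ag_patch_embed(model$encoder$patch, ag_tensor(x))$value
  N1 <- model$config$n_tokens + 1L
  mat_to_tokens_3d(t, dim(x)[1], N1, model$config$embed_dim)
}

# ---- sinusoidal position encoding -----------------------------------------

#' Two-dimensional sinusoidal position encoding
#'
#' Parameter-free grid encoding: the first `d/2` channels encode the
#' vertical coordinate, the last `d/2` the horizontal, each half as
#' interleaved sin/cos pairs of frequency `1/10000^(2i/d)` evaluated at
#' the 0-based grid coordinate.
#'
#' @param d channel count (divisible by 4).
#' @param h,w grid height and width.
#' @return array `[d, h, w]` with values in `[-1, 1]`.
#' @export
sinusoidal_position_encoding <- function(d, h, w) {
  if (d %% 4L != 0L) stop("d must be divisible by 4")
  half <- d %/% 2L
  npair <- half %/% 2L
  omega <- 10000^(-2 * (seq_len(npair) - 1L) / d)
  enc_axis <- function(n) {
    pos <- seq_len(n) - 1L
    ang <- outer(omega, pos)              # [npair, n]
    out <- matrix(0, half, n)
    out[seq(1L, half, by = 2L), ] <- sin(ang)
    out[seq(2L, half, by = 2L), ] <- cos(ang)
    out
  }
  ey <- enc_axis(h)                        # [half, h]
  ex <- enc_axis(w)                        # [half, w]
  out <- array(0, c(d, h, w))
  out[seq_len(half), , ] <- array(rep(ey, times = w), c(half, h, w))
  out[half + seq_len(half), , ] <-
    aperm(array(rep(ex, times = h), c(half, w, h)), c(1, 3, 2))
  out
}

# ---- prompt encoder -------------------------------------------------------

nn_prompt_encoder <- function(cfg) {
  p <- cfg$prompt_widths
  ws_module(
    "prompt_encoder",
    cfg = list(size = cfg$prompt_size, p1 = p[1], p2 = p[2], d = cfg$embed_dim),
    conv1 = nn_conv2d(1L, p[1], 2L, stride = 2L, pad = 0L),
    ln1 = nn_layernorm2d(p[1]),
    conv2 = nn_conv2d(p[1], p[2], 2L, stride = 2L, pad = 0L),
    ln2 = nn_layernorm2d(p[2]),
    conv3 = nn_conv1x1(p[2], cfg$embed_dim)
  )
}

ag_prompt_encoder <- function(pe, m) {
  d <- dim(m$value)
  if (d[2] != 1L || d[3] != pe$cfg$size || d[4] != pe$cfg$size)
    stop("prompt mask must be [batch, 1, ", pe$cfg$size, ", ", pe$cfg$size, "]")
  h <- ag_gelu(fw_layernorm2d(pe$ln1, fw_conv2d(pe$conv1, m)))
  h <- ag_gelu(fw_layernorm2d(pe$ln2, fw_conv2d(pe$conv2, h)))
  fw_conv1x1(pe$conv3, h)
}

#' Encode a coarse prompt mask into the token-grid embedding space
#'
#' Three-layer downsampling network: two stride-2 convolutions with
#' channel-wise layer norm and GELU, then a 1x1 projection to the
#' embedding dimension.
#'
#' @param model a [wavesam_model()].
#' @param m binary prompt batch `[batch, 1, S/4, S/4]`.
#' @return grid feature `[batch, d, S/16, S/16]`.
#' @export
prompt_encoder <- function(model, m) {
  ag_prompt_encoder(model$prompt, ag_tensor(m))$value
}

# ---- mask decoder ---------------------------------------------------------

nn_mask_decoder <- function(cfg) {
  w <- cfg$decoder_widths
  stages <- lapply(seq_len(4L), function(i) {
    ws_module("up_stage",
              tconv = nn_tconv2x2(w[i], w[i + 1L]),
              ln = nn_layernorm2d(w[i + 1L]))
  })
  ws_module(
    "mask_decoder",
    cfg = list(d = cfg$embed_dim, grid = cfg$token_grid,
               heads = cfg$decoder_heads, widths = w),
    blocks = lapply(seq_len(cfg$decoder_depth), function(i)
      nn_transformer_block(cfg$embed_dim, cfg$decoder_heads, cfg$mlp_ratio)),
    stages = stages,
    head = nn_conv1x1(w[5], 1L)
  )
}

ag_mask_decoder <- function(dec, Ei, Ep) {
  di <- dim(Ei$value)
  if (!all(di == dim(Ep$value)))
    stop("image and prompt embeddings must share the same grid shape")
  B <- di[1]; d <- di[2]; G <- di[3]
  pe <- sinusoidal_position_encoding(d, G, G)
  pe_full <- aperm(array(pe, c(d, G, G, B)), c(4, 1, 2, 3))
  f <- ag_addc(ag_add(Ei, Ep), pe_full)          # F0 = Ei + Ep + P
  t <- ag_grid_to_tokens(f)
  N <- G * G
  for (blk in dec$blocks) t <- ag_transformer_block(blk, t, B, N)
  h <- ag_tokens_to_grid(t, B, G, d)
  for (st in dec$stages) {
    h <- ag_gelu(fw_layernorm2d(st$ln, fw_tconv2x2(st$tconv, h)))
  }
  fw_conv1x1(dec$head, h)                        # [B, 1, 16G, 16G]
}

#' Decode fused image and prompt embeddings into segmentation logits
#'
#' Adds the two grid embeddings and a fixed sinusoidal position encoding,
#' runs the decoder transformer blocks over the flattened tokens, then
#' restores resolution through four 2x transposed-convolution stages
#' (each with channel-wise layer norm and GELU) and a final 1x1 head.
#'
#' @param model a [wavesam_model()].
#' @param Ei,Ep grid features `[batch, d, G, G]`.
#' @return segmentation logits `[batch, 1, 16G, 16G]`.
#' @export
mask_decoder <- function(model, Ei, Ep) {
  ag_mask_decoder(model$decoder, ag_tensor(Ei), ag_tensor(Ep))$value
}

# ---- image encoder --------------------------------------------------------

nn_image_encoder <- function(cfg) {
  cin <- if (cfg$dsconv_on_image) 64L else 3L
  ws_module(
    "image_encoder",
    cfg = list(d = cfg$embed_dim, grid = cfg$token_grid,
               depth = cfg$encoder_depth, heads = cfg$encoder_heads,
               use_dsconv_eca = cfg$use_dsconv_eca,
               dsconv_on_image = cfg$dsconv_on_image),
    stem = if (cfg$dsconv_on_image)
      dsconv_eca_block(3L, 64L, cfg$dsconv_k, cfg$eca_gamma, cfg$eca_b)
      else NULL,
    patch = nn_patch_embed(cin, cfg$embed_dim, cfg$patch_size, cfg$n_tokens),
    dsconv_eca = if (cfg$use_dsconv_eca && !cfg$dsconv_on_image)
      dsconv_eca_block(cfg$embed_dim, cfg$embed_dim, cfg$dsconv_k,
                       cfg$eca_gamma, cfg$eca_b)
      else NULL,
    blocks = lapply(seq_len(cfg$encoder_depth), function(i)
      nn_transformer_block(cfg$embed_dim, cfg$encoder_heads, cfg$mlp_ratio)),
    norm = nn_layernorm(cfg$embed_dim)
  )
}

ag_image_encoder <- function(enc, x, training = FALSE) {
  B <- dim(x$value)[1]
  if (!is.null(enc$stem)) x <- ag_dsconv_eca_forward(enc$stem, x, training)
  t <- ag_patch_embed(enc$patch, x)
  N <- enc$cfg$grid^2
  N1 <- N + 1L
  if (!is.null(enc$dsconv_eca)) {
    cls_rows <- (seq_len(B) - 1L) * N1 + 1L
    tok_rows <- setdiff(seq_len(B * N1), cls_rows)
    pt <- ag_rows(t, tok_rows)
    g <- ag_tokens_to_grid(pt, B, enc$cfg$grid, enc$cfg$d)
    g <- ag_dsconv_eca_forward(enc$dsconv_eca, g, training)
    pt2 <- ag_grid_to_tokens(g)
    t <- ag_set_rows(t, tok_rows, pt2)
  }
  for (blk in enc$blocks) t <- ag_transformer_block(blk, t, B, N1)
  t <- fw_layernorm(enc$norm, t)
  cls_rows <- (seq_len(B) - 1L) * N1 + 1L
  tok_rows <- setdiff(seq_len(B * N1), cls_rows)
  pt <- ag_rows(t, tok_rows)
  ag_tokens_to_grid(pt, B, enc$cfg$grid, enc$cfg$d)
}

# replace rows idx of t with `new` (same ncol)
ag_set_rows <- function(t, idx, new) {
  v <- t$value
  v[idx, ] <- new$value
  ag_op(v, list(t, new), function(g) {
    gt <- g
    gt[idx, ] <- 0
    list(gt, g[idx, , drop = FALSE])
  })
}

#' Encode an image batch into the grid feature space
#'
#' Patch embedding (optionally followed by the DSConv-ECA block applied
#' on the patch-token grid), the encoder transformer blocks, a final
#' layer norm, and removal of the class token.
#'
#' @param model a [wavesam_model()].
#' @param x image batch `[batch, 3, S, S]`.
#' @param training logical; batch-statistics mode for batch norms.
#' @return grid feature `[batch, d, S/16, S/16]`.
#' @export
image_encoder <- function(model, x, training = FALSE) {
  ag_image_encoder(model$encoder, ag_tensor(x), training)$value
}

# ---- full model -----------------------------------------------------------

#' Construct the promptable segmentation model
#'
#' Assembles the WTCA image-domain block (optional), the compressed ViT
#' image encoder with the DSConv-ECA grid block (optional), the prompt
#' encoder, and the mask decoder, with all parameters initialised from
#' `seed`.
#'
#' @param config a [model_config()] (default: full configuration).
#' @param seed integer seed for parameter initialisation.
#' @return a list of class `wavesam_model`.
#' @export
wavesam_model <- function(config = model_config(), seed = 42L) {
  stopifnot(inherits(config, "wavesam_config"))
  with_seed(seed, {
    m <- list(
      config = config,
      wtca = if (config$use_wtca) wtca_block(3L, config$wtca_r) else NULL,
      encoder = nn_image_encoder(config),
      prompt = nn_prompt_encoder(config),
      decoder = nn_mask_decoder(config)
    )
    class(m) <- "wavesam_model"
    m
  })
}

ag_wavesam_forward <- function(model, x, mp, training = FALSE) {
  if (!is.null(model$wtca)) x <- ag_wtca_forward(model$wtca, x, training)
  Ei <- ag_image_encoder(model$encoder, x, training)
  Ep <- ag_prompt_encoder(model$prompt, mp)
  ag_mask_decoder(model$decoder, Ei, Ep)
}

#' Full forward pass: image + coarse prompt to segmentation logits
#'
#' @param model a [wavesam_model()].
#' @param x image batch `[batch, 3, S, S]`, intensities in `[0, 1]`.
#' @param mp binary prompt batch `[batch, 1, S/4, S/4]`.
#' @param training logical; batch-statistics mode (FALSE = deterministic
#'   evaluation mode).
#' @return segmentation logits `[batch, 1, S, S]`; apply `plogis()` (or
#'   threshold at 0) for probabilities/masks.
#' @export
wavesam_forward <- function(model, x, mp, training = FALSE) {
  d <- dim(x)
  s <- model$config$image_size
  if (length(d) != 4L || d[2] != 3L || d[3] != s || d[4] != s)
    stop("image batch must be [batch, 3, ", s, ", ", s, "]")
  ag_wavesam_forward(model, ag_tensor(x), ag_tensor(mp), training)$value
}

#' @export
print.wavesam_model <- function(x, ...) {
  cfg <- x$config
  cat("<wavesam_model> image", cfg$image_size, "patch", cfg$patch_size,
      "dim", cfg$embed_dim, "depth", cfg$encoder_depth, "\n")
  rep <- count_parameters(x)
  print(rep)
  invisible(x)
}

collect_buffers <- function(m, prefix = "") {
  out <- list()
  if (!is.list(m)) return(out)
  for (nm in names(m)) {
    el <- m[[nm]]
    sub <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.environment(el) && !is_ag(el)) {
      out[[sub]] <- list(running_mean = el$running_mean,
                         running_var = el$running_var)
    } else if (is.list(el) && nm != "config") {
      out <- c(out, collect_buffers(el, sub))
    }
  }
  out
}

restore_buffers <- function(m, bufs, prefix = "") {
  if (!is.list(m)) return(invisible(NULL))
  for (nm in names(m)) {
    el <- m[[nm]]
    sub <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.environment(el) && !is_ag(el) && !is.null(bufs[[sub]])) {
      el$running_mean <- bufs[[sub]]$running_mean
      el$running_var <- bufs[[sub]]$running_var
    } else if (is.list(el) && nm != "config") {
      restore_buffers(el, bufs, sub)
    }
  }
  invisible(NULL)
}

#' Save / load model checkpoints
#'
#' Checkpoints carry the configuration, every trainable parameter and the
#' batch-norm running statistics in R's native serialisation format.
#'
#' @param model a [wavesam_model()].
#' @param path file path for the checkpoint (`.rds`).
#' @export
wavesam_save <- function(model, path) {
  saveRDS(list(config = unclass(model$config),
               params = state_dict(model[c("wtca", "encoder", "prompt", "decoder")]),
               buffers = collect_buffers(model[c("wtca", "encoder", "prompt", "decoder")])),
          path)
  invisible(path)
}

#' @rdname wavesam_save
#' @export
wavesam_load <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(model_config, ck$config[setdiff(names(ck$config),
                                                 c("token_grid", "n_tokens"))])
  model <- wavesam_model(cfg, seed = 0L)
  sub <- model[c("wtca", "encoder", "prompt", "decoder")]
  load_state_dict(sub, ck$params)
  restore_buffers(sub, ck$buffers)
  model
}
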