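# Trainable-parameter and multiply-accumulate (MAC) budget accounting.
#
# Parameters are counted by enumerating the actual parameter arrays of an
# instantiated model, component by component. MACs are counted analytically
# from the same configuration, one MAC per multiply-add in convolution,
# deconvolution, linear and fixed wavelet filter-bank products -- the
# layer-level convention of standard profilers (normalisations, activations
# and, by default, the attention score/value matrix products are not
# counted; set `include_attention = TRUE` for the latter).

budget_report <- function(components, kind, input_size = NA_integer_) {
  total <- sum(unlist(components))
  structure(
    list(components = components, total = total, kind = kind,
         millions = round(total / 1e6, 2), g = round(total / 1e9, 3),
         input_size = input_size),
    class = "budget_report"
  )
}

#' @export
print.budget_report <- function(x, ...) {
  unit <- if (x$kind == "params") "parameters" else "MACs"
  cat("Budget report (", unit, ")\n", sep = "")
  for (nm in names(x$components))
    cat(sprintf("  %-16s %12.0f\n", nm, x$components[[nm]]))
  if (x$kind == "params")
    cat(sprintf("  %-16s %12.0f  (%.2f M)\n", "total", x$total, x$millions))
  else
    cat(sprintf("  %-16s %12.0f  (%.3f G)\n", "total", x$total, x$g))
  invisible(x)
}

#' Convert a budget report to JSON
#'
#' @param x a `budget_report`.
#' @return a JSON string (per-component and total counts, plus the total
#'   in millions of parameters or G MACs).
#' @export
budget_json <- function(x) {
  stopifnot(inherits(x, "budget_report"))
  jsonlite::toJSON(
    c(x$components,
      list(total = x$total,
           total_human = if (x$kind == "params") x$millions else x$g,
           unit = if (x$kind == "params") "M params" else "G MACs")),
    auto_unbox = TRUE, digits = NA)
}

#' Count trainable parameters per component
#'
#' Enumerates every trainable array of an instantiated model (weights,
#' biases, normalisation affines, class token, position table) and reports
#' per-component and total counts; the headline figure is the total in
#' millions rounded to two decimals.
#'
#' @param model a [wavesam_model()], or a [model_config()] (then a model
#'   is instantiated internally).
#' @return a `budget_report`.
#' @examples
#' \donttest{
#' count_parameters(model_config())$millions          # 15.38
#' count_parameters(model_config(use_wtca = FALSE,
#'                               use_dsconv_eca = FALSE))$millions  # 15.22
#' }
#' @export
count_parameters <- function(model) {
  if (inherits(model, "wavesam_config")) model <- wavesam_model(model, seed = 0L)
  stopifnot(inherits(model, "wavesam_model"))
  enc <- model$encoder
  comp <- list(
    wtca = if (is.null(model$wtca)) 0 else n_params(model$wtca),
    dsconv_eca = (if (is.null(enc$dsconv_eca)) 0 else n_params(enc$dsconv_eca)) +
      (if (is.null(enc$stem)) 0 else n_params(enc$stem)),
    image_encoder = n_params(enc$patch) + n_params(enc$norm) +
      sum(vapply(enc$blocks, n_params, numeric(1))),
    prompt_encoder = n_params(model$prompt),
    mask_decoder = n_params(model$decoder)
  )
  budget_report(comp, "params", model$config$image_size)
}

macs_transformer_block <- function(n_tok, d, mlp, include_attention) {
  m <- n_tok * d * 3 * d +      # qkv projection
    n_tok * d * d +             # output projection
    2 * n_tok * d * mlp         # feedforward
  if (include_attention) m <- m + 2 * n_tok^2 * d
  m
}

macs_wtca <- function(C, H, W, r) {
  C4 <- 4 * C
  hidden <- max(ceiling(C4 / r), 1)
  hw <- (H / 2) * (W / 2)
  4 * C * H * W +               # Haar analysis filter bank (4 taps/coeff)
    hw * C4 * C4 +              # feature-branch 1x1 conv
    C4 * hidden + hidden * C4 + # attention bottleneck (on pooled 1x1 field)
    hw * C4 * C4                # fusion 1x1 conv
}

macs_dsconv_eca <- function(cin, cout, k, H, W, eca_gamma, eca_b) {
  hw <- H * W
  hw * cin * k^2 +              # depthwise
    hw * cin * cout +           # pointwise
    cout * eca_kernel_size(cout, eca_gamma, eca_b) +  # 1-D channel conv
    if (cin != cout) hw * cin * cout else 0           # residual projection
}

#' Count forward-pass multiply-accumulates
#'
#' Analytic MAC count of one forward pass at batch size one, derived from
#' the configuration's layer geometry; the headline figure is the total
#' in G (1e9) rounded to three decimals.
#'
#' @param config a [model_config()] (or a model, whose config is used).
#' @param include_attention also count the attention score and value
#'   matrix products (off by default; see the counting note above).
#' @return a `budget_report`.
#' @examples
#' count_macs(model_config())$g                       # 9.448
#' @export
count_macs <- function(config, include_attention = FALSE) {
  if (inherits(config, "wavesam_model")) config <- config$config
  stopifnot(inherits(config, "wavesam_config"))
  S <- config$image_size; G <- config$token_grid; d <- config$embed_dim
  N <- config$n_tokens; mlp <- config$mlp_ratio * d
  k <- config$dsconv_k
  cin_embed <- if (config$dsconv_on_image) 64L else 3L

  wtca <- if (config$use_wtca) macs_wtca(3, S, S, config$wtca_r) else 0

  ds <- 0
  if (config$dsconv_on_image)
    ds <- macs_dsconv_eca(3L, 64L, k, S, S, config$eca_gamma, config$eca_b)
  else if (config$use_dsconv_eca)
    ds <- macs_dsconv_eca(d, d, k, G, G, config$eca_gamma, config$eca_b)

  enc <- N * d * (cin_embed * config$patch_size^2) +   # patch projection
    config$encoder_depth *
      macs_transformer_block(N + 1, d, mlp, include_attention)

  p <- config$prompt_widths; ps <- config$prompt_size
  prompt <- (ps / 2)^2 * p[1] * (1 * 4) +
    (ps / 4)^2 * p[2] * (p[1] * 4) +
    G^2 * d * p[2]

  w <- config$decoder_widths
  dec <- config$decoder_depth *
    macs_transformer_block(N, d, mlp, include_attention)
  for (i in seq_len(4L)) {
    dec <- dec + (G * 2^i)^2 * w[i + 1] * (w[i] * 4)   # 2x2 transposed conv
  }
  dec <- dec + S^2 * w[5] * 1                          # 1x1 head

  comp <- list(wtca = wtca, dsconv_eca = ds, image_encoder = enc,
               prompt_encoder = prompt, mask_decoder = dec)
  budget_report(comp, "macs", S)
}
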