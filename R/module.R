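# Parameter containers. A module is a named list (class "ws_module") whose
# ag_tensor elements are trainable parameters and whose list elements are
# submodules; `buffers` environments hold non-trainable state (batch-norm
# running statistics). ag_tensors are environments, so parameter updates
# performed by the optimiser are visible through every reference.

ws_param <- function(value) ag_tensor(value, requires_grad = TRUE)

ws_module <- function(type, ...) {
  m <- list(...)
  m$type <- type
  class(m) <- "ws_module"
  m
}

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded model construction
#' and prompt simulation do not disturb user-level randomness.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

init_uniform <- function(n, fan_in) {
  s <- 1 / sqrt(max(fan_in, 1))
  stats::runif(n, -s, s)
}

init_trunc_normal <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

nn_linear <- function(d_in, d_out, bias = TRUE) {
  w <- ws_param(matrix(init_uniform(d_in * d_out, d_in), d_in, d_out))
  b <- if (bias) ws_param(init_uniform(d_out, d_in)) else NULL
  ws_module("linear", w = w, b = b)
}

# General conv: weight matrix [Cout, (Cin/groups)*k*k]
nn_conv2d <- function(cin, cout, k, stride = 1L, pad = 0L, groups = 1L,
                      bias = TRUE) {
  cg <- cin %/% groups
  fan <- cg * k * k
  w <- ws_param(matrix(init_uniform(cout * fan, fan), cout, fan))
  b <- if (bias) ws_param(init_uniform(cout, fan)) else NULL
  ws_module("conv2d", w = w, b = b, k = k, stride = stride, pad = pad,
            groups = groups, cin = cin, cout = cout)
}

nn_conv1x1 <- function(cin, cout, bias = TRUE) {
  w <- ws_param(matrix(init_uniform(cin * cout, cin), cin, cout))
  b <- if (bias) ws_param(init_uniform(cout, cin)) else NULL
  ws_module("conv1x1", w = w, b = b, cin = cin, cout = cout)
}

nn_tconv2x2 <- function(cin, cout, bias = TRUE) {
  fan <- cin * 4L
  w <- ws_param(matrix(init_uniform(cin * 4L * cout, fan), cin, 4L * cout))
  b <- if (bias) ws_param(init_uniform(cout, fan)) else NULL
  ws_module("tconv2x2", w = w, b = b, cin = cin, cout = cout)
}

nn_layernorm <- function(d) {
  ws_module("layernorm", gamma = ws_param(rep(1, d)), beta = ws_param(rep(0, d)))
}

nn_layernorm2d <- function(C) {
  ws_module("layernorm2d", gamma = ws_param(rep(1, C)), beta = ws_param(rep(0, C)))
}

nn_batchnorm2d <- function(C) {
  buf <- new.env(parent = emptyenv())
  buf$running_mean <- rep(0, C)
  buf$running_var <- rep(1, C)
  ws_module("batchnorm2d", gamma = ws_param(rep(1, C)),
            beta = ws_param(rep(0, C)), buffers = buf)
}

nn_conv1d <- function(k, bias = TRUE) {
  w <- ws_param(init_uniform(k, k))
  b <- if (bias) ws_param(init_uniform(1, k)) else NULL
  ws_module("conv1d", w = w, b = b, k = k)
}

# Forward helpers bound to the module structs above
fw_linear <- function(m, x) ag_linear(x, m$w, m$b)
fw_conv2d <- function(m, x) ag_conv2d(x, m$w, m$b, m$k, m$stride, m$pad, m$groups)
fw_conv1x1 <- function(m, x) ag_conv1x1(x, m$w, m$b)
fw_tconv2x2 <- function(m, x) ag_tconv2x2(x, m$w, m$b)
fw_layernorm <- function(m, x) ag_layernorm_rows(x, m$gamma, m$beta)
fw_layernorm2d <- function(m, x) ag_layernorm2d(x, m$gamma, m$beta)
fw_batchnorm2d <- function(m, x, training = FALSE)
  ag_batchnorm2d(x, m$gamma, m$beta, m$buffers, training)
fw_conv1d <- function(m, z) ag_conv1d_channels(z, m$w, m$b)

#' Collect trainable parameters of a module tree
#'
#' @param m a `ws_module` (possibly nested).
#' @param prefix name prefix for the flattened parameter names.
#' @return named list of `ag_tensor` leaves.
#' @keywords internal
collect_params <- function(m, prefix = "") {
  out <- list()
  if (is_ag(m)) {
    out[[prefix]] <- m
    return(out)
  }
  if (!is.list(m)) return(out)
  nms <- names(m)
  if (is.null(nms)) nms <- rep("", length(m))
  for (i in seq_along(m)) {
    el <- m[[i]]
    nm <- if (nzchar(nms[i])) nms[i] else as.character(i)
    if (is.null(el) || nm == "type" || (is.environment(el) && !is_ag(el))) next
    if (is_ag(el) || is.list(el)) {
      sub <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
      out <- c(out, collect_params(el, sub))
    }
  }
  out
}

n_params <- function(m) {
  sum(vapply(collect_params(m), function(p) length(p$value), numeric(1)))
}

# Overwrite every parameter of a module tree with zeros (used to realise
# the zero-initialisation identities of the residual blocks).
zero_params <- function(m) {
  for (p in collect_params(m)) p$value <- p$value * 0
  invisible(m)
}

state_dict <- function(m) lapply(collect_params(m), function(p) p$value)

load_state_dict <- function(m, sd) {
  ps <- collect_params(m)
  stopifnot(all(names(sd) %in% names(ps)))
  for (nm in names(sd)) {
    stopifnot(length(ps[[nm]]$value) == length(sd[[nm]]))
    ps[[nm]]$value <- sd[[nm]]
  }
  invisible(m)
}
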