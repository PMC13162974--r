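# Reverse-mode automatic differentiation on plain R arrays.
#
# A tensor is an environment holding a numeric array plus tape metadata.
# Ops create nodes whose `backfn(grad)` returns one gradient per parent;
# creation order is a valid topological order, so backward() walks node
# ids in reverse. Only subgraphs that can reach a parameter are taped
# (`needs` flag), keeping inference cheap.

.ag_state <- new.env(parent = emptyenv())
.ag_state$id <- 0L

ag_next_id <- function() {
  .ag_state$id <- .ag_state$id + 1L
  .ag_state$id
}

#' Create an autodiff tensor
#'
#' Wraps a numeric array (or vector/matrix) as a leaf node of the
#' computation tape. Parameters are created with `requires_grad = TRUE`;
#' network inputs may also request gradients, e.g. to probe whether a
#' gradient signal reaches the input of a block.
#'
#' @param value numeric array.
#' @param requires_grad logical; accumulate a gradient for this leaf?
#' @return an object of class `ag_tensor`.
#' @keywords internal
ag_tensor <- function(value, requires_grad = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$requires_grad <- requires_grad
  e$needs <- requires_grad
  e$parents <- NULL
  e$backfn <- NULL
  e$id <- ag_next_id()
  class(e) <- "ag_tensor"
  e
}

is_ag <- function(x) inherits(x, "ag_tensor")

ag_value <- function(x) if (is_ag(x)) x$value else x

#' @keywords internal
ag_op <- function(value, parents, backfn) {
  t <- ag_tensor(value)
  t$needs <- any(vapply(parents, function(p) isTRUE(p$needs), logical(1)))
  if (t$needs) {
    t$parents <- parents
    t$backfn <- backfn
  }
  t
}

#' Run backpropagation from a scalar root
#'
#' Seeds the root gradient with ones and accumulates gradients into every
#' reachable leaf created with `requires_grad = TRUE`.
#'
#' @param root `ag_tensor`, typically a scalar loss.
#' @keywords internal
ag_backward <- function(root) {
  nodes <- new.env(parent = emptyenv())
  stack <- list(root)
  while (length(stack) > 0) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (!is.null(nodes[[key]])) next
    nodes[[key]] <- n
    if (!is.null(n$parents)) {
      for (p in n$parents) if (isTRUE(p$needs)) stack[[length(stack) + 1L]] <- p
    }
  }
  ids <- sort(as.integer(ls(nodes)), decreasing = TRUE)
  root$grad <- array(1, dim = if (is.null(dim(root$value))) length(root$value) else dim(root$value))
  for (id in ids) {
    n <- nodes[[as.character(id)]]
    if (is.null(n$backfn) || is.null(n$grad)) next
    gs <- n$backfn(n$grad)
    for (k in seq_along(n$parents)) {
      p <- n$parents[[k]]
      if (!isTRUE(p$needs) || is.null(gs[[k]])) next
      p$grad <- if (is.null(p$grad)) gs[[k]] else p$grad + gs[[k]]
    }
    if (!n$requires_grad) n$grad <- NULL  # free intermediate grads early
  }
  invisible(root)
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- elementwise and scalar ops ------------------------------------------

ag_add <- function(a, b) {
  ag_op(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_sub <- function(a, b) {
  ag_op(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ag_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  ag_op(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ag_div <- function(a, b) {
  av <- a$value; bv <- b$value
  ag_op(av / bv, list(a, b), function(g) list(g / bv, -g * av / bv^2))
}

ag_addc <- function(a, cst) ag_op(a$value + cst, list(a), function(g) list(g))

ag_mulc <- function(a, cst) ag_op(a$value * cst, list(a), function(g) list(g * cst))

ag_sum <- function(a) {
  d <- dim(a$value); if (is.null(d)) d <- length(a$value)
  ag_op(sum(a$value), list(a), function(g) list(array(as.numeric(g), d)))
}

ag_mean <- function(a) {
  n <- length(a$value)
  d <- dim(a$value); if (is.null(d)) d <- n
  ag_op(sum(a$value) / n, list(a), function(g) list(array(as.numeric(g) / n, d)))
}

ag_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  ag_op(s, list(a), function(g) list(g * s * (1 - s)))
}

# Exact GELU: x * Phi(x)
ag_gelu <- function(a) {
  x <- a$value
  ph <- stats::pnorm(x)
  ag_op(x * ph, list(a), function(g) list(g * (ph + x * stats::dnorm(x))))
}

# ---- shape ops ------------------------------------------------------------

ag_reshape <- function(a, dims) {
  old <- dim(a$value); if (is.null(old)) old <- length(a$value)
  v <- a$value; dim(v) <- dims
  ag_op(v, list(a), function(g) { dim(g) <- old; list(g) })
}

ag_aperm <- function(a, perm) {
  inv <- order(perm)
  ag_op(aperm(a$value, perm), list(a), function(g) list(aperm(g, inv)))
}

# Gather rows of a matrix (backward scatter-adds; idx may not repeat).
ag_rows <- function(a, idx, n_rows_in = nrow(a$value)) {
  d2 <- ncol(a$value)
  ag_op(a$value[idx, , drop = FALSE], list(a), function(g) {
    out <- matrix(0, n_rows_in, d2)
    out[idx, ] <- g
    list(out)
  })
}

# Reorder a flat array by a permutation index (e.g. pixel shuffle).
ag_permute_index <- function(a, idx, out_dim) {
  inv <- integer(length(idx)); inv[idx] <- seq_along(idx)
  in_dim <- dim(a$value)
  ag_op(array(a$value[idx], out_dim), list(a), function(g) {
    list(array(as.numeric(g)[inv], in_dim))
  })
}

# ---- linear algebra -------------------------------------------------------

ag_matmul <- function(a, b) {
  av <- a$value; bv <- b$value
  ag_op(av %*% bv, list(a, b), function(g) {
    list(g %*% t(bv), t(av) %*% g)
  })
}

# x [M, d_in] %*% W [d_in, d_out] + b (row broadcast)
ag_linear <- function(x, w, b = NULL) {
  xv <- x$value; wv <- w$value
  y <- xv %*% wv
  if (!is.null(b)) {
    bv <- b$value
    y <- y + matrix(bv, nrow(y), length(bv), byrow = TRUE)
    ag_op(y, list(x, w, b), function(g) {
      list(g %*% t(wv), t(xv) %*% g, colSums(g))
    })
  } else {
    ag_op(y, list(x, w), function(g) list(g %*% t(wv), t(xv) %*% g))
  }
}

# ---- broadcast helpers over [B, C, H, W] ----------------------------------

# x [B,C,H,W] scaled per (batch, channel) by a [B,C]
ag_scale_channels <- function(x, a) {
  xv <- x$value; av <- as.numeric(a$value)
  d <- dim(xv)
  ag_op(xv * av, list(x, a), function(g) {
    gx <- g * av
    ga <- rowSums(matrix(g * xv, d[1] * d[2], d[3] * d[4]))
    dim(ga) <- dim(a$value)
    list(gx, ga)
  })
}

# x [B,C,H,W] + bias[C]
ag_add_channel_bias <- function(x, b) {
  d <- dim(x$value)
  bv <- rep(rep(b$value, each = d[1]), times = d[3] * d[4])
  ag_op(x$value + bv, list(x, b), function(g) {
    gb <- colSums(matrix(aperm(g, c(1, 3, 4, 2)), d[1] * d[3] * d[4], d[2]))
    list(g, gb)
  })
}

# Global average pool: [B,C,H,W] -> [B,C]
ag_gap <- function(x) {
  d <- dim(x$value)
  hw <- d[3] * d[4]
  v <- rowMeans(matrix(x$value, d[1] * d[2], hw))
  dim(v) <- d[1:2]
  ag_op(v, list(x), function(g) {
    list(array(rep(as.numeric(g), times = hw) / hw, d))
  })
}
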