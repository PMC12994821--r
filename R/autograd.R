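# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Every value in the computation graph is an environment ("node") holding
# $val (a numeric matrix), $parents (list of nodes), $backward (a closure
# mapping the incoming gradient to a list of parent gradients) and $needs
# (whether any ancestor requires a gradient). The graph is built eagerly by
# the tg_* operations; tg_backward() runs a topological sweep from a scalar
# loss and accumulates $grad on every node that needs one. Scalars are 1x1
# matrices throughout.

.tg_state <- new.env(parent = emptyenv())
.tg_state$counter <- 0L

tg_new_id <- function() {
  .tg_state$counter <- .tg_state$counter + 1L
  if (.tg_state$counter >= .Machine$integer.max) .tg_state$counter <- 1L
  as.character(.tg_state$counter)
}

#' Create a leaf node
#'
#' @param val Numeric matrix (vectors are promoted to one-row matrices).
#' @param needs Should gradients be accumulated for this leaf? Model
#'   parameters and attribution inputs set this to `TRUE`.
#' @return A graph node.
#' @keywords internal
tg_leaf <- function(val, needs = FALSE) {
  if (!is.matrix(val)) val <- matrix(val, nrow = 1L)
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$parents <- list()
  e$backward <- NULL
  e$needs <- needs
  e$id <- tg_new_id()
  e
}

tg_node <- function(val, parents, backward) {
  e <- new.env(parent = emptyenv())
  e$val <- val
  needs <- FALSE
  for (p in parents) if (p$needs) { needs <- TRUE; break }
  e$parents <- parents
  e$backward <- if (needs) backward else NULL
  e$needs <- needs
  e$id <- tg_new_id()
  e
}

tg_val <- function(node) node$val

# ---- elementary operations -------------------------------------------------

tg_matmul <- function(a, b) {
  tg_node(a$val %*% b$val, list(a, b), function(g) list(
    if (a$needs) g %*% t(b$val) else NULL,
    if (b$needs) crossprod(a$val, g) else NULL
  ))
}

# Add a per-column bias vector to every row of `a`.
tg_addbias <- function(a, b) {
  n <- nrow(a$val)
  bv <- as.numeric(b$val)
  tg_node(a$val + rep(bv, each = n), list(a, b), function(g) list(
    if (a$needs) g else NULL,
    if (b$needs) matrix(colSums(g), nrow = 1L) else NULL
  ))
}

tg_add <- function(a, b) {
  tg_node(a$val + b$val, list(a, b), function(g) list(
    if (a$needs) g else NULL,
    if (b$needs) g else NULL
  ))
}

tg_sub <- function(a, b) {
  tg_node(a$val - b$val, list(a, b), function(g) list(
    if (a$needs) g else NULL,
    if (b$needs) -g else NULL
  ))
}

tg_hadamard <- function(a, b) {
  tg_node(a$val * b$val, list(a, b), function(g) list(
    if (a$needs) g * b$val else NULL,
    if (b$needs) g * a$val else NULL
  ))
}

tg_scale <- function(a, k) {
  tg_node(a$val * k, list(a), function(g) list(if (a$needs) g * k else NULL))
}

tg_relu <- function(a) {
  mask <- a$val > 0
  tg_node(a$val * mask, list(a), function(g) list(
    if (a$needs) g * mask else NULL
  ))
}

tg_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$val))
  tg_node(s, list(a), function(g) list(
    if (a$needs) g * s * (1 - s) else NULL
  ))
}

tg_rows <- function(a, idx) {
  tg_node(a$val[idx, , drop = FALSE], list(a), function(g) list(
    if (a$needs) {
      out <- matrix(0, nrow(a$val), ncol(a$val))
      out[idx, ] <- g
      out
    } else NULL
  ))
}

tg_cols <- function(a, idx) {
  tg_node(a$val[, idx, drop = FALSE], list(a), function(g) list(
    if (a$needs) {
      out <- matrix(0, nrow(a$val), ncol(a$val))
      out[, idx] <- g
      out
    } else NULL
  ))
}

tg_cbind <- function(nodes) {
  widths <- vapply(nodes, function(n) ncol(n$val), 0L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  tg_node(do.call(cbind, lapply(nodes, tg_val)), nodes, function(g) {
    lapply(seq_along(nodes), function(i) {
      if (nodes[[i]]$needs) g[, starts[i]:ends[i], drop = FALSE] else NULL
    })
  })
}

# Reshape a B x (T*D) matrix (token t occupying columns (t-1)*D + 1:D) into
# a token-major stacked (B*T) x D matrix, and back.
tg_stack_tokens <- function(a, n_tokens, d_model) {
  b <- nrow(a$val)
  stack_fwd <- function(m) {
    out <- matrix(0, b * n_tokens, d_model)
    for (t in seq_len(n_tokens)) {
      out[((t - 1L) * b + 1L):(t * b), ] <-
        m[, ((t - 1L) * d_model + 1L):(t * d_model), drop = FALSE]
    }
    out
  }
  stack_bwd <- function(g) {
    out <- matrix(0, b, n_tokens * d_model)
    for (t in seq_len(n_tokens)) {
      out[, ((t - 1L) * d_model + 1L):(t * d_model)] <-
        g[((t - 1L) * b + 1L):(t * b), , drop = FALSE]
    }
    out
  }
  tg_node(stack_fwd(a$val), list(a), function(g) list(
    if (a$needs) stack_bwd(g) else NULL
  ))
}

tg_unstack_tokens <- function(a, n_tokens, d_model) {
  b <- nrow(a$val) %/% n_tokens
  unstack_fwd <- function(m) {
    out <- matrix(0, b, n_tokens * d_model)
    for (t in seq_len(n_tokens)) {
      out[, ((t - 1L) * d_model + 1L):(t * d_model)] <-
        m[((t - 1L) * b + 1L):(t * b), , drop = FALSE]
    }
    out
  }
  unstack_bwd <- function(g) {
    out <- matrix(0, b * n_tokens, d_model)
    for (t in seq_len(n_tokens)) {
      out[((t - 1L) * b + 1L):(t * b), ] <-
        g[, ((t - 1L) * d_model + 1L):(t * d_model), drop = FALSE]
    }
    out
  }
  tg_node(unstack_fwd(a$val), list(a), function(g) list(
    if (a$needs) unstack_bwd(g) else NULL
  ))
}

# Row-wise layer normalization with learnable per-column gain and bias.
tg_layernorm <- function(a, gain, bias, eps = 1e-5) {
  x <- a$val
  n <- nrow(x)
  mu <- rowMeans(x)
  xc <- x - mu
  sd_ <- sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc / sd_
  gv <- as.numeric(gain$val)
  bv <- as.numeric(bias$val)
  y <- xhat * rep(gv, each = n) + rep(bv, each = n)
  tg_node(y, list(a, gain, bias), function(g) list(
    if (a$needs) {
      gg <- g * rep(gv, each = n)
      (gg - rowMeans(gg) - xhat * rowMeans(gg * xhat)) / sd_
    } else NULL,
    if (gain$needs) matrix(colSums(g * xhat), nrow = 1L) else NULL,
    if (bias$needs) matrix(colSums(g), nrow = 1L) else NULL
  ))
}

# ---- attention core --------------------------------------------------------

# Numeric scaled dot-product multi-head attention on token-major stacked
# matrices: q is (B*Tq) x D, k and v are (B*Tk) x D, with token t occupying
# rows (t-1)*B + 1:B. Returns the (B*Tq) x D context plus the cached
# per-head softmax weights needed for the backward pass.
mha_forward_core <- function(q, k, v, n_tokens_q, n_tokens_kv, n_heads) {
  d_model <- ncol(q)
  dh <- d_model %/% n_heads
  b <- nrow(q) %/% n_tokens_q
  scale <- 1 / sqrt(dh)
  out <- matrix(0, nrow(q), d_model)
  wcache <- vector("list", n_heads)
  rows_q <- lapply(seq_len(n_tokens_q), function(t) ((t - 1L) * b + 1L):(t * b))
  rows_k <- lapply(seq_len(n_tokens_kv), function(t) ((t - 1L) * b + 1L):(t * b))
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    kh <- lapply(rows_k, function(r) k[r, cols, drop = FALSE])
    vh <- lapply(rows_k, function(r) v[r, cols, drop = FALSE])
    wlist <- vector("list", n_tokens_q)
    for (i in seq_len(n_tokens_q)) {
      qi <- q[rows_q[[i]], cols, drop = FALSE]
      s <- matrix(0, b, n_tokens_kv)
      for (j in seq_len(n_tokens_kv)) s[, j] <- rowSums(qi * kh[[j]]) * scale
      mx <- s[, 1L]
      if (n_tokens_kv > 1L) {
        for (j in 2:n_tokens_kv) mx <- pmax(mx, s[, j])
      }
      e <- exp(s - mx)
      w <- e / rowSums(e)
      wlist[[i]] <- w
      o <- matrix(0, b, dh)
      for (j in seq_len(n_tokens_kv)) o <- o + w[, j] * vh[[j]]
      out[rows_q[[i]], cols] <- o
    }
    wcache[[h]] <- wlist
  }
  list(out = out, weights = wcache)
}

mha_backward_core <- function(g, q, k, v, wcache,
                              n_tokens_q, n_tokens_kv, n_heads) {
  d_model <- ncol(q)
  dh <- d_model %/% n_heads
  b <- nrow(q) %/% n_tokens_q
  scale <- 1 / sqrt(dh)
  dq <- matrix(0, nrow(q), d_model)
  dk <- matrix(0, nrow(k), d_model)
  dv <- matrix(0, nrow(v), d_model)
  rows_q <- lapply(seq_len(n_tokens_q), function(t) ((t - 1L) * b + 1L):(t * b))
  rows_k <- lapply(seq_len(n_tokens_kv), function(t) ((t - 1L) * b + 1L):(t * b))
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    kh <- lapply(rows_k, function(r) k[r, cols, drop = FALSE])
    vh <- lapply(rows_k, function(r) v[r, cols, drop = FALSE])
    for (i in seq_len(n_tokens_q)) {
      gi <- g[rows_q[[i]], cols, drop = FALSE]
      w <- wcache[[h]][[i]]
      dw <- matrix(0, b, n_tokens_kv)
      for (j in seq_len(n_tokens_kv)) dw[, j] <- rowSums(gi * vh[[j]])
      ds <- w * (dw - rowSums(dw * w)) * scale
      qi <- q[rows_q[[i]], cols, drop = FALSE]
      for (j in seq_len(n_tokens_kv)) {
        dq[rows_q[[i]], cols] <- dq[rows_q[[i]], cols] + ds[, j] * kh[[j]]
        dk[rows_k[[j]], cols] <- dk[rows_k[[j]], cols] + ds[, j] * qi
        dv[rows_k[[j]], cols] <- dv[rows_k[[j]], cols] + w[, j] * gi
      }
    }
  }
  list(dq = dq, dk = dk, dv = dv)
}

tg_mha <- function(q, k, v, n_tokens_q, n_tokens_kv, n_heads) {
  res <- mha_forward_core(q$val, k$val, v$val, n_tokens_q, n_tokens_kv, n_heads)
  tg_node(res$out, list(q, k, v), function(g) {
    grads <- mha_backward_core(g, q$val, k$val, v$val, res$weights,
                               n_tokens_q, n_tokens_kv, n_heads)
    list(
      if (q$needs) grads$dq else NULL,
      if (k$needs) grads$dk else NULL,
      if (v$needs) grads$dv else NULL
    )
  })
}

# ---- losses ----------------------------------------------------------------

tg_mse <- function(a, target) {
  d <- a$val - target
  n <- length(d)
  tg_node(matrix(mean(d * d), 1L, 1L), list(a), function(g) list(
    if (a$needs) as.numeric(g) * 2 * d / n else NULL
  ))
}

tg_bce <- function(p, y, eps = 1e-7) {
  pc <- pmin(pmax(p$val, eps), 1 - eps)
  n <- length(pc)
  v <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  tg_node(matrix(v, 1L, 1L), list(p), function(g) list(
    if (p$needs) as.numeric(g) * (pc - y) / (pc * (1 - pc)) / n else NULL
  ))
}

# Weighted sum of scalar (1x1) nodes.
tg_wsum <- function(nodes, weights) {
  v <- 0
  for (i in seq_along(nodes)) v <- v + weights[i] * nodes[[i]]$val[1L, 1L]
  tg_node(matrix(v, 1L, 1L), nodes, function(g) {
    lapply(seq_along(nodes), function(i) {
      if (nodes[[i]]$needs) matrix(as.numeric(g) * weights[i], 1L, 1L) else NULL
    })
  })
}

tg_sum <- function(a) {
  tg_node(matrix(sum(a$val), 1L, 1L), list(a), function(g) list(
    if (a$needs) matrix(as.numeric(g), nrow(a$val), ncol(a$val)) else NULL
  ))
}

# ---- backward sweep --------------------------------------------------------

#' Run reverse-mode accumulation from a scalar root node
#'
#' Accumulates `$grad` on every node reachable from `root` whose `$needs`
#' flag is set. Gradients on leaves persist until overwritten, so callers
#' reusing parameter leaves across steps must zero them first with
#' `tg_zero_grads()`.
#' @keywords internal
tg_backward <- function(root, seed = 1) {
  # Iterative topological order (DFS postorder).
  topo <- vector("list", 256L)
  n_topo <- 0L
  visited <- new.env(parent = emptyenv())
  stack <- list(list(node = root, child = 0L))
  assign(root$id, TRUE, envir = visited)
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    node <- top$node
    parents <- node$parents
    advanced <- FALSE
    while (top$child < length(parents)) {
      top$child <- top$child + 1L
      p <- parents[[top$child]]
      if (p$needs && !exists(p$id, envir = visited, inherits = FALSE)) {
        assign(p$id, TRUE, envir = visited)
        stack[[length(stack)]] <- top
        stack[[length(stack) + 1L]] <- list(node = p, child = 0L)
        advanced <- TRUE
        break
      }
    }
    if (!advanced) {
      n_topo <- n_topo + 1L
      if (n_topo > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[n_topo]] <- node
      stack[[length(stack)]] <- NULL
    }
  }
  root$grad <- matrix(seed, nrow(root$val), ncol(root$val))
  for (i in rev(seq_len(n_topo))) {
    node <- topo[[i]]
    if (is.null(node$backward) || is.null(node$grad)) next
    grads <- node$backward(node$grad)
    parents <- node$parents
    for (j in seq_along(parents)) {
      gj <- grads[[j]]
      if (is.null(gj)) next
      p <- parents[[j]]
      p$grad <- if (is.null(p$grad)) gj else p$grad + gj
    }
    if (!identical(node, root) && length(node$parents) > 0L) node$grad <- NULL
  }
  invisible(root)
}

tg_zero_grads <- function(leaves) {
  for (p in leaves) p$grad <- NULL
  invisible(NULL)
}

# Central finite-difference gradient of a scalar-valued function of a
# matrix, used as the independent oracle in gradient tests.
fd_gradient <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
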