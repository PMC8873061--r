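# Minimal reverse-mode automatic differentiation over dense matrices.
#
# The sequential models in this package need gradients of a weighted
# cross-entropy through recurrent and attention layers; no autodiff
# framework is available in this R stack, so a small tape is implemented
# here. Nodes are environments holding a value, an accumulated gradient,
# parent links and a pullback closure. Node ids increase monotonically at
# creation, so iterating reachable nodes by decreasing id is a valid
# reverse-topological order. Gradient correctness is verified against
# finite differences in the test suite.

.ad <- new.env(parent = emptyenv())
.ad$counter <- 0L
.ad$tape <- NULL
.ad$tape_len <- 0L

# start recording created nodes (needed before any backward pass);
# the tape is a preallocated list grown by doubling
ad_tape_start <- function(capacity = 4096L) {
  .ad$tape <- vector("list", capacity)
  .ad$tape_len <- 0L
  invisible(NULL)
}

ad_tape_stop <- function() {
  .ad$tape <- NULL
  .ad$tape_len <- 0L
  invisible(NULL)
}

ad_new <- function(value, parents = list(), backfn = NULL, needs = NULL) {
  if (is.null(needs)) {
    needs <- FALSE
    for (p in parents) if (p$needs) { needs <- TRUE; break }
  }
  e <- new.env(parent = emptyenv())
  .ad$counter <- .ad$counter + 1L
  e$id <- .ad$counter
  e$value <- value
  e$parents <- parents
  e$backfn <- backfn
  e$needs <- needs
  e$grad <- NULL
  class(e) <- "ad_node"
  if (!is.null(.ad$tape) && needs) {
    n <- .ad$tape_len + 1L
    if (n > length(.ad$tape)) .ad$tape <- c(.ad$tape, vector("list", length(.ad$tape)))
    .ad$tape[[n]] <- e
    .ad$tape_len <- n
  }
  e
}

ad_const <- function(v) ad_new(as.matrix(v), needs = FALSE)
ad_param <- function(v) ad_new(as.matrix(v), needs = TRUE)

ad_value <- function(x) x$value

# ---- ops -------------------------------------------------------------

ad_matmul <- function(a, b) {
  ad_new(a$value %*% b$value, list(a, b), function(g) {
    list(g %*% t(b$value), t(a$value) %*% g)
  })
}

# a %*% t(b) without materialising the transpose as a node
ad_matmul_nt <- function(a, b) {
  ad_new(a$value %*% t(b$value), list(a, b), function(g) {
    list(g %*% b$value, t(g) %*% a$value)
  })
}

ad_add <- function(a, b) {
  ad_new(a$value + b$value, list(a, b), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  ad_new(a$value - b$value, list(a, b), function(g) list(g, -g))
}

# x (r x n) plus a bias row b (1 x n) broadcast over rows
ad_add_bias <- function(x, b) {
  ad_new(sweep(x$value, 2L, as.vector(b$value), "+"), list(x, b), function(g) {
    list(g, matrix(colSums(g), 1L))
  })
}

ad_add_const <- function(x, m) {
  ad_new(x$value + m, list(x), function(g) list(g))
}

ad_mul <- function(a, b) {
  ad_new(a$value * b$value, list(a, b), function(g) {
    list(g * b$value, g * a$value)
  })
}

ad_scale <- function(x, s) {
  ad_new(x$value * s, list(x), function(g) list(g * s))
}

ad_tanh <- function(x) {
  v <- tanh(x$value)
  ad_new(v, list(x), function(g) list(g * (1 - v * v)))
}

ad_sigmoid <- function(x) {
  v <- 1 / (1 + exp(-x$value))
  ad_new(v, list(x), function(g) list(g * v * (1 - v)))
}

ad_relu <- function(x) {
  v <- x$value
  pos <- v > 0
  v[!pos] <- 0
  ad_new(v, list(x), function(g) list(g * pos))
}

ad_cols <- function(x, idx) {
  nc <- ncol(x$value)
  ad_new(x$value[, idx, drop = FALSE], list(x), function(g) {
    out <- matrix(0, nrow(g), nc)
    out[, idx] <- g
    list(out)
  })
}

ad_rbind <- function(lst) {
  rows <- vapply(lst, function(x) nrow(x$value), integer(1L))
  ends <- cumsum(rows)
  starts <- ends - rows + 1L
  ad_new(do.call(rbind, lapply(lst, ad_value)), lst, function(g) {
    lapply(seq_along(lst), function(i) g[starts[i]:ends[i], , drop = FALSE])
  })
}

ad_cbind <- function(lst) {
  cols <- vapply(lst, function(x) ncol(x$value), integer(1L))
  ends <- cumsum(cols)
  starts <- ends - cols + 1L
  ad_new(do.call(cbind, lapply(lst, ad_value)), lst, function(g) {
    lapply(seq_along(lst), function(i) g[, starts[i]:ends[i], drop = FALSE])
  })
}

# row lookup with accumulation on the backward pass (embedding tables)
ad_embed <- function(w, idx) {
  nr <- nrow(w$value)
  ad_new(w$value[idx, , drop = FALSE], list(w), function(g) {
    agg <- rowsum(g, group = idx)
    out <- matrix(0, nr, ncol(g))
    out[as.integer(rownames(agg)), ] <- agg
    list(out)
  })
}

ad_softmax_rows <- function(x) {
  v <- x$value
  v <- v - apply(v, 1L, max)
  e <- exp(v)
  p <- e / rowSums(e)
  ad_new(p, list(x), function(g) {
    list(p * (g - rowSums(g * p)))
  })
}

# row-wise layer normalisation with learned gain/bias (1 x d each)
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  v <- x$value
  mu <- rowMeans(v)
  cv <- v - mu
  s <- sqrt(rowMeans(cv * cv) + eps)
  xhat <- cv / s
  gam <- as.vector(gamma$value)
  out <- sweep(sweep(xhat, 2L, gam, "*"), 2L, as.vector(beta$value), "+")
  ad_new(out, list(x, gamma, beta), function(g) {
    dgamma <- matrix(colSums(g * xhat), 1L)
    dbeta <- matrix(colSums(g), 1L)
    dxhat <- sweep(g, 2L, gam, "*")
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / s
    list(dx, dgamma, dbeta)
  })
}

# fused weighted softmax cross-entropy over rows:
#   loss = sum_r w_r * (-log softmax(logits)_[r, y_r]) / denom
# rows with weight 0 contribute nothing (their y may be arbitrary)
ad_wce <- function(logits, y, w, denom, eps = 1e-12) {
  v <- logits$value
  v <- v - apply(v, 1L, max)
  e <- exp(v)
  p <- e / rowSums(e)
  picked <- p[cbind(seq_len(nrow(p)), y)]
  loss <- sum(w * (-log(pmax(picked, eps)))) / denom
  ad_new(matrix(loss, 1L, 1L), list(logits), function(g) {
    gs <- as.numeric(g)
    d <- p
    d[cbind(seq_len(nrow(p)), y)] <- d[cbind(seq_len(nrow(p)), y)] - 1
    list(d * (w * gs / denom))
  })
}

# row block of a matrix (used to slice per-timestep inputs out of one
# large precomputed product)
ad_rows_block <- function(x, from, to) {
  nr <- nrow(x$value)
  ad_new(x$value[from:to, , drop = FALSE], list(x), function(g) {
    out <- matrix(0, nr, ncol(g))
    out[from:to, ] <- g
    list(out)
  })
}

# fused LSTM cell update: gates (B x 4d) in [i, f, g, o] column blocks,
# returns c_t = sigm(i)*tanh(g) + sigm(f)*c_prev as one node
ad_lstm_cell <- function(gates, cprev, d) {
  G <- gates$value
  i <- 1 / (1 + exp(-G[, 1:d, drop = FALSE]))
  f <- 1 / (1 + exp(-G[, (d + 1):(2 * d), drop = FALSE]))
  g <- tanh(G[, (2 * d + 1):(3 * d), drop = FALSE])
  cp <- cprev$value
  ad_new(f * cp + i * g, list(gates, cprev), function(gr) {
    dG <- matrix(0, nrow(G), ncol(G))
    dG[, 1:d] <- gr * g * i * (1 - i)
    dG[, (d + 1):(2 * d)] <- gr * cp * f * (1 - f)
    dG[, (2 * d + 1):(3 * d)] <- gr * i * (1 - g * g)
    list(dG, gr * f)
  })
}

# fused LSTM output: h_t = sigm(o) * tanh(c_t)
ad_lstm_out <- function(gates, ct, d) {
  G <- gates$value
  o <- 1 / (1 + exp(-G[, (3 * d + 1):(4 * d), drop = FALSE]))
  tc <- tanh(ct$value)
  ad_new(o * tc, list(gates, ct), function(gr) {
    dG <- matrix(0, nrow(G), ncol(G))
    dG[, (3 * d + 1):(4 * d)] <- gr * tc * o * (1 - o)
    list(dG, gr * o * (1 - tc * tc))
  })
}

# ---- backward --------------------------------------------------------

ad_backward <- function(node) {
  stopifnot(inherits(node, "ad_node"), length(node$value) == 1L)
  if (is.null(.ad$tape)) {
    abort("no active tape: call ad_tape_start() before building the graph")
  }
  tape <- .ad$tape
  len <- .ad$tape_len
  node$grad <- matrix(1, 1L, 1L)
  # tape order is creation order, so the reverse sweep is topological;
  # nodes that never receive a gradient are skipped
  for (k in rev(seq_len(len))) {
    n <- tape[[k]]
    if (n$id > node$id || is.null(n$grad) || is.null(n$backfn)) next
    gs <- n$backfn(n$grad)
    ps <- n$parents
    for (i in seq_along(ps)) {
      p <- ps[[i]]
      if (!p$needs || is.null(gs[[i]])) next
      p$grad <- if (is.null(p$grad)) gs[[i]] else p$grad + gs[[i]]
    }
  }
  invisible(node)
}
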