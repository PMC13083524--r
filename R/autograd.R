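#' @title Minimal reverse-mode automatic differentiation
#'
#' @description
#' The MIL model, the convolutional patch encoder and the gene-set
#' autoencoder are trained end-to-end, which requires gradients through
#' convolutions, normalization layers, softmax attention and the iterative
#' pseudo-inverse inside Nystrom attention. The package carries its own
#' small define-by-run tape for this: every operation `ag_*()` takes and
#' returns `ag_node` objects (environments holding a numeric value, the
#' parent nodes and a backward closure), and [ag_backward()] accumulates
#' gradients by reverse topological sweep. Values are plain R matrices or
#' 4-D arrays laid out `(n, height, width, channel)`; all heavy lifting is
#' delegated to BLAS-level primitives (`%*%`, `rowsum`, vectorized
#' indexing), which keeps step times practical at the bag sizes used here.
#'
#' @name autograd
#' @keywords internal
NULL

.ag <- new.env(parent = emptyenv())
.ag$id <- 0L

ag_next_id <- function() {
  .ag$id <- .ag$id + 1L
  .ag$id
}

#' Create a tape node
#'
#' @param value numeric vector, matrix or array.
#' @param parents list of parent `ag_node`s this value was computed from.
#' @param bfun backward closure: `function(grad)` returning a list of
#'   gradients, one per parent (NULL allowed for parents not requiring
#'   gradients).
#' @param requires does any ancestor require a gradient?
#' @keywords internal
ag_node <- function(value, parents = list(), bfun = NULL, requires = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- if (requires) parents else list()
  e$bfun <- if (requires) bfun else NULL
  e$requires <- requires
  e$grad <- NULL
  e$id <- ag_next_id()
  class(e) <- "ag_node"
  e
}

#' Wrap a constant (no gradient tracked)
#' @param value numeric value.
#' @keywords internal
ag_const <- function(value) ag_node(value, requires = FALSE)

#' Create a learnable parameter node
#'
#' Parameter nodes persist across forward passes; each training step builds
#' a fresh tape referencing the same parameter environments.
#'
#' @param value initial numeric value.
#' @param name optional identifier used in reports.
#' @keywords internal
ag_param <- function(value, name = NULL) {
  e <- ag_node(value, requires = TRUE)
  e$is_param <- TRUE
  e$name <- name
  e
}

as_node <- function(x) if (inherits(x, "ag_node")) x else ag_const(x)

req <- function(...) {
  for (p in list(...)) if (p$requires) return(TRUE)
  FALSE
}

#' Reverse sweep: accumulate gradients into `$grad` of every ancestor
#'
#' @param root scalar-valued output node.
#' @param grad seed gradient (defaults to 1).
#' @keywords internal
ag_backward <- function(root, grad = 1) {
  # iterative topological order over the requiring subgraph
  topo <- vector("list", 256L)
  n_topo <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]]) || !node$requires) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        if (p$requires && is.null(seen[[as.character(p$id)]])) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      n_topo <- n_topo + 1L
      if (n_topo > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[n_topo]] <- node
    }
  }
  if (n_topo == 0L) return(invisible(root))
  topo <- topo[seq_len(n_topo)]
  for (nd in topo) nd$grad <- NULL
  root$grad <- grad
  for (i in rev(seq_len(n_topo))) {
    nd <- topo[[i]]
    if (is.null(nd$grad) || is.null(nd$bfun)) next
    gs <- nd$bfun(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (!p$requires || is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
  }
  invisible(root)
}

#' Zero the stored gradients of a list of parameters
#' @param params list of `ag_param` nodes.
#' @keywords internal
ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

# ---- elementwise / linear algebra ops --------------------------------------

ag_add <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  ag_node(a$value + b$value, list(a, b),
          function(g) list(g, g), req(a, b))
}

ag_sub <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  ag_node(a$value - b$value, list(a, b),
          function(g) list(g, -g), req(a, b))
}

ag_mul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  av <- a$value; bv <- b$value
  ag_node(av * bv, list(a, b),
          function(g) list(g * bv, g * av), req(a, b))
}

#' Multiply by a plain scalar constant
#' @keywords internal
ag_smul <- function(a, s) {
  a <- as_node(a)
  ag_node(a$value * s, list(a), function(g) list(g * s), a$requires)
}

ag_matmul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  av <- a$value; bv <- b$value
  ag_node(av %*% bv, list(a, b),
          function(g) list(g %*% t(bv), t(av) %*% g), req(a, b))
}

ag_t <- function(a) {
  a <- as_node(a)
  ag_node(t(a$value), list(a), function(g) list(t(g)), a$requires)
}

#' Add a length-ncol bias row-vector to every row of a matrix
#' @keywords internal
ag_add_bias <- function(x, b) {
  x <- as_node(x); b <- as_node(b)
  bv <- as.numeric(b$value)
  ag_node(sweep(x$value, 2L, bv, "+"), list(x, b),
          function(g) list(g, colSums(g)), req(x, b))
}

ag_relu <- function(x) {
  x <- as_node(x)
  mask <- x$value > 0
  ag_node(x$value * mask, list(x), function(g) list(g * mask), x$requires)
}

ag_tanh <- function(x) {
  x <- as_node(x)
  y <- tanh(x$value)
  ag_node(y, list(x), function(g) list(g * (1 - y * y)), x$requires)
}

ag_sum <- function(x) {
  x <- as_node(x)
  d <- dim(x$value); v <- x$value
  ag_node(sum(v), list(x),
          function(g) list(array(g, dim = if (is.null(d)) length(v) else d)),
          x$requires)
}

ag_mean <- function(x) ag_smul(ag_sum(x), 1 / length(as_node(x)$value))

#' Row-wise softmax with numerically stable forward
#' @keywords internal
ag_softmax_rows <- function(x) {
  x <- as_node(x)
  v <- x$value
  if (is.null(dim(v))) v <- matrix(v, nrow = 1L)
  m <- apply(v, 1L, max)
  e <- exp(v - m)
  y <- e / rowSums(e)
  ag_node(y, list(x),
          function(g) {
            if (is.null(dim(g))) g <- matrix(g, nrow = 1L)
            list(y * (g - rowSums(g * y)))
          }, x$requires)
}

#' Row-wise layer normalization with learnable affine
#' @keywords internal
ag_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_node(x); gamma <- as_node(gamma); beta <- as_node(beta)
  v <- x$value
  D <- ncol(v)
  mu <- rowMeans(v)
  xc <- v - mu
  va <- rowMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  gv <- as.numeric(gamma$value)
  y <- sweep(xhat, 2L, gv, "*")
  y <- sweep(y, 2L, as.numeric(beta$value), "+")
  ag_node(y, list(x, gamma, beta),
          function(g) {
            gx <- sweep(g, 2L, gv, "*")
            s1 <- rowMeans(gx)
            s2 <- rowMeans(gx * xhat)
            dx <- istd * (gx - s1 - xhat * s2)
            list(dx, colSums(g * xhat), colSums(g))
          }, req(x, gamma, beta))
}

#' Select rows of a matrix
#' @keywords internal
ag_rows <- function(x, idx) {
  x <- as_node(x)
  v <- x$value
  nr <- nrow(v); nc <- ncol(v)
  ag_node(v[idx, , drop = FALSE], list(x),
          function(g) {
            dx <- matrix(0, nr, nc)
            for (k in seq_along(idx)) {
              dx[idx[k], ] <- dx[idx[k], ] + g[k, ]
            }
            list(dx)
          }, x$requires)
}

#' Select columns of a matrix (used to split attention heads)
#' @keywords internal
ag_cols <- function(x, idx) {
  x <- as_node(x)
  v <- x$value
  nr <- nrow(v); nc <- ncol(v)
  ag_node(v[, idx, drop = FALSE], list(x),
          function(g) {
            dx <- matrix(0, nr, nc)
            dx[, idx] <- g
            list(dx)
          }, x$requires)
}

#' Stack matrices by rows
#' @keywords internal
ag_vcat <- function(...) {
  xs <- lapply(list(...), as_node)
  rows <- vapply(xs, function(x) nrow(as.matrix(x$value)), integer(1))
  stops <- cumsum(rows)
  starts <- c(1L, head(stops, -1L) + 1L)
  ag_node(do.call(rbind, lapply(xs, function(x) x$value)), xs,
          function(g) {
            lapply(seq_along(xs), function(i)
              g[starts[i]:stops[i], , drop = FALSE])
          }, do.call(req, xs))
}

#' Concatenate matrices by columns
#' @keywords internal
ag_hcat <- function(...) {
  xs <- lapply(list(...), as_node)
  cols <- vapply(xs, function(x) ncol(as.matrix(x$value)), integer(1))
  stops <- cumsum(cols)
  starts <- c(1L, head(stops, -1L) + 1L)
  ag_node(do.call(cbind, lapply(xs, function(x) x$value)), xs,
          function(g) {
            lapply(seq_along(xs), function(i)
              g[, starts[i]:stops[i], drop = FALSE])
          }, do.call(req, xs))
}

#' Reshape without reordering
#' @keywords internal
ag_reshape <- function(x, dims) {
  x <- as_node(x)
  old <- dim(x$value)
  v <- x$value
  dim(v) <- dims
  ag_node(v, list(x),
          function(g) {
            dim(g) <- old
            list(g)
          }, x$requires)
}

#' Softmax cross-entropy between a 1 x K logit row and an integer label
#'
#' @param logits node holding a 1 x K matrix.
#' @param label integer class in `1..K`.
#' @keywords internal
ag_ce_logits <- function(logits, label) {
  logits <- as_node(logits)
  z <- as.numeric(logits$value)
  m <- max(z)
  lse <- m + log(sum(exp(z - m)))
  p <- exp(z - lse)
  ag_node(lse - z[label], list(logits),
          function(g) {
            d <- p
            d[label] <- d[label] - 1
            list(matrix(g * d, nrow = 1L))
          }, logits$requires)
}

#' Numerical gradient by central differences (test oracle)
#'
#' @param f function mapping a numeric vector to a scalar.
#' @param x numeric vector at which to differentiate.
#' @param eps step size.
#' @keywords internal
ag_num_grad <- function(f, x, eps = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
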