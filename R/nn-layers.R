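# Neural-network layers on top of the autograd tape. Image tensors are 4-D
# arrays dim = (n, height, width, channel); token sequences are matrices
# (token x feature).

.conv_cache <- new.env(parent = emptyenv())

# im2col gather index for one padded image, rows ordered (oh fastest, then ow),
# columns ordered (kh, kw, channel).
conv_im2col_index <- function(hp, wp, cin, k, stride) {
  key <- paste(hp, wp, cin, k, stride, sep = "_")
  if (!is.null(.conv_cache[[key]])) return(.conv_cache[[key]])
  oh <- (hp - k) %/% stride + 1L
  ow <- (wp - k) %/% stride + 1L
  # padded flat index for (h, w, c), h fastest: h + hp*(w-1) + hp*wp*(c-1)
  grid <- expand.grid(oh = seq_len(oh), ow = seq_len(ow))
  kidx <- expand.grid(kh = seq_len(k), kw = seq_len(k), c = seq_len(cin))
  h0 <- (grid$oh - 1L) * stride  # top-left offset (0-based)
  w0 <- (grid$ow - 1L) * stride
  L <- nrow(grid); K <- nrow(kidx)
  h <- outer(h0, kidx$kh, "+")              # L x K, 1-based row in padded img
  w <- outer(w0, kidx$kw, "+")
  cmat <- matrix(kidx$c, L, K, byrow = TRUE)
  I <- h + hp * (w - 1L) + hp * wp * (cmat - 1L)
  out <- list(I = I, oh = oh, ow = ow, L = L, K = K)
  .conv_cache[[key]] <- out
  out
}

pad_nhwc <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, dim = c(d[1], d[2] + 2L * pad, d[3] + 2L * pad, d[4]))
  xp[, pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- x
  xp
}

#' 2-D convolution (NHWC) via im2col
#'
#' @param x node, array `(n, h, w, cin)`.
#' @param w node, array `(k, k, cin, cout)`.
#' @param b node, length-`cout` bias.
#' @param stride,pad integers.
#' @keywords internal
ag_conv2d <- function(x, w, b, stride = 1L, pad = 0L) {
  x <- as_node(x); w <- as_node(w); b <- as_node(b)
  xv <- x$value
  d <- dim(xv)
  n <- d[1]; cin <- d[4]
  k <- dim(w$value)[1]
  if (k == 1L && stride == 1L && pad == 0L) return(ag_conv1x1(x, w, b))
  xp <- pad_nhwc(xv, pad)
  hp <- dim(xp)[2]; wp <- dim(xp)[3]
  ix <- conv_im2col_index(hp, wp, cin, k, stride)
  # (n) x (hp*wp*cin) with n fastest; but dim(xp) = (n,hp,wp,cin) already has
  # n fastest, so matrix() gives exactly rows = n.
  xm <- matrix(xp, nrow = n)
  xcol <- xm[, as.vector(ix$I), drop = FALSE]      # n x (L*K), col (l,k)
  dim(xcol) <- c(n * ix$L, ix$K)
  wm <- matrix(w$value, nrow = ix$K)               # (k*k*cin) x cout
  out <- xcol %*% wm
  out <- sweep(out, 2L, as.numeric(b$value), "+")
  cout <- ncol(wm)
  dim(out) <- c(n, ix$oh, ix$ow, cout)
  ag_node(out, list(x, w, b),
          function(g) {
            dim(g) <- c(n * ix$L, cout)
            dw <- crossprod(xcol, g)
            dim(dw) <- dim(w$value)
            db <- colSums(g)
            dxcol <- g %*% t(wm)                   # (n*L) x K
            dim(dxcol) <- c(n, ix$L * ix$K)
            grp <- as.vector(ix$I)
            acc <- rowsum(t(dxcol), group = grp)   # (#unique) x n
            dxm <- matrix(0, n, hp * wp * cin)
            dxm[, as.integer(rownames(acc))] <- t(acc)
            dim(dxm) <- c(n, hp, wp, cin)
            if (pad > 0L) {
              dxm <- dxm[, pad + seq_len(d[2]), pad + seq_len(d[3]), ,
                         drop = FALSE]
            }
            list(dxm, dw, db)
          }, req(x, w, b))
}

# pointwise (1x1 stride-1) convolution: channel-mixing matrix multiply
ag_conv1x1 <- function(x, w, b) {
  xv <- x$value
  d <- dim(xv)
  cin <- d[4]
  wm <- matrix(w$value, nrow = cin)
  xm <- matrix(xv, ncol = cin)        # (n*h*w) x cin  (n,h,w fastest)
  out <- xm %*% wm
  out <- sweep(out, 2L, as.numeric(b$value), "+")
  dim(out) <- c(d[1], d[2], d[3], ncol(wm))
  ag_node(out, list(x, w, b),
          function(g) {
            dim(g) <- c(d[1] * d[2] * d[3], ncol(wm))
            dw <- crossprod(xm, g)
            dim(dw) <- dim(w$value)
            dx <- g %*% t(wm)
            dim(dx) <- d
            list(dx, dw, colSums(g))
          }, req(x, w, b))
}

#' Depthwise 2-D convolution (NHWC)
#'
#' Implemented through the same im2col gather as [ag_conv2d()] with a
#' block-masked `(k*k*c) x c` kernel matrix (channel `c` only sees its own
#' `k*k` taps), so the whole convolution is a single BLAS product.
#'
#' @param x node, array `(n, h, w, c)`.
#' @param w node, array `(k, k, c)`.
#' @param b node, length-`c` bias (or NULL for none).
#' @param stride,pad integers; default pad is `k %/% 2` (same-padding at
#'   stride 1).
#' @keywords internal
ag_dwconv2d <- function(x, w, b = NULL, stride = 1L, pad = NULL) {
  x <- as_node(x); w <- as_node(w)
  has_b <- !is.null(b)
  if (has_b) b <- as_node(b)
  xv <- x$value
  d <- dim(xv)
  n <- d[1]; C <- d[4]
  k <- dim(w$value)[1]
  if (is.null(pad)) pad <- k %/% 2L
  xp <- pad_nhwc(xv, pad)
  hp <- dim(xp)[2]; wp <- dim(xp)[3]
  ix <- conv_im2col_index(hp, wp, C, k, stride)
  xm <- matrix(xp, nrow = n)
  xcol <- xm[, as.vector(ix$I), drop = FALSE]
  dim(xcol) <- c(n * ix$L, ix$K)      # columns ordered (kh, kw, c)
  kk <- k * k
  blockrow <- rep(seq_len(C), each = kk)        # channel of each xcol column
  diagmask <- cbind(seq_len(ix$K), blockrow)    # (row, col) of kernel taps
  wm <- matrix(0, ix$K, C)
  wm[diagmask] <- as.numeric(w$value)
  out <- xcol %*% wm
  if (has_b) out <- sweep(out, 2L, as.numeric(b$value), "+")
  dim(out) <- c(n, ix$oh, ix$ow, C)
  parents <- if (has_b) list(x, w, b) else list(x, w)
  ag_node(out, parents,
          function(g) {
            dim(g) <- c(n * ix$L, C)
            dwm <- crossprod(xcol, g)
            dw <- array(dwm[diagmask], dim = dim(w$value))
            dxcol <- g %*% t(wm)
            dim(dxcol) <- c(n, ix$L * ix$K)
            acc <- rowsum(t(dxcol), group = as.vector(ix$I))
            dxm <- matrix(0, n, hp * wp * C)
            dxm[, as.integer(rownames(acc))] <- t(acc)
            dim(dxm) <- c(n, hp, wp, C)
            dx <- if (pad > 0L) {
              dxm[, pad + seq_len(d[2]), pad + seq_len(d[3]), , drop = FALSE]
            } else dxm
            db <- if (has_b) colSums(g) else NULL
            if (has_b) list(dx, dw, db) else list(dx, dw)
          }, if (has_b) req(x, w, b) else req(x, w))
}

#' Per-channel learnable scale and shift (no statistics)
#'
#' The light form of channel normalization used inside bottleneck blocks,
#' where the block output already passes through the full statistic-based
#' [ag_channorm()]: `y = x * gamma[c] + beta[c]`.
#'
#' @param x node, array `(n, h, w, c)`.
#' @param gamma,beta nodes, length-`c`.
#' @keywords internal
ag_chanaffine <- function(x, gamma, beta) {
  x <- as_node(x); gamma <- as_node(gamma); beta <- as_node(beta)
  v <- x$value
  d <- dim(v)
  C <- d[4]
  m <- matrix(v, ncol = C)
  y <- sweep(sweep(m, 2L, as.numeric(gamma$value), "*"), 2L,
             as.numeric(beta$value), "+")
  dim(y) <- d
  ag_node(y, list(x, gamma, beta),
          function(g) {
            gm <- matrix(g, ncol = C)
            dx <- sweep(gm, 2L, as.numeric(gamma$value), "*")
            dim(dx) <- d
            list(dx, colSums(gm * m), colSums(gm))
          }, req(x, gamma, beta))
}

#' Per-channel normalization over spatial positions with learnable affine
#'
#' Each image's channels are standardized over their spatial extent and then
#' scaled/shifted by per-channel affine parameters (the two "normalization
#' affine terms" per channel counted in parameter budgets). Statistics are
#' per sample, so evaluation needs no running averages and single-bag
#' batches stay deterministic.
#'
#' @param x node, array `(n, h, w, c)`.
#' @param gamma,beta nodes, length-`c`.
#' @keywords internal
ag_channorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_node(x); gamma <- as_node(gamma); beta <- as_node(beta)
  v <- x$value
  d <- dim(v)
  n <- d[1]; hw <- d[2] * d[3]; C <- d[4]
  # reshape to (hw) x (n*C): need spatial fastest -> permute to (h,w,n,c)
  vp <- aperm(v, c(2L, 3L, 1L, 4L))
  m <- matrix(vp, nrow = hw)
  mu <- colMeans(m)
  xc <- sweep(m, 2L, mu, "-")
  va <- colMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2L, istd, "*")
  gv <- rep(as.numeric(gamma$value), each = n)
  bv <- rep(as.numeric(beta$value), each = n)
  y <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
  dim(y) <- c(d[2], d[3], n, C)
  y <- aperm(y, c(3L, 1L, 2L, 4L))
  ag_node(y, list(x, gamma, beta),
          function(g) {
            gp <- aperm(g, c(2L, 3L, 1L, 4L))
            gm <- matrix(gp, nrow = hw)
            dgamma_full <- colSums(gm * xhat)        # length n*C
            dbeta_full <- colSums(gm)
            dgamma <- colSums(matrix(dgamma_full, nrow = n))
            dbeta <- colSums(matrix(dbeta_full, nrow = n))
            gx <- sweep(gm, 2L, gv, "*")
            s1 <- colMeans(gx)
            s2 <- colMeans(gx * xhat)
            dxm <- sweep(gx, 2L, s1, "-") - sweep(xhat, 2L, s2, "*")
            dxm <- sweep(dxm, 2L, istd, "*")
            dim(dxm) <- c(d[2], d[3], n, C)
            list(aperm(dxm, c(3L, 1L, 2L, 4L)), dgamma, dbeta)
          }, req(x, gamma, beta))
}

#' Global average pooling `(n, h, w, c)` -> `(n, c)`
#' @keywords internal
ag_gap <- function(x) {
  x <- as_node(x)
  d <- dim(x$value)
  hw <- d[2] * d[3]
  vp <- aperm(x$value, c(2L, 3L, 1L, 4L))
  y <- matrix(colMeans(matrix(vp, nrow = hw)), nrow = d[1])
  ag_node(y, list(x),
          function(g) {
            gb <- array(rep(as.vector(g), each = hw) / hw,
                        dim = c(d[2], d[3], d[1], d[4]))
            list(aperm(gb, c(3L, 1L, 2L, 4L)))
          }, x$requires)
}

# ---- parameter initialization and optimizer --------------------------------

# Kaiming-style fan-in init; relies on the caller having seeded the RNG.
init_weight <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

new_linear <- function(d_in, d_out, name = "linear") {
  list(W = ag_param(init_weight(c(d_in, d_out), d_in), paste0(name, ".W")),
       b = ag_param(numeric(d_out), paste0(name, ".b")))
}

lin_fwd <- function(layer, x) ag_add_bias(ag_matmul(x, layer$W), layer$b)

new_layernorm <- function(d, name = "ln") {
  list(gamma = ag_param(rep(1, d), paste0(name, ".g")),
       beta = ag_param(numeric(d), paste0(name, ".b")))
}

collect_params <- function(x) {
  out <- list()
  walk <- function(v) {
    if (inherits(v, "ag_node")) {
      if (isTRUE(v$is_param)) out[[length(out) + 1L]] <<- v
    } else if (is.list(v)) {
      for (e in v) walk(e)
    }
  }
  walk(x)
  out
}

#' Adam optimizer state (optionally with decoupled weight decay)
#'
#' @param params list of parameter nodes.
#' @param lr learning rate.
#' @param beta1,beta2,eps standard Adam moments/fuzz.
#' @param weight_decay decoupled L2 decay rate applied multiplicatively to
#'   weight matrices/kernels (vectors — biases, norm affines, class tokens
#'   stored as vectors — are exempt, as is conventional).
#' @keywords internal
adam_new <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, weight_decay = 0) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr; st$b1 <- beta1; st$b2 <- beta2; st$eps <- eps
  st$wd <- weight_decay
  st$decay_mask <- vapply(params, function(p) {
    d <- dim(p$value)
    !is.null(d) && prod(d) > max(d)  # true matrices/kernels only
  }, logical(1))
  st$t <- 0L
  st$m <- lapply(params, function(p) array(0, dim = dim(p$value) %||% length(p$value)))
  st$v <- st$m
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(st) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$b1^st$t
  bc2 <- 1 - st$b2^st$t
  for (i in seq_along(st$params)) {
    p <- st$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    g <- as.numeric(g)
    m <- st$m[[i]] * st$b1 + (1 - st$b1) * g
    v <- st$v[[i]] * st$b2 + (1 - st$b2) * g * g
    st$m[[i]] <- m
    st$v[[i]] <- v
    upd <- (m / bc1) / (sqrt(v / bc2) + st$eps)
    p$value <- p$value - st$lr * array(upd, dim = dim(p$value) %||% length(p$value))
    if (st$wd > 0 && st$decay_mask[i]) {
      p$value <- p$value * (1 - st$lr * st$wd)
    }
  }
  invisible(st)
}

#' Run code under a local RNG seed, restoring the caller's RNG state
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
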