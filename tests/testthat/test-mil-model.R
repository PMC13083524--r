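test_that("Nystrom attention matches dense attention when landmarks cover the sequence", {
  set.seed(1)
  dense_oracle <- function(Q, K, V) {
    A <- exp(Q %*% t(K) / sqrt(ncol(Q)))
    (A / rowSums(A)) %*% V
  }
  # n = 1: softmax of a scalar is 1, output equals the value row
  q <- matrix(rnorm(4), 1)
  v <- matrix(rnorm(4), 1)
  expect_equal(nystrom_attention(q, q, v, landmarks = 4), v,
               tolerance = 1e-12)

  for (i in 1:3) {
    Q <- matrix(rnorm(32), 8, 4); K <- matrix(rnorm(32), 8, 4)
    V <- matrix(rnorm(32), 8, 4)
    expect_lt(max(abs(nystrom_attention(Q, K, V, landmarks = 8) -
                        dense_oracle(Q, K, V))), 1e-3)
    expect_lt(max(abs(nystrom_attention(Q, K, V, landmarks = 20) -
                        dense_oracle(Q, K, V))), 1e-3)
  }
  expect_error(nystrom_attention(q, q, v, landmarks = 0), "landmarks")
})

test_that("Nystrom approximation error decreases with landmark count", {
  set.seed(11)
  dense_oracle <- function(Q, K, V) {
    A <- exp(Q %*% t(K) / sqrt(ncol(Q)))
    (A / rowSums(A)) %*% V
  }
  errs <- sapply(1:20, function(i) {
    Q <- matrix(rnorm(64 * 16), 64); K <- matrix(rnorm(64 * 16), 64)
    V <- matrix(rnorm(64 * 16), 64)
    ref <- dense_oracle(Q, K, V)
    vapply(c(2, 8, 32), function(m) {
      mean(abs(nystrom_attention(Q, K, V, m) - ref))
    }, numeric(1))
  })
  m_err <- rowMeans(errs)
  expect_gt(m_err[1], m_err[2])
  expect_gt(m_err[2], m_err[3])
})

test_that("square padding repeats leading tokens up to the next square", {
  x <- matrix(rnorm(64 * 4), 64)
  sp <- square_pad(x)
  expect_equal(sp$grid_side, 8L)
  expect_equal(nrow(sp$tokens), 64L)

  x5 <- matrix(seq_len(10), 5)
  sp5 <- square_pad(x5)
  expect_equal(sp5$grid_side, 3L)
  expect_equal(nrow(sp5$tokens), 9L)
  expect_equal(sp5$tokens[6:9, ], x5[1:4, ])

  sp1 <- square_pad(matrix(1, 1, 2))
  expect_equal(sp1$grid_side, 1L)
  expect_equal(nrow(sp1$tokens), 1L)
})

test_that("PPEG is the identity at zero weights and passes the class token through", {
  D <- 4L
  tokens <- rbind(matrix(rnorm(D), 1), matrix(rnorm(9 * D), 9))
  seq9 <- token_sequence(tokens, "image", grid_side = 3L)
  out <- ppeg(seq9)  # default zero kernels
  expect_identical(out$tokens, tokens)

  # a single 3x3 kernel of ones spreads one nonzero token to its clipped
  # 8-neighborhood (plus itself via the residual + center tap)
  params <- list(k3 = dualmil:::ag_param(array(1, c(3, 3, D))),
                 k5 = dualmil:::ag_param(array(0, c(5, 5, D))),
                 k7 = dualmil:::ag_param(array(0, c(7, 7, D))))
  tok2 <- matrix(0, 10, D)
  tok2[1, ] <- 5  # class token
  tok2[1 + 5, ] <- 1  # grid cell (2, 2), the center of the 3x3 grid
  out2 <- ppeg(token_sequence(tok2, "image", 3L), params)
  expect_equal(out2$tokens[1, ], tok2[1, ])  # class token bit-identical
  inst <- out2$tokens[-1, 1]
  # conv adds 1 to all nine cells; residual keeps the original center 1
  expect_equal(inst, c(1, 1, 1, 1, 2, 1, 1, 1, 1))

  expect_error(ppeg(token_sequence(tokens, "gene")), "image")
  expect_error(token_sequence(tokens[1:8, ], "image", grid_side = 3L))
})

test_that("image bag encoding yields uniform attention for identical instances", {
  mm <- mil_model(mil_config(16L, 2L, 8L), seed = 2L)
  one <- matrix(rnorm(16), 1)
  same <- one[rep(1, 6), ]
  out <- encode_image_bag(mm, same)
  expect_length(out$bag_vector, 16L)
  expect_equal(out$attn$weights, rep(1 / 6, 6), tolerance = 1e-9)
  expect_equal(sum(out$attn$weights), 1, tolerance = 1e-9)

  for (n in c(1L, 5L, 64L)) {
    o <- encode_image_bag(mm, matrix(rnorm(n * 16), n))
    expect_length(o$bag_vector, 16L)
    expect_length(o$attn$weights, n)
    expect_equal(sum(o$attn$weights), 1, tolerance = 1e-9)
    expect_true(all(o$attn$weights >= 0))
  }
})

test_that("gene bag encoding is permutation-invariant; image branch is not", {
  mm <- mil_model(mil_config(16L, 2L, 8L), seed = 3L)
  set.seed(4)
  S <- 7L
  lat <- matrix(rnorm(S * 16), S)
  o1 <- encode_gene_bag(mm, lat)
  perm <- sample(S)
  o2 <- encode_gene_bag(mm, lat[perm, ])
  expect_equal(o2$bag_vector, o1$bag_vector, tolerance = 1e-5)
  expect_equal(o2$attn$weights, o1$attn$weights[perm], tolerance = 1e-5)

  expect_equal(encode_gene_bag(mm, lat[1, , drop = FALSE])$attn$weights, 1)
  u <- encode_gene_bag(mm, lat[rep(2, 5), ])
  expect_equal(u$attn$weights, rep(0.2, 5), tolerance = 1e-9)

  # PPEG injects grid structure: permuting patches changes the image bag
  mm$params$img$ppeg$k3$value[] <- 0.1
  imf <- matrix(rnorm(9 * 16), 9)
  b1 <- encode_image_bag(mm, imf)$bag_vector
  b2 <- encode_image_bag(mm, imf[sample(9), ])$bag_vector
  expect_gt(max(abs(b1 - b2)), 1e-6)
})

test_that("cross attention matches the dense single-query oracle", {
  D <- 16L
  mm <- mil_model(mil_config(D, 2L, 8L), seed = 5L)
  set.seed(6)
  q <- rnorm(D)
  kv <- matrix(rnorm(6 * D), 6)
  out <- cross_attend(mm, "img_kv", q, kv)
  expect_length(out$vector, D)
  expect_equal(sum(out$attn$weights), 1, tolerance = 1e-9)

  # oracle: recompute head-by-head from the projection weights
  p <- mm$params$cross_img
  qp <- matrix(q, 1) %*% p$q$W$value + as.numeric(p$q$b$value)
  kp <- sweep(kv %*% p$k$W$value, 2, as.numeric(p$k$b$value), "+")
  vp <- sweep(kv %*% p$v$W$value, 2, as.numeric(p$v$b$value), "+")
  dh <- D / 2
  att <- NULL
  wrows <- NULL
  for (h in 1:2) {
    idx <- (h - 1) * dh + seq_len(dh)
    lg <- qp[, idx, drop = FALSE] %*% t(kp[, idx, drop = FALSE]) / sqrt(dh)
    w <- exp(lg - max(lg)); w <- w / sum(w)
    att <- cbind(att, w %*% vp[, idx, drop = FALSE])
    wrows <- rbind(wrows, w)
  }
  oracle <- att %*% p$o$W$value + as.numeric(p$o$b$value)
  expect_equal(out$vector, as.numeric(oracle), tolerance = 1e-5)
  expect_equal(out$attn$weights, as.numeric(colMeans(wrows)),
               tolerance = 1e-9)

  one <- cross_attend(mm, "gene_kv", q, kv[1, , drop = FALSE])
  expect_equal(one$attn$weights, 1)
  samekv <- cross_attend(mm, "gene_kv", q, kv[rep(3, 5), ])
  expect_equal(samekv$attn$weights, rep(0.2, 5), tolerance = 1e-9)
})

test_that("fusion concatenates exactly four vectors into the classifier", {
  D <- 8L
  mm <- mil_model(mil_config(D, 2L, 4L), seed = 7L)
  vs <- lapply(1:4, function(i) rnorm(D))
  mm$params$classifier$W$value[] <- 0
  mm$params$classifier$b$value[] <- 0
  expect_equal(fuse_and_classify(mm, vs[[1]], vs[[2]], vs[[3]], vs[[4]]),
               c(0, 0))

  W <- matrix(rnorm(4 * D * 2), 4 * D, 2)
  mm$params$classifier$W$value <- W
  expect_equal(fuse_and_classify(mm, vs[[1]], vs[[2]], vs[[3]], vs[[4]]),
               as.numeric(matrix(unlist(vs), 1) %*% W), tolerance = 1e-12)
  expect_error(fuse_and_classify(mm, vs[[1]], vs[[2]], vs[[3]], rnorm(3)),
               "length D")

  out <- forward_patient(mm, matrix(rnorm(5 * D), 5),
                         matrix(rnorm(3 * D), 3))
  expect_equal(out$n_fused, 4L)
  expect_length(out$logits, 2L)
  for (r in out$attention) {
    expect_true(all(r$weights >= -1e-9))
    expect_equal(sum(r$weights), 1, tolerance = 1e-6)
  }
  mechs <- vapply(out$attention, function(r) r$mechanism, character(1))
  expect_setequal(mechs, c("self_image", "self_gene",
                           "cross_img_query_gene", "cross_gene_query_img"))
})

test_that("the self-only ablation reduces the classifier input to 2D", {
  D <- 8L
  mm <- mil_model(mil_config(D, 2L, 4L, self_only = TRUE), seed = 8L)
  expect_equal(nrow(mm$params$classifier$W$value), 2L * D)
  out <- forward_patient(mm, matrix(rnorm(4 * D), 4), matrix(rnorm(3 * D), 3))
  expect_equal(out$n_fused, 2L)
  expect_length(out$logits, 2L)
  expect_error(cross_attend(mm, "img_kv", rnorm(D), matrix(rnorm(D), 1)),
               "disabled")
})
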