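#' @title Dual-attention multimodal MIL model
#'
#' @description
#' Two transformer branches aggregate the per-patient instance sets: the
#' image branch (patch features) uses Nystrom-approximated multi-head
#' self-attention with a pyramid position encoding generator (PPEG) on the
#' squared token grid; the gene branch (gene-set latents) uses the same
#' encoder without positional encoding, making it permutation-equivariant.
#' Bidirectional cross-attention then queries each modality's instance
#' tokens with the other modality's aggregated vector, and the four
#' aggregated vectors (self-image, self-gene, cross-image, cross-gene) are
#' concatenated into a linear classifier.
#'
#' @name mil-model
NULL

#' Model configuration
#'
#' @param feature_dim shared feature dimension `D` (must match the
#'   backbone feature dimension and the gene latent dimension).
#' @param heads attention heads (default 2).
#' @param landmarks Nystrom landmark count (default 8; when landmarks >=
#'   sequence length, attention is computed densely and exactly).
#' @param self_only ablation flag: drop both cross-attention paths; the
#'   classifier then sees `2 * D` inputs.
#' @param ns_iters Newton--Schulz iterations for the landmark
#'   pseudo-inverse.
#' @return A `mil_config` list.
#' @export
mil_config <- function(feature_dim = 32L, heads = 2L, landmarks = 8L,
                       self_only = FALSE, ns_iters = 6L) {
  stopifnot(feature_dim %% heads == 0, landmarks >= 1)
  structure(list(feature_dim = as.integer(feature_dim),
                 heads = as.integer(heads),
                 landmarks = as.integer(landmarks),
                 self_only = isTRUE(self_only),
                 ns_iters = as.integer(ns_iters)),
            class = "mil_config")
}

# ---- Nystrom attention -----------------------------------------------------

landmark_matrix <- function(n, m) {
  sizes <- diff(round(seq(0, n, length.out = m + 1)))
  G <- matrix(0, m, n)
  pos <- 0L
  for (i in seq_len(m)) {
    idx <- pos + seq_len(sizes[i])
    G[i, idx] <- 1 / sizes[i]
    pos <- pos + sizes[i]
  }
  G
}

ag_pinv_ns <- function(A, iters = 6L) {
  m <- nrow(A$value)
  I <- ag_const(diag(m))
  a <- A$value
  scale <- 1 / (max(rowSums(abs(a))) * max(colSums(abs(a))))
  Z <- ag_smul(ag_t(A), scale)
  for (k in seq_len(iters)) {
    AZ <- ag_matmul(A, Z)
    T1 <- ag_sub(ag_smul(I, 7), AZ)
    T2 <- ag_sub(ag_smul(I, 15), ag_matmul(AZ, T1))
    T3 <- ag_sub(ag_smul(I, 13), ag_matmul(AZ, T2))
    Z <- ag_smul(ag_matmul(Z, T3), 0.25)
  }
  Z
}

ag_dense_attention <- function(Q, K, V, scale) {
  A <- ag_softmax_rows(ag_smul(ag_matmul(Q, ag_t(K)), scale))
  ag_matmul(A, V)
}

ag_nystrom_attention <- function(Q, K, V, m, ns_iters = 6L) {
  n <- nrow(Q$value)
  d <- ncol(Q$value)
  scale <- 1 / sqrt(d)
  if (m >= n) return(ag_dense_attention(Q, K, V, scale))
  G <- ag_const(landmark_matrix(n, m))
  Qm <- ag_matmul(G, Q)
  Km <- ag_matmul(G, K)
  F1 <- ag_softmax_rows(ag_smul(ag_matmul(Q, ag_t(Km)), scale))
  F2 <- ag_softmax_rows(ag_smul(ag_matmul(Qm, ag_t(Km)), scale))
  F3 <- ag_softmax_rows(ag_smul(ag_matmul(Qm, ag_t(K)), scale))
  ag_matmul(F1, ag_matmul(ag_pinv_ns(F2, ns_iters), ag_matmul(F3, V)))
}

#' Nystrom-approximated softmax attention
#'
#' Landmark-based low-rank approximation of
#' `softmax(Q K' / sqrt(d)) V` using `landmarks` segment-mean landmarks
#' and an iteratively computed (Newton--Schulz) pseudo-inverse of the
#' landmark kernel. When `landmarks >= nrow(Q)` the computation falls back
#' to exact dense attention.
#'
#' @param Q,K,V `n x d` matrices.
#' @param landmarks number of landmarks (`m >= 1`).
#' @param ns_iters pseudo-inverse iterations.
#' @return `n x d` matrix.
#' @export
nystrom_attention <- function(Q, K, V, landmarks, ns_iters = 6L) {
  if (landmarks < 1) stop("landmarks must be >= 1")
  out <- ag_nystrom_attention(ag_const(as.matrix(Q)), ag_const(as.matrix(K)),
                              ag_const(as.matrix(V)), landmarks, ns_iters)
  out$value
}

# ---- token utilities -------------------------------------------------------

#' Square-pad an instance token matrix
#'
#' Pads `N` instance tokens to the next perfect square `M = ceiling(
#' sqrt(N))^2` by repeating the first `M - N` tokens (appended at the
#' end), recording the grid side for the PPEG convolutions.
#'
#' @param instances `N x D` matrix.
#' @return List with `tokens` (`M x D`), `grid_side`, `n_real`.
#' @export
square_pad <- function(instances) {
  instances <- as.matrix(instances)
  n <- nrow(instances)
  stopifnot(n >= 1)
  g <- ceiling(sqrt(n))
  m <- g * g
  tokens <- if (m > n) {
    rbind(instances, instances[seq_len(m - n), , drop = FALSE])
  } else instances
  list(tokens = tokens, grid_side = as.integer(g), n_real = as.integer(n))
}

#' Token sequence container
#'
#' @param tokens `(1 + N) x D` matrix, class token first.
#' @param modality `"image"` or `"gene"`.
#' @param grid_side integer grid side (image branch) or NA.
#' @param n_real number of non-padded instance tokens.
#' @return A `token_sequence`.
#' @export
token_sequence <- function(tokens, modality = c("image", "gene"),
                           grid_side = NA_integer_, n_real = nrow(tokens) - 1L) {
  modality <- match.arg(modality)
  if (modality == "image") {
    stopifnot(!is.na(grid_side),
              nrow(tokens) - 1L == grid_side^2)
  }
  structure(list(tokens = tokens, modality = modality,
                 grid_side = as.integer(grid_side),
                 n_real = as.integer(n_real)),
            class = "token_sequence")
}

# ---- PPEG ------------------------------------------------------------------

new_ppeg <- function(D, seed_done = TRUE) {
  list(k3 = ag_param(array(0, dim = c(3, 3, D)), "ppeg.k3"),
       k5 = ag_param(array(0, dim = c(5, 5, D)), "ppeg.k5"),
       k7 = ag_param(array(0, dim = c(7, 7, D)), "ppeg.k7"))
}

ag_ppeg <- function(tokens, grid_side, params) {
  # tokens: (1 + g^2) x D node; instance rows laid out row-major on the grid
  D <- ncol(tokens$value)
  g <- grid_side
  cls <- ag_rows(tokens, 1L)
  inst <- ag_rows(tokens, 1L + seq_len(g * g))
  # row-major grid: token r = (i-1)*g + j -> cell (i, j); array reshape is
  # column-major so build (g, g, 1, D) from transposed layout: token index
  # varies j fastest within i. Reshape to (g[j], g[i]) then transpose dims.
  grid <- ag_reshape(inst, c(g, g, 1L, D))        # dims (j, i, 1, D)
  grid <- ag_node(aperm(grid$value, c(3L, 2L, 1L, 4L)), list(grid),
                  function(gr) list(aperm(gr, c(3L, 2L, 1L, 4L))),
                  grid$requires)                  # (1, i, j, D)
  s3 <- ag_dwconv2d(grid, params$k3, b = NULL, stride = 1L)
  s5 <- ag_dwconv2d(grid, params$k5, b = NULL, stride = 1L)
  s7 <- ag_dwconv2d(grid, params$k7, b = NULL, stride = 1L)
  out <- ag_add(grid, ag_add(s3, ag_add(s5, s7)))
  flat <- ag_node(aperm(out$value, c(3L, 2L, 1L, 4L)), list(out),
                  function(gr) list(aperm(gr, c(3L, 2L, 1L, 4L))),
                  out$requires)
  flat <- ag_reshape(flat, c(g * g, D))
  ag_vcat(cls, flat)
}

#' Pyramid position encoding generator
#'
#' Reshapes the instance tokens onto their square grid, applies three
#' same-padded depthwise convolutions (kernels 3, 5, 7), and adds their sum
#' residually; the class token passes through unchanged. With all kernel
#' weights zero this is the identity.
#'
#' @param seq a [token_sequence()] with `modality = "image"`.
#' @param params PPEG parameters (three `(k, k, D)` arrays, e.g. from a
#'   model's `$params$img$ppeg`); defaults to zero kernels.
#' @return A `token_sequence` with updated tokens.
#' @export
ppeg <- function(seq, params = NULL) {
  stopifnot(inherits(seq, "token_sequence"))
  if (seq$modality != "image") stop("ppeg applies to the image branch only")
  n_inst <- nrow(seq$tokens) - 1L
  g <- seq$grid_side
  if (g * g != n_inst) stop("instance count is not a perfect square; pad first")
  D <- ncol(seq$tokens)
  if (is.null(params)) params <- new_ppeg(D)
  out <- ag_ppeg(ag_const(seq$tokens), g, params)
  token_sequence(out$value, "image", g, seq$n_real)
}

# ---- multi-head attention blocks -------------------------------------------

new_msa <- function(D, name) {
  list(q = new_linear(D, D, paste0(name, ".q")),
       k = new_linear(D, D, paste0(name, ".k")),
       v = new_linear(D, D, paste0(name, ".v")),
       o = new_linear(D, D, paste0(name, ".o")),
       ln = new_layernorm(D, paste0(name, ".ln")))
}

head_slices <- function(D, heads) {
  dh <- D %/% heads
  lapply(seq_len(heads), function(h) (h - 1L) * dh + seq_len(dh))
}

# pre-LN residual multi-head self-attention; optionally returns the exact
# class-token attention row (head-averaged) computed densely for reporting.
msa_block <- function(msa, x, cfg, record_cls = FALSE) {
  xn <- ag_layernorm(x, msa$ln$gamma, msa$ln$beta)
  Q <- lin_fwd(msa$q, xn)
  K <- lin_fwd(msa$k, xn)
  V <- lin_fwd(msa$v, xn)
  slices <- head_slices(cfg$feature_dim, cfg$heads)
  outs <- vector("list", cfg$heads)
  cls_rows <- NULL
  for (h in seq_len(cfg$heads)) {
    Qh <- ag_cols(Q, slices[[h]])
    Kh <- ag_cols(K, slices[[h]])
    Vh <- ag_cols(V, slices[[h]])
    outs[[h]] <- ag_nystrom_attention(Qh, Kh, Vh, cfg$landmarks, cfg$ns_iters)
    if (record_cls) {
      dh <- length(slices[[h]])
      logits <- (Qh$value[1, , drop = FALSE] %*% t(Kh$value)) / sqrt(dh)
      w <- exp(logits - max(logits))
      cls_rows <- rbind(cls_rows, w / sum(w))
    }
  }
  att <- do.call(ag_hcat, outs)
  y <- ag_add(x, lin_fwd(msa$o, att))
  list(x = y, cls_attention = if (record_cls) colMeans(cls_rows) else NULL)
}

#' Attention record
#'
#' @param mechanism one of `self_image`, `self_gene`,
#'   `cross_img_query_gene`, `cross_gene_query_img`.
#' @param weights non-negative weights over real instances, summing to 1.
#' @param head_count number of heads averaged.
#' @return An `attention_record`.
#' @export
attention_record <- function(mechanism, weights, head_count) {
  stopifnot(mechanism %in% c("self_image", "self_gene",
                             "cross_img_query_gene", "cross_gene_query_img"))
  w <- as.numeric(weights)
  if (any(w < -1e-9)) stop("attention weights must be non-negative")
  structure(list(mechanism = mechanism, weights = w,
                 head_count = as.integer(head_count)),
            class = "attention_record")
}

# shared self-attention encoder: class token -> block -> (ppeg) -> block ->
# final layer norm; exports the final block's class-token row over real
# instances (head-averaged, renormalized after excluding padding).
encode_branch <- function(branch, feats, cfg, image = TRUE) {
  feats <- as_node(feats)
  n_real <- nrow(feats$value)
  if (image) {
    sp <- square_pad(feats$value)
    g <- sp$grid_side
    if (nrow(sp$tokens) > n_real) {
      feats <- ag_vcat(feats, ag_rows(feats, seq_len(nrow(sp$tokens) - n_real)))
    }
  }
  x <- ag_vcat(branch$cls, feats)
  b1 <- msa_block(branch$msa1, x, cfg, record_cls = FALSE)
  x <- b1$x
  if (image) x <- ag_ppeg(x, g, branch$ppeg)
  b2 <- msa_block(branch$msa2, x, cfg, record_cls = TRUE)
  x <- ag_layernorm(b2$x, branch$ln_out$gamma, branch$ln_out$beta)
  bag <- ag_rows(x, 1L)
  w <- b2$cls_attention[1L + seq_len(n_real)]  # drop cls + padded positions
  w <- w / sum(w)
  rec <- attention_record(if (image) "self_image" else "self_gene",
                          w, cfg$heads)
  seq_out <- token_sequence(x$value, if (image) "image" else "gene",
                            grid_side = if (image) g else NA_integer_,
                            n_real = n_real)
  list(bag_vector = bag, seq = seq_out, attn = rec, tokens = x)
}

# single-query multi-head cross attention over the other modality's
# pre-aggregation instance tokens.
cross_block <- function(cross, query_vec, kv, cfg, mechanism) {
  if (nrow(kv$value) < 1L) stop("empty key/value sequence")
  q <- lin_fwd(cross$q, query_vec)       # 1 x D
  K <- lin_fwd(cross$k, kv)
  V <- lin_fwd(cross$v, kv)
  slices <- head_slices(cfg$feature_dim, cfg$heads)
  outs <- vector("list", cfg$heads)
  wrows <- NULL
  for (h in seq_len(cfg$heads)) {
    qh <- ag_cols(q, slices[[h]])
    Kh <- ag_cols(K, slices[[h]])
    Vh <- ag_cols(V, slices[[h]])
    A <- ag_softmax_rows(ag_smul(ag_matmul(qh, ag_t(Kh)),
                                 1 / sqrt(length(slices[[h]]))))
    outs[[h]] <- ag_matmul(A, Vh)
    wrows <- rbind(wrows, A$value)
  }
  vec <- lin_fwd(cross$o, do.call(ag_hcat, outs))
  list(vector = vec,
       attn = attention_record(mechanism, colMeans(wrows), cfg$heads))
}

#' Construct the dual-attention MIL model
#'
#' @param config a [mil_config()].
#' @param seed parameter initialization seed.
#' @return A `mil_model` holding all parameter nodes.
#' @export
mil_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "mil_config"))
  D <- config$feature_dim
  with_seed(seed, {
    params <- list(
      img = list(cls = ag_param(matrix(stats::rnorm(D, sd = 0.02), 1, D),
                                "img.cls"),
                 msa1 = new_msa(D, "img.msa1"),
                 msa2 = new_msa(D, "img.msa2"),
                 ppeg = new_ppeg(D),
                 ln_out = new_layernorm(D, "img.ln_out")),
      gene = list(cls = ag_param(matrix(stats::rnorm(D, sd = 0.02), 1, D),
                                 "gene.cls"),
                  msa1 = new_msa(D, "gene.msa1"),
                  msa2 = new_msa(D, "gene.msa2"),
                  ln_out = new_layernorm(D, "gene.ln_out"))
    )
    if (!config$self_only) {
      params$cross_img <- list(q = new_linear(D, D, "ci.q"),
                               k = new_linear(D, D, "ci.k"),
                               v = new_linear(D, D, "ci.v"),
                               o = new_linear(D, D, "ci.o"))
      params$cross_gene <- list(q = new_linear(D, D, "cg.q"),
                                k = new_linear(D, D, "cg.k"),
                                v = new_linear(D, D, "cg.v"),
                                o = new_linear(D, D, "cg.o"))
    }
    n_in <- if (config$self_only) 2L * D else 4L * D
    params$classifier <- new_linear(n_in, 2L, "clf")
    structure(list(config = config, params = params), class = "mil_model")
  })
}

#' Aggregate an image bag with the self-attention encoder
#'
#' Class token, Nystrom attention block, PPEG on the squared grid, second
#' attention block, final normalization. The bag vector is the final class
#' token; the attention record is the final block's class-token row over
#' the real (non-padded) instances, head-averaged and renormalized.
#'
#' @param model a [mil_model()].
#' @param features `N x D` patch feature matrix.
#' @return List with `bag_vector` (length D), `seq` (a
#'   [token_sequence()]), `attn` (an [attention_record()]).
#' @export
encode_image_bag <- function(model, features) {
  out <- encode_branch(model$params$img, ag_const(as.matrix(features)),
                       model$config, image = TRUE)
  list(bag_vector = as.numeric(out$bag_vector$value), seq = out$seq,
       attn = out$attn)
}

#' Aggregate gene-set latents with the positional-encoding-free encoder
#'
#' Same as [encode_image_bag()] but without PPEG or square padding, so the
#' bag vector is invariant to gene-set order and the attention weights are
#' equivariant to it.
#'
#' @param model a [mil_model()].
#' @param latents `S x D` gene-set latent matrix.
#' @return List with `bag_vector`, `seq`, `attn`.
#' @export
encode_gene_bag <- function(model, latents) {
  out <- encode_branch(model$params$gene, ag_const(as.matrix(latents)),
                       model$config, image = FALSE)
  list(bag_vector = as.numeric(out$bag_vector$value), seq = out$seq,
       attn = out$attn)
}

#' Single-query cross attention over the other modality's instances
#'
#' @param model a [mil_model()].
#' @param direction `"img_kv"` (image tokens as keys/values, gene bag
#'   vector as query) or `"gene_kv"` (the reverse).
#' @param query_vec length-D aggregated query vector.
#' @param kv `n x D` instance token matrix of the other modality.
#' @return List with `vector` (length D) and `attn`.
#' @export
cross_attend <- function(model, direction = c("img_kv", "gene_kv"),
                         query_vec, kv) {
  direction <- match.arg(direction)
  if (model$config$self_only) stop("cross attention disabled (self_only)")
  cr <- if (direction == "img_kv") model$params$cross_img else
    model$params$cross_gene
  mech <- if (direction == "img_kv") "cross_img_query_gene" else
    "cross_gene_query_img"
  out <- cross_block(cr, ag_const(matrix(query_vec, 1L)),
                     ag_const(as.matrix(kv)), model$config, mech)
  list(vector = as.numeric(out$vector$value), attn = out$attn)
}

#' Concatenate the aggregated vectors and classify
#'
#' Concatenation order: self-image, self-gene, cross-image, cross-gene
#' (the two cross vectors are omitted under the `self_only` ablation).
#'
#' @param model a [mil_model()].
#' @param vec_self_image,vec_self_gene,vec_cross_image,vec_cross_gene
#'   length-D vectors.
#' @return Length-2 logits.
#' @export
fuse_and_classify <- function(model, vec_self_image, vec_self_gene,
                              vec_cross_image = NULL, vec_cross_gene = NULL) {
  D <- model$config$feature_dim
  vs <- if (model$config$self_only) {
    list(vec_self_image, vec_self_gene)
  } else {
    list(vec_self_image, vec_self_gene, vec_cross_image, vec_cross_gene)
  }
  for (v in vs) {
    if (is.null(v) || length(v) != D) stop("each fused vector must have length D")
  }
  z <- matrix(unlist(vs), nrow = 1L)
  as.numeric(z %*% model$params$classifier$W$value +
               as.numeric(model$params$classifier$b$value))
}

# full differentiable forward pass for one patient; img_feats may be a node
# (end-to-end training through the backbone) or a plain matrix.
mil_forward <- function(model, img_feats, gene_feats) {
  cfg <- model$config
  img_feats <- as_node(as_if_matrix(img_feats))
  gene_feats <- as_node(as_if_matrix(gene_feats))
  io <- encode_branch(model$params$img, img_feats, cfg, image = TRUE)
  go <- encode_branch(model$params$gene, gene_feats, cfg, image = FALSE)
  records <- list(io$attn, go$attn)
  if (cfg$self_only) {
    z <- ag_hcat(io$bag_vector, go$bag_vector)
    vecs <- list(vec_self_image = as.numeric(io$bag_vector$value),
                 vec_self_gene = as.numeric(go$bag_vector$value),
                 vec_cross_image = NULL, vec_cross_gene = NULL)
  } else {
    ci <- cross_block(model$params$cross_img, go$bag_vector, img_feats, cfg,
                      "cross_img_query_gene")
    cg <- cross_block(model$params$cross_gene, io$bag_vector, gene_feats, cfg,
                      "cross_gene_query_img")
    records <- c(records, list(ci$attn, cg$attn))
    z <- ag_hcat(io$bag_vector, go$bag_vector, ci$vector, cg$vector)
    vecs <- list(vec_self_image = as.numeric(io$bag_vector$value),
                 vec_self_gene = as.numeric(go$bag_vector$value),
                 vec_cross_image = as.numeric(ci$vector$value),
                 vec_cross_gene = as.numeric(cg$vector$value))
  }
  logits <- lin_fwd(model$params$classifier, z)
  structure(c(vecs, list(logits = logits, attention = records,
                         n_fused = length(Filter(Negate(is.null), vecs)))),
            class = "fusion_output")
}

as_if_matrix <- function(x) {
  if (inherits(x, "ag_node")) return(x)
  as.matrix(x)
}

#' Forward one patient and return the fused output
#'
#' @param model a [mil_model()].
#' @param img_feats `N x D` patch features.
#' @param gene_feats `S x D` gene-set latents.
#' @return A `fusion_output`: the four aggregated vectors, length-2 logits
#'   and all attention records.
#' @export
forward_patient <- function(model, img_feats, gene_feats) {
  out <- mil_forward(model, as.matrix(img_feats), as.matrix(gene_feats))
  out$logits <- as.numeric(out$logits$value)
  out
}
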