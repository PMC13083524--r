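#' Gene-set definition
#'
#' @param set_id identifier (e.g. a GO term or KEGG pathway id).
#' @param member_genes character vector of member gene ids (non-empty,
#'   unique).
#' @param padj adjusted p-value of the set from upstream enrichment
#'   analysis, in `[0, 1]`.
#' @param source one of `"GO"`, `"KEGG"`, `"synthetic"`.
#' @param description free-text description (kept for GMT round-trips).
#' @return A `gene_set` object.
#' @export
gene_set_definition <- function(set_id, member_genes, padj = NA_real_,
                                source = c("synthetic", "GO", "KEGG"),
                                description = "") {
  source <- match.arg(source)
  member_genes <- as.character(member_genes)
  if (length(member_genes) == 0L) stop("member_genes must be non-empty")
  if (anyDuplicated(member_genes)) stop("member_genes must be unique")
  structure(list(set_id = set_id, source = source,
                 member_genes = member_genes, padj = padj,
                 description = description),
            class = "gene_set")
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then member gene ids.
#'
#' @param path file path.
#' @param padj optional named vector or data.frame (`set_id`, `padj`) to
#'   attach adjusted p-values.
#' @param source label for the sets.
#' @return List of `gene_set` objects.
#' @export
read_gmt <- function(path, padj = NULL, source = "synthetic") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (is.data.frame(padj)) {
    padj <- stats::setNames(padj$padj, padj$set_id)
  }
  lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 50))
    p <- if (!is.null(padj) && f[1] %in% names(padj)) padj[[f[1]]] else NA_real_
    gene_set_definition(f[1], f[-(1:2)], padj = p, source = source,
                        description = f[2])
  })
}

#' Write gene sets to a GMT file
#' @param sets list of `gene_set` objects.
#' @param path file path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$set_id, s$description, s$member_genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Keep significantly enriched gene sets
#'
#' Retains sets whose adjusted p-value is strictly below `alpha`
#' (default 0.01), preserving input order.
#'
#' @param sets list of `gene_set` objects with `padj` present.
#' @param alpha significance threshold.
#' @return Filtered list.
#' @export
select_significant <- function(sets, alpha = 0.01) {
  keep <- vapply(sets, function(s) {
    if (is.na(s$padj)) stop(sprintf("set %s has no adjusted p-value", s$set_id))
    s$padj < alpha
  }, logical(1))
  sets[keep]
}

#' TPM normalization with log2 scaling
#'
#' Per patient: counts are divided by gene length in kilobases, scaled so
#' the column sums to one million (transcripts per million), and
#' log2-transformed with a pseudocount. All-zero patient columns stay zero
#' (with a warning) since TPM is undefined there.
#'
#' @param counts genes x patients non-negative matrix with gene rownames.
#' @param lengths_bp per-gene lengths in base pairs (named vector aligned
#'   to, or named like, the count rows).
#' @param pseudocount added before the log (default 1, keeping zeros at
#'   zero).
#' @return Matrix of `log2(TPM + pseudocount)` values, same shape.
#' @export
tpm_log <- function(counts, lengths_bp, pseudocount = 1.0) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths_bp)) && !is.null(rownames(counts))) {
    lengths_bp <- lengths_bp[rownames(counts)]
  }
  if (length(lengths_bp) != nrow(counts)) {
    stop("lengths_bp must align with the count rows")
  }
  if (any(lengths_bp <= 0)) stop("gene lengths must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  rate <- counts / (lengths_bp / 1000)
  csum <- colSums(rate)
  zero <- csum == 0
  if (any(zero)) {
    warning(sprintf("%d patient column(s) have all-zero counts; left as zero",
                    sum(zero)))
    csum[zero] <- 1
  }
  tpm <- sweep(rate, 2L, csum, "/") * 1e6
  tpm[, zero] <- 0
  out <- log2(tpm + pseudocount)
  out[, zero] <- 0
  dimnames(out) <- dimnames(counts)
  out
}

#' Build one patient's zero-padded gene-set tensor
#'
#' Row i holds the expression of set i's member genes in their GMT order,
#' right-padded with zeros to the maximum set size; the binary mask marks
#' real entries. Padded cells are artificial and are excluded from the
#' autoencoder loss via [masked_mse()].
#'
#' @param expr_column named per-gene expression values (one patient).
#' @param sets list of `gene_set` objects.
#' @param patient_id carried on the result.
#' @return A `geneset_tensor` with `values` (S x P) and `mask` (S x P).
#' @export
build_geneset_tensor <- function(expr_column, sets, patient_id = "unknown") {
  stopifnot(length(sets) >= 1)
  sizes <- vapply(sets, function(s) length(s$member_genes), integer(1))
  P <- max(sizes)
  S <- length(sets)
  values <- matrix(0, S, P)
  mask <- matrix(0L, S, P)
  for (i in seq_len(S)) {
    gs <- sets[[i]]$member_genes
    missing <- setdiff(gs, names(expr_column))
    if (length(missing) > 0L) {
      stop(sprintf("unknown gene id(s) %s in set %s",
                   paste(missing, collapse = ", "), sets[[i]]$set_id))
    }
    values[i, seq_along(gs)] <- expr_column[gs]
    mask[i, seq_along(gs)] <- 1L
  }
  rownames(values) <- rownames(mask) <-
    vapply(sets, function(s) s$set_id, character(1))
  structure(list(patient_id = patient_id, values = values, mask = mask),
            class = "geneset_tensor")
}

#' Masked mean squared error
#'
#' `sum(mask * (x - xhat)^2) / sum(mask)`: the reconstruction error over
#' real (non-padded) entries only, so padded values can never influence the
#' loss or its gradients.
#'
#' @param x,xhat equal-shaped numeric matrices.
#' @param mask binary matrix of the same shape with at least one 1.
#' @return Scalar loss.
#' @export
masked_mse <- function(x, xhat, mask) {
  stopifnot(all(dim(x) == dim(xhat)), all(dim(x) == dim(mask)))
  m <- sum(mask)
  if (m == 0) stop("mask has no active entries")
  sum(mask * (x - xhat)^2) / m
}

# tape version used during training (x and mask are constants)
ag_masked_mse <- function(x_const, xhat, mask_const) {
  d <- ag_mul(ag_sub(ag_const(x_const), xhat), ag_const(mask_const))
  ag_smul(ag_sum(ag_mul(d, d)), 1 / sum(mask_const))
}

#' Train the gene-set autoencoder
#'
#' One shared two-layer autoencoder (`P -> hidden -> D` encoder and mirror
#' decoder, tanh nonlinearities) is fit across all sets and patients on the
#' zero-padded rows, minimizing the masked MSE so padding reconstructs
#' freely. The latent layer itself is tanh-bounded, keeping the gene-set
#' features on the `[-1, 1]` scale the attention modules expect. The
#' latent dimension `D` matches the image-branch feature dimension.
#' Training is full-batch Adam and deterministic under the seed.
#'
#' @param tensors list of `geneset_tensor`s sharing the padded width.
#' @param latent_dim latent dimension `D`.
#' @param hidden hidden width (default 256).
#' @param epochs,lr optimization settings.
#' @param seed integer.
#' @return An `autoencoder` list with encoder/decoder layers, the loss
#'   trace and the padded width.
#' @export
train_autoencoder <- function(tensors, latent_dim, hidden = 256L,
                              epochs = 100L, lr = 1e-2, seed = 1L) {
  stopifnot(length(tensors) >= 1)
  P <- ncol(tensors[[1]]$values)
  for (tn in tensors) {
    if (ncol(tn$values) != P) stop("tensors must share the padded width")
  }
  if (latent_dim >= P) {
    warning(sprintf("latent_dim %d >= padded width %d: no compression",
                    latent_dim, P))
  }
  # padded entries are excluded from the loss and zeroed on the way in, so
  # they cannot influence activations, loss or gradients
  M <- do.call(rbind, lapply(tensors, function(tn) tn$mask))
  X <- do.call(rbind, lapply(tensors, function(tn) tn$values)) * M
  ae <- with_seed(seed, list(
    enc1 = new_linear(P, hidden, "ae.enc1"),
    enc2 = new_linear(hidden, latent_dim, "ae.enc2"),
    dec1 = new_linear(latent_dim, hidden, "ae.dec1"),
    dec2 = new_linear(hidden, P, "ae.dec2")
  ))
  params <- collect_params(ae)
  opt <- adam_new(params, lr = lr)
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ag_zero_grad(params)
    z <- ag_tanh(lin_fwd(ae$enc1, ag_const(X)))
    z <- ag_tanh(lin_fwd(ae$enc2, z))
    y <- ag_tanh(lin_fwd(ae$dec1, z))
    y <- lin_fwd(ae$dec2, y)
    loss <- ag_masked_mse(X, y, M)
    ag_backward(loss)
    adam_step(opt)
    trace[ep] <- loss$value
  }
  structure(list(layers = ae, latent_dim = as.integer(latent_dim),
                 input_width = as.integer(P), loss_trace = trace),
            class = "autoencoder")
}

#' Encode a gene-set tensor into latent features
#'
#' Applies the trained encoder row-wise: S padded set rows in, S latent
#' D-vectors out, preserving row order.
#'
#' @param encoder an [train_autoencoder()] result.
#' @param tensor a `geneset_tensor` with matching padded width.
#' @return A `gene_latent` with `features` (S x D matrix).
#' @export
encode_genesets <- function(encoder, tensor) {
  stopifnot(inherits(encoder, "autoencoder"),
            inherits(tensor, "geneset_tensor"))
  if (ncol(tensor$values) != encoder$input_width) {
    stop(sprintf("tensor width %d does not match encoder width %d",
                 ncol(tensor$values), encoder$input_width))
  }
  z <- tanh(sweep((tensor$values * tensor$mask) %*%
                    encoder$layers$enc1$W$value, 2L,
                  as.numeric(encoder$layers$enc1$b$value), "+"))
  z <- tanh(sweep(z %*% encoder$layers$enc2$W$value, 2L,
                  as.numeric(encoder$layers$enc2$b$value), "+"))
  rownames(z) <- rownames(tensor$values)
  structure(list(patient_id = tensor$patient_id, features = z),
            class = "gene_latent")
}

#' Full gene branch: counts to per-patient latents
#'
#' Convenience chain: select significant sets, TPM/log2 normalize, build
#' per-patient padded tensors, train the shared masked-MSE autoencoder and
#' encode everyone.
#'
#' @param counts genes x patients matrix.
#' @param lengths_bp per-gene lengths.
#' @param sets list of `gene_set` objects with `padj`.
#' @param alpha significance threshold on `padj`.
#' @param latent_dim latent dimension `D`.
#' @param epochs,lr,hidden,seed autoencoder settings.
#' @return List with `latents` (named list of `gene_latent`),
#'   `autoencoder`, `sets_used`.
#' @export
gene_branch <- function(counts, lengths_bp, sets, alpha = 0.01,
                        latent_dim = 32L, epochs = 100L, lr = 1e-2,
                        hidden = 256L, seed = 1L) {
  sig <- select_significant(sets, alpha)
  if (length(sig) == 0L) stop("no gene set passes the significance filter")
  expr <- tpm_log(counts, lengths_bp)
  tensors <- lapply(colnames(counts), function(pid) {
    build_geneset_tensor(expr[, pid], sig, patient_id = pid)
  })
  names(tensors) <- colnames(counts)
  ae <- train_autoencoder(tensors, latent_dim, hidden = hidden,
                          epochs = epochs, lr = lr, seed = seed)
  latents <- lapply(tensors, function(tn) encode_genesets(ae, tn))
  list(latents = latents, autoencoder = ae, sets_used = sig,
       tensors = tensors)
}
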