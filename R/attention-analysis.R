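#' Attention table container
#'
#' Patients x gene-sets matrix of aggregated attention weights with
#' per-patient labels; each row sums to one.
#'
#' @param weights patients x sets matrix with dimnames.
#' @param labels named 0/1 vector aligned with the rows.
#' @param mechanism `"self_gene"` or `"cross_gene_query_img"`.
#' @param warning_flags optional character vector of metadata notes.
#' @return An `attention_table`.
#' @export
attention_table <- function(weights, labels,
                            mechanism = c("self_gene",
                                          "cross_gene_query_img"),
                            warning_flags = character(0)) {
  mechanism <- match.arg(mechanism)
  weights <- as.matrix(weights)
  stopifnot(!is.null(rownames(weights)), !is.null(colnames(weights)))
  if (any(abs(rowSums(weights) - 1) > 1e-6)) {
    stop("attention rows must sum to 1")
  }
  labels <- labels[rownames(weights)]
  stopifnot(all(labels %in% c(0L, 1L)), !anyNA(labels))
  structure(list(weights = weights, labels = labels, mechanism = mechanism,
                 warning_flags = warning_flags),
            class = "attention_table")
}

#' Collect per-patient gene-set attention weights from a model
#'
#' Runs the forward pass for each patient and extracts the requested
#' mechanism's weights over gene sets (head-averaged, final attention
#' block, renormalized), one row per patient.
#'
#' @param model,backbone trained networks.
#' @param bags,gene_latents named lists covering `patient_ids`.
#' @param labels named 0/1 vector.
#' @param patient_ids patients to include (e.g. the test split).
#' @param mechanism `"self_gene"` or `"cross_gene_query_img"`.
#' @param trained set FALSE to record an untrained-model warning in the
#'   table metadata.
#' @return An [attention_table()].
#' @export
collect_attention <- function(model, backbone, bags, gene_latents, labels,
                              patient_ids = names(bags),
                              mechanism = c("self_gene",
                                            "cross_gene_query_img"),
                              trained = TRUE) {
  mechanism <- match.arg(mechanism)
  rows <- lapply(patient_ids, function(p) {
    feats <- backbone_forward(backbone,
                              ag_const(bag_to_array(bags[[p]])))$value
    out <- forward_patient(model, feats, gene_latents[[p]]$features)
    rec <- Find(function(r) r$mechanism == mechanism, out$attention)
    if (is.null(rec)) stop("mechanism not present in forward output")
    w <- rec$weights
    w / sum(w)
  })
  W <- do.call(rbind, rows)
  rownames(W) <- patient_ids
  colnames(W) <- rownames(gene_latents[[patient_ids[1]]]$features) %||%
    sprintf("SET%03d", seq_len(ncol(W)))
  flags <- if (!trained) "untrained_model" else character(0)
  attention_table(W, labels, mechanism, warning_flags = flags)
}

#' Mann--Whitney U test between two groups
#'
#' Rank-sum U statistic with an exact p-value for small groups (both
#' n < 8, no ties) and the tie-corrected normal approximation otherwise,
#' via [stats::wilcox.test()]. The returned `U` counts pairs where group A
#' exceeds group B.
#'
#' @param group_a,group_b non-empty numeric vectors.
#' @return List with `U` and `p` (two-sided).
#' @export
mwu <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be non-empty")
  }
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- length(group_a) < 8 && length(group_b) < 8 && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = !exact))
  list(U = unname(ht$statistic), p = unname(ht$p.value))
}

#' Benjamini--Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (`p * m / rank` with a cumulative minimum
#' from the largest p), order-preserving on ranks and never below the raw
#' p-value.
#'
#' @param p_values vector in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
fdr_bh <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH")
}

#' Test every gene set's attention for a class difference
#'
#' Mann--Whitney U per set comparing class-1 and class-0 patients, BH-FDR
#' correction, significance at `p_fdr < alpha`, and an optional seeded
#' label-permutation check for the significant sets.
#'
#' @param table an [attention_table()].
#' @param alpha FDR significance threshold (default 0.01).
#' @param n_perm permutations for the follow-up check (0 to skip).
#' @param seed integer for the permutation draw.
#' @return data.frame: `set_id`, `u_statistic`, `p_raw`, `p_fdr`,
#'   `significant`, `perm_p` (NA where not tested).
#' @export
significance_analysis <- function(table, alpha = 0.01, n_perm = 999L,
                                  seed = 1L) {
  stopifnot(inherits(table, "attention_table"))
  W <- table$weights
  lab <- table$labels
  res <- lapply(colnames(W), function(s) {
    m <- mwu(W[lab == 1L, s], W[lab == 0L, s])
    data.frame(set_id = s, u_statistic = m$U, p_raw = m$p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_fdr <- fdr_bh(res$p_raw)
  res$significant <- res$p_fdr < alpha
  res$perm_p <- NA_real_
  if (n_perm > 0L) {
    for (i in which(res$significant)) {
      res$perm_p[i] <- permutation_check(table, res$set_id[i],
                                         n_perm = n_perm,
                                         seed = seed_mix(seed, i))
    }
  }
  res
}

#' Label-permutation check for one gene set
#'
#' Shuffles patient labels while keeping the attention values fixed and
#' recomputes the absolute difference in group mean attention; the
#' permutation p-value is `(1 + #(perm >= observed)) / (n_perm + 1)`.
#'
#' @param table an [attention_table()].
#' @param set_id column to test.
#' @param n_perm number of permutations (values below 100 warn).
#' @param seed integer.
#' @return Permutation p-value.
#' @export
permutation_check <- function(table, set_id, n_perm = 999L, seed = 1L) {
  stopifnot(inherits(table, "attention_table"))
  if (n_perm < 100L) warning("fewer than 100 permutations is unreliable")
  w <- table$weights[, set_id]
  lab <- table$labels
  obs <- abs(mean(w[lab == 1L]) - mean(w[lab == 0L]))
  with_seed(seed_mix(seed, 67867967), {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      pl <- sample(lab)
      st <- abs(mean(w[pl == 1L]) - mean(w[pl == 0L]))
      if (st >= obs - 1e-15) hits <- hits + 1L
    }
    (1 + hits) / (n_perm + 1)
  })
}

#' Paint patch attention weights onto a slide-shaped canvas
#'
#' Weights are min-max scaled to `[0, 1]` and written into each patch's
#' grid cell (background 0); the top patch is the argmax weight with ties
#' broken by lowest `(row, col)`.
#'
#' @param bag a `patch_bag`.
#' @param attn an [attention_record()] with one weight per patch.
#' @param slide_shape `(height, width)` of the canvas.
#' @return List with `heatmap` (matrix) and `top_patch`
#'   (`c(row_index, col_index)`, 0-based).
#' @export
render_heatmap <- function(bag, attn, slide_shape) {
  stopifnot(inherits(bag, "patch_bag"))
  w <- attn$weights
  if (length(w) != length(bag$patches)) {
    stop("attention length does not match bag size")
  }
  rng <- range(w)
  sw <- if (rng[2] > rng[1]) (w - rng[1]) / (rng[2] - rng[1]) else
    rep(1, length(w))
  ps <- dim(bag$patches[[1]]$image)[1]
  canvas <- matrix(0, slide_shape[1], slide_shape[2])
  for (i in seq_along(bag$patches)) {
    p <- bag$patches[[i]]
    rr <- p$pixel_origin[1] + seq_len(ps)
    cc <- p$pixel_origin[2] + seq_len(ps)
    canvas[rr, cc] <- sw[i]
  }
  ri <- vapply(bag$patches, function(p) p$row_index, integer(1))
  ci <- vapply(bag$patches, function(p) p$col_index, integer(1))
  ord <- order(-w, ri, ci)
  top <- c(ri[ord[1]], ci[ord[1]])
  list(heatmap = canvas, top_patch = top)
}
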