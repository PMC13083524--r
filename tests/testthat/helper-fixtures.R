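# Shared in-code fixtures. Everything is generated at test time; nothing is
# stored on disk.

micro_cohort_config <- function(seed = 7L, n_per_class = 3L) {
  synthetic_cohort_config(
    n_patients_per_class = n_per_class,
    slide_height = 256L, slide_width = 256L,
    patch_size = 64L,
    n_genes = 150L, n_gene_sets = 5L, set_size_range = c(5L, 10L),
    seed = seed
  )
}

# a tiny trained-free model + backbone + data stack for contract tests
micro_stack <- function(seed = 7L, d = 16L, n_per_class = 3L) {
  cfg <- micro_cohort_config(seed, n_per_class)
  co <- simulate_cohort(cfg)
  bags <- build_patch_bags(co$slides, co$labels, patch_size = 64L,
                           max_budget = 4L, seed = seed)
  gb <- suppressWarnings(gene_branch(co$counts, co$gene_lengths, co$gene_sets,
                                     latent_dim = d, epochs = 15L,
                                     seed = seed))
  backbone <- build_backbone(tiny_backbone_spec(d, 64L), seed = seed)
  model <- mil_model(mil_config(d, 2L, 8L), seed = seed)
  list(cohort = co, bags = bags$bags, budget = bags$budget,
       genes = gb, backbone = backbone, model = model)
}

# hand-built scored patches for filtering/selection tests
fake_patch <- function(tissue_fraction, row = 0L, col = 0L, pid = "A",
                       fill = 120) {
  p <- structure(list(
    patient_id = pid, row_index = as.integer(row), col_index = as.integer(col),
    pixel_origin = c(row * 4L, col * 4L),
    image = array(fill, dim = c(4L, 4L, 3L)),
    tissue_fraction = tissue_fraction
  ), class = "patch")
  p
}

# exhaustive Otsu oracle: brute-force search over all 256 thresholds
otsu_bruteforce <- function(slide) {
  g <- if (length(dim(slide)) == 3L) {
    (slide[, , 1] + slide[, , 2] + slide[, , 3]) / 3
  } else slide
  g <- pmin(pmax(round(g), 0), 255)
  best_t <- NA
  best_v <- -Inf
  for (t in 1:255) {
    lo <- g[g < t]; hi <- g[g >= t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(g)
    v <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-12) {
      best_v <- v
      best_t <- t
    }
  }
  best_t
}

# O(n^2) concordant-pair ROC-AUC oracle
roc_auc_pairs <- function(y, s, positive = 1L) {
  ps <- s[y == positive]
  ns <- s[y != positive]
  tot <- 0
  for (a in ps) for (b in ns) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(ps) * length(ns))
}
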