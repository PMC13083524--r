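#' Synthetic multimodal cohort configuration
#'
#' Defines the seeded generator used throughout the test suite: slides are
#' white-background images with dark elliptical tissue blobs (emulating the
#' appearance assumed by Otsu-based tissue detection), a seeded fraction of
#' patch-sized tissue regions carries a class-dependent spot texture, and
#' expression is negative-binomial counts in which designated gene sets are
#' mean-shifted between classes. Identical configuration and seed give
#' byte-identical outputs.
#'
#' @param n_patients_per_class patients per class (cohort size is twice
#'   this).
#' @param slide_height,slide_width slide dimensions in pixels.
#' @param tissue_blob_count number of elliptical tissue blobs per slide.
#' @param tissue_coverage target fraction of slide area covered by tissue.
#' @param patch_size side of the patch-sized texture regions (and of the
#'   tiles used downstream).
#' @param signal_patch_fraction fraction of fully-tissue patch cells that
#'   carry the class texture (0 disables any class signal in images).
#' @param n_genes,n_gene_sets expression panel dimensions.
#' @param set_size_range integer pair, inclusive bounds on gene-set sizes.
#' @param de_set_fraction fraction of gene sets shifted between classes.
#' @param log_fold_change log2 mean shift of member genes in class 1.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param seed master seed; per-patient draws derive from it.
#' @return A `cohort_config` list.
#' @export
synthetic_cohort_config <- function(n_patients_per_class = 40L,
                                    slide_height = 512L,
                                    slide_width = 512L,
                                    tissue_blob_count = 3L,
                                    tissue_coverage = 0.5,
                                    patch_size = 64L,
                                    signal_patch_fraction = 0.6,
                                    n_genes = 400L,
                                    n_gene_sets = 10L,
                                    set_size_range = c(10L, 30L),
                                    de_set_fraction = 0.3,
                                    log_fold_change = 1,
                                    nb_dispersion = 0.1,
                                    seed = 1L) {
  cfg <- list(
    n_patients_per_class = as.integer(n_patients_per_class),
    slide_height = as.integer(slide_height),
    slide_width = as.integer(slide_width),
    tissue_blob_count = as.integer(tissue_blob_count),
    tissue_coverage = tissue_coverage,
    patch_size = as.integer(patch_size),
    signal_patch_fraction = signal_patch_fraction,
    n_genes = as.integer(n_genes),
    n_gene_sets = as.integer(n_gene_sets),
    set_size_range = as.integer(set_size_range),
    de_set_fraction = de_set_fraction,
    log_fold_change = log_fold_change,
    nb_dispersion = nb_dispersion,
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(n_patients_per_class > 0, slide_height > 0, slide_width > 0,
              tissue_blob_count > 0, n_genes > 0, n_gene_sets > 0,
              length(set_size_range) == 2, set_size_range[1] >= 1,
              set_size_range[1] <= set_size_range[2],
              nb_dispersion > 0)
    stopifnot(signal_patch_fraction >= 0, signal_patch_fraction <= 1,
              de_set_fraction >= 0, de_set_fraction <= 1,
              tissue_coverage > 0, tissue_coverage < 1)
  })
  if (cfg$slide_height < 2L * cfg$patch_size ||
      cfg$slide_width < 2L * cfg$patch_size) {
    stop("slide dimensions must be at least twice the patch size")
  }
  structure(cfg, class = "cohort_config")
}

# deterministic small-integer mixing of sub-stream seeds (kept below 2^31)
seed_mix <- function(...) {
  v <- c(...)
  s <- 0
  for (x in v) s <- (s * 69069 + (x %% 2147483647) + 1) %% 2147483629
  as.integer(s)
}

# fixed intensity design: background near 245, tissue near 120, nuclear-like
# spots near 60; all dark-side, so Otsu separates tissue from glass.
.bg_level <- 245
.tissue_level <- 120
.spot_level <- 60

#' Generate one synthetic slide
#'
#' White background with dark elliptical tissue blobs; the blob mask is cut
#' at the field quantile matching `tissue_coverage`, so the covered area
#' tracks the configured target. Within fully-tissue patch cells, a seeded
#' fraction carries the class texture: dark spots whose per-patch frequency
#' depends on the class label (sparser for class 0, denser for class 1).
#'
#' @param config a [synthetic_cohort_config()].
#' @param class_label 0 or 1.
#' @param patient_seed integer; output is a pure function of
#'   `(config, class_label, patient_seed)`.
#' @return `(height, width, 3)` numeric array with values in `0..255`.
#' @export
make_slide <- function(config, class_label, patient_seed) {
  stopifnot(inherits(config, "cohort_config"), class_label %in% c(0L, 1L))
  H <- config$slide_height; W <- config$slide_width
  ps <- config$patch_size
  with_seed(seed_mix(config$seed, 104729, patient_seed, class_label), {
    img <- matrix(stats::rnorm(H * W, mean = .bg_level, sd = 2), H, W)
    # union-of-ellipses field; threshold at the coverage quantile
    # blob centers stay in the central window so the union (cut at the
    # coverage quantile) is a compact region: every slide then contains
    # whole grid-aligned tissue tiles for the downstream validity filter
    nb <- config$tissue_blob_count
    cx <- stats::runif(nb, 0.35 * H, 0.65 * H)
    cy <- stats::runif(nb, 0.35 * W, 0.65 * W)
    r0 <- sqrt(config$tissue_coverage * H * W / (pi * nb))
    ax <- r0 * stats::runif(nb, 0.9, 1.15)
    ay <- r0 * stats::runif(nb, 0.9, 1.15)
    xs <- matrix(seq_len(H), H, W)
    ys <- matrix(seq_len(W), H, W, byrow = TRUE)
    field <- matrix(Inf, H, W)
    for (b in seq_len(nb)) {
      field <- pmin(field, ((xs - cx[b]) / ax[b])^2 + ((ys - cy[b]) / ay[b])^2)
    }
    mask <- field <= stats::quantile(field, config$tissue_coverage)
    img[mask] <- stats::rnorm(sum(mask), mean = .tissue_level, sd = 8)
    # class texture on a seeded fraction of fully-tissue patch cells
    nrow_t <- H %/% ps; ncol_t <- W %/% ps
    cells <- expand.grid(r = seq_len(nrow_t), c = seq_len(ncol_t))
    full <- vapply(seq_len(nrow(cells)), function(i) {
      rr <- (cells$r[i] - 1L) * ps + seq_len(ps)
      cc <- (cells$c[i] - 1L) * ps + seq_len(ps)
      mean(mask[rr, cc]) >= 0.95
    }, logical(1))
    cand <- which(full)
    n_sig <- round(config$signal_patch_fraction * length(cand))
    sig <- if (n_sig > 0) sample(cand, n_sig) else integer(0)
    n_spots <- if (class_label == 0L) 5L else 15L
    for (i in sig) {
      r0i <- (cells$r[i] - 1L) * ps
      c0i <- (cells$c[i] - 1L) * ps
      for (s in seq_len(n_spots)) {
        sr <- r0i + sample.int(ps - 6L, 1L) + 3L
        sc <- c0i + sample.int(ps - 6L, 1L) + 3L
        rad <- 2L
        rr <- (sr - rad):(sr + rad)
        cc <- (sc - rad):(sc + rad)
        disc <- outer(rr - sr, cc - sc, function(a, b) a^2 + b^2) <= rad^2
        blockv <- img[rr, cc]
        blockv[disc] <- stats::rnorm(sum(disc), mean = .spot_level, sd = 5)
        img[rr, cc] <- blockv
      }
    }
    img <- pmin(pmax(round(img), 0), 255)
    array(img, dim = c(H, W, 3L))
  })
}

#' Generate the synthetic expression side of a cohort
#'
#' Negative-binomial counts with log-normal gene base means; genes that are
#' members of the designated differentially expressed (DE) sets have their
#' mean multiplied by `2^log_fold_change` in class-1 patients. Gene sets
#' are disjoint. The emitted adjusted-p table marks DE sets with small
#' values and the rest with large ones (it encodes the known assignment;
#' upstream DE testing is out of scope for the generator).
#'
#' @param config a [synthetic_cohort_config()].
#' @param labels integer vector of 0/1, one per patient; length must equal
#'   `2 * n_patients_per_class`.
#' @return List with `counts` (genes x patients integer matrix),
#'   `gene_lengths` (named vector, bp), `gene_sets` (list of
#'   [gene_set_definition()]), `padj` (data.frame `set_id`, `padj`), and
#'   `de_sets` (character, ground truth).
#' @export
make_expression <- function(config, labels) {
  stopifnot(inherits(config, "cohort_config"))
  n_pat <- 2L * config$n_patients_per_class
  if (length(labels) != n_pat) {
    stop(sprintf("labels must have length %d (2 x n_patients_per_class)",
                 n_pat))
  }
  stopifnot(all(labels %in% c(0L, 1L)))
  if (config$set_size_range[1] * config$n_gene_sets > config$n_genes) {
    stop("gene-set sizes exceed the number of available genes")
  }
  with_seed(seed_mix(config$seed, 15485863), {
    genes <- sprintf("g%04d", seq_len(config$n_genes))
    patients <- sprintf("P%03d", seq_len(n_pat))
    lengths_bp <- stats::setNames(
      round(stats::runif(config$n_genes, 500, 5000)), genes)
    base_mean <- stats::setNames(
      stats::rlnorm(config$n_genes, meanlog = log(50), sdlog = 1), genes)
    sizes <- sample(seq(config$set_size_range[1], config$set_size_range[2]),
                    config$n_gene_sets, replace = TRUE)
    if (sum(sizes) > config$n_genes) {
      stop("gene-set sizes exceed the number of available genes")
    }
    pool <- sample(genes, sum(sizes))
    stops <- cumsum(sizes)
    starts <- c(1L, utils::head(stops, -1L) + 1L)
    set_ids <- sprintf("SET%03d", seq_len(config$n_gene_sets))
    n_de <- round(config$de_set_fraction * config$n_gene_sets)
    de_idx <- if (n_de > 0) sort(sample.int(config$n_gene_sets, n_de)) else integer(0)
    padj_vals <- stats::runif(config$n_gene_sets, 0.1, 0.9)
    padj_vals[de_idx] <- 10^(-stats::runif(length(de_idx), 3, 6))
    gene_sets <- lapply(seq_len(config$n_gene_sets), function(i) {
      gene_set_definition(set_ids[i], pool[starts[i]:stops[i]],
                          padj = padj_vals[i], source = "synthetic")
    })
    de_genes <- unlist(lapply(de_idx, function(i) pool[starts[i]:stops[i]]))
    lfc_mult <- rep(1, config$n_genes)
    lfc_mult[match(de_genes, genes)] <- 2^config$log_fold_change
    counts <- matrix(0L, config$n_genes, n_pat,
                     dimnames = list(genes, patients))
    size_nb <- 1 / config$nb_dispersion
    for (j in seq_len(n_pat)) {
      mu <- base_mean * if (labels[j] == 1L) lfc_mult else 1
      counts[, j] <- stats::rnbinom(config$n_genes, mu = mu, size = size_nb)
    }
    storage.mode(counts) <- "integer"
    list(counts = counts, gene_lengths = lengths_bp, gene_sets = gene_sets,
         padj = data.frame(set_id = set_ids, padj = padj_vals,
                           stringsAsFactors = FALSE),
         de_sets = set_ids[de_idx])
  })
}

#' Generate and optionally write a full synthetic cohort
#'
#' Produces slides, labels and the expression side for a balanced cohort
#' (`n_patients_per_class` per class, class-0 patients first), and when
#' `dir` is given writes them in the plain-text exchange formats consumed
#' by the pipeline: one PNG per slide, counts TSV (gene rows, patient
#' columns), two-column gene-length TSV, GMT gene sets, labels CSV and
#' per-set adjusted-p CSV.
#'
#' @param config a [synthetic_cohort_config()].
#' @param dir output directory, or NULL to keep everything in memory.
#' @return A `cohort` list: `config`, `patients`, `labels` (named 0/1
#'   vector), `slides` (list of arrays), and the [make_expression()]
#'   fields.
#' @export
simulate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  n_pat <- 2L * config$n_patients_per_class
  patients <- sprintf("P%03d", seq_len(n_pat))
  labels <- stats::setNames(
    rep(c(0L, 1L), each = config$n_patients_per_class), patients)
  slides <- lapply(seq_len(n_pat), function(i) {
    make_slide(config, labels[i], patient_seed = i)
  })
  names(slides) <- patients
  expr <- make_expression(config, unname(labels))
  cohort <- c(list(config = config, patients = patients, labels = labels,
                   slides = slides), expr)
  class(cohort) <- "cohort"
  if (!is.null(dir)) {
    dir.create(file.path(dir, "slides"), recursive = TRUE,
               showWarnings = FALSE)
    for (p in patients) {
      png::writePNG(slides[[p]] / 255, file.path(dir, "slides",
                                                 paste0(p, ".png")))
    }
    utils::write.table(
      data.frame(gene_id = rownames(expr$counts), expr$counts,
                 check.names = FALSE),
      file.path(dir, "counts.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(gene_id = names(expr$gene_lengths),
                 length_bp = as.integer(expr$gene_lengths)),
      file.path(dir, "gene_lengths.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    write_gmt(expr$gene_sets, file.path(dir, "gene_sets.gmt"))
    utils::write.csv(
      data.frame(patient_id = patients, label = unname(labels)),
      file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE)
    utils::write.csv(expr$padj, file.path(dir, "set_padj.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(
      data.frame(set_id = expr$de_sets),
      file.path(dir, "de_sets_truth.csv"), row.names = FALSE, quote = FALSE)
  }
  cohort
}

#' Synthetic per-patient gene-set attention table
#'
#' Draws each patient's attention row from a Dirichlet distribution
#' (normalized gamma draws). In class-1 patients the total attention mass
#' of the designated sets is *redistributed among those sets* with a
#' skewed split (weights `(1 + effect)^0, (1 + effect)^1, ...`), while
#' class 0 splits the same mass evenly. Because only the within-group
#' split changes, every designated set's distribution differs between
#' classes, yet non-designated sets keep exactly the same distribution in
#' both classes — a clean ground truth for the significance stage, with
#' no spill-over from row renormalization. At least two shifted sets are
#' needed for a redistribution to exist.
#'
#' @param n_per_class patients per class.
#' @param n_sets number of gene sets (columns).
#' @param shifted_sets integer indices of sets with a class effect.
#' @param effect skew strength; 0 means no signal anywhere.
#' @param seed integer.
#' @param concentration baseline Dirichlet concentration per set.
#' @return An `attention_table` (see [collect_attention()]).
#' @export
make_attention_table <- function(n_per_class, n_sets, shifted_sets = integer(0),
                                 effect = 0, seed = 1L, concentration = 20) {
  stopifnot(n_per_class > 0, n_sets > 0, effect >= 0)
  k <- length(shifted_sets)
  if (k == 1L && effect > 0) {
    stop("need at least two shifted sets to redistribute attention mass")
  }
  with_seed(seed_mix(seed, 32452843), {
    n <- 2L * n_per_class
    labels <- rep(c(0L, 1L), each = n_per_class)
    g <- matrix(stats::rgamma(n * n_sets, shape = concentration, rate = 1),
                n, n_sets)
    w <- g / rowSums(g)
    if (k >= 2L && effect > 0) {
      skew <- (1 + effect)^(seq_len(k) - 1L)
      for (i in which(labels == 1L)) {
        mass <- sum(w[i, shifted_sets])
        split <- stats::rgamma(k, shape = concentration * skew / mean(skew),
                               rate = 1)
        w[i, shifted_sets] <- mass * split / sum(split)
      }
    }
    dimnames(w) <- list(sprintf("P%03d", seq_len(n)),
                        sprintf("SET%03d", seq_len(n_sets)))
    attention_table(w, stats::setNames(labels, rownames(w)),
                    mechanism = "self_gene")
  })
}
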