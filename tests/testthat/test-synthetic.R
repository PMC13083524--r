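test_that("slide generation is deterministic and respects the coverage target", {
  cfg <- micro_cohort_config(seed = 3L)
  s1 <- make_slide(cfg, 1L, patient_seed = 5L)
  s2 <- make_slide(cfg, 1L, patient_seed = 5L)
  expect_identical(s1, s2)
  expect_false(identical(s1, make_slide(cfg, 1L, patient_seed = 6L)))

  # dark-pixel (tissue + spots) area should track the configured coverage
  cov <- vapply(1:10, function(i) {
    sl <- make_slide(cfg, i %% 2L, patient_seed = i)
    mean(sl[, , 1] < 180)
  }, numeric(1))
  expect_gt(mean(cov), 0.5 * 0.8)
  expect_lt(mean(cov), 0.5 * 1.2)
})

test_that("zero signal fraction gives class-symmetric image ensembles", {
  cfg0 <- synthetic_cohort_config(n_patients_per_class = 3L,
                                  slide_height = 192L, slide_width = 192L,
                                  patch_size = 64L,
                                  signal_patch_fraction = 0,
                                  n_genes = 50L, n_gene_sets = 2L,
                                  set_size_range = c(5L, 8L), seed = 9L)
  m0 <- mean(vapply(1:20, function(i)
    mean(make_slide(cfg0, 0L, patient_seed = i)), numeric(1)))
  m1 <- mean(vapply(1:20, function(i)
    mean(make_slide(cfg0, 1L, patient_seed = 1000L + i)), numeric(1)))
  expect_lt(abs(m0 - m1), 2)  # same distribution up to sampling noise
})

test_that("slides too small for a patch are rejected at configuration", {
  expect_error(synthetic_cohort_config(slide_height = 100L,
                                       slide_width = 100L,
                                       patch_size = 64L),
               "twice the patch size")
})

test_that("expression counts are deterministic with NB class shift on DE sets", {
  cfg <- synthetic_cohort_config(n_patients_per_class = 100L,
                                 slide_height = 128L, slide_width = 128L,
                                 patch_size = 64L,
                                 n_genes = 300L, n_gene_sets = 8L,
                                 set_size_range = c(10L, 20L),
                                 de_set_fraction = 0.25,
                                 log_fold_change = 1, nb_dispersion = 0.1,
                                 seed = 21L)
  labels <- rep(c(0L, 1L), each = 100L)
  e1 <- make_expression(cfg, labels)
  e2 <- make_expression(cfg, labels)
  expect_identical(e1$counts, e2$counts)

  # NB mean model: class-1/class-0 empirical mean ratio near 2^lfc = 2
  de_genes <- unlist(lapply(e1$gene_sets, function(s) {
    if (s$set_id %in% e1$de_sets) s$member_genes else NULL
  }))
  m0 <- rowMeans(e1$counts[de_genes, labels == 0L])
  m1 <- rowMeans(e1$counts[de_genes, labels == 1L])
  ratio <- mean(m1 / m0)
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.6)
})

test_that("zero log-fold-change yields no systematic class differences", {
  cfg <- synthetic_cohort_config(n_patients_per_class = 100L,
                                 slide_height = 128L, slide_width = 128L,
                                 patch_size = 64L,
                                 n_genes = 400L, n_gene_sets = 5L,
                                 set_size_range = c(8L, 15L),
                                 log_fold_change = 0, seed = 33L)
  labels <- rep(c(0L, 1L), each = 100L)
  e <- make_expression(cfg, labels)
  pvals <- apply(e$counts, 1L, function(x) {
    stats::t.test(x[labels == 0L], x[labels == 1L])$p.value
  })
  # null calibration: ~5% of genes reach p < 0.05 by chance (binomial sd
  # ~1% at 400 genes), so allow that sampling slack
  expect_gte(mean(pvals > 0.05), 0.92)
})

test_that("oversized gene sets are rejected", {
  expect_error(
    make_expression(
      synthetic_cohort_config(n_patients_per_class = 2L,
                              slide_height = 128L, slide_width = 128L,
                              patch_size = 64L,
                              n_genes = 20L, n_gene_sets = 5L,
                              set_size_range = c(10L, 10L), seed = 1L),
      rep(c(0L, 1L), each = 2L)),
    "exceed")
})

test_that("cohorts are balanced and files round-trip exactly", {
  cfg <- micro_cohort_config(seed = 12L)
  dir <- withr::local_tempdir()
  co <- simulate_cohort(cfg, dir = dir)
  expect_equal(sum(co$labels == 0L), cfg$n_patients_per_class)
  expect_equal(sum(co$labels == 1L), cfg$n_patients_per_class)

  sets2 <- read_gmt(file.path(dir, "gene_sets.gmt"),
                    padj = utils::read.csv(file.path(dir, "set_padj.csv")))
  expect_equal(vapply(sets2, function(s) s$set_id, character(1)),
               vapply(co$gene_sets, function(s) s$set_id, character(1)))
  expect_equal(lapply(sets2, function(s) s$member_genes),
               lapply(co$gene_sets, function(s) s$member_genes))
  expect_equal(vapply(sets2, function(s) s$padj, numeric(1)),
               vapply(co$gene_sets, function(s) s$padj, numeric(1)))

  cts <- utils::read.delim(file.path(dir, "counts.tsv"), row.names = 1,
                           check.names = FALSE)
  expect_identical(as.matrix(cts), co$counts)

  # re-read slide PNG equals the in-memory slide
  s <- png::readPNG(file.path(dir, "slides", "P001.png")) * 255
  expect_equal(round(s[, , 1]), co$slides[["P001"]][, , 1])

  co2 <- simulate_cohort(cfg)
  expect_identical(co2$counts, co$counts)
  expect_identical(co2$slides[["P002"]], co$slides[["P002"]])
})
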